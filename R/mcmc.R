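# Affine-invariant ensemble (stretch-move) sampler, used to draw posterior
# samples for the robust per-cell uncertainty estimate 1.4826 * mad(draws).

stretch_sampler <- function(log_post, init, n_walkers = 24, n_steps = 400,
                            burn = 200, a = 2, init_spread = 0.05) {
  d <- length(init)
  n_walkers <- max(n_walkers, 2 * d + 2)
  walkers <- matrix(rep(init, n_walkers), nrow = n_walkers, byrow = TRUE) +
    matrix(rnorm(n_walkers * d, sd = init_spread), n_walkers, d)
  lp <- apply(walkers, 1, log_post)
  bad <- !is.finite(lp)
  for (i in which(bad)) {  # re-draw invalid starters near the MAP
    for (try in 1:20) {
      walkers[i, ] <- init + rnorm(d, sd = init_spread / 4)
      lp[i] <- log_post(walkers[i, ])
      if (is.finite(lp[i])) break
    }
  }
  keep <- vector("list", n_steps)
  for (step in seq_len(n_steps + burn)) {
    half <- sample.int(n_walkers)
    for (i in seq_len(n_walkers)) {
      j <- half[i]
      if (j == i) j <- half[(i %% n_walkers) + 1]
      z <- (1 + (a - 1) * runif(1))^2 / a
      prop <- walkers[j, ] + z * (walkers[i, ] - walkers[j, ])
      lp_prop <- log_post(prop)
      log_accept <- (d - 1) * log(z) + lp_prop - lp[i]
      if (is.finite(lp_prop) && log(runif(1)) < log_accept) {
        walkers[i, ] <- prop
        lp[i] <- lp_prop
      }
    }
    if (step > burn) keep[[step - burn]] <- walkers
  }
  do.call(rbind, keep)
}

# robust posterior spread: 1.4826 * mad of MCMC draws (columnwise)
robust_spread <- function(draws) {
  apply(draws, 2, function(x) mad(x, constant = 1.4826))
}
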