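# Shared fixtures and independent oracles.

med <- chemolimit::median_params(1)

# Independent brute-force check of the stationary filter: Euler-discretized
# covariance recursion on a fine grid, written directly from the channel
# fields (de-correlated by the textbook substitution), in the channel's
# scaled coordinates. Returns the stationary posterior variance of s.
discrete_filter_oracle <- function(channel, dt, max_iter = 500000) {
  n <- nrow(channel$drift)
  sc <- if (is.null(channel$scale)) rep(1, n) else channel$scale
  Di <- diag(1 / sc, n); Ds <- diag(sc, n)
  A <- Di %*% channel$drift %*% Ds
  Q <- Di %*% channel$process_noise %*% Di
  H <- matrix(channel$obs_map, nrow = 1) %*% Ds
  R <- channel$obs_noise
  S <- Di %*% matrix(channel$cross_noise, ncol = 1)
  At <- A - (S / R) %*% H
  Qt <- Q - (S %*% t(S)) / R
  Ad <- diag(n) + At * dt
  Qd <- Qt * dt
  Rd <- R / dt
  si <- match("s", channel$state_labels)
  P <- diag(n)
  Pss <- NA_real_
  for (i in seq_len(max_iter)) {
    Sk <- (H %*% P %*% t(H))[1] + Rd
    K <- (P %*% t(H)) / Sk
    Pu <- P - K %*% H %*% P
    Pn <- Ad %*% Pu %*% t(Ad) + Qd
    if (i %% 1000 == 0 && max(abs(Pn - P)) < 1e-15 * max(abs(Pn))) {
      Pss <- Pu[si, si]
      P <- Pn
      break
    }
    P <- Pn
    if (i == max_iter) {
      Sk <- (H %*% P %*% t(H))[1] + Rd
      K <- (P %*% t(H)) / Sk
      Pss <- (P - K %*% H %*% P)[si, si]
    }
  }
  Pss * sc[si]^2
}

# exact-model observation series for both channels from one OU signal draw:
# s is an exact-discretization OU process, L its Euler integral; arrivals
# are Poisson counts at rate kD * c0 * exp(L); kinase activity responds to
# the same counts. Returns everything needed for empirical rho^2 checks.
simulate_channel_data <- function(swim, kin, constants, duration, dt, seed) {
  set.seed(seed)
  n <- floor(duration / dt)
  tau_v <- swim$tau_v
  ss <- sqrt(chemolimit:::signal_variance(swim))
  phi <- exp(-dt / tau_v)
  s <- numeric(n)
  s[1] <- ss * rnorm(1)
  innov <- ss * sqrt(1 - phi^2) * rnorm(n)
  for (k in 2:n) s[k] <- phi * s[k - 1] + innov[k]
  L <- cumsum(s) * dt
  c_of_t <- swim$c0 * exp(L)
  arr <- chemolimit::simulate_arrivals(c_of_t, constants, dt)
  act <- chemolimit::simulate_kinase(arr, kin, constants,
                                     r0 = constants$kD * swim$c0, clip = FALSE)
  list(s = s, arr = arr, act = act, dt = dt)
}
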