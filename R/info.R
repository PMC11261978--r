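# Posterior variances and behaviorally-relevant information rates.

#' Stationary posterior of the signal given a channel's past
#'
#' Solves the stationary filtering Riccati equation of the channel
#' (including the correlated process/observation noise term) and extracts
#' the posterior variance of the signal state s given the infinite
#' observation past. The squared correlation between the signal and its
#' optimal causal estimate is rho2 = 1 - P_ss / sigma_s^2.
#'
#' @param channel [linear_channel]
#' @return object of class `posterior_summary` with fields `P_ss`, `rho2`,
#'   `sigma_s2`, `tau_v`, `P` (full posterior covariance), `rel_resid`
#' @export
stationary_posterior <- function(channel) {
  stopifnot(inherits(channel, "linear_channel"))
  if (channel$signal_var == 0) {
    # no gradient: prior and posterior of s are both degenerate at 0
    out <- list(P_ss = 0, rho2 = 0, sigma_s2 = 0, tau_v = channel$tau_v,
                P = NULL, rel_resid = 0)
    class(out) <- "posterior_summary"
    return(out)
  }
  sol <- care_stationary(channel$drift, channel$process_noise,
                         channel$obs_map, channel$obs_noise,
                         channel$cross_noise, channel$scale)
  si <- match("s", channel$state_labels)
  P_ss <- sol$P[si, si]
  P_ss <- min(max(P_ss, 0), channel$signal_var)
  rho2 <- 1 - P_ss / channel$signal_var
  out <- list(P_ss = P_ss, rho2 = rho2, sigma_s2 = channel$signal_var,
              tau_v = channel$tau_v, P = sol$P, rel_resid = sol$rel_resid)
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Stationary posterior: P_ss = %.4g, rho2 = %.4g\n",
              x$P_ss, x$rho2))
  invisible(x)
}

#' Predictive information rate from a stationary posterior
#'
#' For the Gaussian OU signal, the mutual information between the signal a
#' lag tau ahead and the observation past is
#' I(tau) = -(1/2) log(sigma^2(tau) / sigma_s^2) with
#' sigma^2(tau) = sigma_s^2 - (sigma_s^2 - P_ss) exp(-2 tau / tau_v).
#' Its negative derivative at tau = 0 gives the information rate
#' (1 / tau_v) * rho2 / (1 - rho2), which reduces to rho2 / tau_v for
#' small rho2.
#'
#' @param summary [stationary_posterior()] output
#' @param tau_v signal correlation time (s); defaults to the channel's
#' @param bits report bits/s instead of nats/s
#' @return information rate (nats/s, or bits/s if `bits`)
#' @export
predictive_info_rate <- function(summary, tau_v = summary$tau_v, bits = FALSE) {
  stopifnot(inherits(summary, "posterior_summary"))
  rho2 <- summary$rho2
  if (rho2 >= 1) stop("rho2 = 1 is impossible for a noisy channel")
  out <- rho2 / (1 - rho2) / tau_v
  if (bits) out / log(2) else out
}

#' Lagged predictive information of a channel posterior
#'
#' I(tau) = -(1/2) log(sigma^2(tau) / sigma_s^2) for forecasting lags
#' tau >= 0; exposed so that the rate can be checked by finite
#' differencing.
#'
#' @param summary [stationary_posterior()] output
#' @param tau forecasting lags (s)
#' @return mutual information (nats)
#' @export
predictive_info_lagged <- function(summary, tau) {
  stopifnot(inherits(summary, "posterior_summary"), all(tau >= 0))
  if (summary$sigma_s2 == 0) return(rep(0, length(tau)))
  v <- summary$sigma_s2 - (summary$sigma_s2 - summary$P_ss) * exp(-2 * tau / summary$tau_v)
  -0.5 * log(v / summary$sigma_s2)
}

#' Information rates of the arrival and kinase channels
#'
#' Builds both observation channels at a common parameter set, solves the
#' stationary filters, and reports the two behaviorally-relevant
#' information rates, their ratio eta (which obeys the data processing
#' inequality 0 <= eta <= 1), the dimensionless SNRs, and the posterior
#' summaries.
#'
#' @param swim [swim_params] (must have g > 0 for finite rates)
#' @param kin [kinase_params]
#' @param constants [physical_constants]
#' @param bits report rates in bits/s
#' @return object of class `info_summary` with fields `I_r`, `I_a`, `eta`,
#'   `gamma_r`, `gamma_a`, `rho2_rs`, `rho2_as`, `r0`, `posterior_r`,
#'   `posterior_a`
#' @export
info_rates <- function(swim, kin, constants, bits = FALSE) {
  ch_r <- build_arrival_channel(swim, constants)
  post_r <- stationary_posterior(ch_r)
  if (kin$G_r == 0) {
    # zero gain: the kinase observation is pure internal noise
    post_a <- structure(list(P_ss = signal_variance(swim), rho2 = 0,
                             sigma_s2 = signal_variance(swim),
                             tau_v = swim$tau_v, P = NULL, rel_resid = 0),
                        class = "posterior_summary")
  } else {
    ch_a <- build_kinase_channel(swim, kin, constants,
                                 allow_zero_noise = kin$D_n == 0)
    post_a <- stationary_posterior(ch_a)
  }
  I_r <- predictive_info_rate(post_r, bits = bits)
  I_a <- predictive_info_rate(post_a, bits = bits)
  eta <- if (I_r == 0) NA_real_ else I_a / I_r
  if (!is.na(eta) && eta > 1 + 1e-9) {
    stop(sprintf("data processing inequality violated: eta = %.6g", eta))
  }
  out <- list(I_r = I_r, I_a = I_a, eta = eta,
              gamma_r = gamma_r(swim, constants),
              gamma_a = gamma_a(swim, kin, constants),
              rho2_rs = post_r$rho2, rho2_as = post_a$rho2,
              r0 = constants$kD * swim$c0,
              posterior_r = post_r, posterior_a = post_a,
              units = if (bits) "bits/s" else "nats/s")
  class(out) <- "info_summary"
  out
}

#' @export
print.info_summary <- function(x, ...) {
  cat("Behaviorally-relevant information rates\n")
  cat(sprintf("  physical limit  I_r = %.4g %s (gamma_r = %.3g)\n",
              x$I_r, x$units, x$gamma_r))
  cat(sprintf("  kinase activity I_a = %.4g %s (gamma_a = %.3g)\n",
              x$I_a, x$units, x$gamma_a))
  cat(sprintf("  eta = I_a / I_r = %.4g\n", x$eta))
  invisible(x)
}

#' Ratio of the kinase information rate to the physical limit
#'
#' eta = I_a / I_r computed with the stationary-filter engine. In
#' vanishingly small gradients both rates scale as g^2, so eta reaches a
#' g-independent plateau; `eta(..., g0 = TRUE)` evaluates on that plateau
#' (g = 1e-4 per mm) and asserts convergence against a 10x smaller g.
#'
#' @param swim [swim_params]
#' @param kin [kinase_params]
#' @param constants [physical_constants]
#' @param g0 evaluate the vanishing-gradient plateau instead of `swim$g`
#' @param g0_tol relative convergence tolerance for the plateau check
#' @return eta (dimensionless, in \[0, 1\])
#' @export
eta <- function(swim, kin, constants, g0 = FALSE, g0_tol = 0.01) {
  if (g0) {
    s1 <- swim; s1$g <- 1e-4
    s2 <- swim; s2$g <- 1e-5
    e1 <- info_rates(s1, kin, constants)$eta
    e2 <- info_rates(s2, kin, constants)$eta
    if (abs(e1 / e2 - 1) > g0_tol) {
      warning(sprintf("eta plateau not converged: %.4g at g=1e-4 vs %.4g at g=1e-5",
                      e1, e2))
    }
    return(e1)
  }
  if (swim$g <= 0) stop("eta at finite g requires g > 0; use g0 = TRUE for the plateau")
  info_rates(swim, kin, constants)$eta
}

#' First-order uncertainty propagation
#'
#' Variance of a scalar function of independently-uncertain parameters:
#' sigma_f^2 = sum_i (df/dtheta_i)^2 sigma_i^2, with gradients from
#' central finite differences (relative step `rel_step`). Correlations
#' between parameter uncertainties are neglected.
#'
#' @param f function mapping a named numeric vector to a scalar
#' @param theta parameter values (named numeric vector)
#' @param sigma_theta standard errors, same length/order as `theta`
#' @param rel_step relative finite-difference step
#' @return variance of f (the squared standard error)
#' @export
error_propagation <- function(f, theta, sigma_theta, rel_step = 1e-5) {
  stopifnot(length(theta) == length(sigma_theta))
  f0 <- f(theta)
  if (!is.finite(f0)) stop("f is not finite at theta")
  grad <- vapply(seq_along(theta), function(i) {
    h <- rel_step * max(abs(theta[i]), rel_step)
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    fp <- f(tp); fm <- f(tm)
    if (!is.finite(fp) || !is.finite(fm)) {
      stop("f is not finite near theta (parameter ", i, ")")
    }
    (fp - fm) / (2 * h)
  }, numeric(1))
  sum(grad^2 * sigma_theta^2)
}
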