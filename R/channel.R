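# Continuous-time linear-Gaussian observation channels for the
# run-and-tumble signal. Both channels share the latent signal state
# s (OU with variance g^2 sigma_v^2 and correlation time tau_v); they
# differ in what is observed and in the noise that enters.

#' Linear-Gaussian observation channel
#'
#' State-space container: latent drift matrix (1/s), process-noise PSD
#' matrix, a scalar observation row, white observation-noise intensity and
#' the (column) cross-covariance intensity between process and observation
#' noise. State `"s"` must be among the labels; its stationary prior
#' variance must equal the declared `signal_var`.
#'
#' @param drift square drift matrix (1/s)
#' @param process_noise PSD matrix of the latent driving noise (symmetric,
#'   positive semidefinite)
#' @param obs_map numeric row mapping states to the scalar observation
#' @param obs_noise white observation-noise intensity (> 0)
#' @param cross_noise process/observation noise covariance intensity
#'   (column vector; 0 if absent)
#' @param state_labels state names; must contain `"s"`
#' @param signal_var stationary prior variance of state `"s"`
#' @param scale per-state magnitudes used to condition the Riccati solve
#' @return object of class `linear_channel`
#' @export
linear_channel <- function(drift, process_noise, obs_map, obs_noise,
                           cross_noise = NULL, state_labels, signal_var,
                           scale = NULL) {
  n <- nrow(drift)
  stopifnot(ncol(drift) == n, all(dim(process_noise) == n),
            length(obs_map) == n, length(state_labels) == n)
  if (max(abs(process_noise - t(process_noise))) > 1e-12 * max(abs(process_noise), 1)) {
    stop("process_noise must be symmetric")
  }
  if (min(eigen(process_noise, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10 * max(abs(process_noise), 1)) {
    stop("process_noise must be positive semidefinite")
  }
  if (!(obs_noise > 0)) stop("obs_noise must be > 0")
  if (!"s" %in% state_labels) stop("state_labels must contain \"s\"")
  if (is.null(cross_noise)) cross_noise <- rep(0, n)
  si <- match("s", state_labels)
  # OU construction check: stationary var of s is Q_ss / (2 |A_ss|)
  if (signal_var > 0) {
    implied <- process_noise[si, si] / (2 * abs(drift[si, si]))
    if (abs(implied - signal_var) > 1e-8 * signal_var) {
      stop("stationary prior variance of state \"s\" does not equal signal_var")
    }
  }
  structure(list(drift = drift, process_noise = process_noise,
                 obs_map = as.numeric(obs_map), obs_noise = obs_noise,
                 cross_noise = as.numeric(cross_noise),
                 state_labels = state_labels, signal_var = signal_var,
                 scale = scale),
            class = "linear_channel")
}

#' @export
print.linear_channel <- function(x, ...) {
  cat(sprintf("Linear-Gaussian channel: %d states (%s)\n",
              length(x$state_labels), paste(x$state_labels, collapse = ", ")))
  cat(sprintf("  signal variance %.4g, observation noise intensity %.4g\n",
              x$signal_var, x$obs_noise))
  invisible(x)
}

#' Molecule-arrival observation channel
#'
#' Gaussian approximation of the Poisson arrival channel: latent states
#' s (OU signal) and L = log(c/c0) with dL/dt = s; the observation is the
#' arrival-rate deviation r - r0 = r0 * L + sqrt(r0) * white noise, whose
#' intensity r0 is the shot-noise PSD. Valid when many molecules arrive
#' per signal correlation time (r0 * tau_v >> 1; a warning is issued
#' below 10).
#'
#' @param swim [swim_params]; c0 must be > 0
#' @param constants [physical_constants]
#' @return [linear_channel] with states (s, L)
#' @export
build_arrival_channel <- function(swim, constants) {
  stopifnot(inherits(swim, "swim_params"), inherits(constants, "physical_constants"))
  if (!(swim$c0 > 0)) stop("arrival channel undefined at c0 = 0 (no arrivals)")
  r0 <- constants$kD * swim$c0
  if (r0 * swim$tau_v < 10) {
    warning("r0 * tau_v < 10: Gaussian approximation of Poisson arrivals is poor")
  }
  ss2 <- signal_variance(swim)
  ss <- sqrt(ss2)
  A <- matrix(c(-1 / swim$tau_v, 0,
                1, 0), 2, 2, byrow = TRUE)
  Q <- diag(c(2 * ss2 / swim$tau_v, 0))
  sss <- if (ss > 0) ss else 1
  ch <- linear_channel(A, Q, obs_map = c(0, r0), obs_noise = r0,
                       state_labels = c("s", "L"), signal_var = ss2,
                       scale = c(sss, sss * swim$tau_v))
  ch$r0 <- r0
  ch$tau_v <- swim$tau_v
  ch$kind <- "arrival"
  ch
}

#' Kinase-activity observation channel
#'
#' Linear-response kinase channel with an exact delta-function fast lobe
#' (tau_1 = 0). The observation is the activity deviation
#' a - a0 = -Gr * u + n - Gr * sqrt(r0) * white noise, where
#' u = r0 * L - F / tau_2 is the adapted receptor-input deviation (the
#' combination of log-concentration L and the adaptation filter state F
#' that the kinase actually reports; perfect adaptation makes the raw
#' integrator L unobservable at DC, so the channel is built directly in
#' these observable coordinates), and n is the slow internal OU noise
#' (intensity 2 * Dn, correlation time tau_n). The shared arrival shot
#' noise enters both u and the observation, giving the correlated-noise
#' term of the filter.
#'
#' @param swim [swim_params]; c0 must be > 0
#' @param kin [kinase_params]; engine requires tau_1 = 0 (the convention
#'   used for all calculations) and D_n > 0 unless `allow_zero_noise`
#' @param constants [physical_constants]
#' @param allow_zero_noise build the ideal-sensor (D_n = 0) channel, in
#'   which the internal-noise state is dropped; used for limit checks
#' @return [linear_channel] with states (s, u, n) (or (s, u) when D_n = 0)
#' @export
build_kinase_channel <- function(swim, kin, constants, allow_zero_noise = FALSE) {
  stopifnot(inherits(swim, "swim_params"), inherits(kin, "kinase_params"))
  if (!(swim$c0 > 0)) stop("kinase channel undefined at c0 = 0")
  if (kin$tau_1 != 0) {
    stop("the filtering engine uses the exact tau_1 = 0 convention; ",
         "set tau_1 = 0 (the fast lobe becomes the white observation term)")
  }
  if (kin$G_r == 0) stop("G_r = 0 carries no signal; the observation is pure noise")
  if (kin$D_n == 0 && !allow_zero_noise) {
    stop("D_n = 0 degenerates the stationary filter; pass allow_zero_noise ",
         "= TRUE for the ideal-sensor limit")
  }
  r0 <- constants$kD * swim$c0
  ss2 <- signal_variance(swim)
  ss <- sqrt(ss2)
  tau2 <- kin$tau_2
  Gr <- kin$G_r
  with_noise <- kin$D_n > 0
  n_states <- if (with_noise) 3L else 2L
  A <- matrix(0, n_states, n_states)
  A[1, 1] <- -1 / swim$tau_v
  A[2, 1] <- r0
  A[2, 2] <- -1 / tau2
  Qd <- c(2 * ss2 / swim$tau_v, r0 / tau2^2)
  H <- c(0, -Gr)
  S <- c(0, Gr * r0 / tau2)
  labels <- c("s", "u")
  scale <- c(if (ss > 0) ss else 1,
             max(r0 * ss * swim$tau_v, sqrt(r0 / (2 * tau2))))
  if (with_noise) {
    A[3, 3] <- -1 / kin$tau_n
    Qd <- c(Qd, 2 * kin$D_n)
    H <- c(H, 1)
    S <- c(S, 0)
    labels <- c(labels, "n")
    scale <- c(scale, sqrt(kin$D_n * kin$tau_n))
  }
  ch <- linear_channel(A, diag(Qd, n_states), obs_map = H,
                       obs_noise = Gr^2 * r0, cross_noise = S,
                       state_labels = labels, signal_var = ss2,
                       scale = scale)
  ch$r0 <- r0
  ch$tau_v <- swim$tau_v
  ch$kind <- "kinase"
  ch
}
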