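# Closed-form small-signal theory: dimensionless SNRs, information rates,
# response kernels, correlation functions and power spectral densities.

#' Dimensionless signal-to-noise ratio of molecule arrivals
#'
#' gamma_r = 2 * r0 * g^2 * sigma_v^2 * tau_v^3 with r0 = kD * c0 the
#' background arrival rate and g converted to 1/um. Quantifies how well the
#' run-and-tumble signal stands out of arrival shot noise over one signal
#' correlation time.
#'
#' @param swim [swim_params]
#' @param constants [physical_constants]
#' @return dimensionless SNR
#' @export
gamma_r <- function(swim, constants) {
  stopifnot(inherits(swim, "swim_params"), inherits(constants, "physical_constants"))
  r0 <- constants$kD * swim$c0
  2 * r0 * signal_variance(swim) * swim$tau_v^3
}

#' Dimensionless signal-to-noise ratio of kinase activity
#'
#' gamma_a = Gr^2 * r0^2 * g^2 * sigma_v^2 * tau_v / Dn. Since Gr carries
#' units of inverse arrival rate, Gr * r0 is dimensionless and so is
#' gamma_a. An ideal sensor without internal noise (Dn = 0) corresponds to
#' gamma_a = +Inf, which is returned (not an error) as the ideal-sensor
#' flag.
#'
#' @param swim [swim_params]
#' @param kin [kinase_params]
#' @param constants [physical_constants]
#' @return dimensionless SNR (+Inf when D_n = 0)
#' @export
gamma_a <- function(swim, kin, constants) {
  stopifnot(inherits(kin, "kinase_params"))
  r0 <- constants$kD * swim$c0
  num <- kin$G_r^2 * r0^2 * signal_variance(swim) * swim$tau_v
  if (kin$D_n == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / kin$D_n
}

#' Small-signal physical limit on the information rate
#'
#' Leading-order information rate extractable from molecule arrivals,
#' gamma_r / (4 * tau_v) nats/s, valid for gamma_r << 1. A warning is
#' issued above gamma_r = 0.5, where the expansion is unreliable; the
#' filtering engine ([info_rates()]) is exact at any gamma_r.
#'
#' @param gamma_r dimensionless arrival SNR
#' @param tau_v signal correlation time (s)
#' @param bits report bits/s instead of nats/s
#' @return information rate (nats/s, or bits/s if `bits`)
#' @export
info_rate_physical_smallsignal <- function(gamma_r, tau_v, bits = FALSE) {
  if (any(gamma_r < 0) || any(tau_v <= 0)) {
    stop("gamma_r must be >= 0 and tau_v > 0")
  }
  if (any(gamma_r > 0.5)) {
    warning("small-signal expression used outside its validity (gamma_r > 0.5)")
  }
  out <- gamma_r / (4 * tau_v)
  if (bits) out / log(2) else out
}

#' Small-signal information rate encoded in kinase activity
#'
#' Two algebraic readings of the small-signal kinase information rate are
#' provided. The default `"literal"` form is
#' (1 / (4 tau_v)) * gamma_r / (1 + gamma_r / gamma_a)^2, which reduces
#' exactly to the physical limit as gamma_a -> Inf. The `"interpolating"`
#' form (1 / (4 tau_v)) * gamma_a * gamma_r / (gamma_a + gamma_r)
#' additionally reduces to gamma_a / (4 tau_v) in the internal-noise
#' dominated regime gamma_a / gamma_r -> 0. Both are asymptotic
#' conveniences; headline numbers come from the filtering engine.
#'
#' @param gamma_r,gamma_a dimensionless SNRs (gamma_a may be Inf)
#' @param tau_v signal correlation time (s)
#' @param form which algebraic reading to use
#' @param bits report bits/s instead of nats/s
#' @return information rate (nats/s, or bits/s if `bits`)
#' @export
info_rate_kinase_smallsignal <- function(gamma_r, gamma_a, tau_v,
                                         form = c("literal", "interpolating"),
                                         bits = FALSE) {
  form <- match.arg(form)
  if (any(gamma_r < 0) || any(gamma_a < 0) || any(tau_v <= 0)) {
    stop("gamma_r, gamma_a must be >= 0 and tau_v > 0")
  }
  n <- max(length(gamma_r), length(gamma_a), length(tau_v))
  gr <- rep_len(gamma_r, n); ga <- rep_len(gamma_a, n)
  tv <- rep_len(tau_v, n)
  out <- if (form == "literal") {
    gr / (1 + gr / ga)^2 / (4 * tv)
  } else {
    ga * gr / (ga + gr) / (4 * tv)
  }
  out[gr == 0 | ga == 0] <- 0
  # gamma_a = Inf: both forms reduce to the physical limit
  inf_a <- is.infinite(ga) & gr > 0
  out[inf_a] <- gr[inf_a] / (4 * tv[inf_a])
  if (bits) out / log(2) else out
}

#' Kinase linear-response kernel
#'
#' Kr(t) = Gr * \[(1/tau_1) exp(-t/tau_1) - (1/tau_2) exp(-t/tau_2)\] for
#' t >= 0 and 0 for t < 0: two unit-area lobes of opposite sign, so the
#' kernel integrates to zero (perfect adaptation). With `tau_1 = 0` the
#' fast lobe is an exact Dirac delta; the returned values then carry only
#' the slow lobe, and the delta weight Gr is attached as attribute
#' `"delta_weight"`.
#'
#' @param t times (s), any sign
#' @param kin [kinase_params] (tau_1 < tau_2 enforced at construction)
#' @return kernel values (1/s per unit arrival rate); see Details for
#'   tau_1 = 0
#' @export
response_kernel <- function(t, kin) {
  stopifnot(inherits(kin, "kinase_params"))
  slow <- -kin$G_r / kin$tau_2 * exp(-t / kin$tau_2)
  if (kin$tau_1 == 0) {
    out <- ifelse(t >= 0, slow, 0)
    attr(out, "delta_weight") <- kin$G_r
    return(out)
  }
  fast <- kin$G_r / kin$tau_1 * exp(-t / kin$tau_1)
  ifelse(t >= 0, fast + slow, 0)
}

#' Kinase response to a concentration step
#'
#' Activity deviation after a step of size `delta_r` in arrival rate at
#' t = 0: a(t) - a0 = -delta_r * Gr * (exp(-t/tau_2) - exp(-t/tau_1)) for
#' t >= 0 (tau_1 = 0: instantaneous drop by delta_r * Gr followed by
#' adaptation with tau_2). Used by the step-response fits and generators.
#'
#' @param t times since step onset (s)
#' @param kin [kinase_params]
#' @param delta_r step in arrival rate (1/s); delta_r = kD * delta_c
#' @return activity deviation (dimensionless)
#' @export
step_response <- function(t, kin, delta_r) {
  fast <- if (kin$tau_1 == 0) 0 else exp(-t / kin$tau_1)
  ifelse(t < 0, 0, -delta_r * kin$G_r * (exp(-t / kin$tau_2) - fast))
}

#' Autocorrelation of slow internal kinase noise
#'
#' C(t) = Dn * tau_n * exp(-|t| / tau_n); the value at t = 0 is the
#' stationary noise variance Dn * tau_n.
#'
#' @param t lags (s), any sign
#' @param kin [kinase_params]
#' @return autocorrelation (activity^2)
#' @export
noise_autocorrelation <- function(t, kin) {
  stopifnot(inherits(kin, "kinase_params"))
  kin$D_n * kin$tau_n * exp(-abs(t) / kin$tau_n)
}

#' Power spectral decomposition of kinase-activity noise
#'
#' Two noise sources enter kinase activity: slow internal fluctuations
#' with PSD 2 * Dn * tau_n^2 / (1 + w^2 tau_n^2), and molecule-arrival
#' shot noise filtered through the response kernel, with PSD
#' |Kr_hat(w)|^2 * r0 where
#' Kr_hat(w) = Gr * (1/(1 + i w tau_1) - 1/(1 + i w tau_2)).
#' Adaptation suppresses the filtered-arrival PSD at DC; with tau_1 = 0 it
#' plateaus at Gr^2 * r0 at high frequency.
#'
#' @param omega angular frequencies (rad/s)
#' @param swim [swim_params] (supplies c0)
#' @param kin [kinase_params]
#' @param constants [physical_constants]
#' @return data.frame with columns `omega`, `slow_noise`, `filtered_arrival`,
#'   `total` (activity^2 * s)
#' @export
psd_decomposition <- function(omega, swim, kin, constants) {
  r0 <- constants$kD * swim$c0
  slow <- 2 * kin$D_n * kin$tau_n^2 / (1 + omega^2 * kin$tau_n^2)
  fast_lobe <- if (kin$tau_1 == 0) 1 + 0i else 1 / (1 + 1i * omega * kin$tau_1)
  K_hat <- kin$G_r * (fast_lobe - 1 / (1 + 1i * omega * kin$tau_2))
  arrival <- Mod(K_hat)^2 * r0
  data.frame(omega = omega, slow_noise = slow, filtered_arrival = arrival,
             total = slow + arrival)
}
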