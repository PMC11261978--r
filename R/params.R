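#' Swimming-signal parameters
#'
#' Statistics of the behaviorally-relevant signal s(t) = g * vx(t) for a
#' run-and-tumble swimmer in a static exponential gradient: the up-gradient
#' velocity variance `sigma_v2`, the velocity correlation time `tau_v`, the
#' fraction of time spent running `P_run`, the gradient steepness `g`
#' (1/mm at the interface) and the background concentration `c0` (uM).
#'
#' @param sigma_v2 variance of vx ((um/s)^2)
#' @param tau_v signal correlation time (s)
#' @param P_run fraction of time running, in \[0, 1\]
#' @param g gradient steepness (1/mm)
#' @param c0 background ligand concentration (uM)
#' @return object of class `swim_params`
#' @export
swim_params <- function(sigma_v2, tau_v, P_run = 1, g = 0, c0 = 1) {
  stopifnot(length(sigma_v2) == 1, length(tau_v) == 1, length(g) == 1)
  if (!(sigma_v2 > 0)) stop("sigma_v2 must be > 0")
  if (!(tau_v > 0)) stop("tau_v must be > 0")
  if (P_run < 0 || P_run > 1) stop("P_run must lie in [0, 1]")
  if (g < 0) stop("g must be >= 0")
  if (c0 < 0) stop("c0 must be >= 0")
  structure(list(sigma_v2 = sigma_v2, tau_v = tau_v, P_run = P_run,
                 g = g, c0 = c0),
            class = "swim_params")
}

# gradient steepness in 1/um (internal unit)
g_per_um <- function(swim) swim$g * 1e-3

# stationary signal variance sigma_s^2 = g^2 sigma_v^2 (1/s^2)
signal_variance <- function(swim) g_per_um(swim)^2 * swim$sigma_v2

#' Kinase response and noise parameters
#'
#' Linear-response description of CheA kinase activity: gain `G_r` to the
#' molecule arrival rate (units of time, i.e. activity per unit arrival
#' rate), fast response time `tau_1` (0 denotes an exact delta-function
#' fast lobe), adaptation time `tau_2`, and slow internal-noise
#' Ornstein-Uhlenbeck parameters `D_n` (diffusivity, 1/s) and `tau_n`
#' (correlation time, s). `a0` is the baseline activity.
#'
#' @param G_r response gain to arrival rate (s)
#' @param tau_1 fast response time (s); may be 0
#' @param tau_2 adaptation time (s); must exceed tau_1
#' @param D_n internal-noise diffusivity (1/s)
#' @param tau_n internal-noise correlation time (s)
#' @param a0 baseline kinase activity, in \[0, 1\]
#' @return object of class `kinase_params`
#' @export
kinase_params <- function(G_r, tau_1 = 0, tau_2, D_n, tau_n, a0 = 0.3) {
  if (!(tau_1 >= 0)) stop("tau_1 must be >= 0")
  if (!(tau_2 > tau_1)) stop("tau_2 must exceed tau_1 (slow adaptation lobe)")
  if (D_n < 0) stop("D_n must be >= 0")
  if (!(tau_n > 0)) stop("tau_n must be > 0")
  if (a0 < 0 || a0 > 1) stop("a0 must lie in [0, 1]")
  if (G_r < 0) stop("G_r must be >= 0")
  structure(list(G_r = G_r, tau_1 = tau_1, tau_2 = tau_2,
                 D_n = D_n, tau_n = tau_n, a0 = a0),
            class = "kinase_params")
}

#' MWC receptor gain parameters
#'
#' Two-state (Monod-Wyman-Changeux) description of the receptor gain,
#' G(c0) = G_inf * c0 / (c0 + K_i), where `K_i` is the inactive-state
#' dissociation constant and `G_inf` the asymptotic gain.
#'
#' @param G_inf asymptotic gain (dimensionless)
#' @param K_i inactive-state dissociation constant (uM)
#' @return object of class `mwc_gain`
#' @export
mwc_gain <- function(G_inf, K_i) {
  if (!(G_inf > 0) || !(K_i > 0)) stop("G_inf and K_i must be > 0")
  structure(list(G_inf = G_inf, K_i = K_i), class = "mwc_gain")
}

#' Arrival-rate gain implied by the MWC model
#'
#' Gr = G(c0) / r0 with G(c0) = G_inf * c0 / (c0 + K_i) and r0 = kD * c0,
#' i.e. Gr = G_inf / (kD * (c0 + K_i)). In the linear-sensing regime
#' c0 << K_i the gain is constant; in the log-sensing regime c0 >> K_i it
#' falls off as G_inf / r0.
#'
#' @param c0 background concentration (uM), > 0
#' @param mwc [mwc_gain] parameters
#' @param constants [physical_constants]
#' @return gain Gr in units of 1/(arrival rate) = s
#' @export
mwc_gain_Gr <- function(c0, mwc, constants) {
  stopifnot(inherits(mwc, "mwc_gain"), inherits(constants, "physical_constants"))
  if (!(c0 > 0)) stop("mwc_gain_Gr(): gain is defined against a background, c0 > 0")
  mwc$G_inf / (constants$kD * (c0 + mwc$K_i))
}

# ---------------------------------------------------------------------------
# configuration files

.config_keys <- c("D_um2_per_s", "l_um", "sigma_v2", "tau_v", "P_run",
                  "G_r_times_kD", "tau_1", "tau_2", "D_n", "tau_n",
                  "G_inf", "K_i", "c0_uM", "g_per_mm")

#' Read a parameter-set configuration file
#'
#' Parses a YAML configuration with a `constants` block (`D_um2_per_s`,
#' `l_um`, optionally `kD`), an optional `mwc` block (`G_inf`, `K_i`), and
#' a `backgrounds` list whose entries carry, per background concentration
#' `c0_uM`: `sigma_v2`, `tau_v`, `P_run`, `G_r_times_kD`, `tau_1`, `tau_2`,
#' `D_n`, `tau_n` and `g_per_mm`.
#'
#' @param path path to a YAML file
#' @return list with elements `constants` ([physical_constants]), `mwc`
#'   ([mwc_gain] or NULL) and `backgrounds` (list of
#'   `list(swim = swim_params, kin = kinase_params)`, named by c0)
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$constants)) stop("config missing 'constants' block")
  constants <- physical_constants(D = cfg$constants$D_um2_per_s,
                                  l = cfg$constants$l_um,
                                  kD = cfg$constants$kD)
  mwc <- if (!is.null(cfg$mwc)) mwc_gain(cfg$mwc$G_inf, cfg$mwc$K_i) else NULL
  backgrounds <- lapply(cfg$backgrounds, function(b) {
    missing <- setdiff(c("c0_uM", "sigma_v2", "tau_v", "G_r_times_kD",
                         "tau_2", "D_n", "tau_n"), names(b))
    if (length(missing)) {
      stop("config background block missing keys: ", paste(missing, collapse = ", "))
    }
    swim <- swim_params(sigma_v2 = b$sigma_v2, tau_v = b$tau_v,
                        P_run = if (is.null(b$P_run)) 1 else b$P_run,
                        g = if (is.null(b$g_per_mm)) 0 else b$g_per_mm,
                        c0 = b$c0_uM)
    kin <- kinase_params(G_r = b$G_r_times_kD / constants$kD,
                         tau_1 = if (is.null(b$tau_1)) 0 else b$tau_1,
                         tau_2 = b$tau_2, D_n = b$D_n, tau_n = b$tau_n,
                         a0 = if (is.null(b$a0)) 0.3 else b$a0)
    list(swim = swim, kin = kin)
  })
  names(backgrounds) <- vapply(backgrounds, function(b) format(b$swim$c0), "")
  list(constants = constants, mwc = mwc, backgrounds = backgrounds)
}

#' Packaged population-median parameter set
#'
#' Loads the packaged configuration carrying the population-median
#' swimming, kinase-response and kinase-noise parameters measured at
#' background concentrations 0.1, 1 and 10 uM, together with the physical
#' constants (kD carried at its conventional rounded value 1.2e5
#' s^-1 uM^-1) and the fitted MWC gain.
#'
#' @param c0 background concentration (uM): one of 0.1, 1, 10
#' @param g gradient steepness (1/mm) substituted into the swim parameters
#' @return list with `swim`, `kin`, `constants`, `mwc`
#' @export
median_params <- function(c0 = 1, g = 0) {
  path <- system.file("extdata", "median_params.yaml", package = "chemolimit")
  cfg <- read_params_config(path)
  key <- format(c0)
  if (!key %in% names(cfg$backgrounds)) {
    stop("no packaged medians for c0 = ", c0,
         " (available: ", paste(names(cfg$backgrounds), collapse = ", "), ")")
  }
  b <- cfg$backgrounds[[key]]
  b$swim$g <- g
  list(swim = b$swim, kin = b$kin, constants = cfg$constants, mwc = cfg$mwc)
}
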