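# Agent-based simulation: run-and-tumble motion, Poisson molecule
# arrivals, kinase dynamics, and chemotaxis with sensory readouts.

#' Run-and-tumble motion configuration
#'
#' @param speed swimming speed during runs (um/s)
#' @param run_rate tumble initiation rate during runs (1/s)
#' @param tumble_duration_mean mean tumble duration (s); 0 gives
#'   instantaneous reorientations
#' @param directional_persistence mean cosine of the tumble reorientation
#'   angle, in (-1, 1)
#' @param rot_diffusion rotational diffusivity during runs (rad^2/s)
#' @param dimensions 2 or 3
#' @param dt integration step (s)
#' @return object of class `run_tumble_config`
#' @export
run_tumble_config <- function(speed = 23.1, run_rate = 1 / 0.90,
                              tumble_duration_mean = 0.14,
                              directional_persistence = 0.33,
                              rot_diffusion = 0.062,
                              dimensions = 3, dt = 0.01) {
  if (!(speed > 0)) stop("speed must be > 0")
  if (!(run_rate > 0)) stop("run_rate must be > 0")
  if (tumble_duration_mean < 0) stop("tumble_duration_mean must be >= 0")
  if (abs(directional_persistence) >= 1) {
    stop("directional_persistence must lie in (-1, 1)")
  }
  if (rot_diffusion < 0) stop("rot_diffusion must be >= 0")
  if (!dimensions %in% c(2, 3)) stop("dimensions must be 2 or 3")
  tscales <- c(1 / run_rate,
               if (tumble_duration_mean > 0) tumble_duration_mean,
               if (rot_diffusion > 0) 1 / rot_diffusion)
  if (dt > min(tscales) / 10) {
    warning("dt is coarse relative to the fastest motility time scale")
  }
  structure(list(speed = speed, run_rate = run_rate,
                 tumble_duration_mean = tumble_duration_mean,
                 directional_persistence = directional_persistence,
                 rot_diffusion = rot_diffusion, dimensions = dimensions,
                 dt = dt),
            class = "run_tumble_config")
}

#' Simulate a run-and-tumble trajectory
#'
#' Runs have exponential durations (rate `run_rate`) and are interrupted by
#' tumbles of exponential duration during which the cell does not advance;
#' each tumble draws a new direction with the configured mean cosine
#' relative to the old one, and rotational diffusion perturbs the heading
#' during runs. The up-gradient velocity autocorrelation of the ensemble
#' is approximately a decaying exponential whose variance and correlation
#' time are set by the configuration.
#'
#' @param config [run_tumble_config]
#' @param duration trajectory duration (s)
#' @param seed optional RNG seed (integer)
#' @return data.frame of class `trajectory`: `time_s`, `x_um` (up-gradient
#'   position), `vx_um_s`, `state` ("run"/"tumble")
#' @export
simulate_run_tumble <- function(config, duration, seed = NULL) {
  stopifnot(inherits(config, "run_tumble_config"))
  if (duration < 0) stop("duration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sim <- cpp_run_tumble(duration, config$dt, config$speed, config$run_rate,
                        config$tumble_duration_mean,
                        config$directional_persistence,
                        config$rot_diffusion, config$dimensions)
  n <- length(sim$vx)
  out <- data.frame(time_s = (seq_len(n) - 1) * config$dt,
                    x_um = sim$x, vx_um_s = sim$vx,
                    state = ifelse(sim$running == 1L, "run", "tumble"))
  class(out) <- c("trajectory", "data.frame")
  attr(out, "dt") <- config$dt
  out
}

#' Behaviorally-relevant signal along a trajectory
#'
#' In a static exponential gradient of steepness g = d log(c)/dx, the
#' signal is s(t) = g * vx(t) and the concentration along the trajectory
#' is c(t) = c0 * exp(g * x(t)).
#'
#' @param traj [simulate_run_tumble()] output (or any data.frame with
#'   `vx_um_s` and `x_um`)
#' @param g gradient steepness (1/mm)
#' @param c0 background concentration at x = 0 (uM)
#' @return data.frame `time_s`, `s` (1/s), `c_uM`
#' @export
signal_from_trajectory <- function(traj, g, c0 = 1) {
  g_um <- g * 1e-3
  data.frame(time_s = traj$time_s,
             s = g_um * traj$vx_um_s,
             c_uM = c0 * exp(g_um * traj$x_um))
}

#' Simulate molecule arrivals at the receptor sensor
#'
#' Arrival events follow a Poisson process with rate kD * c(t); counts are
#' drawn per bin of width `dt`. `mode = "gaussian"` replaces the Poisson
#' draw with its Gaussian approximation (matched mean and variance).
#'
#' @param c_of_t concentration series (uM), one value per bin
#' @param constants [physical_constants]
#' @param dt bin width (s)
#' @param seed optional RNG seed
#' @param mode "poisson" or "gaussian"
#' @return data.frame of class `arrival_series`: `time_s`, `counts`,
#'   `c_uM`; attribute `dt`
#' @export
simulate_arrivals <- function(c_of_t, constants, dt, seed = NULL,
                              mode = c("poisson", "gaussian")) {
  mode <- match.arg(mode)
  if (any(c_of_t < 0)) stop("concentrations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  lam <- constants$kD * c_of_t * dt
  if (any(lam > .Machine$integer.max / 2)) {
    stop("kD * c * dt too large for count simulation; reduce dt")
  }
  counts <- if (mode == "poisson") {
    rpois(length(lam), lam)
  } else {
    lam + sqrt(lam) * rnorm(length(lam))
  }
  out <- data.frame(time_s = (seq_along(c_of_t) - 1) * dt,
                    counts = counts, c_uM = c_of_t)
  class(out) <- c("arrival_series", "data.frame")
  attr(out, "dt") <- dt
  out
}

#' Simulate kinase activity driven by molecule arrivals
#'
#' Integrates the linear-response model: activity responds to the arrival
#' excess through the biphasic kernel (fast lobe tau_1, adaptation lobe
#' tau_2) and carries slow internal Ornstein-Uhlenbeck noise (D_n, tau_n),
#' simulated with its exact discretization. Output is clipped to \[0, 1\]
#' only on return; the clipping fraction is reported and a fraction above
#' 1 percent signals that the linear model left its validity regime.
#'
#' @param arrivals [simulate_arrivals()] output (constant-background rate
#'   r0 is taken as kD times the first concentration unless given)
#' @param kin [kinase_params]; tau_1 must be 0 or at least 2 * dt
#' @param constants [physical_constants]
#' @param r0 background arrival rate (1/s); defaults to kD * c_uM\[1\]
#' @param seed optional RNG seed
#' @param clip clip activity to \[0, 1\] on output
#' @return numeric activity series with attributes `dt` and
#'   `clip_fraction`
#' @export
simulate_kinase <- function(arrivals, kin, constants, r0 = NULL, seed = NULL,
                            clip = TRUE) {
  stopifnot(inherits(kin, "kinase_params"))
  dt <- attr(arrivals, "dt")
  if (is.null(dt)) stop("arrivals must carry a dt attribute")
  if (kin$tau_1 != 0 && kin$tau_1 < 2 * dt) {
    stop("tau_1 must be 0 (delta lobe) or at least 2 * dt")
  }
  if (is.null(r0)) r0 <- constants$kD * arrivals$c_uM[1]
  if (!is.null(seed)) set.seed(seed)
  a <- cpp_kinase_trace(as.numeric(arrivals$counts), dt, r0, kin$G_r,
                        kin$tau_1, kin$tau_2, kin$D_n, kin$tau_n, kin$a0)
  clip_frac <- mean(a < 0 | a > 1)
  if (clip_frac > 0.01) {
    warning(sprintf("%.1f%% of activity samples clipped: linear kinase model leaving validity",
                    100 * clip_frac))
  }
  if (clip) a <- pmin(pmax(a, 0), 1)
  attr(a, "dt") <- dt
  attr(a, "clip_fraction") <- clip_frac
  a
}

#' Simulate chemotaxis with a sensory readout
#'
#' Agents swim run-and-tumble in a static exponential gradient
#' c(x) = c0 exp(g x) and modulate their tumble rate linearly with a
#' standardized sensory readout, lambda(t) = lambda0 (1 - beta * xhat),
#' clipped at zero. Readouts: `"arrival"` uses the optimal causal estimate
#' of the signal from molecule arrivals (an ideal cell); `"kinase"` uses
#' the standardized kinase deviation -(a - a0)/sd(a) (a cell with access
#' only to its kinase activity); `"kinase_estimate"` applies the optimal
#' causal filter to the kinase activity first.
#'
#' @param config [run_tumble_config] (3-D motion is used)
#' @param swim [swim_params] carrying c0 and g; sigma_v2/tau_v set the
#'   readout filters
#' @param kin [kinase_params]
#' @param constants [physical_constants]
#' @param readout one of "arrival", "kinase", "kinase_estimate"
#' @param modulation_gain beta (kept small so rate modulation stays in the
#'   shallow-response regime)
#' @param duration simulated time per cell (s)
#' @param n_cells number of independent agents
#' @param seed optional RNG seed
#' @param burnin discarded initial time (s)
#' @return one-row data.frame of class `drift_result`: `g`, `vd` (mean
#'   up-gradient drift speed, um/s), `sem`, `n_cells`, `t_total`,
#'   `clip_fraction`, `readout`
#' @export
simulate_chemotaxis <- function(config, swim, kin, constants,
                                readout = c("arrival", "kinase", "kinase_estimate"),
                                modulation_gain = 0.4, duration = 500,
                                n_cells = 100, seed = NULL, burnin = 50) {
  readout <- match.arg(readout)
  stopifnot(inherits(config, "run_tumble_config"))
  if (!is.null(seed)) set.seed(seed)
  g_um <- g_per_um(swim)
  ss2 <- signal_variance(swim)
  mode <- match(readout, c("arrival", "kinase", "kinase_estimate")) - 1L
  Phi <- diag(3); Kg <- rep(0, 3); Hm <- rep(0, 3); Bd <- rep(0, 3)
  if (readout == "arrival") {
    post <- stationary_posterior(build_arrival_channel(swim, constants))
    sd_readout <- sqrt(max(post$rho2, 1e-12) * ss2)
  } else if (readout == "kinase") {
    ch <- build_kinase_channel(swim, kin, constants)
    Sig <- stationary_prior(ch)
    H <- ch$obs_map
    sd_readout <- sqrt((H %*% Sig %*% H)[1] + ch$obs_noise / config$dt)
  } else {
    ch <- build_kinase_channel(swim, kin, constants)
    f <- steady_discrete_filter(ch, config$dt)
    Phi <- f$Phi; Kg <- f$K; Hm <- f$H; Bd <- as.numeric(f$Bd)
    # filter runs in scaled coordinates; standardize its (scaled) s estimate
    sd_readout <- sqrt(max(ss2 - f$P_ss, 1e-30)) / f$s_scale
  }
  res <- cpp_chemotaxis(n_cells, duration, config$dt, burnin,
                        config$speed, config$run_rate,
                        config$tumble_duration_mean,
                        config$directional_persistence, config$rot_diffusion,
                        swim$c0, g_um, constants$kD,
                        kin$G_r, kin$tau_2, kin$D_n, kin$tau_n, kin$a0,
                        mode, modulation_gain, sd_readout,
                        swim$tau_v, ss2, Phi, Kg, Hm, Bd)
  if (res$clip_fraction > 0.05) {
    warning(sprintf("tumble rate clipped at zero %.1f%% of the time: modulation_gain too large",
                    100 * res$clip_fraction))
  }
  vx <- res$mean_vx
  out <- data.frame(g = swim$g, vd = mean(vx), sem = sd(vx) / sqrt(length(vx)),
                    n_cells = n_cells, t_total = n_cells * (duration - burnin),
                    clip_fraction = res$clip_fraction, readout = readout)
  class(out) <- c("drift_result", "data.frame")
  out
}
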