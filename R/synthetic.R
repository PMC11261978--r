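# Seeded generators that emulate the three single-cell experiment types
# (swimming trajectories, FRET step responses, constant-background noise
# traces) with known ground truth, so every inference stage can be tested
# end to end without measured data.
#
# Cell-to-cell variability is drawn log-normally around the population
# medians with a configurable coefficient of variation (default 0.3).

draw_lognormal <- function(n, median, cv) {
  if (cv <= 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  median * exp(rnorm(n, sd = sdlog))
}

#' Generate a swimming-trajectory population
#'
#' Per-cell motility parameters (speed, run rate, tumble duration) are
#' drawn log-normally around the configured medians; each cell swims a
#' run-and-tumble trajectory of exponentially distributed duration (mean
#' `mean_duration_s`, floored at `min_duration_s`). Defaults give a total
#' trajectory time of about 3.4e4 s across the population.
#'
#' @param n_cells number of cells
#' @param config median motility configuration ([run_tumble_config])
#' @param cv log-normal coefficient of variation of per-cell parameters
#' @param mean_duration_s mean trajectory duration (s)
#' @param min_duration_s shortest trajectory kept (s)
#' @param seed RNG seed
#' @return list: `trajectories` (stacked [simulate_run_tumble()] tables
#'   with `cell_id`), `truth` (per-cell parameter table plus the medians)
#' @export
gen_swim_population <- function(n_cells = 4500, config = run_tumble_config(),
                                cv = 0.3, mean_duration_s = 7.6,
                                min_duration_s = 1.5, seed = 1) {
  stopifnot(n_cells >= 1)
  set.seed(seed)
  speed <- draw_lognormal(n_cells, config$speed, cv)
  run_rate <- draw_lognormal(n_cells, config$run_rate, cv)
  tumble_dur <- draw_lognormal(n_cells, config$tumble_duration_mean, cv)
  duration <- pmax(rexp(n_cells, 1 / mean_duration_s), min_duration_s)
  parts <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cfg_i <- config
    cfg_i$speed <- speed[i]
    cfg_i$run_rate <- run_rate[i]
    cfg_i$tumble_duration_mean <- tumble_dur[i]
    tr <- simulate_run_tumble(cfg_i, duration[i])
    tr$cell_id <- i
    parts[[i]] <- tr
  }
  trajectories <- do.call(rbind, parts)
  truth <- list(per_cell = data.frame(cell_id = seq_len(n_cells),
                                      speed = speed, run_rate = run_rate,
                                      tumble_duration_mean = tumble_dur,
                                      duration_s = duration),
                config = config, cv = cv, seed = seed)
  list(trajectories = trajectories, truth = truth)
}

#' Generate a step-response FRET experiment
#'
#' Emulates the stimulus schedule of the kinase response measurements:
#' per block, `pre_s` seconds at background then `post_s` seconds at the
#' stepped concentration, sampled every `sample_dt` seconds; `n_blocks`
#' upward and `n_blocks` downward steps alternate. Responses follow the
#' biphasic kernel of each cell's (log-normally drawn) parameters, with
#' slow OU noise and white measurement noise added. Saturating bookends
#' (activity 0 and 1 segments in FRET units) are emitted for
#' [normalize_activity()].
#'
#' @param n_cells number of cells
#' @param kin median [kinase_params]
#' @param constants [physical_constants]
#' @param c0 background concentration (uM)
#' @param delta_c step size (uM); the down step uses -delta_c
#' @param pre_s,post_s,n_blocks,sample_dt stimulus schedule (s, s, count, s)
#' @param cv per-cell log-normal coefficient of variation
#' @param sigma_m measurement-noise standard deviation per sample
#'   (activity units); default half the median response amplitude, so a
#'   single block has signal-to-noise ~ 2
#' @param fret_gain,fret_offset affine map from activity to FRET units
#' @param seed RNG seed
#' @return list: `traces` (data.frame `cell_id`, `block`, `direction`,
#'   `time_s` since block start, `fret`), `bookends` (per-cell
#'   `fret_min`/`fret_max` levels), `truth`
#' @export
gen_step_response_experiment <- function(n_cells = 20, kin, constants,
                                         c0 = 1, delta_c = 0.1,
                                         pre_s = 7.5, post_s = 30,
                                         n_blocks = 10, sample_dt = 0.75,
                                         cv = 0.3, sigma_m = NULL,
                                         fret_gain = 0.5, fret_offset = 0.2,
                                         seed = 1) {
  stopifnot(inherits(kin, "kinase_params"))
  set.seed(seed)
  delta_r <- constants$kD * delta_c
  if (abs(delta_r * kin$G_r) > 0.5) {
    warning("step excursion exceeds half the activity range: linear response dubious")
  }
  if (is.null(sigma_m)) sigma_m <- abs(delta_r * kin$G_r) / 2
  G <- draw_lognormal(n_cells, kin$G_r, cv)
  tau2 <- draw_lognormal(n_cells, kin$tau_2, cv)
  Dn <- draw_lognormal(n_cells, kin$D_n, cv)
  taun <- draw_lognormal(n_cells, kin$tau_n, cv)
  t_block <- seq(0, pre_s + post_s - sample_dt, by = sample_dt)
  onset <- pre_s
  traces <- vector("list", n_cells * 2 * n_blocks)
  k <- 0
  for (i in seq_len(n_cells)) {
    kin_i <- kinase_params(G_r = G[i], tau_1 = kin$tau_1, tau_2 = tau2[i],
                           D_n = Dn[i], tau_n = taun[i], a0 = kin$a0)
    phi <- exp(-sample_dt / taun[i])
    sd_ou <- sqrt(Dn[i] * taun[i])
    ou <- sd_ou * rnorm(1)
    for (b in seq_len(2 * n_blocks)) {
      dir <- if (b %% 2 == 1) 1 else -1   # alternating up/down
      resp <- step_response(t_block - onset, kin_i, dir * delta_r)
      ou_series <- numeric(length(t_block))
      for (j in seq_along(t_block)) {
        ou <- phi * ou + sd_ou * sqrt(1 - phi^2) * rnorm(1)
        ou_series[j] <- ou
      }
      a <- kin$a0 + resp + ou_series + sigma_m * rnorm(length(t_block))
      k <- k + 1
      traces[[k]] <- data.frame(cell_id = i, block = ceiling(b / 2),
                                direction = if (dir > 0) "up" else "down",
                                time_s = t_block,
                                fret = fret_offset + fret_gain * a)
    }
  }
  bookends <- data.frame(cell_id = seq_len(n_cells),
                         fret_min = fret_offset + fret_gain *
                           (0 + sigma_m * rnorm(n_cells) / sqrt(10)),
                         fret_max = fret_offset + fret_gain *
                           (1 + sigma_m * rnorm(n_cells) / sqrt(10)))
  truth <- list(per_cell = data.frame(cell_id = seq_len(n_cells), G_r = G,
                                      tau_2 = tau2, D_n = Dn, tau_n = taun),
                kin = kin, delta_c = delta_c, delta_r = delta_r,
                sigma_m = sigma_m, fret_gain = fret_gain,
                fret_offset = fret_offset, onset_s = onset, seed = seed)
  list(traces = do.call(rbind, traces), bookends = bookends, truth = truth)
}

#' Average the blocks of a step-response experiment
#'
#' Normalizes each trace by the cell's saturating bookends, aligns blocks
#' to the step onset, flips down-steps, and pools all blocks into a mean
#' response with per-timepoint SEM -- the input expected by
#' [fit_step_response()].
#'
#' @param experiment [gen_step_response_experiment()] output
#' @param cell_id which cell to average
#' @return data.frame `time_s` (since onset), `response` (mean activity
#'   deviation), `sem`
#' @export
average_step_response <- function(experiment, cell_id) {
  tr <- experiment$traces[experiment$traces$cell_id == cell_id, ]
  bk <- experiment$bookends[experiment$bookends$cell_id == cell_id, ]
  if (nrow(tr) == 0) stop("no traces for cell ", cell_id)
  a <- normalize_activity(tr$fret, bk$fret_min, bk$fret_max)
  onset <- experiment$truth$onset_s
  sign <- ifelse(tr$direction == "up", 1, -1)
  pre <- tr$time_s < onset
  # per-block baseline from the pre-step samples
  key <- interaction(tr$block, tr$direction, drop = TRUE)
  base <- tapply(a[pre], key[pre], mean)[key]
  dev <- sign * (a - base)
  tt <- round(tr$time_s - onset, 9)
  mean_r <- tapply(dev, tt, mean)
  sd_r <- tapply(dev, tt, sd)
  n_r <- tapply(dev, tt, length)
  data.frame(time_s = as.numeric(names(mean_r)),
             response = as.numeric(mean_r),
             sem = as.numeric(sd_r / sqrt(n_r)))
}

#' Generate constant-background kinase noise traces
#'
#' Long traces of activity at constant background: baseline + slow OU
#' noise (D_n, tau_n) + white measurement noise, with an optional
#' filtered-arrival noise floor (the tau_1 = 0 white response term),
#' sampled at 1 Hz for 1200 s by default.
#'
#' @param n_cells number of cells
#' @param kin median [kinase_params]
#' @param constants [physical_constants] (needed for the arrival floor)
#' @param c0 background concentration (uM)
#' @param duration_s,dt trace length and sampling interval (s)
#' @param cv per-cell log-normal coefficient of variation
#' @param sigma_m white measurement-noise standard deviation
#' @param arrival_floor include the filtered-arrival white noise term
#' @param seed RNG seed
#' @return list: `traces` (data.frame `cell_id`, `time_s`, `activity`),
#'   `truth`
#' @export
gen_noise_traces <- function(n_cells = 20, kin, constants = NULL, c0 = 1,
                             duration_s = 1200, dt = 1, cv = 0.3,
                             sigma_m = 0.01, arrival_floor = FALSE, seed = 1) {
  stopifnot(inherits(kin, "kinase_params"))
  set.seed(seed)
  Dn <- draw_lognormal(n_cells, kin$D_n, cv)
  taun <- draw_lognormal(n_cells, kin$tau_n, cv)
  n <- floor(duration_s / dt)
  sd_arrival <- if (arrival_floor) {
    if (is.null(constants)) stop("constants needed for the arrival noise floor")
    kin$G_r * sqrt(constants$kD * c0 / dt)
  } else 0
  parts <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    phi <- exp(-dt / taun[i])
    sd_ou <- sqrt(Dn[i] * taun[i])
    innov <- rnorm(n)
    ou <- numeric(n)
    ou[1] <- sd_ou * innov[1]
    for (j in 2:n) ou[j] <- phi * ou[j - 1] + sd_ou * sqrt(1 - phi^2) * innov[j]
    a <- kin$a0 + ou + sigma_m * rnorm(n) +
      if (sd_arrival > 0) sd_arrival * rnorm(n) else 0
    parts[[i]] <- data.frame(cell_id = i, time_s = seq_len(n) * dt - dt,
                             activity = a)
  }
  truth <- list(per_cell = data.frame(cell_id = seq_len(n_cells),
                                      D_n = Dn, tau_n = taun),
                kin = kin, sigma_m = sigma_m, arrival_floor = arrival_floor,
                seed = seed)
  list(traces = do.call(rbind, parts), truth = truth)
}
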