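# Reproduction glue: information-rate tables over background and gradient
# grids, PSD tables, estimator-comparison traces, drift-speed sweeps, and
# CSV output with a units header and configuration hash.

# small FNV-1a hash of a deparsed R object, for output manifests
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Write a results table as CSV with a units header
#'
#' Prepends comment lines recording the column units and a hash of the
#' generating configuration, then writes the table with
#' [utils::write.csv()] semantics.
#'
#' @param df data.frame to write
#' @param path output path
#' @param units named character vector or single string describing units
#' @param config the configuration object the table was computed from
#' @return `path`, invisibly
#' @export
write_table_csv <- function(df, path, units = "", config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(paste(units, collapse = ""))) {
    writeLines(paste0("# units: ", paste(names(units), units, sep = "=",
                                         collapse = "; ")), con)
  }
  if (!is.null(config)) {
    writeLines(paste0("# config_hash: ", config_hash(config)), con)
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Information rates over background and gradient grids
#'
#' Computes the physical-limit and kinase information rates (normalized
#' per g^2) and their ratio eta over a log-spaced background grid and a
#' set of gradient steepnesses, using the MWC model for the
#' background-dependence of the gain and a common set of swimming and
#' noise parameters. `g = 0` rows evaluate the vanishing-gradient plateau
#' (at g = 1e-4 per mm).
#'
#' @param swim [swim_params] template (c0 is swept)
#' @param kin [kinase_params] template (G_r is set from the MWC gain)
#' @param constants [physical_constants]
#' @param mwc [mwc_gain]
#' @param c0_grid background grid (uM); default 40 points/decade over
#'   0.01 to 100
#' @param g_values gradient steepnesses (1/mm); 0 denotes the plateau
#' @return data.frame `c0`, `g`, `I_r_per_g2`, `I_a_per_g2`, `eta`
#'   (rates in nats/s per (1/mm)^2)
#' @export
information_tables <- function(swim, kin, constants, mwc,
                               c0_grid = 10^seq(-2, 2, by = 1 / 40),
                               g_values = c(0, 0.1, 0.2, 0.3, 0.4)) {
  rows <- list()
  for (c0 in c0_grid) {
    for (g in g_values) {
      g_eval <- if (g == 0) 1e-4 else g
      sw <- swim; sw$c0 <- c0; sw$g <- g_eval
      kn <- kin; kn$G_r <- mwc_gain_Gr(c0, mwc, constants)
      ir <- info_rates(sw, kn, constants)
      rows[[length(rows) + 1]] <-
        data.frame(c0 = c0, g = g,
                   I_r_per_g2 = ir$I_r / g_eval^2,
                   I_a_per_g2 = ir$I_a / g_eval^2,
                   eta = ir$eta)
    }
  }
  do.call(rbind, rows)
}

#' PSD tables at the measured backgrounds
#'
#' Evaluates [psd_decomposition()] on a log-spaced angular-frequency grid
#' for each background in the packaged median parameter set.
#'
#' @param c0_values backgrounds (uM)
#' @param omega angular frequencies (rad/s)
#' @return data.frame with `c0` prepended to the decomposition columns
#' @export
psd_tables <- function(c0_values = c(0.1, 1, 10),
                       omega = 10^seq(-3, 2, by = 0.05)) {
  do.call(rbind, lapply(c0_values, function(c0) {
    p <- median_params(c0)
    cbind(c0 = c0, psd_decomposition(omega, p$swim, p$kin, p$constants))
  }))
}

#' Side-by-side optimal signal estimates from arrivals and kinase activity
#'
#' Simulates one run-and-tumble trajectory in a gradient, the Poisson
#' molecule arrivals along it, and the kinase response to those arrivals;
#' then reconstructs the signal causally from each observation stream and
#' reports the empirical squared correlations with the true signal next
#' to the engine predictions.
#'
#' @param swim [swim_params] with g > 0
#' @param kin [kinase_params]
#' @param constants [physical_constants]
#' @param config [run_tumble_config]
#' @param duration trajectory duration (s)
#' @param dt filtering grid (s); arrival counts are drawn on this grid
#' @param seed RNG seed
#' @return list: `traces` (data.frame `time_s`, `s`, `s_hat_arrival`,
#'   `s_hat_kinase`, `activity`), `summary` (empirical and engine rho^2)
#' @export
estimator_comparison <- function(swim, kin, constants,
                                 config = run_tumble_config(),
                                 duration = 2000, dt = 0.02, seed = 1) {
  if (!(swim$g > 0)) stop("estimator comparison needs a finite gradient")
  set.seed(seed)
  cfg <- config
  cfg$dt <- dt
  traj <- simulate_run_tumble(cfg, duration)
  sig <- signal_from_trajectory(traj, swim$g, swim$c0)
  arr <- simulate_arrivals(sig$c_uM, constants, dt)
  act <- simulate_kinase(arr, kin, constants, r0 = constants$kD * swim$c0,
                         clip = FALSE)
  ch_r <- build_arrival_channel(swim, constants)
  ch_a <- build_kinase_channel(swim, kin, constants)
  obs_r <- arrival_observations(arr$counts, dt, constants$kD * swim$c0)
  obs_a <- as.numeric(act) - kin$a0
  sh_r <- causal_estimate(ch_r, obs_r, dt)
  sh_a <- causal_estimate(ch_a, obs_a, dt)
  burn <- seq_len(min(length(sh_r) - 1, ceiling(20 * swim$tau_v / dt)))
  s_true <- sig$s[-burn]
  rho2_emp <- function(est) cor(s_true, est[-burn])^2
  post_r <- stationary_posterior(ch_r)
  post_a <- stationary_posterior(ch_a)
  list(traces = data.frame(time_s = sig$time_s, s = sig$s,
                           s_hat_arrival = as.numeric(sh_r),
                           s_hat_kinase = as.numeric(sh_a),
                           activity = as.numeric(act)),
       summary = data.frame(channel = c("arrival", "kinase"),
                            rho2_empirical = c(rho2_emp(sh_r), rho2_emp(sh_a)),
                            rho2_engine = c(post_r$rho2, post_a$rho2)))
}

#' Drift-speed sweep over gradient steepness
#'
#' Simulates chemotaxis of ideal cells (arrival readout) and kinase-driven
#' cells at each gradient steepness, and pairs the measured drift-speed
#' ratio with the engine prediction sqrt(I_a / I_r).
#'
#' @param g_values gradient steepnesses (1/mm)
#' @param swim,kin,constants parameter set (c0 from `swim`)
#' @param config [run_tumble_config]
#' @param kinase_readout readout mode for the kinase-driven cells
#'   (see [simulate_chemotaxis()])
#' @param n_cells,duration simulation effort per point
#' @param modulation_gain tumble-rate modulation beta
#' @param seed RNG seed (one stream across the sweep)
#' @return data.frame `g`, `vd_ideal`, `sem_ideal`, `vd_kinase`,
#'   `sem_kinase`, `ratio`, `ratio_se`, `engine_ratio`
#' @export
drift_ratio_sweep <- function(g_values = c(0.05, 0.1, 0.2, 0.3, 0.4),
                              swim, kin, constants,
                              config = run_tumble_config(),
                              kinase_readout = "kinase_estimate",
                              n_cells = 200, duration = 500,
                              modulation_gain = 0.4, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in g_values) {
    sw <- swim; sw$g <- g
    ir <- info_rates(sw, kin, constants)
    d_ideal <- simulate_chemotaxis(config, sw, kin, constants,
                                   readout = "arrival",
                                   modulation_gain = modulation_gain,
                                   duration = duration, n_cells = n_cells)
    d_kin <- simulate_chemotaxis(config, sw, kin, constants,
                                 readout = kinase_readout,
                                 modulation_gain = modulation_gain,
                                 duration = duration, n_cells = n_cells)
    ratio <- d_kin$vd / d_ideal$vd
    ratio_se <- abs(ratio) * sqrt((d_kin$sem / d_kin$vd)^2 +
                                    (d_ideal$sem / d_ideal$vd)^2)
    rows[[length(rows) + 1]] <-
      data.frame(g = g, vd_ideal = d_ideal$vd, sem_ideal = d_ideal$sem,
                 vd_kinase = d_kin$vd, sem_kinase = d_kin$sem,
                 ratio = ratio, ratio_se = ratio_se,
                 engine_ratio = sqrt(ir$I_a / ir$I_r))
  }
  do.call(rbind, rows)
}

#' Quick engine self-checks
#'
#' Runs fast internal consistency checks of the filtering engine: the
#' small-signal asymptotic at tiny SNR, the data processing inequality on
#' a coarse parameter grid, and the vanishing-gradient plateau of eta.
#' Returns a named logical vector; all entries TRUE on a healthy build.
#'
#' @return named logical vector
#' @export
validate_engine <- function() {
  p <- median_params(1)
  checks <- c()
  sw <- p$swim; sw$g <- 1e-6
  ir <- info_rates(sw, p$kin, p$constants)
  gr <- gamma_r(sw, p$constants)
  checks["smallsignal_asymptotic"] <-
    abs(ir$I_r / (gr / (4 * sw$tau_v)) - 1) < 0.01
  ok <- TRUE
  for (c0 in c(0.1, 1, 10)) {
    for (g in c(0.05, 0.4)) {
      s2 <- p$swim; s2$c0 <- c0; s2$g <- g
      i2 <- info_rates(s2, p$kin, p$constants)
      ok <- ok && i2$I_a <= i2$I_r + 1e-12
    }
  }
  checks["data_processing_inequality"] <- ok
  e <- eta(p$swim, p$kin, p$constants, g0 = TRUE)
  checks["eta_plateau"] <- is.finite(e) && e > 0 && e < 1
  checks
}
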