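# Parameter-estimation procedures applied to trajectory tables and
# kinase-activity traces (synthetic or user-supplied).
#
# All fits share one recipe: Gaussian likelihood, priors uniform in the
# logarithm of each parameter, MAP point estimates by quasi-Newton
# optimization in log-parameter space, and per-cell uncertainties from the
# robust spread (1.4826 * mad) of affine-invariant ensemble MCMC draws.

new_cell_fit <- function(theta_map, sigma_theta, draws, n_obs, details = list()) {
  structure(list(theta_map = theta_map, sigma_theta = sigma_theta,
                 draws = draws, n_obs = n_obs, details = details),
            class = "cell_fit")
}

#' @export
print.cell_fit <- function(x, ...) {
  cat("Single-cell fit (", x$n_obs, " observations)\n", sep = "")
  for (p in names(x$theta_map)) {
    cat(sprintf("  %-10s %.5g +/- %.3g\n", p, x$theta_map[[p]],
                x$sigma_theta[[p]]))
  }
  invisible(x)
}

#' @export
coef.cell_fit <- function(object, ...) object$theta_map

map_then_sample <- function(log_post, init_log, param_names, n_obs,
                            n_walkers = 24, n_steps = 300, burn = 150,
                            details = list()) {
  obj <- function(p) {
    v <- -log_post(p)
    if (!is.finite(v)) 1e12 else v
  }
  opt <- optim(init_log, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  # gradient polish where the posterior is smooth; MAP may sit on a prior
  # boundary, in which case the simplex result stands
  opt2 <- tryCatch(optim(opt$par, obj, method = "BFGS",
                         control = list(maxit = 500)),
                   error = function(e) NULL)
  if (!is.null(opt2) && is.finite(opt2$value) && opt2$value <= opt$value) {
    opt <- opt2
  }
  map_log <- opt$par
  draws_log <- stretch_sampler(log_post, map_log, n_walkers = n_walkers,
                               n_steps = n_steps, burn = burn)
  draws <- exp(draws_log)
  colnames(draws) <- param_names
  theta <- exp(map_log)
  names(theta) <- param_names
  sigma <- robust_spread(draws)
  names(sigma) <- param_names
  new_cell_fit(theta, sigma, draws, n_obs, details)
}

# ---------------------------------------------------------------------------

#' Select cells in the population-median run-fraction bin
#'
#' Computes the fraction of time spent running, Prun, for every cell with
#' at least two detected tumbles, the (optionally weighted) population
#' median, and the membership of the bin median +/- `window`. The
#' diffusivity-bias correction enters as a per-cell weight hook
#' (`weights`), defaulting to uniform weights.
#'
#' @param trajectories data.frame with columns `cell_id`, `time_s`,
#'   `vx_um_s`, `state` ("run"/"tumble")
#' @param window half-width of the Prun bin around the median
#' @param weights optional named vector of per-cell weights (names =
#'   cell ids)
#' @return list of class `prun_selection`: `cells` (per-cell table with
#'   `P_run`, `n_tumbles`, `duration_s`, `selected`), `median_prun`,
#'   `selected` (cell ids)
#' @export
prun_select <- function(trajectories, window = 0.01, weights = NULL) {
  need <- c("cell_id", "state")
  if (!all(need %in% names(trajectories))) {
    stop("trajectories must have columns cell_id and state")
  }
  by_cell <- split(trajectories, trajectories$cell_id)
  tab <- do.call(rbind, lapply(by_cell, function(df) {
    r <- rle(df$state)
    data.frame(cell_id = df$cell_id[1],
               P_run = mean(df$state == "run"),
               n_tumbles = sum(r$values == "tumble"),
               duration_s = diff(range(df$time_s)) +
                 (df$time_s[2] - df$time_s[1]))
  }))
  rownames(tab) <- NULL
  tab <- tab[tab$n_tumbles >= 2, , drop = FALSE]
  if (nrow(tab) == 0) stop("no cells with at least two detected tumbles")
  w <- if (is.null(weights)) rep(1, nrow(tab)) else {
    as.numeric(weights[as.character(tab$cell_id)])
  }
  if (anyNA(w)) stop("weights must cover every retained cell")
  ord <- order(tab$P_run)
  cw <- cumsum(w[ord]) / sum(w)
  med <- tab$P_run[ord][which(cw >= 0.5)[1]]
  tab$selected <- abs(tab$P_run - med) <= window
  if (!any(tab$selected)) warning("median Prun bin is empty")
  structure(list(cells = tab, median_prun = med,
                 selected = tab$cell_id[tab$selected]),
            class = "prun_selection")
}

#' Duration-weighted ensemble velocity autocorrelation
#'
#' Per-cell non-centered autocorrelation Vi(t) = <vx(t') vx(t' + t)> of
#' the up-gradient velocity, averaged over cells with weights equal to
#' trajectory duration. Cells too short to contribute at least two lags
#' are skipped (with a message). Lags where a cell's record ends simply
#' drop that cell from the average.
#'
#' @param trajectories data.frame with `cell_id`, `time_s`, `vx_um_s`
#' @param max_lag_s largest lag computed (s)
#' @param cells optional subset of cell ids (e.g. the median Prun bin)
#' @return data.frame `lag_s`, `V` ((um/s)^2), `sem`, `n_cells`
#' @export
velocity_autocorrelation <- function(trajectories, max_lag_s = 10,
                                     cells = NULL) {
  if (!is.null(cells)) {
    trajectories <- trajectories[trajectories$cell_id %in% cells, , drop = FALSE]
  }
  by_cell <- split(trajectories, trajectories$cell_id)
  dt <- NULL
  acfs <- list(); weights <- c(); skipped <- 0L
  for (df in by_cell) {
    n <- nrow(df)
    if (n < 4) { skipped <- skipped + 1L; next }
    dt_i <- df$time_s[2] - df$time_s[1]
    if (is.null(dt)) dt <- dt_i
    K <- min(floor(max_lag_s / dt_i), n - 2)
    if (K < 2) { skipped <- skipped + 1L; next }
    a <- acf(df$vx_um_s, lag.max = K, type = "covariance",
             demean = FALSE, plot = FALSE)$acf[, 1, 1]
    a <- a * n / (n - seq(0, K))   # undo the 1/n normalization bias
    acfs[[length(acfs) + 1]] <- a
    weights <- c(weights, n * dt_i)
  }
  if (skipped > 0) message(skipped, " trajectories too short for the lag grid; skipped")
  if (!length(acfs)) stop("no trajectories long enough for the autocorrelation")
  Kmax <- max(lengths(acfs)) - 1
  lag_s <- seq(0, Kmax) * dt
  V <- sem <- nc <- numeric(Kmax + 1)
  for (k in seq(0, Kmax)) {
    have <- which(lengths(acfs) > k)
    vals <- vapply(have, function(i) acfs[[i]][k + 1], numeric(1))
    w <- weights[have]
    m <- sum(w * vals) / sum(w)
    V[k + 1] <- m
    nc[k + 1] <- length(have)
    sem[k + 1] <- if (length(have) > 1) {
      sqrt(sum(w^2 * (vals - m)^2) / sum(w)^2 * length(have) / (length(have) - 1))
    } else NA_real_
  }
  data.frame(lag_s = lag_s, V = V, sem = sem, n_cells = nc)
}

#' Fit a decaying exponential to a velocity autocorrelation
#'
#' MAP fit of V(t) = sigma_v^2 exp(-t / tau_v) over the lag window
#' (default 2 * dt to 10 s) with a Gaussian likelihood weighted by the
#' per-lag SEM and priors uniform in log(sigma_v2), log(tau_v);
#' uncertainties from the robust spread of posterior MCMC draws.
#'
#' @param vac [velocity_autocorrelation()] output (or any data.frame with
#'   `lag_s`, `V`, `sem`)
#' @param window fit window in lag (s); default c(2 * dt, 10)
#' @param n_steps,n_walkers MCMC budget
#' @return [`cell_fit`][prun_select] object with parameters `sigma_v2`,
#'   `tau_v`
#' @export
fit_exponential_autocorr <- function(vac, window = NULL,
                                     n_steps = 300, n_walkers = 24) {
  dt <- vac$lag_s[2] - vac$lag_s[1]
  if (is.null(window)) window <- c(2 * dt, 10)
  keep <- vac$lag_s >= window[1] & vac$lag_s <= window[2] &
    is.finite(vac$sem) & vac$sem > 0
  t <- vac$lag_s[keep]; V <- vac$V[keep]; sem <- vac$sem[keep]
  if (length(t) < 3) stop("fewer than 3 usable lags in the fit window")
  if (max(vac$V) <= 0) stop("non-positive autocorrelation at zero lag")
  log_post <- function(p) {
    sv2 <- exp(p[1]); tv <- exp(p[2])
    if (!is.finite(sv2) || !is.finite(tv) || tv > 1e4 || tv < 1e-3) return(-Inf)
    -0.5 * sum((V - sv2 * exp(-t / tv))^2 / sem^2)
  }
  pos <- V > 0
  init_tv <- if (sum(pos) > 2) {
    fitc <- coef(lm(log(V[pos]) ~ t[pos]))
    max(min(-1 / fitc[2], 100), 0.05)
  } else 1
  init <- c(log(max(max(V), 1e-6)), log(init_tv))
  map_then_sample(log_post, init, c("sigma_v2", "tau_v"), length(t),
                  n_walkers, n_steps)
}

#' Fit the biphasic kernel to an averaged step response
#'
#' MAP fit of the activity deviation after a concentration step,
#' -delta_r * G * (exp(-t/tau_2) - exp(-t/tau_1)), with Gaussian
#' likelihood (per-timepoint SEM) and log-uniform priors on (G, tau_1,
#' tau_2). A fast time below the sampling interval is not identifiable;
#' it is then reported with `tau1_pinned = TRUE` in the details and should
#' be treated as 0 downstream.
#'
#' @param time_s times since step onset (s)
#' @param response mean activity deviation at each time
#' @param sem standard error at each time
#' @param delta_r arrival-rate step size (1/s), kD * delta_c
#' @param fit_tau1 fit tau_1 (TRUE) or pin it to 0
#' @param n_steps,n_walkers MCMC budget
#' @return [`cell_fit`][prun_select] with parameters `G_r`, (`tau_1`,)
#'   `tau_2`
#' @export
fit_step_response <- function(time_s, response, sem, delta_r,
                              fit_tau1 = TRUE, n_steps = 300, n_walkers = 24) {
  stopifnot(length(time_s) == length(response), length(sem) == length(response))
  ok <- is.finite(response) & is.finite(sem) & sem > 0 & time_s >= 0
  t <- time_s[ok]; y <- response[ok]; s <- sem[ok]
  if (length(t) < 4) stop("too few usable time points")
  dt_obs <- min(diff(sort(unique(t))))
  if (fit_tau1) {
    log_post <- function(p) {
      G <- exp(p[1]); t1 <- exp(p[2]); t2 <- exp(p[3])
      if (t2 <= t1 || t2 > 1e3 || t1 < 1e-4) return(-Inf)
      m <- -delta_r * G * (exp(-t / t2) - exp(-t / t1))
      -0.5 * sum((y - m)^2 / s^2)
    }
    amp0 <- max(abs(y))
    init <- c(log(max(amp0 / delta_r, 1e-12)), log(dt_obs / 4), log(max(t[length(t)] / 3, 1)))
    fit <- map_then_sample(log_post, init, c("G_r", "tau_1", "tau_2"),
                           length(t), n_walkers, n_steps)
    fit$details$tau1_pinned <- fit$theta_map[["tau_1"]] < dt_obs
    if (fit$details$tau1_pinned) {
      message("tau_1 below the sampling interval: not identifiable, pin to 0 downstream")
    }
  } else {
    log_post <- function(p) {
      G <- exp(p[1]); t2 <- exp(p[2])
      if (t2 > 1e3 || t2 < 1e-2) return(-Inf)
      m <- -delta_r * G * exp(-t / t2)
      -0.5 * sum((y - m)^2 / s^2)
    }
    amp0 <- max(abs(y))
    init <- c(log(max(amp0 / delta_r, 1e-12)), log(max(t[length(t)] / 3, 1)))
    fit <- map_then_sample(log_post, init, c("G_r", "tau_2"),
                           length(t), n_walkers, n_steps)
    fit$details$tau1_pinned <- TRUE
  }
  fit
}

#' Kinase activity from a FRET trace
#'
#' Affine normalization a(t) = (FRET(t) - FRETmin) / (FRETmax - FRETmin)
#' using the FRET levels at minimum and maximum kinase activity measured
#' with saturating stimuli. Values outside \[0, 1\] are permitted but
#' reported via the `"outside_fraction"` attribute.
#'
#' @param fret FRET signal series
#' @param fret_min FRET level at minimum kinase activity
#' @param fret_max FRET level at maximum kinase activity (> fret_min)
#' @return activity series in activity units
#' @export
normalize_activity <- function(fret, fret_min, fret_max) {
  if (!(fret_max > fret_min)) stop("degenerate FRET range: fret_max must exceed fret_min")
  a <- (fret - fret_min) / (fret_max - fret_min)
  attr(a, "outside_fraction") <- mean(a < 0 | a > 1)
  a
}

#' Fit slow-noise parameters to a constant-background activity trace
#'
#' Marginal likelihood of (D_n, tau_n, measurement-noise variance) for the
#' model a(t) = a0 + OU(D_n, tau_n) + white measurement noise, computed by
#' recursive Gaussian (Kalman) filtering of the discretized OU process;
#' MAP and MCMC-draw uncertainties as in the other fits. The trace is
#' demeaned; a linear trend exceeding 3 sigma is flagged as
#' non-stationary.
#'
#' @param activity activity trace (numeric)
#' @param dt sampling interval (s)
#' @param n_steps,n_walkers MCMC budget
#' @return [`cell_fit`][prun_select] with parameters `D_n`, `tau_n`,
#'   `sigma_m2`
#' @export
fit_noise_params <- function(activity, dt = 1, n_steps = 300, n_walkers = 24) {
  y <- as.numeric(activity)
  if (anyNA(y)) stop("activity contains NA")
  n <- length(y)
  if (n < 50) stop("trace too short for noise-parameter inference")
  tt <- seq_len(n) * dt
  tr <- summary(lm(y ~ tt))$coefficients
  # crude flag only: slow OU wander mimics trends, so ask for a drift that
  # is both formally significant and large against the fluctuation scale
  nonstationary <- abs(tr[2, 1] / tr[2, 2]) > 3 &&
    abs(tr[2, 1]) * (n * dt) > 1.5 * sd(y)
  if (nonstationary) warning("linear trend exceeds 3 sigma: trace may be non-stationary")
  y <- y - mean(y)
  v <- var(y)
  log_post <- function(p) {
    Dn <- exp(p[1]); tn <- exp(p[2]); r <- exp(p[3])
    # tau_n is the slow-fluctuation time scale: components faster than the
    # sampling interval are measurement noise by definition
    if (tn < 2 * dt || tn > 1e4 || Dn > 1e2 || r > 1e2) return(-Inf)
    phi <- exp(-dt / tn)
    q <- Dn * tn * (1 - phi^2)
    cpp_ou_loglik(y, phi, q, r)
  }
  inits <- list(c(log(max(v * 0.8, 1e-8) / 10), log(10), log(max(v * 0.2, 1e-8))),
                c(log(max(v * 0.5, 1e-8) / 3), log(3), log(max(v * 0.5, 1e-8))),
                c(log(max(v * 0.9, 1e-8) / 30), log(30), log(max(v * 0.1, 1e-8))))
  # crude multi-start, then polish the best
  lp <- vapply(inits, log_post, numeric(1))
  init <- inits[[which.max(lp)]]
  fit <- map_then_sample(log_post, init, c("D_n", "tau_n", "sigma_m2"),
                         n, n_walkers, n_steps)
  fit$details$nonstationary <- nonstationary
  fit
}

#' Robust population summary of single-cell estimates
#'
#' Population medians of the per-cell MAP estimates, with squared
#' uncertainty combining cell-to-cell variation and single-cell
#' uncertainty:
#' sigma^2 = (1/N) (1.4826 mad(theta_MAP))^2 + (1/N^2) sum_k sigma_k^2.
#'
#' @param fits list of [`cell_fit`][prun_select] objects sharing parameter
#'   names
#' @return data.frame of class `population_summary`: `parameter`,
#'   `median`, `sigma` (standard error of the median), `n_cells`
#' @export
population_summary <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "cell_fit")))
  params <- names(fits[[1]]$theta_map)
  th <- do.call(rbind, lapply(fits, function(f) f$theta_map[params]))
  sg <- do.call(rbind, lapply(fits, function(f) f$sigma_theta[params]))
  N <- nrow(th)
  out <- data.frame(parameter = params,
                    median = apply(th, 2, median),
                    sigma = sqrt(apply(th, 2, function(x) mad(x, constant = 1.4826))^2 / N +
                                   colSums(sg^2) / N^2),
                    n_cells = N)
  rownames(out) <- NULL
  class(out) <- c("population_summary", "data.frame")
  out
}

#' Fit the MWC gain model across backgrounds
#'
#' Least-squares fit, in log space, of the background dependence of the
#' arrival-rate gain: kD * Gr = G_inf / (c0 + K_i). Logarithms give the
#' order-of-magnitude-smaller gains equal weight. Deterministic
#' multi-start optimization over a log grid.
#'
#' @param gains data.frame with columns `c0` (uM) and `kD_Gr`
#'   (dimensionless, kD times the fitted gain)
#' @return [mwc_gain] with attributes `fitted` (predicted kD_Gr) and
#'   `sse` (sum of squared log errors)
#' @export
fit_mwc <- function(gains) {
  stopifnot(all(c("c0", "kD_Gr") %in% names(gains)))
  if (nrow(gains) < 2) stop("need gains at two or more backgrounds")
  if (any(gains$kD_Gr <= 0) || any(gains$c0 <= 0)) stop("gains and c0 must be positive")
  obj <- function(p) {
    sum((log(gains$kD_Gr) - (p[1] - log(gains$c0 + exp(p[2]))))^2)
  }
  starts <- expand.grid(lG = log(max(gains$kD_Gr) * c(0.5, 2, 10) * max(gains$c0)),
                        lK = log(c(0.01, 0.1, 1, 10) * stats::median(gains$c0)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS", control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  out <- mwc_gain(G_inf = exp(best$par[1]), K_i = exp(best$par[2]))
  attr(out, "fitted") <- out$G_inf / (gains$c0 + out$K_i)
  attr(out, "sse") <- best$value
  out
}
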