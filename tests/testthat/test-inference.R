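# helper: build a trajectory table with exact run fractions and >= 2 tumbles
make_prun_table <- function(prun, n = 1000, dt = 0.05) {
  do.call(rbind, lapply(seq_along(prun), function(i) {
    n_run <- round(n * prun[i])
    n_tum <- n - n_run
    h1 <- ceiling(n_tum / 2); h2 <- n_tum - h1
    states <- c(rep("run", ceiling(n_run / 2)), rep("tumble", h1),
                rep("run", floor(n_run / 2)), rep("tumble", h2))
    data.frame(cell_id = i, time_s = seq_len(n) * dt - dt,
               vx_um_s = 0, state = states)
  }))
}

test_that("Prun binning keeps the median bin and discards tumble-poor cells", {
  # identical cells: everyone is in the median bin
  tab <- make_prun_table(rep(0.8, 5))
  sel <- prun_select(tab)
  expect_equal(sort(sel$selected), 1:5)
  expect_equal(sel$median_prun, 0.8)

  # cells with fewer than two tumbles are dropped
  one_tumble <- data.frame(cell_id = 99, time_s = seq_len(100) * 0.05 - 0.05,
                           vx_um_s = 0,
                           state = c(rep("run", 90), rep("tumble", 10)))
  sel2 <- prun_select(rbind(tab, one_tumble))
  expect_false(99 %in% sel2$cells$cell_id)

  # known Prun spread: selected fraction equals the window mass
  prun <- seq(0.60, 0.90, by = 0.002)
  tab3 <- make_prun_table(prun)
  sel3 <- prun_select(tab3, window = 0.01)
  realized <- round(1000 * prun) / 1000   # run fraction actually emitted
  expected <- which(abs(realized - median(realized)) <= 0.01)
  expect_equal(sort(sel3$selected), expected)
})

test_that("weight hook shifts the weighted median", {
  prun <- c(0.6, 0.7, 0.8)
  tab <- make_prun_table(prun)
  w <- c("1" = 10, "2" = 1, "3" = 1)
  sel <- prun_select(tab, weights = w)
  expect_equal(sel$median_prun, 0.6)
})

test_that("velocity autocorrelation reduces to the single-cell estimate", {
  set.seed(11)
  n <- 400
  vx <- as.numeric(arima.sim(list(ar = 0.9), n)) * 5
  tab <- data.frame(cell_id = 1, time_s = seq_len(n) * 0.05 - 0.05,
                    vx_um_s = vx)
  vac <- velocity_autocorrelation(tab, max_lag_s = 2)
  k <- 7
  manual <- sum(vx[1:(n - k)] * vx[(1 + k):n]) / (n - k)
  expect_equal(vac$V[k + 1], manual, tolerance = 1e-12)
  expect_true(all(is.na(vac$sem)))  # one cell: no ensemble spread

  # white-noise velocity decorrelates immediately
  set.seed(12)
  tabw <- do.call(rbind, lapply(1:40, function(i) {
    data.frame(cell_id = i, time_s = seq_len(200) * 0.05 - 0.05,
               vx_um_s = rnorm(200, sd = 3))
  }))
  vw <- velocity_autocorrelation(tabw, max_lag_s = 2)
  expect_true(all(abs(vw$V[-1]) < 4 * vw$sem[-1]))
  expect_equal(vw$V[1], 9, tolerance = 0.15)
})

test_that("exponential autocorrelation fit recovers exact inputs and scales", {
  t <- seq(0, 8, by = 0.05)
  V <- 150 * exp(-t / 1.3)
  vac <- data.frame(lag_s = t, V = V, sem = rep(1e-4, length(t)))
  set.seed(5)
  fit <- fit_exponential_autocorr(vac, n_steps = 80)
  expect_equal(coef(fit)[["sigma_v2"]], 150, tolerance = 1e-3)
  expect_equal(coef(fit)[["tau_v"]], 1.3, tolerance = 1e-3)
  expect_true(all(fit$sigma_theta > 0))
  # doubling V doubles sigma_v2, leaves tau_v unchanged
  vac2 <- vac; vac2$V <- 2 * vac2$V
  fit2 <- fit_exponential_autocorr(vac2, n_steps = 80)
  expect_equal(coef(fit2)[["sigma_v2"]] / coef(fit)[["sigma_v2"]], 2,
               tolerance = 1e-3)
  expect_equal(coef(fit2)[["tau_v"]], coef(fit)[["tau_v"]], tolerance = 1e-3)
  # degenerate input rejected
  vac3 <- vac; vac3$V <- -vac3$V
  expect_error(fit_exponential_autocorr(vac3), "non-positive")
})

test_that("step-response fit recovers kernel parameters", {
  t <- seq(0, 30, by = 0.75)
  delta_r <- 1.2e4
  kin_true <- kinase_params(G_r = 1.9e-5, tau_1 = 1.5, tau_2 = 9,
                            D_n = 1e-4, tau_n = 8.7)
  y <- step_response(t, kin_true, delta_r)
  set.seed(6)
  fit <- fit_step_response(t, y, rep(1e-5, length(t)), delta_r, n_steps = 100)
  expect_equal(coef(fit)[["G_r"]], 1.9e-5, tolerance = 0.01)
  expect_equal(coef(fit)[["tau_1"]], 1.5, tolerance = 0.02)
  expect_equal(coef(fit)[["tau_2"]], 9, tolerance = 0.02)
  expect_false(fit$details$tau1_pinned)

  # an unresolvably fast lobe is flagged for pinning to zero
  kin0 <- kinase_params(G_r = 1.9e-5, tau_1 = 0, tau_2 = 9,
                        D_n = 1e-4, tau_n = 8.7)
  y0 <- step_response(t, kin0, delta_r) + 1e-4 * rnorm(length(t))
  expect_message(
    fit0 <- fit_step_response(t, y0, rep(1e-3, length(t)), delta_r,
                              n_steps = 60),
    "not identifiable")
  expect_true(fit0$details$tau1_pinned)
  # pinned fit recovers the slow lobe cleanly
  fitp <- fit_step_response(t, y0, rep(1e-3, length(t)), delta_r,
                            fit_tau1 = FALSE, n_steps = 60)
  expect_equal(coef(fitp)[["tau_2"]], 9, tolerance = 0.1)
})

test_that("activity normalization is the stated affine rescale", {
  expect_equal(as.numeric(normalize_activity(rep(2, 5), 2, 4)), rep(0, 5))
  expect_equal(as.numeric(normalize_activity(rep(4, 5), 2, 4)), rep(1, 5))
  expect_equal(as.numeric(normalize_activity(3, 2, 4)), 0.5)
  expect_error(normalize_activity(1, 4, 4), "degenerate")
  out <- normalize_activity(c(1, 3, 5), 2, 4)
  expect_equal(attr(out, "outside_fraction"), 2 / 3)
})

test_that("noise-parameter fit recovers an OU + measurement-noise trace", {
  set.seed(31)
  kin <- kinase_params(G_r = 2e-5, tau_1 = 0, tau_2 = 7.4,
                       D_n = 8.1e-4, tau_n = 8.7)
  dat <- gen_noise_traces(n_cells = 1, kin = kin, duration_s = 1200, dt = 1,
                          cv = 0, sigma_m = 0.01, seed = 31)
  tr <- dat$traces
  fit <- fit_noise_params(tr$activity, dt = 1, n_steps = 150)
  expect_lt(abs(coef(fit)[["D_n"]] - 8.1e-4), 3 * fit$sigma_theta[["D_n"]])
  expect_lt(abs(coef(fit)[["tau_n"]] - 8.7), 3 * fit$sigma_theta[["tau_n"]])

  # pure white noise: the slow-noise component collapses
  set.seed(32)
  fitw <- fit_noise_params(0.3 + 0.02 * rnorm(1200), dt = 1, n_steps = 100)
  ou_var <- coef(fitw)[["D_n"]] * coef(fitw)[["tau_n"]]
  expect_lt(ou_var, 0.2 * 0.02^2)
})

test_that("population summary implements the robust two-term uncertainty", {
  mk <- function(theta, sigma) {
    new_cell_fit(c(x = theta), c(x = sigma), matrix(theta, 1, 1,
                                                    dimnames = list(NULL, "x")), 10)
  }
  # identical cells: cell-to-cell term vanishes
  fits <- lapply(1:5, function(i) mk(2, 0.3))
  ps <- population_summary(fits)
  expect_equal(ps$median, 2)
  expect_equal(ps$sigma^2, 0.3^2 / 5)
  # permutation invariance
  set.seed(41)
  fits2 <- lapply(rnorm(9, 5), function(m) mk(m, 0.1))
  p1 <- population_summary(fits2)
  p2 <- population_summary(rev(fits2))
  expect_equal(p1$median, p2$median)
  expect_equal(p1$sigma, p2$sigma)
  # Gaussian calibration: 1.4826 * mad ~ sd at N = 100
  set.seed(1)
  th <- rnorm(100)
  expect_equal(mad(th, constant = 1.4826), sd(th), tolerance = 0.1)
  # adding a median cell with tiny uncertainty does not increase sigma
  p3 <- population_summary(c(fits2, list(mk(p1$median, 1e-6))))
  expect_lte(p3$sigma, p1$sigma * (1 + 1e-9))
})

test_that("MWC gain fit recovers exact and printed gain tables", {
  # exact generation: exact recovery
  truth <- mwc_gain(G_inf = 3.5, K_i = 0.81)
  c0 <- c(0.1, 1, 10)
  tab <- data.frame(c0 = c0, kD_Gr = truth$G_inf / (c0 + truth$K_i))
  fit <- fit_mwc(tab)
  expect_equal(fit$G_inf, 3.5, tolerance = 1e-6)
  expect_equal(fit$K_i, 0.81, tolerance = 1e-6)

  # printed (rounded) population medians: K_i in the vicinity of 0.81 uM
  printed <- data.frame(c0 = c(0.1, 1, 10), kD_Gr = c(3.2, 2.28, 0.251))
  fitp <- fit_mwc(printed)
  expect_gt(fitp$K_i, 0.3)
  expect_lt(fitp$K_i, 1.8)
  expect_gt(fitp$G_inf, 2)
  expect_lt(fitp$G_inf, 6)

  # two points: the saturated system is solved exactly
  two <- printed[c(1, 3), ]
  fit2 <- fit_mwc(two)
  K_exact <- (3.2 * 0.1 - 0.251 * 10) / (0.251 - 3.2)
  G_exact <- 3.2 * (0.1 + K_exact)
  expect_equal(fit2$K_i, K_exact, tolerance = 1e-5)
  expect_equal(fit2$G_inf, G_exact, tolerance = 1e-5)
  expect_error(fit_mwc(printed[1, , drop = FALSE]), "two or more")
})
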