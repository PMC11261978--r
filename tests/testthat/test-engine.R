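test_that("arrival channel is the OU-signal/integrated-log-concentration model", {
  sw <- med$swim; sw$g <- 0.1
  ch <- build_arrival_channel(sw, med$constants)
  ss2 <- (0.1e-3)^2 * sw$sigma_v2
  # OU construction: stationary prior variance of s
  expect_equal(ch$process_noise[1, 1] * sw$tau_v / 2, ss2)
  expect_equal(ch$signal_var, ss2)
  expect_equal(ch$obs_noise, med$constants$kD * sw$c0)
  # no gradient: the observation carries no signal
  sw0 <- med$swim; sw0$g <- 0
  p0 <- stationary_posterior(build_arrival_channel(sw0, med$constants))
  expect_equal(p0$P_ss, 0)
  expect_equal(p0$rho2, 0)
  # no arrivals at c0 = 0
  swc <- med$swim; swc$c0 <- 0
  expect_error(build_arrival_channel(swc, med$constants), "c0")
  # Gaussian approximation warning at low arrival numbers
  swlow <- med$swim; swlow$c0 <- 1e-5
  expect_warning(build_arrival_channel(swlow, med$constants), "Gaussian")
})

test_that("stationary posterior approaches the small-signal closed form", {
  r0 <- med$constants$kD * 1
  g_tiny <- sqrt(1e-6 / (2 * r0 * 146 * 1.19^3)) * 1e3  # gamma_r = 1e-6
  sw <- med$swim; sw$g <- g_tiny
  post <- stationary_posterior(build_arrival_channel(sw, med$constants))
  expect_equal(post$rho2 / (1e-6 / 4), 1, tolerance = 0.01)
})

test_that("an uninformative channel returns the prior", {
  sw <- med$swim; sw$g <- 0.1
  ch <- build_arrival_channel(sw, med$constants)
  ch$obs_noise <- ch$obs_noise * 1e12
  post <- stationary_posterior(ch)
  expect_equal(post$P_ss / ch$signal_var, 1, tolerance = 1e-5)
  expect_lt(post$rho2, 1e-5)
})

test_that("engine agrees with the brute-force discrete filter to <0.5%", {
  for (g in c(0.05, 0.4)) {
    sw <- med$swim; sw$g <- g
    ch_r <- build_arrival_channel(sw, med$constants)
    ch_a <- build_kinase_channel(sw, med$kin, med$constants)
    for (ch in list(ch_r, ch_a)) {
      P_engine <- stationary_posterior(ch)$P_ss
      P_oracle <- discrete_filter_oracle(ch, dt = 1e-3 * sw$tau_v)
      expect_lt(abs(P_oracle / P_engine - 1), 0.005)
    }
  }
})

test_that("kinase channel reduces to the arrival channel as internal noise vanishes", {
  sw <- med$swim; sw$g <- 0.1
  I_r <- predictive_info_rate(stationary_posterior(build_arrival_channel(sw, med$constants)))
  kin_tiny <- med$kin; kin_tiny$D_n <- med$kin$D_n * 1e-6
  I_tiny <- predictive_info_rate(stationary_posterior(
    build_kinase_channel(sw, kin_tiny, med$constants)))
  expect_equal(I_tiny / I_r, 1, tolerance = 0.01)
  # exactly zero noise (flagged ideal-sensor limit, noise state dropped)
  kin0 <- med$kin; kin0$D_n <- 0
  expect_error(build_kinase_channel(sw, kin0, med$constants), "allow_zero_noise")
  I_0 <- predictive_info_rate(stationary_posterior(
    build_kinase_channel(sw, kin0, med$constants, allow_zero_noise = TRUE)))
  expect_equal(I_0 / I_r, 1, tolerance = 0.01)
  # eta -> 1 for the ideal sensor
  expect_equal(info_rates(sw, kin0, med$constants)$eta, 1, tolerance = 0.01)
  # zero gain carries no information
  kinG <- med$kin; kinG$G_r <- 0
  expect_equal(info_rates(sw, kinG, med$constants)$I_a, 0)
  # the engine requires the delta-lobe convention
  kin1 <- med$kin; kin1$tau_1 <- 0.5
  expect_error(build_kinase_channel(sw, kin1, med$constants), "tau_1")
})

test_that("predictive information rate follows the Gaussian lag identity", {
  sw <- med$swim; sw$g <- 0.2
  post <- stationary_posterior(build_arrival_channel(sw, med$constants))
  rate <- predictive_info_rate(post)
  expect_equal(rate, post$rho2 / (1 - post$rho2) / sw$tau_v)
  # finite-difference check on I(tau)
  h <- 1e-4
  fd <- (predictive_info_lagged(post, 0) - predictive_info_lagged(post, h)) / h
  expect_equal(fd / rate, 1, tolerance = 1e-3)
  # rho2 = 0 gives zero rate
  sw0 <- med$swim; sw0$g <- 0
  expect_equal(predictive_info_rate(stationary_posterior(
    build_arrival_channel(sw0, med$constants))), 0)
  # small-rho2 expansion: rate ~ rho2 / tau_v to second order
  r0 <- med$constants$kD
  g_tiny <- sqrt(1e-5 / (2 * r0 * 146 * 1.19^3)) * 1e3
  swt <- med$swim; swt$g <- g_tiny
  pt <- stationary_posterior(build_arrival_channel(swt, med$constants))
  expect_equal(predictive_info_rate(pt) * swt$tau_v / pt$rho2, 1,
               tolerance = 2 * pt$rho2)
})

test_that("eta sits on a g-independent plateau in vanishing gradients", {
  e <- eta(med$swim, med$kin, med$constants, g0 = TRUE)
  expect_true(is.finite(e) && e > 0 && e < 1)
  # direct two-point convergence check
  s1 <- med$swim; s1$g <- 1e-4
  s2 <- med$swim; s2$g <- 1e-5
  e1 <- info_rates(s1, med$kin, med$constants)$eta
  e2 <- info_rates(s2, med$kin, med$constants)$eta
  expect_lt(abs(e1 / e2 - 1), 0.01)
  expect_error(eta(med$swim, med$kin, med$constants), "g > 0")
})

test_that("data processing inequality holds across the parameter grid", {
  ok <- TRUE
  worst <- 0
  for (c0 in 10^seq(-1, 1, length.out = 5)) {
    for (g in c(0.05, 0.1, 0.2, 0.3, 0.4)) {
      for (fac in 10^seq(-1, 1, length.out = 5)) {
        sw <- med$swim; sw$c0 <- c0; sw$g <- g
        kin <- med$kin; kin$D_n <- med$kin$D_n * fac
        ir <- info_rates(sw, kin, med$constants)
        worst <- max(worst, ir$I_a - ir$I_r)
        ok <- ok && (ir$I_a <= ir$I_r + 1e-12)
      }
    }
  }
  expect_true(ok)
  expect_lte(worst, 1e-12)
})

test_that("information rates are monotone in gain, noise, background and gradient", {
  base <- function(mod = list()) {
    sw <- med$swim; sw$g <- 0.1
    kin <- med$kin
    for (nm in names(mod)) {
      if (nm %in% names(kin)) kin[[nm]] <- mod[[nm]] else sw[[nm]] <- mod[[nm]]
    }
    info_rates(sw, kin, med$constants)
  }
  # I_a non-decreasing in G_r
  Ia <- vapply(med$kin$G_r * c(0.25, 0.5, 1, 2, 4),
               function(G) base(list(G_r = G))$I_a, numeric(1))
  expect_true(all(diff(Ia) >= -1e-15))
  # I_a non-increasing in D_n
  Ia2 <- vapply(med$kin$D_n * c(0.1, 0.5, 1, 5, 10),
                function(D) base(list(D_n = D))$I_a, numeric(1))
  expect_true(all(diff(Ia2) <= 1e-15))
  # I_r strictly increasing in c0 and g
  Ir_c <- vapply(c(0.1, 0.5, 1, 5, 10), function(c0) base(list(c0 = c0))$I_r,
                 numeric(1))
  expect_true(all(diff(Ir_c) > 0))
  Ir_g <- vapply(c(0.05, 0.1, 0.2, 0.4), function(g) base(list(g = g))$I_r,
                 numeric(1))
  expect_true(all(diff(Ir_g) > 0))
})

test_that("error propagation matches the analytic chain rule and scales eta", {
  th <- c(a = 3, b = 5)
  sg <- c(0.1, 0.2)
  expect_equal(error_propagation(function(t) t[["a"]], th, sg), 0.01,
               tolerance = 1e-6)
  expect_equal(error_propagation(function(t) t[["a"]] * t[["b"]], th, sg),
               5^2 * 0.1^2 + 3^2 * 0.2^2, tolerance = 1e-6)
  # uncertainty of eta at the measured background, printed parameter SEMs:
  # order of the printed +/- 0.002
  f <- function(t) {
    sw <- swim_params(sigma_v2 = t[["sigma_v2"]], tau_v = t[["tau_v"]],
                      g = 1e-4, c0 = 1)
    kin <- kinase_params(G_r = t[["GkD"]] / med$constants$kD,
                         tau_2 = t[["tau_2"]], D_n = t[["D_n"]],
                         tau_n = t[["tau_n"]])
    info_rates(sw, kin, med$constants)$eta
  }
  th <- c(sigma_v2 = 146, tau_v = 1.19, GkD = 2.28, tau_2 = 7.4,
          D_n = 8.1e-4, tau_n = 8.7)
  sg <- c(5, 0.01, 0.05, 0.3, 0.9e-4, 0.9)
  sd_eta <- sqrt(error_propagation(f, th, sg, rel_step = 1e-4))
  expect_gt(sd_eta, 2e-4)
  expect_lt(sd_eta, 2e-2)
})
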