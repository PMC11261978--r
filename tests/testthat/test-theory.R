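test_that("gamma_r reproduces the shallow-gradient SNR and its scalings", {
  sw <- swim_params(sigma_v2 = 146, tau_v = 1.19, g = 0.05, c0 = 1)
  pc <- physical_constants(kD = 1.2e5)
  expect_equal(signif(gamma_r(sw, pc), 2), 0.15)
  sw0 <- sw; sw0$g <- 0
  expect_equal(gamma_r(sw0, pc), 0)
  sw2 <- sw; sw2$g <- 0.1
  expect_equal(gamma_r(sw2, pc), 4 * gamma_r(sw, pc))
})

test_that("gamma_a follows its definition and flags the ideal sensor", {
  pc <- physical_constants(kD = 1.2e5)
  sw <- swim_params(sigma_v2 = 146, tau_v = 1.19, g = 0.01, c0 = 1)
  kin <- kinase_params(G_r = 2.28 / 1.2e5, tau_2 = 7.4, D_n = 8.1e-4, tau_n = 8.7)
  # hand arithmetic: 2.28^2 * (1e-5)^2 * 146 * 1.19 / 8.1e-4
  expect_equal(gamma_a(sw, kin, pc), 1.1149e-4, tolerance = 1e-3)
  kin0 <- kin; kin0$D_n <- 0
  expect_identical(gamma_a(sw, kin0, pc), Inf)
  sw0 <- sw; sw0$g <- 0
  expect_equal(gamma_a(sw0, kin, pc), 0)
  expect_equal(gamma_a(sw0, kin0, pc), 0)
})

test_that("small-signal information rates obey their limits and units", {
  expect_equal(info_rate_physical_smallsignal(0.15, 1.19), 0.0315126,
               tolerance = 1e-6)
  expect_equal(info_rate_physical_smallsignal(0, 1), 0)
  expect_equal(info_rate_physical_smallsignal(0.1, 0.5),
               2 * info_rate_physical_smallsignal(0.1, 1))
  expect_warning(info_rate_physical_smallsignal(0.6, 1), "validity")
  # bits conversion
  expect_equal(info_rate_physical_smallsignal(0.1, 1, bits = TRUE),
               0.025 / log(2))

  # kinase rate: ideal-sensor limit equals the physical limit
  expect_equal(info_rate_kinase_smallsignal(0.15, Inf, 1.19),
               info_rate_physical_smallsignal(0.15, 1.19))
  expect_equal(info_rate_kinase_smallsignal(0, 1, 1), 0)
  expect_equal(info_rate_kinase_smallsignal(1, 0, 1), 0)
  expect_equal(info_rate_kinase_smallsignal(1, 1, 1), 1 / 16)
  expect_equal(info_rate_kinase_smallsignal(1, 1, 1, form = "interpolating"),
               1 / 8)
  # monotone convergence to the physical limit as gamma_a grows
  ga <- 10^seq(-2, 6, by = 1)
  rates <- info_rate_kinase_smallsignal(0.1, ga, 1.19)
  expect_true(all(diff(rates) > 0))
  expect_lt(abs(rates[length(ga)] / info_rate_physical_smallsignal(0.1, 1.19) - 1),
            1e-5)
  # interpolating form has the stated internal-noise-dominated limit
  expect_equal(info_rate_kinase_smallsignal(1e3, 1e-3, 1, form = "interpolating"),
               1e-3 / 4, tolerance = 1e-5)
})

test_that("small-signal eta is independent of gradient steepness", {
  pc <- physical_constants(kD = 1.2e5)
  kin <- kinase_params(G_r = 2.28 / 1.2e5, tau_2 = 7.4, D_n = 8.1e-4, tau_n = 8.7)
  eta_ss <- function(g) {
    sw <- swim_params(sigma_v2 = 146, tau_v = 1.19, g = g, c0 = 1)
    gr <- gamma_r(sw, pc); ga <- gamma_a(sw, kin, pc)
    info_rate_kinase_smallsignal(gr, ga, 1.19) /
      info_rate_physical_smallsignal(gr, 1.19)
  }
  expect_lt(abs(eta_ss(0.001) / eta_ss(0.01) - 1), 1e-10)
})

test_that("MWC gain has the saturating background dependence", {
  pc <- physical_constants(kD = 1.2e5)
  mwc <- mwc_gain(G_inf = 3.5, K_i = 0.81)
  # at c0 = K_i the gain G(c0) = kD * Gr * c0 is half its asymptote
  expect_equal(mwc_gain_Gr(0.81, mwc, pc) * pc$kD * 0.81, 3.5 / 2)
  # log-sensing regime: Gr ~ G_inf / r0
  c_hi <- 0.81 * 1e4
  expect_equal(mwc_gain_Gr(c_hi, mwc, pc), 3.5 / (pc$kD * c_hi),
               tolerance = 1e-3)
  expect_equal(mwc_gain_Gr(10, mwc, pc) * pc$kD, 3.5 / 10.81, tolerance = 1e-9)
  expect_error(mwc_gain_Gr(0, mwc, pc), "c0 > 0")
})

test_that("response kernel adapts perfectly and has the right short-time lobe", {
  kin <- kinase_params(G_r = 2e-5, tau_1 = 0.4, tau_2 = 7.4,
                       D_n = 8.1e-4, tau_n = 8.7)
  t <- seq(0, 200, by = 1e-3)
  ker <- response_kernel(t, kin)
  expect_equal(pracma::trapz(t, ker), 0, tolerance = 1e-6 * kin$G_r)
  expect_equal(ker[1], kin$G_r * (1 / 0.4 - 1 / 7.4))
  expect_true(all(response_kernel(c(-1, -0.1), kin) == 0))
  expect_error(kinase_params(G_r = 1, tau_1 = 8, tau_2 = 7.4,
                             D_n = 1e-4, tau_n = 8.7), "tau_2")
  # delta-lobe convention at tau_1 = 0
  kin0 <- kinase_params(G_r = 2e-5, tau_1 = 0, tau_2 = 7.4,
                        D_n = 8.1e-4, tau_n = 8.7)
  ker0 <- response_kernel(t, kin0)
  expect_equal(attr(ker0, "delta_weight"), 2e-5)
  expect_equal(pracma::trapz(t, ker0) + attr(ker0, "delta_weight"), 0,
               tolerance = 1e-6 * kin0$G_r)
})

test_that("step response is biphasic: fast drop then slow recovery to baseline", {
  kin <- kinase_params(G_r = 2e-5, tau_1 = 0.4, tau_2 = 7.4,
                       D_n = 8.1e-4, tau_n = 8.7)
  delta_r <- 1.2e4
  t <- seq(0, 150, by = 0.01)
  resp <- step_response(t, kin, delta_r)
  expect_lt(min(resp), -0.1)             # fast drop
  expect_gt(which.min(resp), 2)          # reached after onset
  expect_equal(resp[length(resp)], 0, tolerance = 1e-8)  # adaptation
  # convolving the kernel with a step in r reproduces it
  ker <- response_kernel(t, kin)
  conv <- -delta_r * pracma::cumtrapz(t, ker)
  expect_lt(max(abs(conv - resp)), 1e-3 * max(abs(resp)))
  # a constant shift in r leaves no asymptotic activity change
  expect_lt(abs(step_response(20 * kin$tau_2, kin, delta_r)), 1e-8)
})

test_that("noise autocorrelation is a symmetric exponential with variance Dn*tau_n", {
  kin <- kinase_params(G_r = 2e-5, tau_1 = 0, tau_2 = 7.4,
                       D_n = 8.1e-4, tau_n = 8.7)
  expect_equal(noise_autocorrelation(0, kin), 7.047e-3, tolerance = 1e-4)
  expect_equal(noise_autocorrelation(3.2, kin), noise_autocorrelation(-3.2, kin))
  expect_equal(noise_autocorrelation(8.7, kin), noise_autocorrelation(0, kin) / exp(1))
})

test_that("PSD decomposition has the stated limits and integrates to the variances", {
  p <- med
  sw <- p$swim; sw$c0 <- 1
  kin <- p$kin
  psd0 <- psd_decomposition(0, sw, kin, p$constants)
  expect_equal(psd0$slow_noise, 2 * kin$D_n * kin$tau_n^2)
  expect_equal(psd0$filtered_arrival, 0)
  # tau_1 = 0: high-frequency plateau of the filtered-arrival PSD
  r0 <- p$constants$kD * sw$c0
  psd_hi <- psd_decomposition(1e4, sw, kin, p$constants)
  expect_equal(psd_hi$filtered_arrival, kin$G_r^2 * r0, tolerance = 1e-6)
  # integral of the slow-noise PSD over omega/2pi equals Dn*tau_n
  f <- function(w) 2 * kin$D_n * kin$tau_n^2 / (1 + w^2 * kin$tau_n^2)
  I <- 2 * integrate(f, 0, Inf, rel.tol = 1e-10)$value / (2 * pi)
  expect_equal(I, kin$D_n * kin$tau_n, tolerance = 1e-3)
  psd_num <- psd_decomposition(10^seq(-4, 4, by = 0.001), sw, kin, p$constants)
  I_num <- pracma::trapz(psd_num$omega, psd_num$slow_noise) / pi
  expect_equal(I_num, kin$D_n * kin$tau_n, tolerance = 1e-3)
  # slow internal noise dominates at experimentally observable frequencies
  obs <- psd_decomposition(10^seq(-3, 0, by = 0.1), sw, kin, p$constants)
  expect_true(all(obs$slow_noise > obs$filtered_arrival))
})
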