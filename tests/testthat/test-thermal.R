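test_that("fit_arrhenius matches a reference weighted lm() on the ln scale", {
  set.seed(41)
  Tv <- seq(280, 360, 10)
  Rg <- ns_constants()$Rgas
  g <- 7.4 * exp(-8 / (Rg * Tv)) * (1 + rnorm(length(Tv), 0, 0.02))
  sig <- 0.02 * g
  f <- fit_arrhenius(Tv, g, sig, sign_mode = "rate")
  ref <- lm(log(g) ~ I(1 / Tv), weights = (g / sig)^2)
  expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-9)
  expect_equal(f$ea_kJ, -unname(coef(ref)[2]) * Rg, tolerance = 1e-9)
  expect_equal(f$ea_se_kJ,
               unname(sqrt(diag(vcov(ref)))[2]) * Rg, tolerance = 1e-6)
  expect_equal(f$ea_kcal, f$ea_kJ / 4.184, tolerance = 1e-12)
})

test_that("Arrhenius recovery is exact on noiseless data for both sign modes", {
  Tv <- seq(280, 360, 10)
  Rg <- ns_constants()$Rgas
  fr <- fit_arrhenius(Tv, 7.4 * exp(-8 / (Rg * Tv)), sign_mode = "rate")
  expect_equal(fr$ea_kJ, 8, tolerance = 1e-9)
  expect_equal(fr$prefactor, 7.4, tolerance = 1e-9)
  ft <- fit_arrhenius(Tv, 0.04 * exp(10 / (Rg * Tv)), sign_mode = "time")
  expect_equal(ft$ea_kJ, 10, tolerance = 1e-9)
  expect_equal(predict(ft, Tv), 0.04 * exp(10 / (Rg * Tv)),
               tolerance = 1e-9)
})

test_that("noiseless VFT parameters are recovered", {
  Tv <- seq(283, 363, 10)
  tau <- 0.1 * exp(5 * 150 / (Tv - 150))
  f <- fit_vft(Tv, tau)
  expect_equal(f$tau0, 0.1, tolerance = 1e-2)
  expect_equal(f$d_strength, 5, tolerance = 1e-2)
  expect_equal(f$t0, 150, tolerance = 0.5)
  expect_equal(f$fragility, 1 / f$d_strength, tolerance = 1e-12)
  expect_false(f$t0_at_bound)
  expect_output(print(f), "VFT fit")
})

test_that("thermal-law selection picks the generating law when noiseless", {
  Tv <- seq(270, 360, 10)
  Rg <- ns_constants()$Rgas
  sa <- select_thermal_law(Tv, 0.05 * exp(12 / (Rg * Tv)))
  expect_equal(sa$law, "arrhenius")
  sv <- select_thermal_law(Tv, 0.1 * exp(5 * 150 / (Tv - 150)))
  expect_equal(sv$law, "vft")
  expect_gt(sv$delta_aicc, 2)
  expect_output(print(sv), "Thermal-law selection")
  expect_warning(select_thermal_law(Tv[1:4], 0.05 * exp(12 / (Rg * Tv[1:4]))),
                 "too few")
})

test_that("pseudo_diffusion obeys its formula and scaling invariance", {
  d <- pseudo_diffusion(1.2, 2)
  expect_equal(d$A2_per_ps, 1.2^2 / 4, tolerance = 1e-12)
  expect_equal(d$cm2_per_s_1e5, d$A2_per_ps * 10, tolerance = 1e-12)
  # invariant under <l> -> c <l>, tau -> c^2 tau
  d2 <- pseudo_diffusion(3 * 1.2, 9 * 2)
  expect_equal(d2$A2_per_ps, d$A2_per_ps, tolerance = 1e-12)
  expect_error(pseudo_diffusion(1, 0), "tau")
})

test_that("resilience converts the MSD slope to a force constant", {
  Tv <- seq(280, 330, 10)
  slope <- 0.004
  msd <- data.frame(temperature = Tv, msd_total = 0.1 + slope * (Tv - 280))
  r <- resilience(msd)
  expect_equal(r$slope_A2_per_K, slope, tolerance = 1e-10)
  expect_equal(r$force_constant_N_per_m,
               2 * 1.380649e-23 / (slope * 1e-20), tolerance = 1e-9)
  expect_false(r$overflow)
  flat <- data.frame(temperature = Tv, msd_total = rep(0.1, length(Tv)))
  rf <- resilience(flat)
  expect_true(rf$overflow)
  expect_true(is.infinite(rf$force_constant_N_per_m))
})

test_that("breakpoint detection flags a slope change and not a line", {
  Tv <- seq(280, 360, 5)
  set.seed(51)
  lin <- 0.01 * (Tv - 270) * (1 + rnorm(length(Tv), 0, 0.02))
  b0 <- detect_breakpoint(data.frame(temperature = Tv, msd_total = lin),
                          sigma = 0.02 * 0.01 * (Tv - 270))
  expect_true(b0$linear)
  expect_true(is.na(b0$t_star))
  kink <- ifelse(Tv <= 320, 0.01 * (Tv - 270), 0.5 + 0.03 * (Tv - 320))
  kn <- kink * (1 + rnorm(length(Tv), 0, 0.02))
  b1 <- detect_breakpoint(data.frame(temperature = Tv, msd_total = kn),
                          sigma = 0.02 * kink)
  expect_false(b1$linear)
  expect_lt(abs(b1$t_star - 320), 10 + 1e-9)
  expect_gt(b1$slope_high / b1$slope_low, 2)
  expect_output(print(b1), "slope change")
  expect_error(detect_breakpoint(data.frame(temperature = Tv[1:5],
                                            msd_total = lin[1:5])),
               "6 points")
})
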