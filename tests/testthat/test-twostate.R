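test_that("population fractions follow the Boltzmann ratio", {
  Rg <- ns_constants()$Rgas
  p <- population_fraction(12, 25, 300)
  dG <- 12 - 300 * 25 / 1000
  r <- exp(-dG / (Rg * 300))
  expect_equal(p$p1 / p$p2, r, tolerance = 1e-12)
  expect_equal(p$p1 + p$p2, 1, tolerance = 1e-12)
  # dG = 0 gives equal populations
  p0 <- population_fraction(3, 10, 300)
  expect_equal(p0$p1, 0.5, tolerance = 1e-12)
  expect_error(population_fraction(1, 1, -5), "temperature")
})

test_that("two_state_elastic obeys its limits", {
  q <- seq(0, 5, 0.1)
  s <- two_state_elastic(q, 0.05, 1.4, 12, 25, 300)
  expect_equal(s[1], 1)                  # q = 0
  expect_true(all(s > 0 & s <= 1))
  # d = 0 removes the jump term entirely
  s0 <- two_state_elastic(q, 0.05, 0, 12, 25, 300)
  expect_equal(s0, exp(-0.05 * q^2), tolerance = 1e-12)
  expect_error(two_state_elastic(q, -1, 1, 1, 1, 300), "dx0_sq")
})

test_that("noiseless two-state scans are recovered to high precision", {
  q <- seq(0.2, 4.5, length.out = 25)
  Tv <- seq(283, 363, 10)
  d <- 1.4; dH <- 12; dS <- 25
  I <- t(vapply(Tv, function(Tk)
    two_state_elastic(q, 0.04 + 0.0015 * (Tk - 283), d, dH, dS, Tk),
    numeric(length(q))))
  es <- elastic_scan_set(q, I, matrix(1e-6, length(Tv), length(q)),
                         conditions(Tv, 1))
  f <- fit_two_state(es)
  expect_equal(f$coefficients$d, d, tolerance = 1e-6)
  expect_equal(f$coefficients$dH, dH, tolerance = 1e-6)
  expect_equal(f$coefficients$dS, dS, tolerance = 1e-6)
  expect_equal(f$coefficients$scale, 1, tolerance = 1e-6)
  expect_output(print(f), "Two-state global fit")
  expect_named(coef(f)[1:4], c("d", "dH", "dS", "scale"))
  expect_equal(dim(predict(f)), c(length(Tv), length(q)))
})

test_that("the fit reports the dH >= 0 branch of the sign degeneracy", {
  # data generated with the mirrored parameters must come back canonical
  q <- seq(0.2, 4.5, length.out = 25)
  Tv <- seq(283, 363, 10)
  I <- t(vapply(Tv, function(Tk)
    two_state_elastic(q, 0.05, 1.4, -12, -25, Tk), numeric(length(q))))
  es <- elastic_scan_set(q, I, matrix(1e-6, length(Tv), length(q)),
                         conditions(Tv, 1))
  f <- fit_two_state(es)
  expect_gte(f$coefficients$dH, 0)
  expect_equal(f$coefficients$dH, 12, tolerance = 1e-4)
  expect_equal(f$coefficients$dS, 25, tolerance = 1e-4)
})

test_that("d = 0 data flags dH/dS as unidentifiable", {
  q <- seq(0.2, 4.5, length.out = 25)
  Tv <- seq(283, 363, 10)
  set.seed(11)
  I <- t(vapply(Tv, function(Tk)
    two_state_elastic(q, 0.05, 0, 12, 25, Tk) *
      (1 + rnorm(length(q), 0, 0.005)), numeric(length(q))))
  es <- elastic_scan_set(q, pmax(I, 1e-6),
                         matrix(0.005, length(Tv), length(q)),
                         conditions(Tv, 1))
  f <- fit_two_state(es)
  expect_true(f$unidentifiable["dH"] || f$unidentifiable["dS"] ||
                f$coefficients$d < 0.2)
})

test_that("total_msd combines the intra- and inter-well terms", {
  Tv <- c(290, 310, 330)
  params <- list(dx0_sq = c(0.04, 0.05, 0.06), d = 1.4, dH = 12, dS = 25,
                 temperatures = Tv, pressure = 1)
  m <- total_msd(params)
  p <- population_fraction(12, 25, Tv)
  expect_equal(m$msd_total,
               c(0.04, 0.05, 0.06) + p$p1 * p$p2 * 1.4^2 / 3,
               tolerance = 1e-12)
  expect_s3_class(m, "msd_curve")
  expect_equal(attr(m, "pressure"), 1)
})
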