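test_that("noiseless QENS maps are recovered through the full reduction", {
  gt <- preset_profiles("piezophile_like")
  qd <- generate_qens_dataset(gt, seed = 1, noise = "none",
                              temperatures = 300)
  tp <- qd$params[[1]]
  rq <- reduce_qens(qd$raw$sample, qd$raw$empty_cell, qd$raw$buffer,
                    qd$raw$vanadium, gt$backgrounds$displaced_fraction)
  f <- fit_qens(rq, extract_eisf(rq))
  expect_equal(f$coefficients$tau, tp$tau, tolerance = 1e-3)
  expect_equal(f$coefficients$jump_len, tp$jump_len, tolerance = 1e-3)
  expect_equal(f$coefficients$gamma_loc, tp$gamma_loc, tolerance = 1e-3)
  expect_equal(f$a0, tp$a0, tolerance = 1e-3)
  expect_true(f$corr_tau_jump_len > -1 && f$corr_tau_jump_len < 1)
  expect_output(print(f), "QENS global fit")
  expect_named(coef(f),
               c("tau", "jump_len", "gamma_loc", "scale_amp", "dw_msd"))
})

test_that("the joint tau-jump_len region contains the estimate and truth", {
  # the region is built from the fit covariance, so it is only meaningful
  # on data whose stated sigmas reflect real statistical noise
  gt <- preset_profiles("piezophile_like")
  qd <- generate_qens_dataset(gt, seed = 3, noise = "none",
                              temperatures = 300)
  tp <- qd$params[[1]]
  set.seed(33)
  noisy <- poissonize_qens(qd$reference, counts = 1e4)
  f <- fit_qens(noisy, make_eisf_curve(qd$reference$q, tp$a0),
                a0_mode = "fixed")
  expect_true(in_tau_l_region(f, f$coefficients$tau,
                              f$coefficients$jump_len))
  expect_true(in_tau_l_region(f, tp$tau, tp$jump_len, level = 3))
  expect_false(in_tau_l_region(f, tp$tau * 100, tp$jump_len * 5))
})

test_that("fit_qens rejects malformed inputs", {
  gt <- preset_profiles("piezophile_like")
  qd <- generate_qens_dataset(gt, seed = 1, noise = "none",
                              temperatures = c(300, 320))
  e <- make_eisf_curve(qd$reference$q, rep(0.5, length(qd$reference$q)))
  expect_error(fit_qens(qd$reference, e), "single condition")
  one <- subset_condition(qd$reference, 1)
  few <- rebin_energy(one, step = 0.02, window = c(-1.4, 1.4),
                      qrange = c(0.55, 0.65))
  expect_error(fit_qens(few, e), "q channels")
})

test_that("model_free_fit selects one component for a single Lorentzian", {
  q <- seq(0.6, 1.8, 0.2)
  omega <- seq(-1.5, 1.5, 0.02)
  nq <- length(q); nw <- length(omega)
  R <- matrix(rep(resolution_profile(omega), nq), nq, nw, byrow = TRUE)
  hw <- 0.25                                   # q-independent width
  m <- t(vapply(seq_len(nq), function(j)
    convolve_resolution(lorentzian(omega, hw), R[j, ], omega),
    numeric(nw)))
  set.seed(21)
  noisy <- pmax(m * (1 + rnorm(length(m), 0, 0.02)), 0)
  qd <- qens_dataset(q, omega, array(noisy, c(1, nq, nw)),
                     array(pmax(0.02 * m, 1e-5), c(1, nq, nw)),
                     R, NULL, conditions(300, 1))
  mf <- model_free_fit(qd, max_components = 2)
  expect_equal(mf$n_best, 1L)
  tab <- mf$components[[1]]
  expect_equal(stats::median(tab$hwhm), hw, tolerance = 0.05)
  expect_equal(mf$trends$trend[1], "flat")
  expect_output(print(mf), "Lorentzian survey")
})

test_that("model_free_fit finds two widths on two-component data", {
  gt <- preset_profiles("piezophile_like")
  qd <- generate_qens_dataset(gt, seed = 9, noise = "none",
                              temperatures = 340)
  mf <- model_free_fit(qd$reference, max_components = 3)
  expect_gte(mf$n_best, 2L)
})
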