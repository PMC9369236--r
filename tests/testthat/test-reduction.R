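test_that("subtract_backgrounds matches the hand-computed algebra", {
  q <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  cd <- conditions(300, 1)
  mk <- function(v, s, kind, tr)
    raw_measurement(kind, elastic_scan_set(q, matrix(v, 1), matrix(s, 1), cd),
                    tr)
  s_v <- c(2.0, 1.8, 1.6, 1.4, 1.2); s_e <- rep(0.02, 5)
  b_v <- c(0.5, 0.45, 0.4, 0.35, 0.3); b_e <- rep(0.01, 5)
  c_v <- rep(0.2, 5); c_e <- rep(0.005, 5)
  f <- 0.1
  out <- subtract_backgrounds(mk(s_v, s_e, "sample", 0.9),
                              mk(c_v, c_e, "empty_cell", 0.95),
                              mk(b_v, b_e, "buffer", 0.92),
                              displaced_fraction = f)
  expect_equal(as.vector(out$intensity),
               s_v / 0.9 - (1 - f) * b_v / 0.92 - f * c_v / 0.95,
               tolerance = 1e-12)
  expect_equal(as.vector(out$sigma),
               sqrt((s_e / 0.9)^2 + ((1 - f) * b_e / 0.92)^2 +
                      (f * c_e / 0.95)^2),
               tolerance = 1e-12)
  expect_error(subtract_backgrounds(mk(s_v, s_e, "sample", 0.9),
                                    mk(c_v, c_e, "empty_cell", 0.95),
                                    mk(b_v, b_e, "buffer", 0.92),
                                    displaced_fraction = 1.2),
               "displaced_fraction")
})

test_that("negative corrected intensities are clipped and counted", {
  q <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  cd <- conditions(300, 1)
  mk <- function(v, kind, tr)
    raw_measurement(kind,
                    elastic_scan_set(q, matrix(v, 1), matrix(0.01, 1, 5), cd),
                    tr)
  out <- subtract_backgrounds(mk(rep(0.1, 5), "sample", 1),
                              mk(rep(0.0001, 5), "empty_cell", 1),
                              mk(rep(0.5, 5), "buffer", 1),
                              displaced_fraction = 0)
  expect_true(all(out$intensity == 0))
  expect_equal(attr(out, "n_clipped"), 5L)
})

test_that("propagated errors match a Monte-Carlo estimate within 10%", {
  set.seed(1234)
  q <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  cd <- conditions(300, 1)
  s_mu <- c(2.0, 1.8, 1.6, 1.4, 1.2); s_sd <- 0.05
  b_mu <- rep(0.5, 5); b_sd <- 0.02
  c_mu <- rep(0.2, 5); c_sd <- 0.01
  v_mu <- c(1.1, 1.0, 0.9, 1.0, 1.1); v_sd <- 0.01
  mk <- function(v, s, kind, tr)
    raw_measurement(kind, elastic_scan_set(q, matrix(v, 1), matrix(s, 1), cd),
                    tr)
  one <- function(sv, bv, cv, vv) {
    red <- reduce_elastic(mk(sv, rep(s_sd, 5), "sample", 0.9),
                          mk(cv, rep(c_sd, 5), "empty_cell", 0.95),
                          mk(bv, rep(b_sd, 5), "buffer", 0.92),
                          mk(vv, rep(v_sd, 5), "vanadium", 1),
                          displaced_fraction = 0.1)
    as.vector(red$intensity)
  }
  base <- reduce_elastic(mk(s_mu, rep(s_sd, 5), "sample", 0.9),
                         mk(c_mu, rep(c_sd, 5), "empty_cell", 0.95),
                         mk(b_mu, rep(b_sd, 5), "buffer", 0.92),
                         mk(v_mu, rep(v_sd, 5), "vanadium", 1),
                         displaced_fraction = 0.1)
  reps <- replicate(2000, one(s_mu + rnorm(5, 0, s_sd),
                              b_mu + rnorm(5, 0, b_sd),
                              c_mu + rnorm(5, 0, c_sd),
                              v_mu + rnorm(5, 0, v_sd)))
  mc_sd <- apply(reps, 1, sd)
  expect_equal(as.vector(base$sigma), mc_sd, tolerance = 0.10)
})

test_that("vanadium normalization divides per q and masks bad channels", {
  q <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  cd <- conditions(300, 1)
  es <- elastic_scan_set(q, matrix(2, 1, 5), matrix(0.01, 1, 5), cd)
  van_ok <- raw_measurement("vanadium",
                            elastic_scan_set(q, matrix(c(1, 2, 4, 2, 1), 1),
                                             matrix(1e-6, 1, 5), cd), 1)
  out <- normalize_vanadium(es, van_ok)
  expect_equal(as.vector(out$intensity), 2 / c(1, 2, 4, 2, 1),
               tolerance = 1e-9)
  mask <- rep(TRUE, 5); mask[3] <- FALSE
  van_bad <- raw_measurement("vanadium",
                             elastic_scan_set(q, matrix(c(1, 2, 0, 2, 1), 1),
                                              matrix(1e-6, 1, 5), cd, mask), 1)
  expect_warning(out2 <- normalize_vanadium(es, van_bad), "auto-masked")
  expect_false(out2$mask[3])
})

test_that("detailed-balance correction symmetrizes a quantum-asymmetric map", {
  q <- c(0.6, 1.0, 1.4, 1.8, 2.2)
  omega <- seq(-1, 1, 0.02); nw <- length(omega)
  Tk <- 300
  sym <- outer(1 / (1 + q), lorentzian(omega, 0.2))
  asym <- sweep(sym, 2, exp(ns_constants()$hbar * omega /
                              (2 * ns_constants()$kB * Tk)), "*")
  R <- matrix(rep(resolution_profile(omega), 5), 5, nw, byrow = TRUE)
  qd <- qens_dataset(q, omega, array(asym, c(1, 5, nw)),
                     array(0.01, c(1, 5, nw)), R, NULL, conditions(Tk, 1))
  out <- detailed_balance_correct(qd)
  got <- out$s_qw[1, , ]
  expect_equal(got, sym, tolerance = 1e-12)
  # symmetry on the (symmetric) grid
  expect_equal(got[, ], got[, rev(seq_len(nw))], tolerance = 1e-10)
})

test_that("temperature binning takes error-weighted means with weighted labels", {
  q <- c(0.5, 1.0, 1.5, 2.0, 2.5)
  Tv <- c(300, 302, 311, 313)
  I <- matrix(rep(c(1.0, 1.2, 2.0, 2.4), 5), 4, 5)
  S <- matrix(rep(c(0.1, 0.2, 0.1, 0.1), 5), 4, 5)
  es <- elastic_scan_set(q, I, S, conditions(Tv, 1))
  b <- bin_temperature(es, width = 10)
  expect_equal(nrow(b$conditions), 2)
  w <- 1 / c(0.1, 0.2)^2
  expect_equal(b$intensity[1, 1], sum(w * c(1.0, 1.2)) / sum(w),
               tolerance = 1e-12)
  expect_equal(b$sigma[1, 1], 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_equal(b$conditions$temperature[1],
               sum(5 * w * c(300, 302)) / sum(5 * w), tolerance = 1e-12)
  expect_equal(b$intensity[2, 1], mean(c(2.0, 2.4)), tolerance = 1e-12)
})

test_that("merge_updown averages consistent scans and refuses hysteresis", {
  q <- seq(0.5, 2.5, 0.5)
  Tv <- c(290, 300, 310)
  up <- elastic_scan_set(q, matrix(1.00, 3, 5), matrix(0.01, 3, 5),
                         conditions(Tv, 1))
  dn <- elastic_scan_set(q, matrix(1.01, 3, 5), matrix(0.02, 3, 5),
                         conditions(Tv, 1))
  m <- merge_updown(up, dn)
  wu <- 1 / 0.01^2; wd <- 1 / 0.02^2
  expect_equal(m$intensity[1, 1], (wu * 1.00 + wd * 1.01) / (wu + wd),
               tolerance = 1e-12)
  bad <- elastic_scan_set(q, matrix(2.0, 3, 5), matrix(0.01, 3, 5),
                          conditions(Tv, 1))
  err <- tryCatch(merge_updown(up, bad), error = identity)
  expect_s3_class(err, "piezodyn_hysteresis_error")
  expect_true(is.matrix(err$discrepant))
  expect_true(all(err$discrepant))
})

test_that("energy rebinning conserves integrated flux and trims q", {
  q <- seq(0.4, 2.2, 0.2)
  omega <- seq(-1.6, 1.6, 0.01); nw <- length(omega)
  nq <- length(q)
  spec <- outer(rep(1, nq), lorentzian(omega, 0.3))
  R <- matrix(rep(resolution_profile(omega), nq), nq, nw, byrow = TRUE)
  qd <- qens_dataset(q, omega, array(spec, c(1, nq, nw)),
                     array(0.01, c(1, nq, nw)), R, NULL, conditions(300, 1))
  rb <- rebin_energy(qd, step = 0.05, window = c(-1.5, 1.5),
                     qrange = c(0.6, 1.8))
  expect_true(all(rb$q >= 0.6 & rb$q <= 1.8))
  # the new bins span [-1.525, 1.525], whose edges coincide with old channel
  # edges, so the total flux over the new window is conserved exactly
  old_in <- abs(omega) <= 1.52 + 1e-9
  expect_equal(sum(rb$s_qw[1, 1, ]) * 0.05,
               sum(spec[2, old_in]) * 0.01, tolerance = 1e-10)
  expect_equal(rowSums(rb$resolution) * 0.05, rep(1, length(rb$q)),
               tolerance = 1e-9)
  expect_error(rebin_energy(qd, window = c(-5, 5)), "outside")
})
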