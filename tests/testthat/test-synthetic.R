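test_that("generators are reproducible given the seed", {
  gt <- preset_profiles("piezophile_like")
  a <- generate_elastic_dataset(gt, seed = 77, noise = "poisson",
                                pressures = 1)
  b <- generate_elastic_dataset(gt, seed = 77, noise = "poisson",
                                pressures = 1)
  expect_identical(a$raw$sample$data$intensity, b$raw$sample$data$intensity)
  c1 <- generate_qens_dataset(gt, seed = 78, noise = "poisson")
  c2 <- generate_qens_dataset(gt, seed = 78, noise = "poisson")
  expect_identical(c1$raw$sample$data$s_qw, c2$raw$sample$data$s_qw)
  d <- generate_elastic_dataset(gt, seed = 79, noise = "poisson",
                                pressures = 1)
  expect_false(identical(a$raw$sample$data$intensity,
                         d$raw$sample$data$intensity))
})

test_that("poisson noise has variance equal to its mean within 10%", {
  # per-channel sample variance over 500 replicates against the configured
  # Poisson mean, on a handful of channels spanning two decades of intensity
  gt <- preset_profiles("piezophile_like")
  ref <- generate_elastic_dataset(gt, seed = 1, noise = "none",
                                  pressures = 1,
                                  temperatures = c(283, 323, 363))
  counts <- 4000
  mu <- ref$raw$sample$data$intensity * counts
  set.seed(314)
  draws <- array(rpois(500 * length(mu), mu), c(dim(mu), 500))
  vr <- apply(draws, c(1, 2), var)
  ratio <- vr / mu
  expect_lt(max(abs(apply(ratio, 1, mean) - 1)), 0.10)
})

test_that("raw sets carry the declared kinds and transmissions", {
  gt <- preset_profiles("piezosensitive_like")
  ed <- generate_elastic_dataset(gt, seed = 2, noise = "none",
                                 pressures = 1)
  expect_equal(vapply(ed$raw, `[[`, character(1), "kind"),
               c(sample = "sample", empty_cell = "empty_cell",
                 buffer = "buffer", vanadium = "vanadium"))
  expect_equal(ed$raw$sample$transmission, gt$backgrounds$t_sample)
  expect_equal(ed$raw$vanadium$transmission, gt$backgrounds$t_vanadium)
})

test_that("true_qens_params evaluates the configured thermal laws", {
  gt <- preset_profiles("piezophile_like")
  Rg <- ns_constants()$Rgas
  tp <- true_qens_params(gt, 310, 1)
  expect_equal(tp$tau, gt$qens$tau0 * exp(gt$qens$ea_tau / (Rg * 310)),
               tolerance = 1e-12)
  expect_equal(tp$gamma_loc,
               gt$qens$gamma0 * exp(-gt$qens$ea_gamma / (Rg * 310)),
               tolerance = 1e-12)
  gv <- preset_profiles("piezosensitive_like")
  tv <- true_qens_params(gv, 310, 1)
  expect_equal(tv$tau,
               0.1 * exp(5 * 150 / (310 - 150)), tolerance = 1e-12)
})

test_that("presets are flagged as fabricated defaults", {
  gt <- preset_profiles("piezophile_like")
  expect_true(attr(gt, "fabricated_defaults"))
  expect_error(preset_profiles("unknown"), "unknown preset")
})

test_that("qens generator scales each q row to the requested total counts", {
  gt <- preset_profiles("piezophile_like")
  qd <- generate_qens_dataset(gt, seed = 12, noise = "poisson",
                              counts = 1e4, temperatures = 300)
  raw <- qd$raw$sample$data$s_qw[1, , ]
  ref <- raw * NA
  # counts = value / sigma^2 channel-wise for pure Poisson (sigma = sqrt(n)/s)
  for (j in seq_len(nrow(raw))) {
    sig <- qd$raw$sample$data$sigma[1, j, ]
    pos <- raw[j, ] > 0
    scale <- stats::median(raw[j, pos] / sig[pos]^2)
    expect_equal(sum(raw[j, ]) * scale, 1e4, tolerance = 0.05)
  }
})
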