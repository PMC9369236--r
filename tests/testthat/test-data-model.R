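test_that("conditions validates and recycles", {
  cd <- conditions(c(283, 293), 1, "s1")
  expect_equal(nrow(cd), 2)
  expect_equal(cd$pressure, c(1, 1))
  expect_error(conditions(-1, 1), "temperatures")
  expect_error(conditions(300, 0.5), "pressures")
})

test_that("elastic_scan_set enforces its invariants", {
  q <- seq(0.2, 2, length.out = 10)
  I <- matrix(1, 2, 10); S <- matrix(0.01, 2, 10)
  cd <- conditions(c(283, 293), 1)
  es <- elastic_scan_set(q, I, S, cd)
  expect_s3_class(es, "elastic_scan_set")
  expect_error(elastic_scan_set(rev(q), I, S, cd), "increasing")
  expect_error(elastic_scan_set(q, I, -S, cd), "sigma")
  expect_error(elastic_scan_set(q, I[, 1:9], S[, 1:9], cd), "n_q")
  expect_error(elastic_scan_set(q, -I, S, cd), ">= 0")
  expect_error(elastic_scan_set(q, I, S, cd, mask = c(TRUE, FALSE)), "mask")
  In <- I; In[1, 3] <- -1
  mask <- rep(TRUE, 10); mask[3] <- FALSE
  expect_s3_class(elastic_scan_set(q, In, S, cd, mask), "elastic_scan_set")
  expect_output(print(es), "Elastic scan set")
})

test_that("qens_dataset enforces grid and resolution invariants", {
  q <- c(0.6, 1.0, 1.4)
  omega <- seq(-1, 1, 0.05)
  nw <- length(omega)
  s <- array(1, c(1, 3, nw)); e <- array(0.01, c(1, 3, nw))
  R <- matrix(rep(resolution_profile(omega), 3), 3, nw, byrow = TRUE)
  cd <- conditions(300, 1)
  qd <- qens_dataset(q, omega, s, e, R, NULL, cd)
  expect_s3_class(qd, "qens_dataset")
  expect_error(qens_dataset(q, omega, s, e, 2 * R, NULL, cd),
               "integrate to 1")
  expect_error(qens_dataset(q, omega[c(1:10, 12:nw)],
                            s[, , -11], e[, , -11], R[, -11], NULL, cd),
               "evenly spaced")
  expect_error(qens_dataset(q, omega, -s, e, R, NULL, cd), ">= 0")
  expect_output(print(qd), "QENS dataset")
})

test_that("subset_condition extracts one condition", {
  q <- c(0.6, 1.0, 1.4, 1.8, 2.0)
  omega <- seq(-1, 1, 0.05); nw <- length(omega)
  s <- array(runif(2 * 5 * nw) + 0.5, c(2, 5, nw))
  e <- array(0.01, c(2, 5, nw))
  R <- matrix(rep(resolution_profile(omega), 5), 5, nw, byrow = TRUE)
  qd <- qens_dataset(q, omega, s, e, R, NULL, conditions(c(300, 320), 1))
  one <- subset_condition(qd, 2)
  expect_equal(nrow(one$conditions), 1)
  expect_equal(one$conditions$temperature, 320)
  expect_equal(one$s_qw[1, , ], s[2, , ])
  expect_error(subset_condition(qd, 3), "out of range")
})

test_that("raw_measurement validates kind and transmission", {
  q <- seq(0.2, 2, length.out = 6)
  es <- elastic_scan_set(q, matrix(1, 1, 6), matrix(0.01, 1, 6),
                         conditions(300, 1))
  rm1 <- raw_measurement("sample", es, 0.9)
  expect_equal(rm1$kind, "sample")
  expect_error(raw_measurement("cheese", es), "arg")
  expect_error(raw_measurement("sample", es, transmission = 0), "transmission")
  expect_error(raw_measurement("sample", es, transmission = 1.2),
               "transmission")
  expect_error(raw_measurement("sample", list()), "payload|elastic_scan_set")
  expect_error(raw_measurement("sample", es, scan_direction = "sideways"),
               "scan_direction")
})

test_that("physical constants carry the expected values and units", {
  k <- ns_constants()
  expect_equal(k$hbar, 0.6582119, tolerance = 1e-6)
  expect_equal(k$kB, 0.0861733, tolerance = 1e-6)
  expect_equal(k$Rgas, 0.0083145, tolerance = 1e-6)
  expect_equal(k$kB_J, 1.380649e-23)
})
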