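test_that("delta13c matches the PDB definition and round-trips", {
  expect_equal(delta13c(0.0112372), 0)
  expect_equal(delta13c(2 * 0.0112372), 1000)
  # invert at -28.0116 permil and round-trip
  r <- ratio_from_delta13c(-28.0116)
  expect_equal(delta13c(r), -28.0116, tolerance = 1e-9)
  expect_equal(r, 0.0109224, tolerance = 1e-5)
  expect_error(delta13c(0), "> 0")
  expect_error(delta13c(-1), "> 0")
})

test_that("two-pool mixing fractions are exact at the end-members", {
  expect_equal(miscanthus_fraction(-28, -28, -12)$fraction, 0)
  expect_equal(miscanthus_fraction(-12, -28, -12)$fraction, 1)
  expect_equal(miscanthus_fraction(-20, -28, -12)$fraction, 0.5)
})

test_that("mixing model is affine, antisymmetric under end-member
           exchange, and clamps out-of-range values", {
  d0 <- -28; dr <- -12
  dn <- seq(-27, -13, by = 0.5)
  f <- miscanthus_fraction(dn, d0, dr)$fraction
  # affine in delta_n: doubling the offset doubles the fraction
  expect_equal(miscanthus_fraction(d0 + 4, d0, dr)$fraction * 2,
               miscanthus_fraction(d0 + 8, d0, dr)$fraction)
  expect_equal(diff(f), rep(0.5 / 16, length(f) - 1), tolerance = 1e-12)
  # swapping end-members maps f -> 1 - f
  expect_equal(miscanthus_fraction(dn, dr, d0)$fraction, 1 - f)

  res <- miscanthus_fraction(-29, d0, dr)
  expect_equal(res$fraction, 0)
  expect_true(res$out_of_range)
  expect_equal(res$fraction_raw, -1 / 16)

  expect_error(miscanthus_fraction(-20, -20, -20), "coincide")
  expect_warning(miscanthus_fraction(-20, -22, -18), "ill-conditioned")
})

test_that("stock partition is exactly additive", {
  p <- partition_stock(0.25, 40)
  expect_equal(c(p$c_mis_stock, p$c3_stock), c(10, 30))
  expect_equal(partition_stock(0, 55)$c_mis_stock, 0)
  expect_equal(partition_stock(1, 55)$c3_stock, 0)
  set.seed(7)
  f <- runif(50)
  s <- runif(50, 10, 90)
  p <- partition_stock(f, s)
  expect_equal(p$c_mis_stock + p$c3_stock, s, tolerance = 0)
})

test_that("stratum summaries give means, SEs, and T6-T12 differences", {
  d <- tibble::tibble(
    hybrid = "Mxg", position = "centre", depth_top_cm = 0,
    time_point = rep(c(6, 12), each = 2),
    fraction = c(0.2, 0.4, 0.5, 0.5)
  )
  s <- stratum_summary(d)
  t6 <- s[s$time_point == 6, ]
  expect_equal(t6$mean, 0.3)
  expect_equal(t6$se, 0.1)
  t12 <- s[s$time_point == 12, ]
  expect_equal(t12$se, 0)
  diffs <- attr(s, "diff_t6_t12")
  expect_equal(diffs$diff_t6_t12, 0.2)

  single <- stratum_summary(d[1, ])
  expect_true(single$singleton)
  expect_true(is.na(single$se))
})

test_that("noiseless synthetic trial is recovered exactly end-to-end", {
  tr <- generate_trial(trial_design(seed = 21), noiseless_params())
  st <- compute_core_stocks(tr$cores,
                            weights = list(`6` = area_weights("t6"),
                                           `12` = area_weights("t12")))
  part <- partition_cores(tr$cores, stocks = st$profiles)
  truth <- tr$truth[tr$truth$time_point > 0, ]
  m <- dplyr::inner_join(
    part, truth,
    by = c("hybrid", "position", "depth_top_cm", "time_point")
  )
  expect_gt(nrow(m), 0)
  expect_equal(m$fraction, m$true_c4_fraction, tolerance = 1e-12)
  # partitioned stocks add back to the total
  expect_equal(m$c_mis_stock + m$c3_stock, m$stock_fixed, tolerance = 1e-12)
})

test_that("per-core and stratum-mean orderings agree when noiseless", {
  tr <- generate_trial(trial_design(seed = 22), noiseless_params())
  per_core <- partition_cores(tr$cores)
  per_stratum <- partition_cores(tr$cores, per_core = FALSE)
  a <- stratum_summary(per_core)
  key <- paste(a$hybrid, a$position, a$depth_top_cm, a$time_point)
  b_key <- paste(per_stratum$hybrid, per_stratum$position,
                 per_stratum$depth_top_cm, per_stratum$time_point)
  expect_equal(a$mean, per_stratum$fraction[match(key, b_key)],
               tolerance = 1e-12)
})

test_that("parameter recovery under realistic noise is accurate", {
  # delta noise 0.2 permil, 16 permil separation, 12 cores per stratum:
  # Monte-Carlo mean absolute error of the stratum mean stays within 0.03
  errs <- vapply(1:200, function(s) {
    d0 <- -28; dr <- -12; f_true <- 0.3
    set.seed(1000 + s)
    dn <- d0 + f_true * (dr - d0) + rnorm(12, 0, 0.2)
    mean(miscanthus_fraction(dn, d0, dr)$fraction) - f_true
  }, numeric(1))
  expect_lte(mean(abs(errs)), 0.03)
})
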