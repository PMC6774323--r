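test_that("acid-wash correction rescales %C by the mass ratio", {
  expect_equal(acid_corrected_soc(2.0, 0.95, 1.00), 1.90)
  expect_equal(acid_corrected_soc(3.5, 1.00, 1.00), 3.50)
  expect_equal(acid_corrected_soc(0.0, 0.9, 1.0), 0.0)
  expect_error(acid_corrected_soc(2.0, 1.1, 1.0), "cannot add mass")
})

test_that("layer soil mass and stock follow the areal conversions", {
  # 15 cm layer at bulk density 1.0573 g/cm3 over 1 ha = 1586 Mg
  area <- pi * 42.5^2
  expect_equal(soil_mass_per_layer(900, area),
               1.0573 * 0.15 * 1e4, tolerance = 1e-3)
  expect_equal(soil_mass_per_layer(0, 123), 0)
  expect_equal(soil_mass_per_layer(1, 1e4), 1.0)
  expect_error(soil_mass_per_layer(1, 0), "> 0")

  expect_equal(layer_stock(1586, 19.0), 30.134)
  expect_equal(layer_stock(1234, 0), 0)
  expect_equal(layer_stock(3000, 25), 75.0)
})

test_that("ESM stock matches the analytic natural-spline oracle", {
  # collinear knots: exact regardless of method
  expect_equal(esm_profile_stock(c(1500, 1500), c(35, 35), 3000), 70)
  # knot coincides with evaluation point
  expect_equal(esm_profile_stock(c(1500, 1600), c(40, 30), 1500), 40)

  # interior evaluation vs the independent tridiagonal solve
  sm <- c(1500, 1600)
  st <- c(40, 30)
  got <- esm_profile_stock(sm, st, 3000)
  want <- natural_spline_oracle(c(0, cumsum(sm)), c(0, cumsum(st)), 3000)
  expect_equal(got, want, tolerance = 1e-9)

  # 4-knot profile, several evaluation points
  sm <- c(1200, 1400, 1600)
  st <- c(38, 27, 16)
  for (ref in c(800, 2000, 3000, 4100)) {
    expect_equal(esm_profile_stock(sm, st, ref),
                 natural_spline_oracle(c(0, cumsum(sm)), c(0, cumsum(st)),
                                       ref),
                 tolerance = 1e-9)
  }
})

test_that("ESM equals the fixed-depth stock when the profile mass equals
           the reference mass", {
  sm <- c(1450, 1550)
  st <- c(41.2, 28.9)
  expect_equal(esm_profile_stock(sm, st, sum(sm)), sum(st),
               tolerance = 1e-9)
})

test_that("ESM is invariant to re-slicing the profile", {
  # same continuous profile cut at different boundaries that both include
  # the reference mass as a knot: the cumulative stock there is the exact
  # integral, so the spline value is slicing-independent
  conc <- function(m) 0.03 - 4e-6 * m # declining concentration with mass
  slices <- function(bounds) {
    sm <- diff(bounds)
    st <- sapply(seq_along(sm), function(i) {
      integrate(conc, bounds[i], bounds[i + 1])$value
    })
    list(sm = sm, st = st)
  }
  a <- slices(c(0, 1500, 3000, 3400))
  b <- slices(c(0, 800, 2100, 3000, 3400))
  expect_equal(esm_profile_stock(a$sm, a$st, 3000),
               esm_profile_stock(b$sm, b$st, 3000), tolerance = 1e-9)

  # constant concentration: cumulative curve is linear, so any slicing and
  # any interior reference agree
  a <- slices <- list(sm = c(1000, 1000, 1000), st = c(30, 30, 30))
  b <- list(sm = c(600, 1700, 700), st = c(18, 51, 21))
  expect_equal(esm_profile_stock(a$sm, a$st, 2750),
               esm_profile_stock(b$sm, b$st, 2750), tolerance = 1e-6)
})

test_that("ESM refuses silent extrapolation", {
  expect_error(esm_profile_stock(c(1000, 1000), c(30, 30), 3000),
               "extrapolate")
  expect_silent(esm_profile_stock(c(1000, 1000), c(30, 30), 3000,
                                  extrapolate = TRUE))
})

test_that("plot-level scaling is an area-weighted mean", {
  w12 <- area_weights("t12")
  expect_equal(sum(w12), 1)
  expect_equal(plot_stock(c(centre = 90, edge = 70, inter_row = 60), w12),
               0.0982 * 90 + 0.5339 * 70 + 0.3679 * 60)
  expect_equal(plot_stock(c(centre = 90, edge = 70, inter_row = 60), w12),
               68.285, tolerance = 1e-3)
  # convexity: equal stocks pass through
  s <- 73.2
  expect_equal(plot_stock(c(centre = s, edge = s, inter_row = s), w12), s)
  # permutation invariance
  expect_equal(
    plot_stock(c(inter_row = 60, centre = 90, edge = 70), w12),
    plot_stock(c(centre = 90, edge = 70, inter_row = 60), w12)
  )
  expect_error(plot_stock(c(centre = 90, edge = 70), w12), "inter_row")
  expect_error(area_weights(c(centre = 0.6, edge = 0.6)), "sum to 1")
})

test_that("table-level stocks recover the generator's ground truth when
           noise is off", {
  tr <- generate_trial(trial_design(seed = 11), noiseless_params())
  st <- compute_core_stocks(tr$cores,
                            weights = list(`6` = area_weights("t6"),
                                           `12` = area_weights("t12")))
  top12 <- st$layers[st$layers$time_point == 12 &
                       st$layers$depth_top_cm == 0, ]
  # stock = BD x thickness x %C: 1.04 g/cm3 * 15 cm * 2.8% -> Mg C/ha
  expect_equal(top12$stock_fixed_mg_ha,
               rep(1.04 * 15 * 100 * 0.028, nrow(top12)), tolerance = 1e-9)
  expect_equal(top12$bulk_density_g_cm3, rep(1.04, nrow(top12)),
               tolerance = 1e-9)
  # plot totals in the plausible whole-profile range
  plots12 <- st$plots[st$plots$time_point == 12, ]
  expect_true(all(plots12$stock_fixed > 50 & plots12$stock_fixed < 100))
  # ESM at 3000 Mg/ha is smaller than the full fixed-depth profile here
  # (profile mass ~3420 Mg/ha exceeds the reference)
  expect_true(all(plots12$stock_esm < plots12$stock_fixed))
})
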