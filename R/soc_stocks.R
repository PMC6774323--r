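# SOC stock computation: acid-wash correction, per-layer soil mass,
# fixed-depth stocks and cubic-spline equivalent-soil-mass (ESM) stocks,
# plus area-weighted scaling of the three core positions to plot level.

#' Acid-wash corrected soil organic carbon
#'
#' Carbonate removal by acid washing also removes mass; the measured \%C of
#' the washed sample is rescaled to the whole soil:
#' `SOC = POC * ODW_acid / ODW_initial`.
#'
#' @param pct_c_acid \% organic C measured on the acid-washed sample.
#' @param odw_acid_g oven-dried mass after acid washing, g.
#' @param odw_initial_g oven-dried mass before acid washing, g.
#' @return SOC as \% of whole soil.
#' @export
#' @examples
#' acid_corrected_soc(2.0, 0.95, 1.00) # 1.9
acid_corrected_soc <- function(pct_c_acid, odw_acid_g, odw_initial_g) {
  check_number(pct_c_acid, "pct_c_acid", 0, 100)
  check_positive(odw_acid_g, "odw_acid_g")
  check_positive(odw_initial_g, "odw_initial_g")
  if (any(odw_acid_g > odw_initial_g)) {
    abort_input("acid washing cannot add mass: odw_acid_g > odw_initial_g")
  }
  pct_c_acid * odw_acid_g / odw_initial_g
}

#' Soil mass of a depth layer, Mg/ha
#'
#' Converts the dried core-sample mass over the core cross-section to an
#' areal soil mass: `M_soil = M_sample / A_sample * 1e4` with mass in g and
#' area in mm2, giving Mg/ha.
#'
#' @param sample_mass_g dried soil mass of the layer, g.
#' @param core_area_mm2 core cross-sectional area, mm2.
#' @return soil mass, Mg/ha.
#' @export
#' @examples
#' soil_mass_per_layer(900, pi * 42.5^2)
soil_mass_per_layer <- function(sample_mass_g, core_area_mm2) {
  check_positive(sample_mass_g, "sample_mass_g", strict = FALSE)
  check_positive(core_area_mm2, "core_area_mm2")
  sample_mass_g / core_area_mm2 * 1e4
}

#' SOC stock of a soil-mass layer
#'
#' `stock = M_soil * SOC_cont / 1000` with soil mass in Mg/ha and carbon
#' concentration in kg C per Mg soil (numerically 10 x \%C).
#'
#' @param soil_mass soil mass, Mg/ha.
#' @param soc_concentration carbon concentration, kg C / Mg soil.
#' @return SOC stock, Mg C/ha.
#' @export
layer_stock <- function(soil_mass, soc_concentration) {
  check_positive(soil_mass, "soil_mass", strict = FALSE)
  check_positive(soc_concentration, "soc_concentration", strict = FALSE)
  soil_mass * soc_concentration / 1000
}

#' Equivalent-soil-mass SOC stock of a profile
#'
#' Fits a cubic spline through the origin and the cumulative
#' (soil mass, SOC stock) points of the profile and evaluates cumulative
#' SOC at a reference soil mass (default 0-3000 Mg/ha), removing
#' bulk-density artefacts from stock comparisons. A natural spline is used;
#' if the fitted cumulative curve is non-monotone (physically impossible, a
#' spline artefact on irregular profiles) a monotone Hyman-filtered spline
#' is substituted with a warning.
#'
#' @param soil_mass per-layer soil masses, Mg/ha, ordered top to bottom.
#' @param stock per-layer SOC stocks, Mg C/ha (same order).
#' @param reference_mass cumulative soil mass at which to evaluate, Mg/ha.
#' @param extrapolate allow evaluation beyond the profile's total mass;
#'   disabled by default and an explicit error is raised instead.
#' @return SOC stock within the 0-`reference_mass` layer, Mg C/ha.
#' @export
#' @examples
#' esm_profile_stock(c(1500, 1500), c(35, 35), 3000) # 70
esm_profile_stock <- function(soil_mass, stock, reference_mass = 3000,
                              extrapolate = FALSE) {
  if (length(soil_mass) < 2 || length(stock) != length(soil_mass)) {
    abort_input("need >= 2 layers with matching stock values")
  }
  check_positive(soil_mass, "soil_mass")
  check_positive(stock, "stock", strict = FALSE)
  check_positive(reference_mass, "reference_mass")
  cum_mass <- cumsum(soil_mass)
  cum_stock <- cumsum(stock)
  if (any(diff(cum_mass) <= 0)) {
    abort_input("cumulative soil mass must be strictly increasing")
  }
  if (reference_mass > cum_mass[length(cum_mass)] && !extrapolate) {
    abort_input("reference mass ", reference_mass,
                " exceeds profile total ", round(cum_mass[length(cum_mass)], 3),
                " Mg/ha; set extrapolate = TRUE to allow")
  }
  x <- c(0, cum_mass)
  y <- c(0, cum_stock)
  fit <- splinefun(x, y, method = "natural")
  grid <- seq(0, max(x[length(x)], reference_mass), length.out = 512)
  if (any(diff(fit(grid)) < -1e-9) || any(fit(grid) < -1e-9)) {
    warning("natural spline non-monotone; using monotone interpolant",
            call. = FALSE)
    fit <- splinefun(x, y, method = "hyman")
  }
  unname(fit(reference_mass))
}

#' Core-position area weights
#'
#' Ground-cover fractions used to scale centre / edge / inter-row core
#' stocks to plot level. Defaults are the year-12 survey fractions; the
#' year-6 fractions are available as `area_weights("t6")`.
#'
#' @param which `"t12"`, `"t6"`, or a named numeric vector of fractions.
#' @return named numeric vector summing to 1.
#' @export
area_weights <- function(which = "t12") {
  if (is.numeric(which)) {
    w <- which
  } else {
    w <- switch(which,
      t6  = c(centre = 0.081, edge = 0.245, inter_row = 0.674),
      t12 = c(centre = 0.0982, edge = 0.5339, inter_row = 0.3679),
      abort_input("unknown weight set `", which, "`")
    )
  }
  if (is.null(names(w)) || any(!nzchar(names(w)))) {
    abort_input("area weights must be named by position")
  }
  if (abs(sum(w) - 1) > 1e-9) abort_input("area weights must sum to 1")
  if (any(w <= 0) || any(w >= 1)) {
    abort_input("each area weight must be in (0, 1)")
  }
  w
}

#' Area-weighted plot-level stock
#'
#' @param stocks named numeric vector of per-position stocks, Mg C/ha.
#' @param weights named area fractions, see [area_weights()].
#' @return plot-level stock, Mg C/ha.
#' @export
#' @examples
#' plot_stock(c(centre = 90, edge = 70, inter_row = 60), area_weights("t12"))
plot_stock <- function(stocks, weights = area_weights("t12")) {
  weights <- area_weights(weights)
  missing <- setdiff(names(weights), names(stocks))
  if (length(missing)) {
    abort_input("missing stock for position(s): ",
                paste(missing, collapse = ", "))
  }
  sum(stocks[names(weights)] * weights)
}

#' Per-core and per-plot SOC stocks from a core table
#'
#' Applies the acid-wash correction, per-layer soil mass, fixed-depth and
#' ESM stock calculations to every core of a core-layer table (as produced
#' by [generate_trial()] or read from CSV in the same dialect), then scales
#' positions to plot level with the supplied area weights. Baseline (T0)
#' cores, which have no position structure, are averaged per plot.
#'
#' @param cores core-layer table (tibble/data.frame).
#' @param weights named area fractions for the position scaling, or a named
#'   list of such vectors keyed by time point (`"6"`, `"12"`).
#' @param reference_mass ESM reference soil mass, Mg/ha.
#' @param esm_per_core fit the ESM spline per core (default) rather than on
#'   the plot-mean profile.
#' @return list with `layers` (per core-layer stocks and bulk density),
#'   `profiles` (per-core 0-30 cm fixed-depth and ESM stocks) and `plots`
#'   (area-weighted plot-level stocks, both methods).
#' @export
compute_core_stocks <- function(cores, weights = area_weights("t12"),
                                reference_mass = 3000,
                                esm_per_core = TRUE) {
  needed <- c("block", "hybrid", "position", "time_point", "sample_mass_g",
              "core_area_mm2", "pct_c_acid", "odw_acid_g", "odw_initial_g",
              "depth_top_cm", "depth_bottom_cm")
  miss <- setdiff(needed, names(cores))
  if (length(miss)) {
    abort_input("core table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!"core" %in% names(cores)) cores$core <- 1L

  layers <- dplyr::mutate(
    tibble::as_tibble(cores),
    soc_pct = acid_corrected_soc(.data$pct_c_acid, .data$odw_acid_g,
                                 .data$odw_initial_g),
    soc_conc_kg_mg = .data$soc_pct * 10,
    soil_mass_mg_ha = soil_mass_per_layer(.data$sample_mass_g,
                                          .data$core_area_mm2),
    stock_fixed_mg_ha = layer_stock(.data$soil_mass_mg_ha,
                                    .data$soc_conc_kg_mg),
    bulk_density_g_cm3 = .data$sample_mass_g /
      (.data$core_area_mm2 / 100 *
         (.data$depth_bottom_cm - .data$depth_top_cm))
  )

  layer_src <- layers
  if (!esm_per_core) {
    # pool the replicate cores of a plot/position into one mean profile
    # before spline fitting
    layer_src <- layers |>
      dplyr::group_by(.data$block, .data$hybrid, .data$position,
                      .data$time_point, .data$depth_top_cm) |>
      dplyr::summarise(
        soil_mass_mg_ha = mean(.data$soil_mass_mg_ha),
        stock_fixed_mg_ha = mean(.data$stock_fixed_mg_ha),
        core = 1L, .groups = "drop"
      )
  }

  profiles <- layer_src |>
    dplyr::group_by(.data$block, .data$hybrid, .data$position,
                    .data$time_point, .data$core) |>
    dplyr::arrange(.data$depth_top_cm, .by_group = TRUE) |>
    dplyr::summarise(
      stock_fixed = sum(.data$stock_fixed_mg_ha),
      stock_esm = esm_profile_stock(.data$soil_mass_mg_ha,
                                    .data$stock_fixed_mg_ha,
                                    reference_mass, extrapolate = TRUE),
      .groups = "drop"
    )

  plots <- profiles |>
    dplyr::group_by(.data$block, .data$hybrid, .data$time_point) |>
    dplyr::group_modify(function(d, key) {
      if (all(d$position == "baseline")) {
        return(tibble::tibble(stock_fixed = mean(d$stock_fixed),
                              stock_esm = mean(d$stock_esm)))
      }
      w <- if (is.list(weights) && !is.null(names(weights))) {
        wk <- weights[[as.character(key$time_point)]]
        if (is.null(wk)) abort_input("no weights for time point ",
                                     key$time_point)
        wk
      } else {
        weights
      }
      pos_fixed <- tapply(d$stock_fixed, d$position, mean)
      pos_esm <- tapply(d$stock_esm, d$position, mean)
      tibble::tibble(
        stock_fixed = plot_stock(pos_fixed, w),
        stock_esm = plot_stock(pos_esm, w)
      )
    }) |>
    dplyr::ungroup()

  list(layers = layers, profiles = profiles, plots = plots)
}
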