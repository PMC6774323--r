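# Built-in study constants, default scenario configurations, structured
# (YAML) run-configuration loading, and the end-to-end reference LCA check.

#' Built-in trial and LCA constants
#'
#' The surveyed core-position area fractions, per-layer bulk densities, the
#' Miscanthus NPP schedule of the conversion scenario, and the LCA energy /
#' emission constants, collected so the reference LCA chain needs no
#' external inputs.
#'
#' @return nested list of constants.
#' @export
trial_constants <- function() {
  list(
    area_fractions = list(
      t6 = c(centre = 0.081, edge = 0.245, inter_row = 0.674),
      t12 = c(centre = 0.0982, edge = 0.5339, inter_row = 0.3679)
    ),
    bulk_density = list(
      `0` = c(1.14, 1.11), `6` = c(1.08, 1.13), `12` = c(1.04, 1.21)
    ),
    npp_miscanthus = c(
      `2005` = 1.9, `2006` = 2.2, `2007` = 16.7, `2008` = 23.2,
      `2009` = 21.2, `2010` = 22.0, `2011` = 26.3, `2012` = 22.9,
      `2013` = 21.7, `2014` = 18.3, `2015` = 14.3, `2016` = 19.3,
      `2017` = 16.0
    ),
    npp_grassland = 8,
    conversion_residue_dm = 1.5,
    initial_soc = c(grassland = 77, luc = 78.8),
    soil = list(clay = 18, sand = 58, silt = 24, ph = 6,
                water_table_depth_m = 3),
    climate = c(mean_temp = 6.7, annual_precip = 1074),
    lca = list(
      soc_diff_c = 4, production_gwp = 4.4,
      n2o_establishment_kg = 8.83, n2o_reversion_kg = 7.29,
      cumulative_yield = 180, energy_content = 17.95, hhv = 18,
      gwp100_n2o = 298
    )
  )
}

#' Default grassland and LUC scenario configurations
#'
#' The continued-grassland counterfactual (initial SOC 77 Mg C/ha, constant
#' 8 Mg DM/ha annual yield) and the grassland-to-Miscanthus conversion
#' scenario (initial SOC 78.8 Mg C/ha including killed-pasture input, the
#' yield-trial NPP schedule with 16 Mg DM/ha projected after 2016, and
#' 1.5 Mg DM/ha conversion-year residue), both 2005-2020.
#'
#' @return named list of two [scenario_config()] objects.
#' @export
default_scenarios <- function() {
  k <- trial_constants()
  list(
    grassland = scenario_config(
      land_use = "grassland",
      initial_soc = k$initial_soc[["grassland"]],
      bulk_density = k$bulk_density[["0"]],
      npp_schedule = k$npp_grassland
    ),
    miscanthus = scenario_config(
      land_use = "miscanthus",
      initial_soc = k$initial_soc[["luc"]],
      bulk_density = k$bulk_density[["6"]],
      npp_schedule = k$npp_miscanthus,
      conversion_year = 2005,
      conversion_residue_dm = k$conversion_residue_dm
    )
  )
}

#' Run both default scenarios and difference them
#'
#' @param climate optional monthly climate table; generated for 2005-2016
#'   from the site climatology (and gap-filled to 2020 by monthly means)
#'   when omitted.
#' @param seed seed for generated climate.
#' @param params [rothc_params()].
#' @return list with both scenario results, the annual difference series
#'   and scalar end-of-simulation summaries (Mg C/ha).
#' @export
run_default_scenarios <- function(climate = NULL, seed = 1L,
                                  params = rothc_params()) {
  if (is.null(climate)) {
    climate <- generate_climate(2005, 2016, seed = seed)
  }
  cfg <- default_scenarios()
  grass <- run_scenario(cfg$grassland, climate, params)
  mxg <- run_scenario(cfg$miscanthus, climate, params)
  ann <- dplyr::inner_join(
    dplyr::select(grass$annual, "year", grass_soc = "soc_total"),
    dplyr::select(mxg$annual, "year", mxg_soc = "soc_total"),
    by = "year"
  )
  ann$difference <- ann$grass_soc - ann$mxg_soc
  last <- nrow(ann)
  list(
    grassland = grass, miscanthus = mxg, annual = ann,
    soc_difference = ann$difference[last],
    grassland_loss = cfg$grassland$initial_soc - ann$grass_soc[last],
    miscanthus_loss = cfg$miscanthus$initial_soc - ann$mxg_soc[last]
  )
}

#' Reference LCA chain check
#'
#' Runs the whole GWP arithmetic from the built-in constants and compares
#' every derived quantity with its expected published-precision value:
#' 15 Mg CO2-eq/ha, 5 g CO2-eq/MJ for the SOC difference, running sums 9,
#' 10 and 11 g CO2-eq/MJ, a 125\% increase over the production chain,
#' N2O conversions 4.13 and 3.41 Mg CO2-eq/ha, and the headline
#' 180 kg CO2-eq/Mg DM.
#'
#' @return list with `result` (the [miscanthus_lca()] output), `checks`
#'   (tibble of quantity, computed, expected, pass) and `ok`.
#' @export
#' @examples
#' run_reference_lca()$ok
run_reference_lca <- function() {
  k <- trial_constants()$lca
  res <- miscanthus_lca(
    soc_diff_c = k$soc_diff_c, production_gwp = k$production_gwp,
    n2o_establishment_kg = k$n2o_establishment_kg,
    n2o_reversion_kg = k$n2o_reversion_kg,
    cumulative_yield = k$cumulative_yield,
    energy_content = k$energy_content, hhv = k$hhv,
    gwp100_n2o = k$gwp100_n2o
  )
  tab <- res$table
  checks <- tibble::tibble(
    quantity = c("soc_co2eq_display", "soc_gwp_display",
                 "production_display", "sum_soc", "sum_establishment",
                 "sum_reversion", "increase_pct",
                 "n2o_establishment_co2eq", "n2o_reversion_co2eq",
                 "headline_kg_per_mg_dm"),
    computed = c(
      round_half_up(res$soc_co2eq),
      tab$display_gwp[tab$label == "soc_difference"],
      tab$display_gwp[tab$label == "production"],
      tab$display_sum[tab$label == "soc_difference"],
      tab$display_sum[tab$label == "establishment_n2o"],
      tab$display_sum[tab$label == "reversion_n2o"],
      res$increase_pct,
      round_half_up(res$n2o_co2eq[["establishment"]], 2),
      round_half_up(res$n2o_co2eq[["reversion"]], 2),
      res$headline_kg_per_mg_dm
    ),
    expected = c(15, 5, 4, 9, 10, 11, 125, 4.13, 3.41, 180)
  )
  checks$pass <- abs(checks$computed - checks$expected) < 1e-9
  list(result = res, checks = checks, ok = all(checks$pass))
}

# run-configuration loading --------------------------------------------------

#' Validate a structured run configuration
#'
#' Reads a YAML configuration, checks every declared field against the
#' package's invariants (area fractions summing to one, non-negative NPP,
#' ordered depth layers, existing input paths, ...) and returns the
#' normalized configuration. All violations are collected and reported
#' together with their field paths, not first-failure-only.
#'
#' @param path path to a YAML file, or an already-parsed list.
#' @return validated configuration list (invisibly annotated with class
#'   `run_config`).
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) abort_input("config file not found: ", path)
    yaml::read_yaml(path)
  } else {
    path
  }
  errors <- character()
  note <- function(field, msg) {
    errors <<- c(errors, paste0(field, ": ", msg))
  }

  if (!is.null(cfg$seed) &&
      (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))) {
    note("seed", "must be an integer")
  }
  if (!is.null(cfg$npp_schedule)) {
    npp <- unlist(cfg$npp_schedule)
    if (!is.numeric(npp) || any(npp < 0)) {
      note("npp_schedule", "must be non-negative numeric")
    }
  }
  if (!is.null(cfg$area_weights)) {
    w <- unlist(cfg$area_weights)
    if (!is.numeric(w) || abs(sum(w) - 1) > 1e-9) {
      note("area_weights", "fractions must sum to 1")
    } else if (any(w <= 0 | w >= 1)) {
      note("area_weights", "each fraction must be in (0, 1)")
    }
  }
  if (!is.null(cfg$depth_layers)) {
    dl <- do.call(rbind, cfg$depth_layers)
    if (any(dl[, 2] <= dl[, 1])) {
      note("depth_layers", "bottom must exceed top")
    }
  }
  if (!is.null(cfg$reference_mass) &&
      (!is.numeric(cfg$reference_mass) || cfg$reference_mass <= 0)) {
    note("reference_mass", "must be > 0")
  }
  if (!is.null(cfg$initial_soc) &&
      (!is.numeric(cfg$initial_soc) || cfg$initial_soc <= 0)) {
    note("initial_soc", "must be > 0")
  }
  for (f in c("cores", "climate", "stocks")) {
    p <- cfg$paths[[f]]
    if (!is.null(p) && !file.exists(p)) {
      note(paste0("paths.", f), paste0("file not found: ", p))
    }
  }
  if (length(errors)) {
    abort_input("invalid configuration:\n  ",
                paste(errors, collapse = "\n  "))
  }
  class(cfg) <- c("run_config", class(cfg))
  cfg
}
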