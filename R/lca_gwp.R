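# Global-warming-potential arithmetic: converts SOC-stock differences and
# soil N2O totals into g CO2-eq per MJ of feedstock energy and assembles
# the running-sum LCA table.

#' Convert a carbon mass to CO2 equivalents
#'
#' Molecular-weight conversion: `CO2 = C x 44/12`.
#'
#' @param mass_c carbon mass, Mg C/ha (signed; gains allowed).
#' @return Mg CO2-eq/ha.
#' @export
#' @examples
#' c_to_co2(4) # 14.667
c_to_co2 <- function(mass_c) {
  check_number(mass_c, "mass_c")
  mass_c * 44 / 12
}

#' Convert an N2O-N mass to CO2 equivalents
#'
#' `CO2-eq = N x 44/28 x GWP100 / 1000` (kg N2O-N/ha to Mg CO2-eq/ha).
#' The default 100-year factor of 298 is the only standard value that
#' jointly reproduces the published conversion pairs 8.83 kg N2O-N/ha ->
#' 4.13 Mg CO2-eq/ha and 7.29 -> 3.41.
#'
#' @param mass_n N2O-N mass, kg N/ha.
#' @param gwp100 100-year global warming potential of N2O.
#' @return Mg CO2-eq/ha.
#' @export
n2o_n_to_co2eq <- function(mass_n, gwp100 = 298) {
  check_positive(mass_n, "mass_n", strict = FALSE)
  check_positive(gwp100, "gwp100")
  mass_n * 44 / 28 * gwp100 / 1000
}

#' Feedstock energy over the crop lifetime
#'
#' @param cumulative_yield lifetime yield, Mg DM/ha (default 180 over 15
#'   years).
#' @param energy_content feedstock energy content, GJ/Mg DM (default
#'   17.95).
#' @return energy, MJ/ha.
#' @export
#' @examples
#' feedstock_energy() # 3231000
feedstock_energy <- function(cumulative_yield = 180,
                             energy_content = 17.95) {
  check_positive(cumulative_yield, "cumulative_yield", strict = FALSE)
  check_positive(energy_content, "energy_content")
  cumulative_yield * energy_content * 1000
}

#' GWP intensity per MJ of feedstock energy
#'
#' @param mass_co2eq emission, Mg CO2-eq/ha.
#' @param energy_mj feedstock energy, MJ/ha.
#' @return g CO2-eq/MJ.
#' @export
gwp_per_mj <- function(mass_co2eq, energy_mj) {
  check_number(mass_co2eq, "mass_co2eq")
  check_positive(energy_mj, "energy_mj")
  mass_co2eq * 1e6 / energy_mj
}

#' GWP intensity per Mg of dry matter
#'
#' `g/MJ x GJ/Mg = kg/Mg`, using the feedstock's higher heating value.
#'
#' @param total_g_per_mj GWP intensity, g CO2-eq/MJ.
#' @param hhv higher heating value, GJ/Mg DM (default 18).
#' @return kg CO2-eq/Mg DM.
#' @export
#' @examples
#' gwp_per_mg_dm(10, 18) # 180
gwp_per_mg_dm <- function(total_g_per_mj, hhv = 18) {
  check_number(total_g_per_mj, "total_g_per_mj")
  check_positive(hhv, "hhv")
  total_g_per_mj * hhv
}

#' Assemble the running-sum LCA table
#'
#' Keeps full-precision values and running sums internally and also emits
#' the display values (rounded half-away-from-zero to `display_digits`),
#' mirroring how such tables are printed.
#'
#' @param components named numeric vector of GWP line items, g CO2-eq/MJ,
#'   in table order.
#' @param display_digits decimal places for the displayed columns.
#' @return tibble with label, `gwp_g_per_mj`, `running_sum`,
#'   `display_gwp`, `display_sum` (the first row's running sum is blank,
#'   i.e. `NA`, as in the printed layout).
#' @export
#' @examples
#' assemble_lca_table(c(production = 4.4, soc = 4.539))
assemble_lca_table <- function(components, display_digits = 0) {
  if (length(components) < 1 || is.null(names(components))) {
    abort_input("`components` must be a named vector with >= 1 entry")
  }
  sums <- cumsum(components)
  tibble::tibble(
    label = names(components),
    gwp_g_per_mj = unname(components),
    running_sum = unname(sums),
    display_gwp = round_half_up(unname(components), display_digits),
    display_sum = c(NA_real_,
                    round_half_up(unname(sums[-1]), display_digits))
  )
}

#' Percentage increase of the running sum over the first component
#'
#' Computed on the displayed (integer-rounded) values, as in the printed
#' comparison: adding a displayed SOC cost of 5 to a production cost
#' displayed as 4 gives (9 - 4) / 4 = 125 \%.
#'
#' @param table output of [assemble_lca_table()].
#' @param through label of the last component included (default: second
#'   row).
#' @return percentage increase.
#' @export
lca_increase_pct <- function(table, through = table$label[2]) {
  i <- match(through, table$label)
  if (is.na(i) || i < 2) abort_input("`through` must name a later row")
  base <- table$display_gwp[1]
  (table$display_sum[i] - base) / base * 100
}

#' Full SOC + N2O life-cycle GWP chain
#'
#' Chains the conversions from a SOC-stock difference (grassland
#' counterfactual minus crop scenario at end of life) and establishment /
#' reversion soil-N2O totals to the GWP table per MJ and the headline
#' intensity per Mg of dry matter.
#'
#' @param soc_diff_c SOC difference, Mg C/ha.
#' @param production_gwp production-chain GWP, g CO2-eq/MJ (literature
#'   constant; default 4.4).
#' @param n2o_establishment_kg establishment-phase N2O, kg N2O-N/ha.
#' @param n2o_reversion_kg reversion-phase N2O, kg N2O-N/ha.
#' @param cumulative_yield,energy_content see [feedstock_energy()].
#' @param hhv higher heating value, GJ/Mg DM.
#' @param gwp100_n2o 100-year GWP of N2O.
#' @return list: `table` (see [assemble_lca_table()]), `soc_co2eq`,
#'   `n2o_co2eq` (establishment, reversion), `increase_pct`,
#'   `headline_g_per_mj` (displayed sum through establishment N2O),
#'   `headline_kg_per_mg_dm`, `total_g_per_mj` (full-precision grand sum).
#' @export
#' @examples
#' res <- miscanthus_lca(soc_diff_c = 4)
#' res$table
miscanthus_lca <- function(soc_diff_c = 4, production_gwp = 4.4,
                           n2o_establishment_kg = 8.83,
                           n2o_reversion_kg = 7.29,
                           cumulative_yield = 180, energy_content = 17.95,
                           hhv = 18, gwp100_n2o = 298) {
  energy <- feedstock_energy(cumulative_yield, energy_content)
  soc_co2 <- c_to_co2(soc_diff_c)
  n2o_est <- n2o_n_to_co2eq(n2o_establishment_kg, gwp100_n2o)
  n2o_rev <- n2o_n_to_co2eq(n2o_reversion_kg, gwp100_n2o)
  comps <- c(
    production = production_gwp,
    soc_difference = gwp_per_mj(soc_co2, energy),
    establishment_n2o = gwp_per_mj(n2o_est, energy),
    reversion_n2o = gwp_per_mj(n2o_rev, energy)
  )
  tab <- assemble_lca_table(comps)
  headline <- tab$display_sum[match("establishment_n2o", tab$label)]
  list(
    table = tab,
    soc_co2eq = soc_co2,
    n2o_co2eq = c(establishment = n2o_est, reversion = n2o_rev),
    increase_pct = lca_increase_pct(tab, "soc_difference"),
    headline_g_per_mj = headline,
    headline_kg_per_mg_dm = gwp_per_mg_dm(headline, hhv),
    total_g_per_mj = tab$running_sum[nrow(tab)],
    fossil_reference = c(natural_gas = 59, coal = 121)
  )
}
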