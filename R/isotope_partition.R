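# delta-13C natural-abundance two-pool partitioning of SOC into
# Miscanthus-derived (C4) and pre-existing grassland (C3) carbon.

# 13C/12C of the Pee Dee Belemnite standard
PDB_RATIO <- 0.0112372

#' delta-13C from a raw isotope ratio
#'
#' `delta13C = (R / R_PDB - 1) * 1000` with R_PDB = 0.0112372 (Pee Dee
#' Belemnite).
#'
#' @param ratio_13c_12c measured 13C/12C ratio (> 0).
#' @return delta-13C, permil vs PDB.
#' @export
#' @examples
#' delta13c(0.0112372) # 0
delta13c <- function(ratio_13c_12c) {
  check_positive(ratio_13c_12c, "ratio_13c_12c")
  (ratio_13c_12c / PDB_RATIO - 1) * 1000
}

#' Inverse of [delta13c()]
#' @param delta_permil delta-13C, permil.
#' @return 13C/12C ratio.
#' @export
ratio_from_delta13c <- function(delta_permil) {
  (delta_permil / 1000 + 1) * PDB_RATIO
}

#' Miscanthus-derived fraction of SOC (two-pool mixing)
#'
#' `C_mis = (delta_n - delta_0) / (delta_r - delta_0)` where `delta_0` is
#' the pre-conversion (T0) soil signature (C3 end-member), `delta_r` the
#' below-ground-biomass signature at the sampling time (C4 end-member) and
#' `delta_n` the measured soil signature. Raw fractions outside [0, 1]
#' (measurement noise can push below 0) are clamped; the unclamped value
#' and a flag are retained for audit.
#'
#' @param delta_n measured soil delta-13C, permil.
#' @param delta_0 C3 end-member, permil.
#' @param delta_r C4 end-member, permil.
#' @param separation_floor smallest |delta_r - delta_0| (permil) for which
#'   the mixing model is considered well conditioned; below it a warning is
#'   issued and the result flagged.
#' @return tibble with `fraction` (clamped), `fraction_raw`, and logical
#'   flags `out_of_range` and `ill_conditioned`.
#' @export
#' @examples
#' miscanthus_fraction(-20, -28, -12)$fraction # 0.5
miscanthus_fraction <- function(delta_n, delta_0, delta_r,
                                separation_floor = 5) {
  check_number(delta_n, "delta_n")
  check_number(delta_0, "delta_0")
  check_number(delta_r, "delta_r")
  sep <- abs(delta_r - delta_0)
  if (any(sep == 0)) {
    abort_input("end-members coincide (delta_r == delta_0): ",
                "mixing model undefined")
  }
  ill <- sep < separation_floor
  if (any(ill)) {
    warning("end-member separation below ", separation_floor,
            " permil; fraction is ill-conditioned", call. = FALSE)
  }
  raw <- (delta_n - delta_0) / (delta_r - delta_0)
  tibble::tibble(
    fraction = pmin(1, pmax(0, raw)),
    fraction_raw = raw,
    out_of_range = raw < 0 | raw > 1,
    ill_conditioned = ill
  )
}

#' Split a SOC stock into C4- and C3-derived parts
#'
#' @param fraction Miscanthus-derived fraction in [0, 1].
#' @param total_stock total SOC stock, Mg C/ha.
#' @return tibble with `c_mis_stock`, `c3_stock` (their sum equals
#'   `total_stock` exactly) and the inputs.
#' @export
partition_stock <- function(fraction, total_stock) {
  check_number(fraction, "fraction", 0, 1)
  check_positive(total_stock, "total_stock", strict = FALSE)
  c4 <- fraction * total_stock
  tibble::tibble(fraction = fraction, total_stock = total_stock,
                 c_mis_stock = c4, c3_stock = total_stock - c4)
}

#' Partition every post-conversion core of a trial
#'
#' For each T6/T12 core-layer, computes the Miscanthus-derived fraction
#' using (a) `delta_0`: the T0 plot-level mean soil delta-13C for the same
#' depth layer, falling back to the block mean then the trial mean where T0
#' cores are absent (pre-conversion coring covered only part of the trial),
#' and (b) `delta_r`: the below-ground-biomass delta-13C of the same core
#' when present (`bg_delta13c_permil`), else a trial-wide mean, else the
#' supplied default.
#'
#' @param cores core-layer table with `delta13c_permil` (and optionally
#'   `bg_delta13c_permil`) columns.
#' @param stocks optional `profiles`-style table of per-core stocks (from
#'   [compute_core_stocks()]); when supplied, per-layer stocks are joined
#'   and partitioned.
#' @param delta_r_default fallback C4 end-member, permil.
#' @param per_core if `TRUE` (default) fractions are computed per core then
#'   averaged; otherwise stratum-mean deltas are mixed.
#' @param separation_floor see [miscanthus_fraction()].
#' @return tibble of per core-layer partition results.
#' @export
partition_cores <- function(cores, stocks = NULL, delta_r_default = -12,
                            per_core = TRUE, separation_floor = 5) {
  if (!"delta13c_permil" %in% names(cores)) {
    abort_input("core table lacks `delta13c_permil`")
  }
  cores <- tibble::as_tibble(cores)
  t0 <- dplyr::filter(cores, .data$time_point == 0)
  post <- dplyr::filter(cores, .data$time_point > 0)
  if (nrow(t0) == 0) abort_input("no T0 (baseline) cores to define delta_0")
  if (nrow(post) == 0) abort_input("no post-conversion cores to partition")

  d0_plot <- t0 |>
    dplyr::group_by(.data$block, .data$hybrid, .data$depth_top_cm) |>
    dplyr::summarise(d0_plot = mean(.data$delta13c_permil), .groups = "drop")
  d0_block <- t0 |>
    dplyr::group_by(.data$block, .data$depth_top_cm) |>
    dplyr::summarise(d0_block = mean(.data$delta13c_permil), .groups = "drop")
  d0_trial <- t0 |>
    dplyr::group_by(.data$depth_top_cm) |>
    dplyr::summarise(d0_trial = mean(.data$delta13c_permil), .groups = "drop")

  out <- post |>
    dplyr::left_join(d0_plot, by = c("block", "hybrid", "depth_top_cm")) |>
    dplyr::left_join(d0_block, by = c("block", "depth_top_cm")) |>
    dplyr::left_join(d0_trial, by = "depth_top_cm") |>
    dplyr::mutate(
      delta_0 = dplyr::coalesce(.data$d0_plot, .data$d0_block,
                                .data$d0_trial)
    )
  if ("bg_delta13c_permil" %in% names(out)) {
    bg_mean <- mean(out$bg_delta13c_permil, na.rm = TRUE)
    out$delta_r <- dplyr::coalesce(out$bg_delta13c_permil, bg_mean)
  } else {
    out$delta_r <- delta_r_default
  }

  if (!per_core) {
    # mix stratum-mean deltas instead of averaging per-core fractions
    out <- out |>
      dplyr::group_by(.data$hybrid, .data$position, .data$depth_top_cm,
                      .data$depth_bottom_cm, .data$time_point) |>
      dplyr::summarise(
        delta13c_permil = mean(.data$delta13c_permil),
        delta_0 = mean(.data$delta_0), delta_r = mean(.data$delta_r),
        .groups = "drop"
      )
  }
  frac <- miscanthus_fraction(out$delta13c_permil, out$delta_0, out$delta_r,
                              separation_floor)
  out <- dplyr::bind_cols(
    dplyr::select(out, -dplyr::any_of(c("d0_plot", "d0_block", "d0_trial"))),
    frac
  )

  if (!is.null(stocks) && per_core) {
    join_keys <- intersect(
      c("block", "hybrid", "position", "time_point", "core"),
      intersect(names(out), names(stocks))
    )
    out <- dplyr::left_join(out, stocks, by = join_keys)
    if ("stock_fixed" %in% names(out)) {
      out$c_mis_stock <- out$fraction * out$stock_fixed
      out$c3_stock <- out$stock_fixed - out$c_mis_stock
    }
  }
  out
}

#' Group means, standard errors and T6-to-T12 differences
#'
#' @param partitions output of [partition_cores()] (or any table with a
#'   `fraction` column and stratum keys).
#' @param by character vector of grouping columns (default hybrid,
#'   position, depth and time point).
#' @param value column to summarise.
#' @return tibble of group `mean`, `se` (`NA`, flagged, for singleton
#'   groups), `n`, plus a `diff_t6_t12` table attribute when both time
#'   points are present.
#' @export
stratum_summary <- function(partitions,
                            by = c("hybrid", "position", "depth_top_cm",
                                   "time_point"),
                            value = "fraction") {
  miss <- setdiff(c(by, value), names(partitions))
  if (length(miss)) {
    abort_input("missing column(s): ", paste(miss, collapse = ", "))
  }
  res <- partitions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      se = if (dplyr::n() >= 2) {
        stats::sd(.data[[value]]) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(singleton = .data$n < 2)

  if ("time_point" %in% by && all(c(6, 12) %in% res$time_point)) {
    keys <- setdiff(by, "time_point")
    wide <- res |>
      dplyr::filter(.data$time_point %in% c(6, 12)) |>
      dplyr::select(dplyr::all_of(keys), "time_point", "mean") |>
      tidyr_pivot(keys)
    attr(res, "diff_t6_t12") <- wide
  }
  res
}

# minimal wide pivot (keys x time 6/12) without a tidyr dependency
tidyr_pivot <- function(d, keys) {
  d6 <- d[d$time_point == 6, c(keys, "mean")]
  d12 <- d[d$time_point == 12, c(keys, "mean")]
  names(d6)[names(d6) == "mean"] <- "mean_t6"
  names(d12)[names(d12) == "mean"] <- "mean_t12"
  out <- dplyr::inner_join(d6, d12, by = keys)
  out$diff_t6_t12 <- out$mean_t12 - out$mean_t6
  out
}
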