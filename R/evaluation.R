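# Model-vs-measurement agreement statistics: RMSE and relative error as a
# percentage of the observed mean, and a t-based 95% confidence half-width
# on measurement replicates for the within/outside-CI verdict.

check_paired <- function(observed, predicted) {
  if (length(observed) < 1 || length(observed) != length(predicted)) {
    abort_input("`observed` and `predicted` must have equal length >= 1")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    abort_input("missing values in paired series")
  }
  if (mean(observed) == 0) {
    abort_input("observed mean is zero; percentage statistics undefined")
  }
  invisible(TRUE)
}

#' Root mean square error as a percentage of the observed mean
#'
#' `RMSE\% = 100 / mean(O) * sqrt(sum((P - O)^2) / n)`.
#'
#' @param observed measured values (e.g. SOC stocks, Mg C/ha).
#' @param predicted matched simulated values.
#' @return RMSE, \% of the observed mean.
#' @export
#' @examples
#' rmse_percent(c(50, 150), c(60, 140)) # 10
rmse_percent <- function(observed, predicted) {
  check_paired(observed, predicted)
  100 / mean(observed) *
    sqrt(sum((predicted - observed)^2) / length(observed))
}

#' Relative error (signed bias) as a percentage of the observed mean
#'
#' `RE\% = 100 / mean(O) * sum(P - O) / n`.
#'
#' @inheritParams rmse_percent
#' @return RE, \% of the observed mean.
#' @export
#' @examples
#' relative_error_percent(100, 105) # 5
relative_error_percent <- function(observed, predicted) {
  check_paired(observed, predicted)
  100 / mean(observed) * sum(predicted - observed) / length(observed)
}

#' 95\% confidence half-width of replicate observations
#'
#' Two-sided t-based half-width of the mean of measurement replicates,
#' expressed as a percentage of the replicate mean; optionally returns a
#' within/outside verdict for a supplied agreement statistic (a model whose
#' RMSE\% or RE\% falls inside the measurement CI cannot be distinguished
#' from measurement error).
#'
#' @param replicates numeric vector of replicate observations (n >= 2).
#' @param statistic optional statistic (\%) to compare against the
#'   half-width.
#' @param conf confidence level.
#' @return list with `half_width_pct`, `mean`, `n`, and (when `statistic`
#'   is given) logical `within`.
#' @export
ci95_bounds <- function(replicates, statistic = NULL, conf = 0.95) {
  if (length(replicates) < 2) abort_input("need >= 2 replicates for a CI")
  if (anyNA(replicates)) abort_input("missing replicate values")
  m <- mean(replicates)
  if (m == 0) abort_input("replicate mean is zero")
  n <- length(replicates)
  hw <- qt(1 - (1 - conf) / 2, df = n - 1) * sd(replicates) / sqrt(n)
  out <- list(half_width_pct = 100 * hw / abs(m), mean = m, n = n)
  if (!is.null(statistic)) {
    out$within <- abs(statistic) <= out$half_width_pct
  }
  out
}

#' Agreement report between measured and simulated SOC
#'
#' @param observed measured stocks with optional replicate sets.
#' @param predicted matched simulated stocks.
#' @param replicates optional numeric vector of measurement replicates used
#'   for the CI (defaults to `observed`).
#' @return tibble, one row per statistic, with value, CI half-width and
#'   verdict.
#' @export
evaluate_agreement <- function(observed, predicted, replicates = observed) {
  rmse <- rmse_percent(observed, predicted)
  re <- relative_error_percent(observed, predicted)
  ci <- ci95_bounds(replicates, statistic = NULL)
  tibble::tibble(
    statistic = c("rmse_pct", "re_pct"),
    value = c(rmse, re),
    ci95_half_width_pct = ci$half_width_pct,
    within_ci = abs(c(rmse, re)) <= ci$half_width_pct
  )
}
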