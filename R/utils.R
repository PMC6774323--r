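#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm sd qt setNames splinefun approxfun
#' @importFrom utils read.csv write.csv
NULL

# argument checking ----------------------------------------------------------

abort_input <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_input("`", name, "` must be numeric and non-missing")
  }
  if (any(x < lower) || any(x > upper)) {
    abort_input("`", name, "` must lie in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_input("`", name, "` must be numeric and non-missing")
  }
  if (strict && any(x <= 0)) abort_input("`", name, "` must be > 0")
  if (!strict && any(x < 0)) abort_input("`", name, "` must be >= 0")
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used for the GWP summary table: ties round away from
#' zero (so 8.5 -> 9), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic substreams ---------------------------------------------------

# Stable 31-bit hash of a key string; used to derive per-stratum RNG
# substreams so that adding strata never perturbs existing draws.
stratum_seed <- function(base_seed, key) {
  chars <- utf8ToInt(key)
  h <- 0
  for (ch in chars) h <- (h * 31 + ch) %% 2147483647L
  as.integer((base_seed + h) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
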