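# Goodness-of-fit statistics used to evaluate simulated against observed
# series (soil water deficit, LAI, dry matter).

.check_pair <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(simulated))) {
    stop("non-finite values in input", call. = FALSE)
  }
}

#' Coefficient of determination
#'
#' Squared Pearson correlation between observed and simulated series
#' (ordinary, not through the origin).
#'
#' @param observed,simulated Equal-length numeric vectors.
#' @return R squared in [0, 1].
#' @export
r_squared <- function(observed, simulated) {
  .check_pair(observed, simulated)
  if (stats::sd(observed) == 0 || stats::sd(simulated) == 0) {
    stop("r_squared undefined for a constant series", call. = FALSE)
  }
  stats::cor(observed, simulated)^2
}

#' Willmott index of agreement
#'
#' \eqn{d = 1 - \sum (S_i - O_i)^2 / \sum (|S_i - \bar O| + |O_i - \bar O|)^2},
#' bounded in [0, 1] with 1 for perfect agreement. If every value of both
#' series equals the observed mean the denominator vanishes and 1 is
#' returned by convention (with a message).
#'
#' @param observed,simulated Equal-length numeric vectors.
#' @return Index of agreement in [0, 1].
#' @export
willmott_d <- function(observed, simulated) {
  .check_pair(observed, simulated)
  obar <- mean(observed)
  denom <- sum((abs(simulated - obar) + abs(observed - obar))^2)
  if (denom == 0) {
    message("willmott_d: identical constant series; returning 1 by convention")
    return(1)
  }
  1 - sum((simulated - observed)^2) / denom
}

#' Mean absolute error as a percentage of the observed mean
#'
#' @param observed,simulated Equal-length numeric vectors; the observed mean
#'   must be non-zero.
#' @return MAE in percent.
#' @export
mae_percent <- function(observed, simulated) {
  .check_pair(observed, simulated)
  if (mean(observed) == 0) stop("mae_percent undefined: observed mean is zero",
                                call. = FALSE)
  100 * mean(abs(simulated - observed)) / mean(observed)
}

#' All three fit statistics at once
#'
#' @param observed,simulated Equal-length numeric vectors.
#' @return List with `r_squared`, `willmott_d`, `mae_percent`.
#' @export
fit_statistics <- function(observed, simulated) {
  list(r_squared = r_squared(observed, simulated),
       willmott_d = willmott_d(observed, simulated),
       mae_percent = mae_percent(observed, simulated))
}
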