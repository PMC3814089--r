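#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two sequences, penalising both decorrelation
#' and systematic deviation from the identity line:
#' \deqn{CCC = \frac{2\,\mathrm{cov}(x,y)}{\mathrm{var}(x) + \mathrm{var}(y) + (\bar{x}-\bar{y})^2}}
#' with population (1/n) moments. `|CCC| <= |r|` (Pearson) always holds,
#' with equality only when the two sequences share mean and variance.
#'
#' @param x,y Numeric vectors of equal length >= 2, finite, not both
#'   constant.
#' @return Scalar in \[-1, 1\].
#' @examples
#' concordance_correlation(1:4, c(1, 2, 3, 6))
#' @export
concordance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  if (vx == 0 && vy == 0) {
    stop("CCC undefined: both sequences are constant", call. = FALSE)
  }
  denom <- vx + vy + (mx - my)^2
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / denom
}

#' Absolute relative error in percent
#'
#' `100 * |estimate - truth| / |truth|`, vectorised over both arguments.
#'
#' @param estimate,truth Numeric; `truth` must be non-zero.
#' @return Non-negative percentage(s).
#' @export
relative_error_pct <- function(estimate, truth) {
  if (any(truth == 0)) stop("relative error undefined for truth = 0", call. = FALSE)
  100 * abs(estimate - truth) / abs(truth)
}

#' Summarise a set of values as mean plus interval
#'
#' Three interval conventions used when reporting Monte-Carlo sweeps:
#' `"minmax"` (mean with observed minimum and maximum), `"ci95"`
#' (mean +/- 1.96 standard errors, normal approximation) and `"se"`
#' (mean +/- one standard error).
#'
#' @param values Non-empty numeric vector.
#' @param mode One of `"minmax"`, `"ci95"`, `"se"`.
#' @return Named vector `c(mean, lo, hi)`.
#' @export
summarize_values <- function(values, mode = c("minmax", "ci95", "se")) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop("no values to summarise", call. = FALSE)
  m <- mean(values)
  if (mode == "minmax") {
    return(c(mean = m, lo = min(values), hi = max(values)))
  }
  se <- if (length(values) == 1) 0 else stats::sd(values) / sqrt(length(values))
  half <- if (mode == "ci95") 1.96 * se else se
  c(mean = m, lo = m - half, hi = m + half)
}
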