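#' Fisher's Z transform and its inverse
#'
#' `fisher_z()` maps a correlation coefficient to Fisher's Z scale
#' (`atanh(r)`), on which effect sizes are approximately Gaussian even at
#' high magnitudes; `inv_fisher_z()` maps back (`tanh(z)`). The two are
#' exact inverses on (-1, 1).
#'
#' @param r Numeric vector of correlations, strictly inside (-1, 1).
#' @param z Numeric vector of Fisher-Z values.
#' @return Numeric vector of the same length.
#' @examples
#' fisher_z(0.5)
#' inv_fisher_z(fisher_z(0.5))
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r) | abs(r) >= 1)) {
    stop("fisher_z() requires |r| < 1; got values at or beyond +/-1. ",
         "Use clamp_r() on correlations reported as exactly +/-1.",
         call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Sampling variance of a Fisher-Z effect size
#'
#' The large-sample variance of `Zr` is `1/(n - 3)`, where `n` is the total
#' number of animals used in the test. It applies to every conversion route
#' (reported correlations, two-group tests, group summaries, frequency
#' tables) because all are keyed to the same total n.
#'
#' @param n_total Integer vector of total sample sizes; must be >= 4.
#' @return Numeric vector of sampling variances.
#' @examples
#' zr_variance(103) # 0.01
#' @export
zr_variance <- function(n_total) {
  if (any(is.na(n_total)) || any(n_total <= 3)) {
    stop("zr_variance() requires n_total >= 4 (variance 1/(n - 3) is ",
         "undefined otherwise).", call. = FALSE)
  }
  1 / (n_total - 3)
}

#' Clamp boundary correlations
#'
#' Correlations reported as exactly +/-1 have infinite Fisher-Z and zero
#' information under the 1/(n-3) variance model; they are clamped to
#' +/-0.999 with a warning so the transform stays finite.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @param bound Magnitude to clamp to (default 0.999).
#' @return Numeric vector with |r| < 1.
#' @export
clamp_r <- function(r, bound = 0.999) {
  hit <- is.finite(r) & abs(r) >= 1
  if (any(hit)) {
    warning(sum(hit), " correlation(s) at or beyond +/-1 clamped to +/-",
            bound, call. = FALSE)
    r[hit] <- sign(r[hit]) * bound
  }
  r
}

#' Hedges' small-sample correction factor
#'
#' @param df Error degrees of freedom (n1 + n2 - 2 for a two-group design).
#' @return The correction factor J = 1 - 3 / (4 df - 1).
#' @keywords internal
hedges_j <- function(df) 1 - 3 / (4 * df - 1)

#' Standardized mean difference (Hedges' d) from two-group summaries
#'
#' Computes the bias-corrected standardized mean difference
#' `d = J * (mean_1 - mean_2) / s_pooled`, with `s_pooled` the
#' (n-1)-weighted pooled standard deviation and `J = 1 - 3/(4(n1+n2-2) - 1)`
#' the small-sample correction. By convention group 1 is the "high-state"
#' group (young / attractive / large / good-condition / mated /
#' few-parasites), so a positive d means the high-state group is choosier.
#'
#' @param mean_1,mean_2 Group means on the behaviour scale.
#' @param sd_1,sd_2 Group standard deviations (>= 0, not both zero).
#' @param n_1,n_2 Group sizes (>= 2).
#' @return Numeric vector of corrected standardized mean differences.
#' @examples
#' hedges_d(5, 2, 20, 3, 2, 20) # J * 1
#' @export
hedges_d <- function(mean_1, sd_1, n_1, mean_2, sd_2, n_2) {
  stopifnot(n_1 >= 2, n_2 >= 2, sd_1 >= 0, sd_2 >= 0)
  s_pooled <- sqrt(((n_1 - 1) * sd_1^2 + (n_2 - 1) * sd_2^2) / (n_1 + n_2 - 2))
  if (any(s_pooled <= 0)) {
    stop("hedges_d(): pooled SD is zero (both groups have zero variance); ",
         "the standardized difference is undefined.", call. = FALSE)
  }
  hedges_j(n_1 + n_2 - 2) * (mean_1 - mean_2) / s_pooled
}

#' Convert a standardized mean difference to a correlation
#'
#' Uses the exact unequal-n constant `a = (n1 + n2)^2 / (n1 * n2)`:
#' `d / sqrt(d^2 + a)`. For balanced designs a = 4, recovering the
#' familiar approximation; for the unbalanced designs common in field
#' studies the exact form reduces bias.
#'
#' @param d Standardized mean difference.
#' @param n_1,n_2 Group sizes (>= 2).
#' @return Correlation with |r| < 1; the sign of d is preserved.
#' @examples
#' d_to_r(1, 20, 20) # 1/sqrt(5)
#' @export
d_to_r <- function(d, n_1, n_2) {
  stopifnot(n_1 >= 2, n_2 >= 2)
  a <- (n_1 + n_2)^2 / (n_1 * n_2)
  d / sqrt(d^2 + a)
}

#' Convert a two-group test statistic to a correlation
#'
#' A t statistic is first converted to a bias-corrected standardized mean
#' difference, `d = J * t * sqrt(1/n1 + 1/n2)` with `J` evaluated at
#' `df = n1 + n2 - 2`, then to r via [d_to_r()]. This is algebraically the
#' same estimator as [hedges_d()] applied to the underlying group
#' summaries, so the two routes agree exactly on the same data. An F
#' statistic with one numerator degree of freedom is handled as
#' `t = sign * sqrt(F)`, where the sign must be supplied from the reported
#' direction (F itself is unsigned).
#'
#' @param value The test statistic (t, possibly signed; or F >= 0).
#' @param n_1,n_2 Group sizes.
#' @param kind `"t"` (default) or `"F"` (one numerator df).
#' @param direction For `kind = "F"`, +1 or -1 giving the sign of the
#'   underlying group difference.
#' @return Correlation with |r| < 1.
#' @examples
#' test_stat_to_r(2, 20, 20)
#' test_stat_to_r(4, 20, 20, kind = "F", direction = 1) # identical to t = 2
#' @export
test_stat_to_r <- function(value, n_1, n_2, kind = c("t", "F"), direction = 1) {
  kind <- match.arg(kind)
  if (kind == "F") {
    if (any(value < 0)) stop("F statistics must be nonnegative.", call. = FALSE)
    if (any(!direction %in% c(-1, 1))) {
      stop("For F statistics supply direction = +1 or -1 (F cannot be ",
           "signed from its value alone).", call. = FALSE)
    }
    value <- direction * sqrt(value)
  }
  d <- hedges_j(n_1 + n_2 - 2) * value * sqrt(1 / n_1 + 1 / n_2)
  d_to_r(d, n_1, n_2)
}

#' Phi coefficient of a 2x2 frequency table
#'
#' For choice counts cross-tabulated as chooser state (rows) by chosen
#' option (columns), phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)) is the
#' correlation-scale effect size; |phi| = sqrt(chi-squared / N). A single
#' zero cell is fine; a zero margin leaves phi undefined.
#'
#' @param a,b,c,d Nonnegative cell counts, row-wise
#'   (`a`,`b` = high-state row; `a`,`c` = first option column).
#' @return The phi coefficient, in `[-1, 1]`.
#' @examples
#' freq_table_to_r(6, 2, 3, 9)
#' @export
freq_table_to_r <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Cell counts must be nonnegative integers.", call. = FALSE)
  }
  margins <- cbind(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("Degenerate 2x2 table: a zero margin leaves phi undefined.",
         call. = FALSE)
  }
  (a * d - b * c) / sqrt(apply(margins, 1, prod))
}

#' Orient a raw correlation by the high-state convention
#'
#' Effect sizes are coded so that a positive correlation always means that
#' choosier individuals are young, attractive, large, in good condition,
#' mated, or carry few parasites. When the raw statistic's positive
#' direction already points toward that pole (`"as_predicted"`) the value
#' is returned unchanged; when it points the other way (`"reversed"`) the
#' sign is flipped.
#'
#' @param raw_r Signed correlation(s) with |r| < 1.
#' @param high_state_direction `"as_predicted"` or `"reversed"` (recycled).
#' @return The oriented correlation(s).
#' @examples
#' code_direction(0.2, "as_predicted")
#' code_direction(-0.3, "reversed")
#' @export
code_direction <- function(raw_r, high_state_direction) {
  if (any(!high_state_direction %in% c("as_predicted", "reversed"))) {
    stop("high_state_direction must be 'as_predicted' or 'reversed'.",
         call. = FALSE)
  }
  if (any(!is.finite(raw_r) | abs(raw_r) >= 1)) {
    stop("code_direction() requires |raw_r| < 1 (clamp boundary values ",
         "first).", call. = FALSE)
  }
  ifelse(high_state_direction == "reversed", -raw_r, raw_r)
}
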