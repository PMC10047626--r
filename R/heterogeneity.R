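#' Typical sampling variance of a set of effect sizes
#'
#' The "typical" within-study variance used to put sampling error on the
#' same footing as the between-effect variance components:
#' `sigma2_m = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))` with weights
#' `w_i = 1/v_i`. When all sampling variances are equal it reduces to
#' their common value.
#'
#' @param v Numeric vector of sampling variances (> 0), length >= 2.
#' @return The typical sampling variance (scalar).
#' @examples
#' typical_sampling_variance(c(0.01, 0.02)) # 0.015
#' @export
typical_sampling_variance <- function(v) {
  if (length(v) < 2) stop("Need at least 2 sampling variances.", call. = FALSE)
  if (any(v <= 0)) stop("Sampling variances must be positive.", call. = FALSE)
  w <- 1 / v
  (length(v) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Partition heterogeneity into level-wise I-squared
#'
#' I-squared is the percentage of effect-size variance not attributable to
#' sampling error. For the multilevel model it decomposes additively over
#' the random levels: `I2_level = 100 * sigma2_level / (sum(sigma2) +
#' sigma2_m)`, where `sigma2_m` is the typical sampling variance of the
#' data. The level components sum exactly to the total.
#'
#' @param fit An intercept-only `mc_fit`; alternatively supply `sigma2`
#'   (named variance components) and `sigma2_m` directly.
#' @param sigma2 Named numeric vector of variance components (used when
#'   `fit` is NULL).
#' @param sigma2_m Typical sampling variance (used when `fit` is NULL).
#' @return A tibble with one row per level plus a `"total"` row: `level`,
#'   `sigma2`, `i2_percent`; the typical sampling variance is attached as
#'   attribute `"sigma2_m"`.
#' @examples
#' i2_partition(sigma2 = c(study = 0.03, obs = 0.01), sigma2_m = 0.01)
#' @export
i2_partition <- function(fit = NULL, sigma2 = NULL, sigma2_m = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "mc_fit"))
    sigma2 <- fit$sigma2
    sigma2_m <- typical_sampling_variance(fit$model$v)
  }
  stopifnot(!is.null(sigma2), !is.null(sigma2_m), sigma2_m > 0,
            all(sigma2 >= 0))
  denom <- sum(sigma2) + sigma2_m
  i2 <- 100 * sigma2 / denom
  out <- tibble::tibble(
    level = c(names(sigma2), "total"),
    sigma2 = c(unname(sigma2), sum(sigma2)),
    i2_percent = c(unname(i2), sum(i2))
  )
  attr(out, "sigma2_m") <- sigma2_m
  out
}
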