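#' Publication-bias tests: time trend and small-study effect
#'
#' Fits the multilevel model with no intercept and two fixed covariates —
#' mean-centered publication year and the standard error `sqrt(v)` — over
#' the full random structure. A nonzero year slope indicates a temporal
#' trend in reported effects (e.g. decline effects); a positive SE slope
#' is the Egger-type funnel-asymmetry signature of selective publication
#' of significant small studies. A covariate that is constant across
#' effects cannot be estimated alongside the others; it is dropped with a
#' warning recorded on the result.
#'
#' @param data An `mc_data` object.
#' @param intercept Include an intercept (default FALSE, the
#'   minus-intercept form; set TRUE for the conventional all-in
#'   regression).
#' @param random Random levels, as in [build_model()].
#' @param ... Passed to [meta_fit()].
#' @return An object of class `mc_bias`: list with `slopes` (tibble:
#'   term, estimate, std.error, z, p), `fit`, `dropped` (character vector
#'   of dropped covariates).
#' @export
bias_test <- function(data, intercept = FALSE,
                      random = c("phylo", "species", "study", "obs"), ...) {
  stopifnot(inherits(data, "mc_data"))
  eff <- data$effects
  covs <- list(year_c = eff$publication_year - mean(eff$publication_year),
               se = sqrt(eff$v))
  kept <- bias_drop_constant(covs, intercept = intercept)
  if (length(kept$covs) == 0) {
    stop("Both bias covariates are constant; the test model is empty.",
         call. = FALSE)
  }
  fit <- meta_fit(data, moderator = NULL, intercept = intercept,
                  covariates = kept$covs, random = random, ...)
  sl <- tidy(fit)
  sl <- sl[sl$term %in% names(kept$covs), ]
  structure(list(slopes = tibble::tibble(term = sl$term,
                                         estimate = sl$estimate,
                                         std.error = sl$std.error,
                                         z = sl$statistic, p = sl$p.value),
                 fit = fit, dropped = kept$dropped),
            class = "mc_bias")
}

# Drop covariates that carry no information: always those with zero
# variance when an intercept is present (perfect collinearity); in a
# no-intercept model only all-zero columns are unusable, but constant
# ones are flagged.
bias_drop_constant <- function(covs, intercept) {
  dropped <- character()
  for (nm in names(covs)) {
    x <- covs[[nm]]
    const <- stats::sd(x) < 1e-12
    if (const && (intercept || all(abs(x) < 1e-12))) {
      warning("Covariate '", nm, "' is constant; dropped from the bias model.",
              call. = FALSE)
      dropped <- c(dropped, nm)
      covs[[nm]] <- NULL
    } else if (const) {
      warning("Covariate '", nm, "' is constant across effects; its slope ",
              "is an intercept in disguise.", call. = FALSE)
    }
  }
  list(covs = covs, dropped = dropped)
}

#' Bias-adjusted mean effect size
#'
#' Refits the model with an intercept plus mean-centered publication year
#' and the sampling variance `v` as fixed covariates. The intercept of
#' this model is the mean effect expected for an average-year study of
#' unbounded precision (v = 0), i.e. the effect adjusted for both the time
#' trend and the small-study effect; it is computed regardless of whether
#' either bias test was significant. Back-transformed confidence and
#' prediction intervals accompany the adjusted mean.
#'
#' @param data An `mc_data` object.
#' @param random Random levels, as in [build_model()].
#' @param ... Passed to [meta_fit()].
#' @return An object of class `mc_bias_adjust`: list with
#'   `adjusted_mean_r`, `adjusted_ci_r`, `adjusted_pi_r`, `slopes`, `fit`,
#'   `dropped`.
#' @export
adjusted_mean <- function(data,
                          random = c("phylo", "species", "study", "obs"),
                          ...) {
  stopifnot(inherits(data, "mc_data"))
  eff <- data$effects
  covs <- list(year_c = eff$publication_year - mean(eff$publication_year),
               v = eff$v)
  kept <- bias_drop_constant(covs, intercept = TRUE)
  fit <- meta_fit(data, moderator = NULL, intercept = TRUE,
                  covariates = if (length(kept$covs)) kept$covs else NULL,
                  random = random, ...)
  b0 <- fit$beta[["intercept"]]
  s0 <- fit$se[[which(names(fit$beta) == "intercept")]]
  tau <- sqrt(s0^2 + sum(fit$sigma2))
  sl <- tidy(fit)
  sl <- sl[sl$term %in% names(kept$covs), ]
  structure(
    list(adjusted_mean_r = tanh(b0),
         adjusted_ci_r = tanh(b0 + c(-1, 1) * fit$zcrit * s0),
         adjusted_pi_r = tanh(b0 + c(-1, 1) * fit$zcrit * tau),
         slopes = tibble::tibble(term = sl$term, estimate = sl$estimate,
                                 std.error = sl$std.error, z = sl$statistic,
                                 p = sl$p.value),
         fit = fit, dropped = kept$dropped),
    class = "mc_bias_adjust")
}

#' @export
print.mc_bias <- function(x, ...) {
  cat("<mc_bias> publication-bias tests (minus-intercept meta-regression)\n")
  print(as.data.frame(x$slopes), digits = 4)
  if (length(x$dropped)) cat("Dropped constant covariates:",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mc_bias_adjust <- function(x, ...) {
  cat(sprintf("<mc_bias_adjust> adjusted mean r = %.4f, CI = %.4f to %.4f, PI = %.4f to %.4f\n",
              x$adjusted_mean_r, x$adjusted_ci_r[1], x$adjusted_ci_r[2],
              x$adjusted_pi_r[1], x$adjusted_pi_r[2]))
  print(as.data.frame(x$slopes), digits = 4)
  invisible(x)
}

#' Funnel-plot data export
#'
#' Per-effect correlation and precision (1/SE on the Zr scale), the raw
#' material of a funnel plot.
#'
#' @param data An `mc_data` object.
#' @return A tibble with `record_id`, `r`, `zr`, `se`, `precision`.
#' @export
funnel_data <- function(data) {
  stopifnot(inherits(data, "mc_data"))
  dplyr::transmute(data$effects, record_id = .data$record_id, r = .data$r,
                   zr = .data$zr, se = sqrt(.data$v),
                   precision = 1 / sqrt(.data$v))
}
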