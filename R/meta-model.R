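#' Build a multilevel meta-analytic model specification
#'
#' Prepares the response, fixed-effect design and random-effect structure
#' for the four-level model: effects are nested in studies and species,
#' with a phylogenetic level sharing the species mapping but carrying the
#' Brownian correlation matrix of the (re-calibrated, pruned) tree, and an
#' observation-level component capturing residual heterogeneity.
#'
#' With a categorical moderator and `intercept = TRUE`, factor levels with
#' fewer than `min_k` effects are excluded (their records dropped, counts
#' reported) before reference-level dummy coding — the omnibus QM test is
#' then robust to near-empty categories. With `intercept = FALSE` every
#' level gets its own indicator column and no records are dropped, which
#' estimates a separate mean per category.
#'
#' @param data An `mc_data` object from [build_dataset()].
#' @param moderator Optional name of a moderator column in the effect
#'   table.
#' @param intercept Include a model intercept (default TRUE).
#' @param covariates Optional named list/data frame of numeric covariates
#'   (one value per effect) appended to the design, e.g. centered
#'   publication year.
#' @param random Random levels to include, a subset of
#'   `c("phylo", "species", "study", "obs")`.
#' @param min_k Minimum effects per moderator level for inclusion in an
#'   intercept model (default 10).
#' @return An object of class `mc_model`.
#' @export
build_model <- function(data, moderator = NULL, intercept = TRUE,
                        covariates = NULL,
                        random = c("phylo", "species", "study", "obs"),
                        min_k = 10) {
  stopifnot(inherits(data, "mc_data"))
  random <- if (length(random) == 0) character(0) else
    match.arg(random, several.ok = TRUE)
  eff <- data$effects
  dropped <- tibble::tibble(record_id = character(), level = character())

  mod_levels <- NULL
  if (!is.null(moderator)) {
    if (!moderator %in% names(eff)) {
      stop("Moderator '", moderator, "' is not a column of the effect table.",
           call. = FALSE)
    }
    mvals <- eff[[moderator]]
    if (!is.numeric(mvals)) {
      counts <- table(mvals)
      if (intercept) {
        keep_lv <- names(counts)[counts >= min_k]
        if (length(keep_lv) < 2) {
          stop("Moderator '", moderator, "' has fewer than 2 levels with at ",
               "least ", min_k, " effects; the design is degenerate.",
               call. = FALSE)
        }
        drop_rows <- !mvals %in% keep_lv
        if (any(drop_rows)) {
          dropped <- tibble::tibble(record_id = eff$record_id[drop_rows],
                                    level = as.character(mvals[drop_rows]))
          rlang::inform(paste0("Excluded ", sum(drop_rows), " effect(s) in ",
                               length(counts) - length(keep_lv),
                               " moderator level(s) with k < ", min_k, "."))
          eff <- eff[!drop_rows, ]
          mvals <- mvals[!drop_rows]
        }
        mod_levels <- keep_lv
      } else {
        if (length(counts) < 1) stop("Moderator has no levels.", call. = FALSE)
        mod_levels <- names(counts)
      }
      mvals <- factor(mvals, levels = mod_levels)
    }
    eff[[".moderator"]] <- mvals
  }

  k <- nrow(eff)
  X <- if (is.null(moderator)) {
    if (!intercept && is.null(covariates)) {
      stop("A model needs an intercept, a moderator, or covariates.",
           call. = FALSE)
    }
    if (intercept) matrix(1, k, 1, dimnames = list(NULL, "intercept")) else
      matrix(0, k, 0)
  } else if (is.numeric(eff$.moderator)) {
    Xm <- cbind(eff$.moderator)
    colnames(Xm) <- moderator
    if (intercept) cbind(intercept = 1, Xm) else Xm
  } else if (intercept) {
    Xm <- stats::model.matrix(~.moderator, data = eff)
    colnames(Xm) <- c("intercept", paste0(moderator, "_", mod_levels[-1]))
    Xm
  } else {
    Xm <- stats::model.matrix(~0 + .moderator, data = eff)
    colnames(Xm) <- paste0(moderator, "_", mod_levels)
    Xm
  }

  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    if (nrow(cv) != k) stop("Covariates must have one row per effect.",
                            call. = FALSE)
    X <- cbind(X, as.matrix(cv))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("Fixed-effect design is rank deficient.", call. = FALSE)
  }

  species <- eff$species
  sp_present <- unique(species)
  M <- list()
  if ("phylo" %in% random) {
    A <- if (length(sp_present) < 2) {
      matrix(1, 1, 1, dimnames = list(sp_present, sp_present))
    } else {
      tr <- if (length(sp_present) < ape::Ntip(data$tree)) {
        prune_tree(data$tree, sp_present, recalibrate = TRUE)
      } else {
        data$tree
      }
      brownian_correlation(tr)
    }
    idx <- match(species, rownames(A))
    M$phylo <- A[idx, idx, drop = FALSE]
    dimnames(M$phylo) <- NULL
  }
  if ("species" %in% random) {
    M$species <- outer(species, species, "==") * 1
  }
  if ("study" %in% random) {
    M$study <- outer(eff$study_id, eff$study_id, "==") * 1
  }
  if ("obs" %in% random) {
    M$obs <- diag(k)
  }

  structure(
    list(y = eff$zr, v = eff$v, X = X, M = M, k = k, p = ncol(X),
         random = names(M), effects = eff, moderator = moderator,
         moderator_levels = mod_levels, intercept = intercept,
         dropped = dropped, tree = data$tree, variant = data$variant,
         logdet_xtx = as.numeric(determinant(crossprod(X),
                                             logarithm = TRUE)$modulus)),
    class = "mc_model"
  )
}

# Cholesky with a logged ridge-jitter fallback for near-singular V.
chol_safe <- function(V) {
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) {
    rlang::inform("V was numerically singular; adding 1e-10 ridge jitter.")
    U <- chol(V + diag(1e-10, nrow(V)))
  }
  U
}

# Core REML evaluation at fixed variance components. Returns the negative
# restricted log-likelihood (with all constants, so it matches standard
# software), optionally its gradient wrt log(sigma2), and the GLS
# fixed-effect solution at these components.
reml_eval <- function(model, sigma2, grad = FALSE) {
  k <- model$k; p <- model$p
  V <- diag(model$v, k)
  for (l in seq_along(model$M)) {
    if (sigma2[l] > 0) V <- V + sigma2[l] * model$M[[l]]
  }
  U <- chol_safe(V)
  Z <- forwardsolve(t(U), cbind(model$X, model$y))
  zX <- Z[, seq_len(p), drop = FALSE]
  zy <- Z[, p + 1]
  XtViX <- crossprod(zX)
  XtViy <- crossprod(zX, zy)[, 1]
  cX <- chol(XtViX)
  beta <- backsolve(cX, forwardsolve(t(cX), XtViy))
  quad <- sum(zy^2) - sum(XtViy * beta)
  logdet_v <- 2 * sum(log(diag(U)))
  logdet_xvx <- 2 * sum(log(diag(cX)))
  ll <- -0.5 * (k - p) * log(2 * pi) + 0.5 * model$logdet_xtx -
    0.5 * (logdet_v + logdet_xvx + quad)
  out <- list(nll = -ll, beta = beta, beta_cov = chol2inv(cX),
              XtViX = XtViX)
  if (grad) {
    Vi <- chol2inv(U)
    W <- Vi %*% model$X
    WB <- W %*% out$beta_cov
    Viy <- backsolve(U, zy)
    Py <- Viy - WB %*% crossprod(W, model$y)
    P <- Vi - WB %*% t(W)
    g <- vapply(seq_along(model$M), function(l) {
      Mm <- model$M[[l]]
      trPM <- sum(P * Mm)
      qf <- as.numeric(crossprod(Py, Mm %*% Py))
      0.5 * (trPM - qf) * sigma2[l]   # d(nll)/d log(sigma2_l)
    }, numeric(1))
    out$grad <- g
  }
  out
}

#' Restricted log-likelihood of a multilevel model
#'
#' Evaluates the REML objective
#' `-1/2 (k - p) log(2 pi) + 1/2 log|X'X| - 1/2 (log|V| + log|X'V^-1 X| +
#' r' V^-1 r)` at the given variance components, where
#' `V = sigma2_phylo A + sigma2_species S + sigma2_study T + sigma2_obs I
#' + diag(v)` and `r` is the GLS residual. Constants are included, so the
#' value is directly comparable to standard meta-analytic software.
#'
#' @param model An `mc_model` from [build_model()].
#' @param sigma2 Numeric vector of variance components (>= 0), one per
#'   random level of the model, in the model's level order.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(model, sigma2) {
  stopifnot(inherits(model, "mc_model"),
            length(sigma2) == length(model$M), all(sigma2 >= 0))
  -reml_eval(model, sigma2)$nll
}

# Default multi-start points on the variance scale, scaled by a crude
# total-heterogeneity estimate. Includes a zeros-boundary start.
reml_starts <- function(model, n_starts = 5) {
  L <- length(model$M)
  s2 <- max(stats::var(model$y) - mean(model$v), 1e-3)
  starts <- list(
    rep(s2 / L, L),
    rep(1e-8, L),
    { x <- rep(0.05 * s2 / max(L - 1, 1), L); x[L] <- 0.95 * s2; x },
    { x <- rep(0.05 * s2 / max(L - 1, 1), L); x[1] <- 0.95 * s2; x },
    rep(0.1 * s2, L)
  )
  unique(starts[seq_len(min(n_starts, length(starts)))])
}

#' Fit a multilevel random-effects meta-analysis by REML
#'
#' Estimates the variance components of the phylogeny / species / study /
#' observation hierarchy by restricted maximum likelihood (optimized on
#' the log-variance scale with analytic gradients and multiple starting
#' points, including a zeros-boundary start), then solves the generalized
#' least-squares fixed effects `beta = (X'V^-1 X)^-1 X'V^-1 y` with
#' covariance `(X'V^-1 X)^-1`. Components the optimizer pins below 1e-12
#' are reported as exactly zero. Wald (normal) 95% confidence intervals
#' are formed on the Fisher-Z scale and back-transformed to the
#' correlation scale endpoint-wise.
#'
#' @param data An `mc_data` object, or an `mc_model` from [build_model()]
#'   (in which case the design arguments are ignored).
#' @inheritParams build_model
#' @param ci_level Confidence level (default 0.95).
#' @param control List of optimizer settings: `n_starts` (default 5),
#'   `iter_max` (300), `rel_tol` (1e-12), `pin_tol` (1e-12).
#' @return An object of class `mc_fit`.
#' @examples
#' truth <- simulation_truth(n_species = 10, n_studies = 15, seed = 7)
#' dat <- simulate_dataset(truth)
#' fit <- meta_fit(dat)
#' fit
#' @export
meta_fit <- function(data, moderator = NULL, intercept = TRUE,
                     covariates = NULL,
                     random = c("phylo", "species", "study", "obs"),
                     min_k = 10, ci_level = 0.95, control = list()) {
  model <- if (inherits(data, "mc_model")) {
    data
  } else {
    build_model(data, moderator = moderator, intercept = intercept,
                covariates = covariates, random = random, min_k = min_k)
  }
  ctrl <- utils::modifyList(
    list(n_starts = 5, iter_max = 300, rel_tol = 1e-12, pin_tol = 1e-12),
    control)
  if (model$k <= model$p) {
    stop("Need more effects (k = ", model$k, ") than fixed-effect columns ",
         "(p = ", model$p, ").", call. = FALSE)
  }

  L <- length(model$M)
  if (L == 0) {
    sigma2 <- numeric(0)
    final <- reml_eval(model, sigma2)
  } else {
    obj <- function(theta) reml_eval(model, exp(theta))$nll
    grd <- function(theta) reml_eval(model, exp(theta), grad = TRUE)$grad
    best <- NULL
    for (s in reml_starts(model, ctrl$n_starts)) {
      res <- tryCatch(
        stats::nlminb(log(pmax(s, 1e-10)), obj, gradient = grd,
                      lower = -35, upper = 5,
                      control = list(iter.max = ctrl$iter_max,
                                     rel.tol = ctrl$rel_tol)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$objective < best$objective)) {
        best <- res
      }
    }
    if (is.null(best)) {
      stop("REML optimization failed from every starting point.",
           call. = FALSE)
    }
    sigma2 <- exp(best$par)
    sigma2[sigma2 < ctrl$pin_tol] <- 0
    final <- reml_eval(model, sigma2)
  }
  names(sigma2) <- model$random

  beta <- final$beta
  names(beta) <- colnames(model$X)
  beta_cov <- final$beta_cov
  dimnames(beta_cov) <- list(colnames(model$X), colnames(model$X))
  se <- sqrt(diag(beta_cov))
  zcrit <- stats::qnorm((1 + ci_level) / 2)

  fit <- structure(
    list(model = model, beta = beta, beta_cov = beta_cov, se = se,
         sigma2 = sigma2, reml_loglik = -final$nll, k = model$k,
         p = model$p, ci_level = ci_level, zcrit = zcrit),
    class = "mc_fit")

  if (model$intercept && "intercept" %in% names(beta)) {
    b0 <- beta[["intercept"]]
    s0 <- se[[which(names(beta) == "intercept")]]
    fit$mean_r <- tanh(b0)
    fit$ci_r <- tanh(b0 + c(-1, 1) * zcrit * s0)
    tau <- sqrt(s0^2 + sum(sigma2))
    fit$pi_r <- tanh(b0 + c(-1, 1) * zcrit * tau)
  }
  fit
}

#' Prediction interval of an intercept-only fit
#'
#' The 95% prediction interval widens the confidence interval by the
#' summed random-effect variances: on the Fisher-Z scale it is
#' `beta0 +/- z * sqrt(SE^2 + sum(sigma2))`, back-transformed to the
#' correlation scale. It estimates the range of true effects expected in
#' a new study; with all variance components zero it coincides with the
#' confidence interval.
#'
#' @param fit An `mc_fit` with an intercept.
#' @return A tibble with the interval on both scales.
#' @export
prediction_interval <- function(fit) {
  stopifnot(inherits(fit, "mc_fit"))
  if (!"intercept" %in% names(fit$beta)) {
    stop("Prediction intervals are defined for intercept models.",
         call. = FALSE)
  }
  b0 <- fit$beta[["intercept"]]
  s0 <- fit$se[[which(names(fit$beta) == "intercept")]]
  tau <- sqrt(s0^2 + sum(fit$sigma2))
  zr_bounds <- b0 + c(-1, 1) * fit$zcrit * tau
  tibble::tibble(scale = c("zr", "r"),
                 lower = c(zr_bounds[1], tanh(zr_bounds[1])),
                 upper = c(zr_bounds[2], tanh(zr_bounds[2])))
}

#' Omnibus Wald test of moderator coefficients
#'
#' The QM statistic `b' cov(b)^-1 b` over the tested coefficients,
#' compared to a chi-square with one degree of freedom per coefficient.
#' By default all non-intercept coefficients are tested.
#'
#' @param fit An `mc_fit`.
#' @param coefs Indices or names of coefficients to test (default: all
#'   non-intercept terms).
#' @return A tibble with `qm`, `df`, `p`.
#' @export
qm_test <- function(fit, coefs = NULL) {
  stopifnot(inherits(fit, "mc_fit"))
  if (is.null(coefs)) coefs <- setdiff(names(fit$beta), "intercept")
  if (is.character(coefs)) coefs <- match(coefs, names(fit$beta))
  if (length(coefs) == 0 || anyNA(coefs)) {
    stop("No valid coefficients to test.", call. = FALSE)
  }
  b <- fit$beta[coefs]
  S <- fit$beta_cov[coefs, coefs, drop = FALSE]
  qm <- tryCatch(as.numeric(crossprod(b, solve(S, b))),
                 error = function(e) stop("Sub-covariance of the tested ",
                                          "coefficients is singular.",
                                          call. = FALSE))
  df <- length(coefs)
  tibble::tibble(qm = qm, df = df, p = stats::pchisq(qm, df, lower.tail = FALSE))
}

#' Marginal R-squared of a moderator model
#'
#' The share of total variance (fixed + random) explained by the fixed
#' moderators: `Var(X beta) / (Var(X beta) + sum(sigma2))`, with the
#' variance taken over the k fitted values. Sampling variance is excluded
#' from the denominator, mirroring how heterogeneity is defined.
#'
#' @param fit An `mc_fit` with at least one non-intercept term.
#' @return A proportion in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "mc_fit"))
  fitted_vals <- as.numeric(fit$model$X %*% fit$beta)
  vf <- stats::var(fitted_vals)
  vf / (vf + sum(fit$sigma2))
}

#' Pairwise post hoc contrasts between moderator levels
#'
#' For a no-intercept categorical fit (one mean per level), computes all
#' pairwise Wald contrasts `z = (b_i - b_j) / sqrt(var_i + var_j -
#' 2 cov_ij)` among levels with at least `min_k` effects, with
#' Holm-adjusted p-values.
#'
#' @param fit A no-intercept `mc_fit` over a categorical moderator.
#' @param min_k Minimum effects per level to enter the contrasts.
#' @return A tibble of contrasts.
#' @export
pairwise_posthoc <- function(fit, min_k = 10) {
  stopifnot(inherits(fit, "mc_fit"))
  model <- fit$model
  if (is.null(model$moderator) || model$intercept) {
    stop("pairwise_posthoc() needs a no-intercept categorical moderator fit.",
         call. = FALSE)
  }
  counts <- table(factor(model$effects$.moderator,
                         levels = model$moderator_levels))
  keep <- names(counts)[counts >= min_k]
  if (length(keep) < 2) {
    stop("Fewer than 2 levels with k >= ", min_k, ".", call. = FALSE)
  }
  idx <- match(paste0(model$moderator, "_", keep), names(fit$beta))
  pairs <- utils::combn(seq_along(keep), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- idx[pairs[1, j]]; i2 <- idx[pairs[2, j]]
    diff <- fit$beta[i1] - fit$beta[i2]
    vd <- fit$beta_cov[i1, i1] + fit$beta_cov[i2, i2] -
      2 * fit$beta_cov[i1, i2]
    z <- if (vd <= 0) 0 else diff / sqrt(vd)
    tibble::tibble(level_1 = keep[pairs[1, j]], level_2 = keep[pairs[2, j]],
                   estimate = unname(diff), z = unname(z),
                   p = 2 * stats::pnorm(-abs(z)))
  })
  res$p_adjusted <- stats::p.adjust(res$p, method = "holm")
  res
}

#' Full moderator analysis
#'
#' Runs the two companion meta-regressions for one categorical moderator:
#' (1) an intercept model excluding levels with fewer than `min_k` effects,
#' from which the omnibus QM test and marginal R-squared are taken, and
#' (2) a no-intercept model over all levels, giving each category's mean
#' correlation with confidence interval (the orchard-plot summary), plus
#' Holm-adjusted pairwise contrasts among the well-sampled levels.
#'
#' @inheritParams build_model
#' @param ... Passed on to [meta_fit()].
#' @return An object of class `mc_moderator`: a list with `test` (tibble:
#'   moderator, k, r2_marginal, qm, df, p), `levels` (per-category means),
#'   `pairwise`, and the two fits.
#' @export
moderator_analysis <- function(data, moderator, min_k = 10, ...) {
  fit_qm <- meta_fit(data, moderator = moderator, intercept = TRUE,
                     min_k = min_k, ...)
  fit_means <- meta_fit(data, moderator = moderator, intercept = FALSE,
                        min_k = min_k, ...)
  qmt <- qm_test(fit_qm)
  counts <- table(factor(fit_means$model$effects$.moderator,
                         levels = fit_means$model$moderator_levels))
  lv_names <- fit_means$model$moderator_levels
  idx <- match(paste0(moderator, "_", lv_names), names(fit_means$beta))
  levels_tbl <- tibble::tibble(
    level = lv_names,
    k = as.integer(counts[lv_names]),
    mean_r = tanh(fit_means$beta[idx]),
    ci_lower_r = tanh(fit_means$beta[idx] - fit_means$zcrit * fit_means$se[idx]),
    ci_upper_r = tanh(fit_means$beta[idx] + fit_means$zcrit * fit_means$se[idx])
  )
  pairwise <- if (sum(counts >= min_k) >= 2) {
    pairwise_posthoc(fit_means, min_k = min_k)
  } else {
    NULL
  }
  structure(
    list(test = tibble::tibble(moderator = moderator, k = fit_qm$k,
                               r2_marginal = marginal_r2(fit_qm),
                               qm = qmt$qm, df = qmt$df, p = qmt$p),
         levels = levels_tbl, pairwise = pairwise,
         fit_qm = fit_qm, fit_means = fit_means),
    class = "mc_moderator")
}

#' @export
print.mc_fit <- function(x, digits = 4, ...) {
  cat("<mc_fit> multilevel REML meta-analysis: k =", x$k,
      "effects, ", x$p, "fixed coefficient(s)\n")
  cat("Random components (Zr^2):\n")
  print(round(x$sigma2, digits + 2))
  cat("REML log-likelihood:", format(x$reml_loglik, digits = digits + 2), "\n")
  tb <- tidy(x)
  print(as.data.frame(tb), digits = digits)
  if (!is.null(x$mean_r)) {
    cat(sprintf("Mean r = %.*f, %d%% CI = %.*f to %.*f, %d%% PI = %.*f to %.*f\n",
                digits, x$mean_r, round(100 * x$ci_level),
                digits, x$ci_r[1], digits, x$ci_r[2],
                round(100 * x$ci_level),
                digits, x$pi_r[1], digits, x$pi_r[2]))
  }
  invisible(x)
}

#' @export
print.mc_moderator <- function(x, ...) {
  cat("<mc_moderator> QM test:\n")
  print(as.data.frame(x$test), digits = 4)
  cat("Per-level means (no-intercept refit):\n")
  print(as.data.frame(x$levels), digits = 4)
  if (!is.null(x$pairwise)) {
    cat("Pairwise Holm-adjusted contrasts:\n")
    print(as.data.frame(x$pairwise), digits = 4)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multilevel meta-analytic fit
#'
#' One row per fixed-effect coefficient on the Fisher-Z scale, with Wald
#' statistics and confidence bounds.
#'
#' @param x An `mc_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mc_fit <- function(x, ...) {
  est <- unname(x$beta)
  se <- unname(x$se)
  tibble::tibble(
    term = names(x$beta), estimate = est, std.error = se,
    statistic = est / se, p.value = 2 * stats::pnorm(-abs(est / se)),
    conf.low = est - x$zcrit * se, conf.high = est + x$zcrit * se
  )
}

#' Glance at a multilevel meta-analytic fit
#'
#' One-row model summary: effect count, REML log-likelihood, variance
#' components, and (for intercept fits) the back-transformed mean
#' correlation with its confidence and prediction intervals.
#'
#' @param x An `mc_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mc_fit <- function(x, ...) {
  out <- tibble::tibble(k = x$k, p = x$p, reml_loglik = x$reml_loglik,
                        sigma2_total = sum(x$sigma2))
  for (nm in names(x$sigma2)) out[[paste0("sigma2_", nm)]] <- x$sigma2[[nm]]
  if (!is.null(x$mean_r)) {
    out$mean_r <- x$mean_r
    out$ci_lower_r <- x$ci_r[1]; out$ci_upper_r <- x$ci_r[2]
    out$pi_lower_r <- x$pi_r[1]; out$pi_upper_r <- x$pi_r[2]
  }
  out
}
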