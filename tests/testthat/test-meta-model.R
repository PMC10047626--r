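test_that("with no random levels the fit is the inverse-variance mean", {
  dat <- levels_dataset(c(age = 2), seed = 3)
  dat$effects$zr <- c(0.1, 0.3)
  dat$effects$v <- c(0.01, 0.01)
  fit <- meta_fit(dat, random = character(0))
  expect_equal(unname(fit$beta), 0.2)
  expect_equal(unname(fit$se), sqrt(1 / 200), tolerance = 1e-12)
  # PI collapses onto the CI when every variance component is zero
  pi_tbl <- prediction_interval(fit)
  expect_equal(unlist(pi_tbl[pi_tbl$scale == "r", c("lower", "upper")],
                      use.names = FALSE), fit$ci_r)
})

test_that("the REML objective matches a brute-force dense evaluation", {
  dat <- small_dataset(21, n_studies = 6)   # k = 12
  model <- build_model(dat)
  for (s2 in list(c(0, 0, 0, 0), c(0.01, 0.02, 0.03, 0.04),
                  c(0.2, 0, 0.05, 0.001))) {
    ours <- reml_loglik(model, s2)
    naive <- -naive_reml_nll(s2, model$y, model$v, model$X, model$M)
    expect_equal(ours, naive, tolerance = 1e-8)
  }
})

test_that("shifting sampling variance into the observation component leaves V unchanged", {
  dat <- small_dataset(22, n_studies = 6)
  model <- build_model(dat)
  c0 <- min(model$v) / 2
  model_shift <- model
  model_shift$v <- model$v + c0
  base <- reml_loglik(model, c(0.01, 0.005, 0.02, 0.03))
  shifted <- reml_loglik(model_shift, c(0.01, 0.005, 0.02, 0.03 - c0))
  expect_equal(base, shifted, tolerance = 1e-10)
})

test_that("a single-component fit matches a 1-D grid search of the objective", {
  dat <- small_dataset(23, n_species = 4, n_studies = 5)
  fit <- meta_fit(dat, random = "study")
  model <- build_model(dat, random = "study")
  grid <- seq(0, 0.3, by = 0.0005)
  ll <- vapply(grid, function(s) reml_loglik(model, s), numeric(1))
  expect_lt(abs(unname(fit$sigma2) - grid[which.max(ll)]), 5e-4)
  expect_gte(fit$reml_loglik, max(ll) - 1e-8)
})

test_that("the fitter agrees with an independent multilevel REML implementation", {
  skip_if_not_installed("metafor")
  dat <- small_dataset(31, n_species = 8, n_studies = 12, n_range = c(15, 80))
  fit <- suppressMessages(meta_fit(dat))
  eff <- dat$effects
  eff$phylo <- eff$species
  eff$obs_id <- eff$record_id
  A <- brownian_correlation(prune_tree(dat$tree, unique(eff$species)))
  mf <- metafor::rma.mv(zr, v,
                        random = list(~1 | phylo, ~1 | species,
                                      ~1 | study_id, ~1 | obs_id),
                        R = list(phylo = A), data = eff, method = "REML")
  expect_equal(unname(fit$beta), as.numeric(mf$beta), tolerance = 1e-4)
  expect_equal(unname(fit$se), mf$se, tolerance = 1e-3)
  expect_equal(unname(fit$sigma2), mf$sigma2, tolerance = 1e-3)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(mf)),
               tolerance = 1e-6)
})

test_that("a two-level fit matches the classic random-effects model", {
  skip_if_not_installed("metafor")
  dat <- small_dataset(33, n_studies = 10,
                       sigma2 = c(phylo = 0, species = 0, study = 0,
                                  obs = 0.05))
  fit <- meta_fit(dat, random = "obs")
  mf <- metafor::rma(yi = dat$effects$zr, vi = dat$effects$v,
                     method = "REML")
  expect_equal(unname(fit$beta), as.numeric(mf$beta), tolerance = 1e-6)
  expect_equal(unname(fit$sigma2), mf$tau2, tolerance = 1e-4)
})

test_that("estimates are invariant to effect-row permutation", {
  dat <- small_dataset(24)
  fit1 <- suppressMessages(meta_fit(dat))
  set.seed(99)
  perm <- sample(dat$k)
  dat2 <- build_dataset(dat$effects[perm, ], dat$tree, dat$variant)
  fit2 <- suppressMessages(meta_fit(dat2))
  expect_equal(unname(fit2$beta), unname(fit1$beta), tolerance = 1e-8)
  expect_equal(unname(fit2$sigma2), unname(fit1$sigma2), tolerance = 1e-6)
})

test_that("moderator designs follow the minimum-k exclusion rule", {
  dat <- levels_dataset(c(body_size = 50, condition = 67, age = 9), seed = 5)
  m_int <- suppressMessages(build_model(dat, moderator = "state_factor",
                                        intercept = TRUE))
  expect_equal(ncol(m_int$X), 2)          # intercept + one dummy
  expect_equal(m_int$k, 117)              # the 9 age records are dropped
  expect_equal(nrow(m_int$dropped), 9)

  m_noint <- build_model(dat, moderator = "state_factor", intercept = FALSE)
  expect_equal(ncol(m_noint$X), 3)        # one indicator per level, none dropped
  expect_equal(m_noint$k, 126)

  expect_error(build_model(levels_dataset(c(age = 30, condition = 5)),
                           moderator = "state_factor", intercept = TRUE),
               "degenerate")
})

test_that("the QM statistic is the Wald quadratic form with its z^2 identity", {
  dat <- levels_dataset(c(body_size = 20, condition = 20), seed = 7,
                        zr_by_level = c(0.05, 0.25))
  fit <- meta_fit(dat, moderator = "state_factor", random = "obs")
  qm <- qm_test(fit)
  tb <- tidy(fit)
  z <- tb$statistic[tb$term != "intercept"]
  expect_equal(qm$qm, z^2, tolerance = 1e-12)
  expect_equal(qm$df, 1)
  expect_equal(qm$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("QM is near zero when group means are equal and noiseless", {
  dat <- levels_dataset(c(body_size = 15, condition = 15), seed = 11)
  dat$effects$zr <- 0.2          # identical effects, no spread
  dat$effects$v <- 0.01
  fit <- meta_fit(dat, moderator = "state_factor", random = character(0))
  qm <- qm_test(fit)
  expect_lt(qm$qm, 1e-20)
  expect_equal(qm$p, 1, tolerance = 1e-10)
})

test_that("the prediction interval follows its closed form and monotonicity", {
  fit <- structure(
    list(beta = c(intercept = 0.0902), se = 0.033,
         sigma2 = c(study = 0.2, obs = 0.131), zcrit = qnorm(0.975),
         ci_level = 0.95),
    class = "mc_fit")
  pi_tbl <- prediction_interval(fit)
  tau <- sqrt(0.033^2 + 0.331)
  expect_equal(pi_tbl$lower[pi_tbl$scale == "zr"],
               0.0902 - qnorm(0.975) * tau)
  expect_equal(pi_tbl$upper[pi_tbl$scale == "r"],
               tanh(0.0902 + qnorm(0.975) * tau))
  # width strictly increases in each component
  widths <- vapply(c(0, 0.05, 0.1), function(extra) {
    f2 <- fit; f2$sigma2["obs"] <- f2$sigma2["obs"] + extra
    p <- prediction_interval(f2)
    diff(unlist(p[p$scale == "zr", c("lower", "upper")]))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("marginal R-squared matches hand evaluation and its limits", {
  dat <- levels_dataset(c(body_size = 15, condition = 15), seed = 13,
                        zr_by_level = c(0, 0.4))
  fit <- meta_fit(dat, moderator = "state_factor", random = "obs")
  fitted_vals <- as.numeric(fit$model$X %*% fit$beta)
  expect_equal(marginal_r2(fit),
               var(fitted_vals) / (var(fitted_vals) + sum(fit$sigma2)))
  expect_gte(marginal_r2(fit), 0)
  expect_lte(marginal_r2(fit), 1)

  # no level spread -> R2 = 0
  dat0 <- levels_dataset(c(body_size = 15, condition = 15), seed = 17)
  dat0$effects$zr <- 0.1
  fit0 <- meta_fit(dat0, moderator = "state_factor", random = "obs")
  expect_lt(marginal_r2(fit0), 1e-10)
})

test_that("pairwise post hoc contrasts cover all well-sampled pairs with Holm adjustment", {
  dat <- levels_dataset(c(age = 12, attractiveness = 14, body_size = 16,
                          condition = 18, mating_status = 20), seed = 19)
  fit <- meta_fit(dat, moderator = "state_factor", intercept = FALSE,
                  random = "obs")
  ph <- pairwise_posthoc(fit)
  expect_equal(nrow(ph), choose(5, 2))
  expect_equal(ph$p_adjusted, holm_oracle(ph$p))
  expect_equal(ph$p_adjusted, p.adjust(ph$p, "holm"))

  # duplicated data in two levels -> identical means, z = 0, p = 1
  dup <- levels_dataset(c(body_size = 12, condition = 12), seed = 23)
  dup$effects$zr <- rep(dup$effects$zr[1:12], 2)
  dup$effects$v <- rep(dup$effects$v[1:12], 2)
  fit_dup <- meta_fit(dup, moderator = "state_factor", intercept = FALSE,
                      random = character(0))
  ph_dup <- pairwise_posthoc(fit_dup)
  expect_equal(ph_dup$z, 0, tolerance = 1e-10)
  expect_equal(ph_dup$p, 1, tolerance = 1e-10)
})

test_that("moderator analysis assembles QM, per-level means, and contrasts", {
  dat <- levels_dataset(c(body_size = 25, condition = 30, age = 6), seed = 29,
                        zr_by_level = c(0.05, 0.2, 0))
  res <- suppressMessages(moderator_analysis(dat, "state_factor",
                                             random = c("study", "obs")))
  expect_s3_class(res, "mc_moderator")
  expect_equal(res$test$k, 55)                  # age (k = 6) excluded from QM
  expect_equal(nrow(res$levels), 3)             # but present in level means
  expect_equal(res$levels$k, c(6, 25, 30))
  expect_true(all(res$levels$ci_lower_r < res$levels$mean_r),
              all(res$levels$mean_r < res$levels$ci_upper_r))
  expect_equal(nrow(res$pairwise), 1)           # only two levels with k >= 10
})

test_that("tidy and glance expose the fit in broom shape", {
  dat <- small_dataset(41, n_studies = 8)
  fit <- suppressMessages(meta_fit(dat))
  tb <- tidy(fit)
  expect_named(tb, c("term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  gl <- glance(fit)
  expect_equal(gl$k, dat$k)
  expect_equal(gl$mean_r, fit$mean_r)
  expect_equal(gl$sigma2_total, sum(fit$sigma2))
})
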