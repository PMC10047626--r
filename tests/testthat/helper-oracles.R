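# Independent oracles and fixture builders shared across tests.
# The naive REML implementation deliberately uses a different numerical
# path from the package (explicit solve()/determinant() instead of
# Cholesky, gradient-free Nelder-Mead instead of nlminb with analytic
# gradients) so agreement is evidence, not tautology.

naive_reml_nll <- function(sigma2, y, v, X, M) {
  if (any(!is.finite(sigma2)) || any(sigma2 > 1e6)) return(1e10)
  k <- length(y); p <- ncol(X)
  V <- diag(v, k)
  for (l in seq_along(M)) V <- V + sigma2[l] * M[[l]]
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(1e10)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  resid <- y - X %*% beta
  quad <- as.numeric(t(resid) %*% Vi %*% resid)
  ld_v <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ld_x <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  ld_xtx <- as.numeric(determinant(t(X) %*% X, logarithm = TRUE)$modulus)
  -(-0.5 * (k - p) * log(2 * pi) + 0.5 * ld_xtx -
      0.5 * (ld_v + ld_x + quad))
}

naive_reml_fit <- function(y, v, X, M) {
  obj <- function(theta) naive_reml_nll(exp(theta), y, v, X, M)
  s2 <- max(var(y) - mean(v), 1e-3)
  L <- length(M)
  starts <- list(log(rep(s2 / L, L)), rep(-12, L), log(rep(0.3 * s2, L)))
  best <- NULL
  for (st in starts) {
    r <- optim(st, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    r <- optim(r$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || r$value < best$value) best <- r
  }
  sigma2 <- exp(best$par)
  sigma2[sigma2 < 1e-12] <- 0
  k <- length(y)
  V <- diag(v, k)
  for (l in seq_along(M)) V <- V + sigma2[l] * M[[l]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- as.numeric(solve(XtViX, t(X) %*% Vi %*% y))
  list(beta = beta, sigma2 = sigma2, beta_cov = solve(XtViX),
       nll = best$value)
}

# Brute-force Holm step-down adjustment.
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, (n - seq_len(n) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Small simulated dataset for fitter tests.
small_dataset <- function(seed, n_species = 6, n_studies = 6,
                          effects_per_study = 2, sigma2 = c(phylo = 0.02,
                                                            species = 0.01,
                                                            study = 0.03,
                                                            obs = 0.04),
                          beta0 = 0.15, n_range = c(15, 60), ...) {
  simulate_dataset(simulation_truth(
    beta0 = beta0, sigma2 = sigma2, n_species = n_species,
    n_studies = n_studies, effects_per_study = effects_per_study,
    n_range = n_range, seed = seed, ...))
}

# Hand-built dataset with chosen moderator level counts; effects carry
# plain normal noise so designs are deterministic in shape.
levels_dataset <- function(level_k, seed = 1, zr_by_level = NULL) {
  set.seed(seed)
  lv <- names(level_k)
  k <- sum(level_k)
  tree <- read_species_tree(text = "((spa,spb),(spc,spd));")
  fac <- rep(lv, level_k)
  zr <- if (is.null(zr_by_level)) rnorm(k, 0.1, 0.2) else
    rep(zr_by_level, level_k) + rnorm(k, 0, 0.05)
  effects <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(k)),
    study_id = sprintf("s%03d", rep(seq_len(ceiling(k / 2)), each = 2)[seq_len(k)]),
    species = sample(c("spa", "spb", "spc", "spd"), k, replace = TRUE),
    sex = "female", state_factor = fac,
    taxonomic_group = "insect", state_variation = "natural",
    courter_interaction = "physical", data_type = "correlation",
    publication_year = sample(1990:2019, k, replace = TRUE),
    n_total = sample(20:80, k, replace = TRUE),
    directionless = FALSE, r = tanh(zr), zr = zr, v = 1 / (sample(20:80, k, replace = TRUE) - 3)
  )
  effects$v <- 1 / (effects$n_total - 3)
  build_dataset(effects, tree, "full")
}

# Records tibble in the CSV schema with simple correlation payloads.
schema_records <- function(n = 3, n_total = 33, directionless = FALSE,
                           r = 0.3, species = "spa") {
  k <- n
  tibble::tibble(
    record_id = sprintf("rec%02d", seq_len(k)),
    study_id = "s001", species = species, sex = "female",
    state_factor = "body_size", taxonomic_group = "insect",
    state_variation = "natural", courter_interaction = "physical",
    data_type = "correlation", publication_year = 2005L,
    n_total = as.integer(n_total),
    high_state_direction = "as_predicted",
    directionless = rep_len(directionless, k),
    r = rep_len(r, k), stat_kind = NA_character_, stat_value = NA_real_,
    stat_df = NA_real_, n1 = NA_integer_, n2 = NA_integer_, m1 = NA_real_,
    sd1 = NA_real_, m2 = NA_real_, sd2 = NA_real_, a = NA_integer_,
    b = NA_integer_, c = NA_integer_, d = NA_integer_
  )
}
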