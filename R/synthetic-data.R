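# Stage-split seeding: each generation stage draws under its own seed
# derived from the root seed, so adding or reordering later stages never
# perturbs earlier draws. Stage ids: 1 tree, 2 species effects, 3 study
# effects, 4 observation effects, 5 design (n, years, moderators),
# 6 sampling error, 7 censoring, 8 raw payloads.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + 97 * stage) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth parameters for a simulated meta-analytic dataset
#'
#' Bundles the generating parameters of the synthetic study design: a
#' grand mean effect on the Fisher-Z scale, optional per-level moderator
#' offsets, the four variance components, the sampling design (species,
#' studies, effects per study, per-effect sample sizes), a publication-year
#' trend, and a censoring probability that converts nonsignificant effects
#' into directionless (zero-coded) records — mimicking studies that report
#' "no significant effect" without a direction.
#'
#' The defaults are the package's reference recovery design: 40 species,
#' 80 studies of 2 effects each (k = 160), variance components
#' (phylo, species, study, obs) = (0.02, 0.01, 0.03, 0.04) on the Zr^2
#' scale and a grand mean of 0.1 — heterogeneity dominating sampling error,
#' as in real mate-choice data.
#'
#' @param beta0 Grand mean on the Zr scale.
#' @param moderator_effects Optional named numeric vector of Zr offsets
#'   per state factor (names from the six state factors).
#' @param sigma2 Named variance components
#'   `c(phylo=, species=, study=, obs=)`, all >= 0.
#' @param n_species,n_studies,effects_per_study Design counts.
#' @param n_range Inclusive integer range for per-effect total n (lower
#'   bound >= 4).
#' @param censor_prob Probability that a nonsignificant effect
#'   (|zr|/sqrt(v) < 1.96) is reported directionless.
#' @param year_range Inclusive publication-year range.
#' @param trend_per_year Zr change per publication year.
#' @param seed Root seed for all stages.
#' @return An object of class `simulation_truth` (a validated list).
#' @export
simulation_truth <- function(beta0 = 0.1, moderator_effects = NULL,
                             sigma2 = c(phylo = 0.02, species = 0.01,
                                        study = 0.03, obs = 0.04),
                             n_species = 40, n_studies = 80,
                             effects_per_study = 2, n_range = c(10, 100),
                             censor_prob = 0, year_range = c(1980, 2019),
                             trend_per_year = 0, seed = 1) {
  stopifnot(
    is.numeric(beta0), length(beta0) == 1,
    all(c("phylo", "species", "study", "obs") %in% names(sigma2)),
    all(sigma2 >= 0),
    n_species >= 2, n_studies >= 2, effects_per_study >= 1,
    length(n_range) == 2, n_range[1] >= 4, n_range[2] >= n_range[1],
    censor_prob >= 0, censor_prob <= 1,
    length(year_range) == 2, year_range[2] >= year_range[1]
  )
  if (!is.null(moderator_effects)) {
    stopifnot(all(names(moderator_effects) %in% mc_enums$state_factor))
  }
  structure(
    list(beta0 = beta0, moderator_effects = moderator_effects,
         sigma2 = sigma2[c("phylo", "species", "study", "obs")],
         n_species = n_species, n_studies = n_studies,
         effects_per_study = effects_per_study, n_range = n_range,
         censor_prob = censor_prob, year_range = year_range,
         trend_per_year = trend_per_year, seed = as.integer(seed)),
    class = "simulation_truth")
}

#' Simulate a pure-birth species tree
#'
#' Grows a Yule topology by repeatedly splitting a uniformly chosen extant
#' tip into a cherry, then Grafen-calibrates the result to unit depth.
#' Deterministic given the seed.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A calibrated ultrametric [ape::phylo] tree with tips
#'   `sp001, sp002, ...`.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  stopifnot(n_species >= 2)
  labs <- sprintf("sp%03d", seq_len(n_species))
  newick <- with_seed(seed, {
    # Yule growth: split a uniformly chosen extant tip into a cherry.
    # Labels are fixed-width, so token replacement is unambiguous.
    nwk <- sprintf("(%s,%s);", labs[1], labs[2])
    if (n_species > 2) {
      for (i in 3:n_species) {
        t <- labs[sample.int(i - 1, 1)]
        nwk <- sub(t, sprintf("(%s,%s)", t, labs[i]), nwk, fixed = TRUE)
      }
    }
    nwk
  })
  grafen_calibrate(read_species_tree(text = newick))
}

#' Simulate a dataset with known ground truth
#'
#' Draws species-level effects jointly from the Brownian covariance
#' `sigma2_phylo * A` plus independent `sigma2_species`, independent study
#' and observation effects, a per-year trend, and per-effect sampling
#' error with variance `1/(n - 3)` for n drawn uniformly from `n_range`.
#' Each effect whose observed |zr|/sqrt(v) falls below 1.96 is converted
#' to a directionless zero with probability `censor_prob` (significant
#' effects are never altered). Studies are assigned uniformly to species;
#' state factors are assigned uniformly at the effect level.
#'
#' @param truth A [simulation_truth()] object.
#' @return An `mc_data` object (full variant) with attributes `"truth"`
#'   and `"latent"` (a tibble of per-effect latent components and the
#'   pre-censoring observed zr) for recovery scoring.
#' @export
simulate_dataset <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  tree <- simulate_tree(truth$n_species, stage_seed(truth$seed, 1))
  A <- brownian_correlation(tree)
  sp <- rownames(A)
  ns <- length(sp)

  u_phylo <- with_seed(stage_seed(truth$seed, 2), {
    z <- stats::rnorm(ns)
    as.numeric(t(chol(A + diag(1e-10, ns))) %*% z) *
      sqrt(truth$sigma2[["phylo"]])
  })
  u_species <- with_seed(stage_seed(truth$seed, 2) + 1L,
                         stats::rnorm(ns, 0, sqrt(truth$sigma2[["species"]])))

  study_ids <- sprintf("study%03d", seq_len(truth$n_studies))
  study_sp <- with_seed(stage_seed(truth$seed, 3),
                        sample(sp, truth$n_studies, replace = TRUE))
  u_study <- with_seed(stage_seed(truth$seed, 3) + 1L,
                       stats::rnorm(truth$n_studies, 0,
                                    sqrt(truth$sigma2[["study"]])))

  k <- truth$n_studies * truth$effects_per_study
  study_of <- rep(seq_len(truth$n_studies), each = truth$effects_per_study)
  u_obs <- with_seed(stage_seed(truth$seed, 4),
                     stats::rnorm(k, 0, sqrt(truth$sigma2[["obs"]])))

  design <- with_seed(stage_seed(truth$seed, 5), {
    list(
      n_total = sample(truth$n_range[1]:truth$n_range[2], k, replace = TRUE),
      year = sample(truth$year_range[1]:truth$year_range[2],
                    truth$n_studies, replace = TRUE),
      state_factor = sample(mc_enums$state_factor, k, replace = TRUE),
      state_variation = sample(mc_enums$state_variation, k, replace = TRUE),
      courter_interaction = sample(mc_enums$courter_interaction, k,
                                   replace = TRUE)
    )
  })
  year <- design$year[study_of]
  v <- zr_variance(design$n_total)

  mod_off <- rep(0, k)
  if (!is.null(truth$moderator_effects)) {
    hit <- design$state_factor %in% names(truth$moderator_effects)
    mod_off[hit] <- truth$moderator_effects[design$state_factor[hit]]
  }
  sp_idx <- match(study_sp[study_of], sp)
  true_zr <- truth$beta0 + mod_off +
    truth$trend_per_year * (year - mean(year)) +
    u_phylo[sp_idx] + u_species[sp_idx] + u_study[study_of] + u_obs

  zr_obs <- with_seed(stage_seed(truth$seed, 6),
                      stats::rnorm(k, true_zr, sqrt(v)))

  nonsig <- abs(zr_obs) / sqrt(v) < stats::qnorm(0.975)
  censored <- nonsig & with_seed(stage_seed(truth$seed, 7),
                                 stats::runif(k)) < truth$censor_prob
  zr <- ifelse(censored, 0, zr_obs)

  tax_groups <- c("insect", "fish", "bird", "mammal")
  tax_of_sp <- tax_groups[(seq_len(ns) - 1) %% length(tax_groups) + 1]

  effects <- tibble::tibble(
    record_id = sprintf("obs%04d", seq_len(k)),
    study_id = study_ids[study_of],
    species = study_sp[study_of],
    sex = "female",
    state_factor = design$state_factor,
    taxonomic_group = tax_of_sp[sp_idx],
    state_variation = design$state_variation,
    courter_interaction = design$courter_interaction,
    data_type = "correlation",
    publication_year = as.integer(year),
    n_total = as.integer(design$n_total),
    directionless = censored,
    r = tanh(zr),
    zr = zr,
    v = v
  )
  out <- build_dataset(effects, tree, variant = "full")
  attr(out, "truth") <- truth
  attr(out, "latent") <- tibble::tibble(
    record_id = effects$record_id, true_zr = true_zr, zr_uncensored = zr_obs,
    u_phylo = u_phylo[sp_idx], u_species = u_species[sp_idx],
    u_study = u_study[study_of], u_obs = u_obs, censored = censored
  )
  out
}

# Integer 2x2 table whose phi approximates a target correlation: balanced
# row totals, cell splits proportional to (1 +/- r)/2, with guards against
# zero margins and degenerate |phi| = 1 tables.
r_to_freq_table <- function(r, n) {
  row1 <- n %/% 2L
  row2 <- n - row1
  a <- min(max(round(row1 * (1 + r) / 2), 0L), row1)
  d <- min(max(round(row2 * (1 + r) / 2), 0L), row2)
  b <- row1 - a
  c <- row2 - d
  if (b + d == 0L) { a <- a - 1L; b <- b + 1L }
  if (a + c == 0L) { b <- b - 1L; a <- a + 1L }
  if (a == 0L && d == 0L) { a <- a + 1L; b <- b - 1L }   # phi = -1 guard
  if (b == 0L && c == 0L) { b <- b + 1L; a <- a - 1L }   # phi = +1 guard
  c(a = as.integer(a), b = as.integer(b), c = as.integer(c),
    d = as.integer(d))
}

#' Re-express simulated effects as raw study statistics
#'
#' Converts each simulated effect into one of the four raw payload types
#' (reported correlation, two-group t statistic, group means and SDs, or a
#' 2x2 frequency table), assigned round-robin, such that running the
#' coding pipeline on the resulting records reproduces each effect's r —
#' exactly for the algebraic routes, and within rounding error for integer
#' frequency tables. Directionless records are emitted as correlation
#' payloads (their raw statistic is never used).
#'
#' @param dataset An `mc_data` from [simulate_dataset()].
#' @param seed Unused at present (payload construction is deterministic);
#'   kept so future stochastic payload features do not change signatures.
#' @return A tibble of effect-size records in the CSV schema layout,
#'   ready for [validate_effects()] / [write_effects()].
#' @export
simulate_raw_payloads <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "mc_data"))
  eff <- dataset$effects
  types <- mc_enums$data_type
  rec <- purrr::map_dfr(seq_len(nrow(eff)), function(i) {
    row <- eff[i, ]
    type <- if (row$directionless) "correlation" else
      types[(i - 1) %% length(types) + 1]
    n <- row$n_total
    base <- tibble::tibble(
      record_id = row$record_id, study_id = row$study_id,
      species = row$species, sex = row$sex, state_factor = row$state_factor,
      taxonomic_group = row$taxonomic_group,
      state_variation = row$state_variation,
      courter_interaction = row$courter_interaction,
      data_type = type, publication_year = row$publication_year,
      n_total = n,
      high_state_direction = if (row$directionless) NA_character_ else
        "as_predicted",
      directionless = row$directionless,
      r = NA_real_, stat_kind = NA_character_, stat_value = NA_real_,
      stat_df = NA_real_, n1 = NA_integer_, n2 = NA_integer_,
      m1 = NA_real_, sd1 = NA_real_, m2 = NA_real_, sd2 = NA_real_,
      a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_
    )
    r <- row$r
    n1 <- n %/% 2L
    n2 <- n - n1
    aa <- (n1 + n2)^2 / (n1 * n2)
    d_val <- r * sqrt(aa) / sqrt(1 - r^2)
    if (type == "correlation") {
      base$r <- if (row$directionless) 0 else r
    } else if (type == "group_means") {
      base$n1 <- n1; base$n2 <- n2
      base$m1 <- d_val / hedges_j(n - 2); base$m2 <- 0
      base$sd1 <- 1; base$sd2 <- 1
    } else if (type == "group_test") {
      base$n1 <- n1; base$n2 <- n2
      base$stat_kind <- "t"
      base$stat_value <- d_val / (hedges_j(n - 2) * sqrt(1 / n1 + 1 / n2))
      base$stat_df <- n - 2
    } else {
      tab <- r_to_freq_table(r, n)
      base$a <- tab[["a"]]; base$b <- tab[["b"]]
      base$c <- tab[["c"]]; base$d <- tab[["d"]]
    }
    base
  })
  rec
}
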