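test_that("simulated trees are deterministic, Yule-grown, and calibrated", {
  t1 <- simulate_tree(25, 7)
  t2 <- simulate_tree(25, 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_tree(25, 8)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
  expect_equal(ape::Ntip(simulate_tree(2, 1)), 2)
  depths <- ape::node.depth.edgelength(t1)[1:25]
  expect_lt(max(abs(depths - 1)), 1e-9)
})

test_that("identical truth gives byte-identical CSV and Newick outputs", {
  tr <- simulation_truth(n_species = 8, n_studies = 10, censor_prob = 0.3,
                         seed = 42)
  d1 <- simulate_dataset(tr)
  d2 <- simulate_dataset(tr)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_effects(simulate_raw_payloads(d1), p1)
  write_effects(simulate_raw_payloads(d2), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
})

test_that("the noise-free limit clusters tightly at the grand mean", {
  tr <- simulation_truth(beta0 = 0.25,
                         sigma2 = c(phylo = 0, species = 0, study = 0,
                                    obs = 0),
                         n_species = 6, n_studies = 20,
                         n_range = c(5000, 5000), censor_prob = 0, seed = 9)
  d <- simulate_dataset(tr)
  expect_lt(max(abs(d$effects$zr - 0.25)), 0.1)
  expect_equal(attr(d, "latent")$true_zr, rep(0.25, d$k))
})

test_that("censoring only ever zeroes nonsignificant effects", {
  tr <- simulation_truth(beta0 = 0.1, n_species = 10, n_studies = 30,
                         censor_prob = 1, n_range = c(8, 40), seed = 11)
  d <- simulate_dataset(tr)
  lat <- attr(d, "latent")
  zcrit <- qnorm(0.975)
  wald <- abs(lat$zr_uncensored) / sqrt(d$effects$v)
  # with censor_prob = 1 every nonsignificant effect is directionless
  expect_equal(d$effects$directionless, wald < zcrit)
  # significant effects are never altered
  expect_equal(d$effects$zr[wald >= zcrit], lat$zr_uncensored[wald >= zcrit])
  # the reduced variant keeps exactly the significant effects
  reduced <- build_dataset(d$effects[!d$effects$directionless, ], d$tree,
                           "reduced")
  expect_equal(reduced$k, sum(wald >= zcrit))
})

test_that("latent variance components reproduce their generating values", {
  tr0 <- simulation_truth(n_species = 15, n_studies = 20, seed = 0)
  comps <- purrr::map_dfr(1:300, function(s) {
    tr <- simulation_truth(n_species = 15, n_studies = 20, seed = s)
    lat <- attr(simulate_dataset(tr), "latent")
    # mean square over the unique draws is unbiased for each component
    # (marginal variances equal sigma2 even under phylogenetic correlation)
    tibble::tibble(
      phylo = mean(lat$u_phylo[!duplicated(lat$u_phylo)]^2),
      species = mean(lat$u_species[!duplicated(lat$u_species)]^2),
      study = mean(lat$u_study[!duplicated(lat$u_study)]^2),
      obs = mean(lat$u_obs^2)
    )
  })
  truth <- tr0$sigma2
  for (nm in names(truth)) {
    expect_lt(abs(mean(comps[[nm]]) - truth[[nm]]) / truth[[nm]], 0.10)
  }
})

test_that("raw payloads invert to the target correlations", {
  tr <- simulation_truth(n_species = 8, n_studies = 20, n_range = c(20, 60),
                         seed = 13)
  d <- simulate_dataset(tr)
  rec <- simulate_raw_payloads(d)
  expect_equal(nrow(attr(validate_effects(rec), "rejects")), 0)
  coded <- suppressMessages(code_effects(rec, "full"))
  coded <- coded[match(d$effects$record_id, coded$record_id), ]
  types <- rec$data_type[match(d$effects$record_id, rec$record_id)]
  exact <- types %in% c("correlation", "group_means", "group_test")
  expect_equal(coded$r[exact], d$effects$r[exact], tolerance = 1e-10)
  # frequency tables are integer-rounded; error bounded by the cell grid
  freq <- types == "frequency"
  n_freq <- d$effects$n_total[freq]
  expect_true(all(abs(coded$r[freq] - d$effects$r[freq]) <= 4 / n_freq))
})

test_that("exhaustive small-n frequency tables stay within the rounding bound", {
  # all target correlations on a grid at n = 20: discretized phi is within
  # the worst-case perturbation of one count per row
  n <- 20L
  for (r in seq(-0.9, 0.9, by = 0.05)) {
    tab <- choosiness:::r_to_freq_table(r, n)
    phi <- freq_table_to_r(tab["a"], tab["b"], tab["c"], tab["d"])
    expect_lte(abs(unname(phi) - r), 4 / n)
  }
})

test_that("truth objects validate their inputs", {
  expect_error(simulation_truth(n_range = c(3, 10)), "n_range")
  expect_error(simulation_truth(censor_prob = 1.5), "censor_prob")
  expect_error(simulation_truth(sigma2 = c(phylo = -0.1, species = 0,
                                           study = 0, obs = 0)))
  expect_error(simulation_truth(moderator_effects = c(charisma = 0.2)))
})

test_that("moderator offsets and year trends enter the latent means", {
  tr <- simulation_truth(beta0 = 0, n_species = 10, n_studies = 40,
                         moderator_effects = c(body_size = 0.5),
                         sigma2 = c(phylo = 0, species = 0, study = 0,
                                    obs = 0),
                         n_range = c(4000, 4000), seed = 17)
  d <- simulate_dataset(tr)
  lat <- attr(d, "latent")
  is_bs <- d$effects$state_factor == "body_size"
  expect_equal(unique(lat$true_zr[is_bs]), 0.5)
  expect_equal(unique(lat$true_zr[!is_bs]), 0)

  tr2 <- simulation_truth(beta0 = 0, n_species = 10, n_studies = 40,
                          trend_per_year = 0.02,
                          sigma2 = c(phylo = 0, species = 0, study = 0,
                                     obs = 0),
                          n_range = c(4000, 4000), seed = 18)
  d2 <- simulate_dataset(tr2)
  lat2 <- attr(d2, "latent")
  yr <- d2$effects$publication_year
  expect_equal(lat2$true_zr, 0.02 * (yr - mean(yr)), tolerance = 1e-12)
})

test_that("plot builders return ggplot objects", {
  dat <- small_dataset(71, n_species = 6, n_studies = 10)
  fit <- suppressMessages(meta_fit(dat, random = c("study", "obs")))
  expect_s3_class(plot_funnel(dat, fit), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  res <- suppressMessages(moderator_analysis(dat, "state_factor", min_k = 1,
                                             random = c("study", "obs")))
  expect_s3_class(plot_orchard(res), "ggplot")
})
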