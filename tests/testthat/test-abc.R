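make_small_table <- function(n = 300, seed = 21) {
  scns <- invasion_topologies()[1:2]
  build_reference_table(scns, n_sims_per_scenario = n, n_loci = 9, seed = seed)
}

test_that("reference tables are schema-complete and seed-reproducible", {
  tab <- make_small_table(60)
  expect_equal(nrow(tab), 120)
  expect_equal(sort(unique(tab$scenario)), c("floreana_first", "two_mainland_intros"))
  sn <- attr(tab, "stat_names")
  expect_true(all(sn %in% names(tab)))
  expect_equal(sum(grepl("^fst_", sn)), 6) # 4 sampled demes
  expect_false(anyNA(tab[, sn]))

  tab2 <- make_small_table(60)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  expect_error(
    build_reference_table(invasion_topologies()[1], 10),
    ">= 2 scenarios"
  )
})

test_that("posteriors sum to one, are order-invariant and symmetric for identical scenarios", {
  scn <- eq_scenario(ne = "N", sample = 20L)
  pr <- tibble::tibble(
    param = c("N", "mu"), dist = c("logunif", "logunif"),
    lo = c(100, 1e-4), hi = c(10000, 1e-3)
  )
  twins <- list(s1 = scn, s2 = scn)
  tab <- build_reference_table(twins,
    n_sims_per_scenario = 800,
    priors = list(s1 = pr, s2 = pr), n_loci = 9, seed = 31
  )
  obs <- summary_stats(
    simulate_scenario(scn, params = c(N = 1000, mu = 5e-4), n_loci = 9, seed = 32)
  )
  rej <- scenario_posterior(tab, obs, n_closest = 100, method = "rejection")
  expect_equal(sum(rej$posterior), 1, tolerance = 1e-9)
  expect_lt(abs(rej$posterior[1] - 0.5), 0.2) # symmetry within MC noise
  logi <- scenario_posterior(tab, obs, n_closest = 100, method = "logistic")
  expect_equal(sum(logi$posterior), 1, tolerance = 1e-6)

  # scenario order does not change the probabilities
  tab_rev <- tab[order(tab$scenario, decreasing = TRUE), ]
  attr(tab_rev, "stat_names") <- attr(tab, "stat_names")
  rej2 <- scenario_posterior(tab_rev, obs, n_closest = 100, method = "rejection")
  expect_equal(
    rej$posterior[match(rej2$scenario, rej$scenario)],
    rej2$posterior,
    tolerance = 1e-9
  )
  expect_error(scenario_posterior(tab, obs, n_closest = 1e6), "exceeds")
})

test_that("parameter estimation adjusts toward truth and orders quantiles", {
  scn <- eq_scenario(ne = "N", sample = 25L)
  pr <- tibble::tibble(
    param = c("N", "mu"), dist = c("logunif", "unif"),
    lo = c(100, 5e-4), hi = c(10000, 5e-4)
  )
  tab <- build_reference_table(list(eq = scn, eq2 = scn),
    n_sims_per_scenario = 1200,
    priors = list(eq = pr, eq2 = pr), n_loci = 12, seed = 41
  )
  obs <- summary_stats(
    simulate_scenario(scn, params = c(N = 1000, mu = 5e-4), n_loci = 12, seed = 42)
  )
  est <- suppressWarnings(estimate_parameters(tab, obs, "eq", n_closest = 120))
  n_row <- est[est$param == "N", ]
  expect_true(n_row$q025 < n_row$median & n_row$median < n_row$q975)
  expect_gt(n_row$median, 1000 / 2)
  expect_lt(n_row$median, 1000 * 2)

  # flat likelihood: a parameter the statistics do not depend on gets back
  # (approximately) its prior
  pr_flat <- dplyr::bind_rows(pr, tibble::tibble(
    param = "ghost", dist = "unif", lo = 0, hi = 1
  ))
  tabf <- build_reference_table(list(eq = scn, eq2 = scn),
    n_sims_per_scenario = 800,
    priors = list(eq = pr_flat, eq2 = pr_flat), n_loci = 9, seed = 43
  )
  estf <- suppressWarnings(estimate_parameters(tabf, obs, "eq", n_closest = 300))
  g <- estf[estf$param == "ghost", ]
  expect_lt(abs(g$median - 0.5), 0.15)
  expect_lt(g$q025, 0.15)
  expect_gt(g$q975, 0.85)
})

test_that("model checking projects the observed inside the predictive cloud", {
  scns <- invasion_topologies()[1:2]
  tab <- build_reference_table(scns, n_sims_per_scenario = 500, n_loci = 9, seed = 51)
  obs <- summary_stats(
    simulate_scenario(scns[[1]], params = separated_params(), n_loci = 9, seed = 52)
  )
  mc <- model_check(tab, obs, scns[[1]],
    n_closest = 60, n_pred = 80,
    n_loci = 9, seed = 53
  )
  expect_true(all(mc$tail$tail_prob >= 0 & mc$tail$tail_prob <= 1))
  # observed generated from the fitted scenario: at most one statistic in
  # the extreme tails
  expect_gte(sum(mc$tail$tail_prob > 0.05), nrow(mc$tail) - 1)
  expect_equal(sum(mc$pca$type == "observed"), 1)

  # PCA projection of the observed is invariant to reference row order
  tab_perm <- tab[sample(nrow(tab)), ]
  attr(tab_perm, "stat_names") <- attr(tab, "stat_names")
  mc2 <- model_check(tab_perm, obs, scns[[1]],
    n_closest = 60, n_pred = 10,
    n_loci = 9, seed = 53
  )
  o1 <- mc$pca[mc$pca$type == "observed", c("PC1", "PC2")]
  o2 <- mc2$pca[mc2$pca$type == "observed", c("PC1", "PC2")]
  expect_equal(abs(unlist(o1)), abs(unlist(o2)), tolerance = 1e-6)
})

test_that("confidence errors separate distinguishable scenarios and not twins", {
  # maximally distinct pair: with vs without a 100-fold founder bottleneck
  demes <- tibble::tibble(
    deme = c("Src", "Isl"), ne = c("5000", "500"),
    sample = c(15L, 15L)
  )
  no_bn <- scenario("no_bottleneck", demes, tibble::tibble(
    type = "split", time = "80", deme = "Isl", parent_a = "Src"
  ))
  with_bn <- scenario("with_bottleneck", demes, tibble::tibble(
    type = c("split", "bottleneck"),
    time = c("80", "20"), deme = "Isl",
    parent_a = c("Src", NA), size = c(NA, "5"), duration = c(NA, "60")
  ))
  pr <- tibble::tibble(
    param = "mu", dist = "logunif", lo = 1e-4, hi = 1e-3
  )
  scns <- list(no_bottleneck = no_bn, with_bottleneck = with_bn)
  prs <- list(no_bottleneck = pr, with_bottleneck = pr)
  tab <- build_reference_table(scns,
    n_sims_per_scenario = 700, priors = prs,
    n_loci = 9, seed = 61
  )
  err <- confidence_errors(scns, tab,
    n_pseudo_per_scenario = 30, priors = prs,
    n_closest = 70, seed = 62
  )
  expect_true(all(err$type1 >= 0 & err$type1 <= 1))
  expect_true(all(err$type2_mean >= 0 & err$type2_mean <= 1))
  expect_lt(max(err$type1), 0.2)
  expect_match(err$type2_label[1], "^\\d\\.\\d{2} \\[\\d\\.\\d{2}-\\d\\.\\d{2}\\]$")

  # indistinguishable twins: type-I around one half
  twin_scn <- eq_scenario(ne = "800", sample = 15L, name = "twin")
  twins <- list(t1 = twin_scn, t2 = twin_scn)
  prt <- list(t1 = pr, t2 = pr)
  tab2 <- build_reference_table(twins,
    n_sims_per_scenario = 400, priors = prt,
    n_loci = 9, seed = 63
  )
  err2 <- suppressWarnings(confidence_errors(twins, tab2,
    n_pseudo_per_scenario = 40,
    priors = prt, n_closest = 80, seed = 64
  ))
  expect_lt(abs(mean(err2$type1) - 0.5), 0.2)
  expect_warning(
    confidence_errors(twins, tab2,
      n_pseudo_per_scenario = 4, priors = prt,
      n_closest = 80, seed = 65
    ),
    "unstable"
  )
})
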