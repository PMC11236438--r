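test_that("pairwise Weir-Cockerham theta matches the nested-ANOVA oracle", {
  ds <- toy_two_pops(seed = 11)
  d <- tibble::as_tibble(ds)
  per <- ssrinvasion:::wc_theta(ds, per_locus = TRUE)
  for (L in ssr_loci(ds)) {
    s <- d[d$locus == L, ]
    expect_equal(per$theta[per$locus == L], anova_theta(s$a1, s$a2, s$pop),
      tolerance = 1e-10
    )
  }
  # multi-locus value is the ratio of summed components
  expect_equal(
    pairwise_fst(ds)["A", "B"],
    sum(per$a) / sum(per$abc)
  )
})

test_that("pairwise FST boundary cases behave", {
  # fixed for different alleles -> theta = 1
  d <- tibble::tibble(
    id = paste0("i", 1:8), pop = rep(c("A", "B"), each = 4),
    locus = "L1", a1 = rep(c(1L, 2L), each = 4), a2 = rep(c(1L, 2L), each = 4)
  )
  expect_equal(pairwise_fst(ssr_dataset(d))["A", "B"], 1)

  # a population split at random from one pool -> |theta| small
  fr <- dplyr::bind_rows(lapply(1:9, function(L) {
    tibble::tibble(pop = c("A", "B"), locus = paste0("L", L)) |>
      tidyr::crossing(allele = 1:4) |>
      dplyr::mutate(freq = 0.25)
  }))
  same <- generate_from_frequencies(fr, 10, seed = 77)
  th <- pairwise_fst(same)["A", "B"]
  expect_lt(abs(th), 0.05)

  # negative estimates kept by default, truncated on request
  if (th < 0) {
    expect_equal(pairwise_fst(same, truncate = TRUE)["A", "B"], 0)
  }
  # Nei Gst estimator also available and on a comparable scale
  gst <- pairwise_fst(same, estimator = "nei_gst")["A", "B"]
  expect_lt(abs(gst), 0.1)
})

test_that("AMOVA components match brute-force sums of squares", {
  ds <- generate_island_fixture(seed = 23)
  am <- amova(ds, n_permutations = 49, seed = 1)
  d2 <- ssrinvasion:::amova_distance(ds)
  ip <- dplyr::distinct(tibble::as_tibble(ds), id, pop)
  pop <- ip$pop[match(rownames(d2), ip$id)]
  ss <- brute_amova(d2, pop)
  expect_equal(unname(am$ss["among"]), unname(ss["among"]))
  expect_equal(unname(am$ss["within"]), unname(ss["within"]))
  expect_equal(sum(am$percent), 100, tolerance = 1e-8)
  expect_true(am$p_value > 0 && am$p_value <= 1)
})

test_that("AMOVA boundary behavior: no structure vs complete fixation", {
  # random split of one pool: among-population percentage ~ 0 (truncated)
  fr <- dplyr::bind_rows(lapply(1:8, function(L) {
    tidyr::crossing(pop = c("A", "B", "C"), locus = paste0("L", L), allele = 1:4) |>
      dplyr::mutate(freq = 0.25)
  }))
  pool <- generate_from_frequencies(fr, 12, seed = 1)
  am0 <- amova(pool, n_permutations = 99, seed = 2)
  expect_lt(am0$percent[1], 8)
  expect_gt(am0$p_value, 0.02)

  # two populations fixed for different alleles at all loci -> 100% among
  d <- dplyr::bind_rows(lapply(1:3, function(L) {
    tibble::tibble(
      id = paste0("i", 1:8), pop = rep(c("A", "B"), each = 4),
      locus = paste0("L", L),
      a1 = rep(c(1L, 2L), each = 4), a2 = rep(c(1L, 2L), each = 4)
    )
  }))
  am1 <- amova(ssr_dataset(d), n_permutations = 99, seed = 3)
  expect_equal(unname(am1$percent[1]), 100)
  # with 4+4 individuals only ~70 distinct label partitions exist, so the
  # permutation p cannot drop below ~0.04
  expect_lt(am1$p_value, 0.1)

  # tidy/glance expose the same numbers
  expect_equal(glance(am1)$phi_st, am1$phi_st)
  expect_equal(sum(tidy(am1)$percent), 100)
  expect_error(amova(pool, n_permutations = 0), "n_permutations")
})

test_that("Mantel test: perfect correlation, exact enumeration, oracle parity", {
  lab <- c("SantaCruz", "SanCristobal", "Isabela", "Floreana")
  m1 <- matrix(0, 4, 4, dimnames = list(lab, lab))
  m1[upper.tri(m1)] <- c(1, 2, 3, 4, 5, 6)
  m1 <- m1 + t(m1)
  m2 <- 2 + 3 * m1
  diag(m2) <- 0
  res <- mantel_test(m1, m2)
  expect_equal(res$r, 1)
  expect_equal(res$n_perm, 23) # 4! - 1 non-identity permutations
  expect_equal(res$mode, "exact_enumeration")

  # exact mode equals full-enumeration by hand on a random pair
  set.seed(4)
  a <- matrix(0, 4, 4, dimnames = list(lab, lab))
  a[upper.tri(a)] <- runif(6)
  a <- a + t(a)
  b <- matrix(0, 4, 4, dimnames = list(lab, lab))
  b[upper.tri(b)] <- runif(6)
  b <- b + t(b)
  got <- mantel_test(a, b)
  perms <- ssrinvasion:::all_permutations(4)
  ut <- upper.tri(a)
  rs <- vapply(perms, function(pm) cor(a[ut], b[pm, pm][ut]), 1.0)
  p_hand <- (sum(rs[-1] >= rs[1] - 1e-12) + 1) / 24
  expect_equal(got$p_value, p_hand)
  expect_equal(got$r, rs[1])

  # vegan agrees on r (independent implementation)
  vg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 99)
  expect_equal(got$r, unname(vg$statistic), tolerance = 1e-12)

  expect_error(mantel_test(a, b[1:3, 1:3]), "mismatch")
  z <- a
  z[] <- 1
  diag(z) <- 0
  expect_equal(mantel_test(a, z)$mode, "degenerate")
})

test_that("migration network: normalization, symmetry, directionality", {
  # exchangeable populations: near-symmetric network, max edge = 1
  fr <- dplyr::bind_rows(lapply(1:12, function(L) {
    tidyr::crossing(pop = c("A", "B"), locus = paste0("L", L), allele = 1:5) |>
      dplyr::mutate(freq = 0.2)
  }))
  same <- generate_from_frequencies(fr, 40, seed = 6)
  mig <- relative_migration(same, seed = 1)
  expect_equal(max(mig$m), 1)
  expect_lt(abs(mig$m["A", "B"] - mig$m["B", "A"]), 0.35)

  # source-sink: sink founded from a large source through a long bottleneck
  scn <- scenario(
    "ss",
    tibble::tibble(deme = c("Src", "Snk"), ne = c("20000", "200"), sample = c(30L, 30L)),
    tibble::tibble(type = "split", time = "100", deme = "Snk", parent_a = "Src")
  )
  ds <- simulate_scenario(scn, mutation_rate = 5e-4, params = c(mu = 5e-4), n_loci = 15, seed = 101)
  migb <- relative_migration(ds, n_bootstrap = 30, seed = 2)
  expect_gt(migb$m["Src", "Snk"], migb$m["Snk", "Src"])
  frac <- mean(migb$boot["Src", "Snk", ] > migb$boot["Snk", "Src", ])
  expect_gte(frac, 0.9)

  # all three statistics produce normalized directed networks
  for (st in c("nm", "gst", "d")) {
    m <- relative_migration(ds, statistic = st)$m
    expect_equal(max(m), 1)
    expect_equal(unname(diag(m)), c(0, 0))
  }
  expect_equal(nrow(tidy(mig)), 2)
})
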