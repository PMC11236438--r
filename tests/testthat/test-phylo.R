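test_that("Nei distance matches long-hand J arithmetic and boundary cases", {
  # one locus, two pops with known frequencies
  fr <- tibble::tibble(
    pop = rep(c("X", "Y"), each = 2), locus = "L1",
    allele = c(1L, 2L, 1L, 2L), freq = c(0.8, 0.2, 0.3, 0.7),
    count = c(16L, 4L, 6L, 14L), genes = 20L
  )
  D <- nei_distance(fr)
  jx <- 0.8^2 + 0.2^2
  jy <- 0.3^2 + 0.7^2
  jxy <- 0.8 * 0.3 + 0.2 * 0.7
  expect_equal(D["X", "Y"], -log(jxy / sqrt(jx * jy)))
  expect_equal(D["X", "X"], 0)
  expect_equal(D, t(D))

  # identical tables -> 0; disjoint alleles -> infinite sentinel
  fr_same <- fr
  fr_same$freq <- rep(c(0.8, 0.2), 2)
  expect_equal(nei_distance(fr_same)["X", "Y"], 0)
  fr_disj <- tibble::tibble(
    pop = rep(c("X", "Y"), each = 2), locus = "L1",
    allele = c(1L, 2L, 3L, 4L), freq = c(0.5, 0.5, 0.5, 0.5), genes = 20L
  )
  expect_true(is.infinite(nei_distance(fr_disj)["X", "Y"]))

  # nei78 applies the unbiased J correction (larger J, smaller D here)
  ds <- toy_two_pops(seed = 3)
  d72 <- nei_distance(ds, "nei72")["A", "B"]
  d78 <- nei_distance(ds, "nei78")["A", "B"]
  expect_false(isTRUE(all.equal(d72, d78)))
  expect_true(d78 >= 0 || is.finite(d78))
})

test_that("UPGMA reproduces the hand-worked merge and is ultrametric", {
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  tr <- upgma_tree(m)
  # expected ((A:1,B:1):1,C:2)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 4)
  expect_equal(cp["B", "C"], 4)
  root_depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(max(root_depths) - min(root_depths), 0, tolerance = 1e-9)

  # ultrametric input is reproduced exactly; agrees with hclust average link
  ds <- generate_island_fixture(seed = 31)
  D <- suppressWarnings(nei_distance(ds))
  tr2 <- upgma_tree(D)
  cp2 <- ape::cophenetic.phylo(tr2)
  tr3 <- upgma_tree(cp2[rownames(D), rownames(D)])
  expect_equal(
    ape::cophenetic.phylo(tr3)[rownames(D), rownames(D)],
    cp2[rownames(D), rownames(D)],
    tolerance = 1e-9
  )
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  expect_equal(sort(unique(round(cp2[upper.tri(cp2)], 9))),
    sort(unique(round(stats::cophenetic(hc)[], 9))),
    tolerance = 1e-6
  )

  # label permutation gives an isomorphic tree
  perm <- c("C", "A", "B")
  trp <- upgma_tree(m[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(trp)), 0,
    ignore_attr = TRUE
  )
  expect_error(upgma_tree(matrix(c(0, NA, NA, 0), 2)), "NaN/NA")
})

test_that("locus bootstrap supports behave at the boundaries", {
  # identical loci -> every support 100
  base <- tibble::tibble(
    id = paste0("i", 1:6), pop = rep(c("A", "B", "C"), each = 2),
    a1 = c(1L, 1L, 2L, 2L, 3L, 3L), a2 = c(1L, 2L, 2L, 3L, 3L, 3L)
  )
  d <- dplyr::bind_rows(lapply(1:5, function(L) {
    dplyr::mutate(base, locus = paste0("L", L))
  }))
  tr <- bootstrap_tree(ssr_dataset(d[, c("id", "pop", "locus", "a1", "a2")]),
    n_boot = 50, seed = 1
  )
  sup <- as.numeric(tr$node.label)
  expect_true(all(sup == 100))

  # two clearly separated groups get near-certain support
  rows <- list()
  for (p in 1:4) {
    grp_off <- ifelse(p <= 2, 0L, 100L)
    for (L in 1:9) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        pop = paste0("P", p), locus = paste0("L", L),
        allele = grp_off + 10L * p + c(0L, 1L), freq = 0.5
      )
    }
  }
  ds <- generate_from_frequencies(dplyr::bind_rows(rows), 10, seed = 5)
  trg <- bootstrap_tree(ds, n_boot = 100, seed = 2)
  sup2 <- as.numeric(trg$node.label)
  expect_true(all(sup2 >= 0 & sup2 <= 100))
  expect_equal(sup2[1], 100) # root
  expect_true(any(sup2 >= 99)) # the group bipartition

  one_locus <- ds[ds$locus == "L1", ]
  expect_error(
    bootstrap_tree(ssrinvasion:::new_ssr_tbl(one_locus,
      loci = "L1",
      pops = ssr_pops(ds)
    ), n_boot = 10),
    ">= 2 loci"
  )
})

test_that("Newick write/read round-trips topology, heights and supports", {
  ds <- generate_island_fixture(seed = 12)
  tr <- bootstrap_tree(ds, n_boot = 30, seed = 3)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  back <- read_newick(tf)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(
    ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
    ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
    tolerance = 1e-9
  )
  expect_setequal(back$node.label, tr$node.label)

  # two-leaf tree and reserved-character quoting
  m <- matrix(c(0, 3, 3, 0), 2, dimnames = list(
    c("San Cristobal", "B"),
    c("San Cristobal", "B")
  ))
  t2 <- upgma_tree(m)
  tf2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t2, tf2)
  txt <- readLines(tf2)
  expect_match(txt, "'San Cristobal':1.5", fixed = TRUE)
  expect_equal(sort(read_newick(tf2)$tip.label), sort(c("B", "San Cristobal")))
})

test_that("individual-level trees treat each individual as a population", {
  ds <- generate_island_fixture(seed = 14, n_pops = 2, n_per_pop = 4)
  tr <- bootstrap_tree(ds, n_boot = 10, seed = 1, by_individual = TRUE)
  expect_equal(length(tr$tip.label), 8)
  expect_setequal(tr$tip.label, unique(ds$id))
})
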