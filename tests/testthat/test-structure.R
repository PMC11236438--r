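test_that("dosage matrix encodes copies, conserves row sums, mean-imputes", {
  d <- dplyr::bind_rows(
    tibble::tibble(
      id = c("i1", "i2", "i3"), pop = "A", locus = "L1",
      a1 = c(1L, 1L, NA), a2 = c(1L, 2L, NA)
    ),
    tibble::tibble(
      id = c("i1", "i2", "i3"), pop = "A", locus = "L2",
      a1 = 5L, a2 = 5L
    )
  )
  m <- genotypes_to_allele_matrix(ssr_dataset(d), na_policy = "keep")
  expect_equal(unname(m["i1", c("L1.1", "L1.2")]), c(2, 0))
  expect_equal(unname(m["i2", c("L1.1", "L1.2")]), c(1, 1))
  expect_true(all(is.na(m["i3", c("L1.1", "L1.2")])))

  # mean imputation equals 2 x locus allele frequency among scored rows
  mi <- genotypes_to_allele_matrix(ssr_dataset(d), na_policy = "mean")
  expect_equal(unname(mi["i3", "L1.1"]), mean(c(2, 1)))

  # an individual with no scored locus at all is dropped with a warning
  d0 <- tibble::tibble(
    id = c("i1", "i2"), pop = "A", locus = "L1",
    a1 = c(1L, NA), a2 = c(2L, NA)
  )
  expect_warning(m0 <- genotypes_to_allele_matrix(ssr_dataset(d0)), "dropping")
  expect_equal(rownames(m0), "i1")

  # row sums = 2 x number of scored loci
  ds <- generate_island_fixture(seed = 8)
  mk <- genotypes_to_allele_matrix(ds, na_policy = "keep")
  scored <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ds), id),
    k = sum(!is.na(a1)), .groups = "drop"
  )
  rs <- rowSums(mk, na.rm = TRUE)
  expect_equal(unname(rs[scored$id]), 2 * scored$k)
})

test_that("BIC selects the true K on disjoint-allele populations", {
  mkfix <- function(seed) {
    rows <- list()
    for (p in 1:3) {
      for (L in 1:6) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          pop = paste0("P", p), locus = paste0("L", L),
          allele = 10 * p + L, freq = 1
        )
      }
    }
    generate_from_frequencies(dplyr::bind_rows(rows), 12, seed = seed)
  }
  hits <- 0
  for (s in 1:20) {
    cl <- find_clusters(mkfix(s), max_K = 6, seed = s)
    hits <- hits + (cl$K == 3)
  }
  expect_gte(hits / 20, 0.95)

  cl <- find_clusters(mkfix(1), max_K = 6, seed = 1)
  expect_equal(cl$bic$K[which.min(cl$bic$bic)], cl$K)
  expect_equal(nrow(cl$assignments), 36)
  # determinism given seed
  cl2 <- find_clusters(mkfix(1), max_K = 6, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)
  expect_error(find_clusters(mkfix(1), max_K = 1), "max_K")
  expect_error(find_clusters(mkfix(1), n_restarts = 0), "n_restarts")
})

test_that("BIC curve is shallow on unstructured data", {
  # a single panmictic pool: no K gives a decisive drop; the improvement
  # of the best K over K = 1 stays small relative to a structured dataset
  fr <- dplyr::bind_rows(lapply(1:8, function(L) {
    tidyr::crossing(pop = "A", locus = paste0("L", L), allele = 1:4) |>
      dplyr::mutate(freq = 0.25)
  }))
  pan <- generate_from_frequencies(fr, 60, seed = 5)
  cl_null <- find_clusters(pan, max_K = 6, seed = 2)
  drop_null <- cl_null$bic$bic[1] - min(cl_null$bic$bic)

  rows <- list()
  for (p in 1:3) {
    for (L in 1:8) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        pop = paste0("P", p), locus = paste0("L", L), allele = 10 * p, freq = 1
      )
    }
  }
  strct <- generate_from_frequencies(dplyr::bind_rows(rows), 20, seed = 5)
  cl_str <- find_clusters(strct, max_K = 6, seed = 2)
  drop_str <- cl_str$bic$bic[1] - min(cl_str$bic$bic)
  expect_gt(drop_str, 5 * max(drop_null, 1))
})

test_that("DAPC separates disjoint populations with certainty", {
  rows <- list()
  for (p in 1:2) {
    for (L in 1:6) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        pop = paste0("P", p), locus = paste0("L", L),
        allele = 10 * p + c(0L, 1L), freq = 0.5
      )
    }
  }
  ds <- generate_from_frequencies(dplyr::bind_rows(rows), 15, seed = 4)
  dp <- dapc_fit(ds)
  expect_equal(mean(dp$assigned == dp$coords$group), 1)
  expect_true(all(apply(dp$posterior, 1, max) > 0.99))
  expect_equal(unname(rowSums(dp$posterior)), rep(1, 30))
  # axis count = min(n_da, K - 1)
  expect_equal(length(dp$prop_var), 1)

  # permuting individual order permutes coordinates identically
  d <- tibble::as_tibble(ds)
  set.seed(1)
  ids <- unique(d$id)
  perm <- sample(ids)
  d2 <- d[order(match(d$id, perm)), ]
  dp2 <- dapc_fit(ssr_dataset(d2, loci = ssr_loci(ds)))
  c1 <- dp$coords[match(ids, dp$coords$id), ]
  c2 <- dp2$coords[match(ids, dp2$coords$id), ]
  expect_equal(abs(c1$LD1), abs(c2$LD1), tolerance = 1e-6)

  one <- ds[ds$pop == "P1", ]
  expect_error(
    dapc_fit(ssrinvasion:::new_ssr_tbl(one, loci = ssr_loci(ds), pops = "P1")),
    ">= 2 groups"
  )
})

test_that("PCoA reconstructs Euclidean configurations and honors the trace identity", {
  set.seed(2)
  xy <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(xy))
  rownames(D) <- colnames(D) <- paste0("s", 1:12)
  pc <- pcoa_dist(D)
  got <- as.matrix(pc$coords[, c("Axis1", "Axis2")])
  expect_lt(procrustes_rms(xy, got), 1e-8)

  # eigenvalue sum equals total centered squared-distance inertia
  n <- nrow(D)
  inertia <- sum(D^2) / (2 * n)
  J <- diag(n) - 1 / n
  expect_equal(sum(pc$eigenvalues), sum(diag(-0.5 * J %*% D^2 %*% J)),
    tolerance = 1e-8
  )

  # collinear points: one positive axis carries ~100% of positive inertia
  x <- cbind(c(0, 1, 3), 0)
  Dc <- as.matrix(dist(x))
  pcc <- pcoa_dist(Dc)
  expect_gt(pcc$prop_var[1], 0.999)

  expect_error(pcoa_dist(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  # agrees with classical cmdscale up to sign
  cm <- stats::cmdscale(D, k = 2)
  expect_equal(abs(got[, 1]), abs(unname(cm[, 1])), tolerance = 1e-8)
})
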