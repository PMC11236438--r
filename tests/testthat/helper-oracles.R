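# Independent oracles and tiny fixtures used across the suite. These are
# deliberately written from first principles (enumeration, nested ANOVA,
# set algebra) so they never share code paths with the implementation.

# Exact HWE probability-test p-value for a biallelic sample by complete
# enumeration: tables with fixed allele counts are indexed by the
# heterozygote count h; P(table) is proportional to 2^h / (n11! n12! n22!).
enum_hwe_p <- function(a1, a2) {
  stopifnot(length(unique(c(a1, a2))) == 2)
  al <- sort(unique(c(a1, a2)))
  n <- length(a1)
  nA <- sum(c(a1, a2) == al[1])
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logk <- vapply(hs, function(h) {
    n11 <- (nA - h) / 2
    n22 <- n - n11 - h
    h * log(2) - lfactorial(n11) - lfactorial(n22) - lfactorial(h)
  }, 1.0)
  pr <- exp(logk - max(logk))
  pr <- pr / sum(pr)
  obs_h <- sum(a1 != a2)
  obs_k <- logk[match(obs_h, hs)]
  sum(pr[logk <= obs_k + 1e-9])
}

# Weir-Cockerham theta for ONE locus via the nested ANOVA (mean squares)
# formulation: gene copies nested in individuals nested in populations,
# indicator response per allele, components summed over alleles.
anova_theta <- function(a1, a2, pop) {
  keep <- !is.na(a1)
  a1 <- a1[keep]
  a2 <- a2[keep]
  pop <- pop[keep]
  alleles <- sort(unique(c(a1, a2)))
  pops <- unique(pop)
  r <- length(pops)
  n_i <- as.vector(table(factor(pop, levels = pops)))
  n_tot <- sum(n_i)
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  num <- den <- 0
  for (A in alleles) {
    y <- cbind(as.numeric(a1 == A), as.numeric(a2 == A)) # gene copies
    ybar_ind <- rowMeans(y)
    ybar_pop <- tapply(ybar_ind, factor(pop, levels = pops), mean)
    ybar_all <- sum(ybar_ind) / n_tot
    ssg <- sum((y - ybar_ind)^2) # within individuals
    ssi <- 2 * sum((ybar_ind - ybar_pop[match(pop, pops)])^2)
    ssa <- 2 * sum(n_i * (ybar_pop - ybar_all)^2)
    msg <- ssg / n_tot
    msi <- ssi / (n_tot - r)
    msa <- ssa / (r - 1)
    s2_g <- msg
    s2_i <- (msi - msg) / 2
    s2_a <- (msa - msi) / (2 * nc)
    num <- num + s2_a
    den <- den + s2_a + s2_i + s2_g
  }
  num / den
}

# brute-force AMOVA sums of squares from definitional double loops
brute_amova <- function(d2, pop) {
  N <- length(pop)
  pops <- unique(pop)
  ss_tot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_tot <- ss_tot + d2[i, j]
  ss_tot <- ss_tot / N
  ss_wp <- 0
  for (p in pops) {
    idx <- which(pop == p)
    s <- 0
    if (length(idx) > 1) {
      for (i in idx) for (j in idx) s <- s + d2[i, j]
    }
    ss_wp <- ss_wp + s / (2 * length(idx))
  }
  c(among = ss_tot - ss_wp, within = ss_wp, total = ss_tot)
}

# small deterministic 2-population fixture with moderate differentiation
toy_two_pops <- function(seed = 11, n = 12, n_loci = 4) {
  rows <- list()
  set.seed(seed)
  for (L in seq_len(n_loci)) {
    pa <- c(0.7, 0.2, 0.1)
    pb <- c(0.2, 0.5, 0.3)
    rows[[length(rows) + 1]] <- tibble::tibble(
      pop = "A", locus = paste0("L", L), allele = 1:3, freq = pa
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      pop = "B", locus = paste0("L", L), allele = 1:3, freq = pb
    )
  }
  generate_from_frequencies(dplyr::bind_rows(rows), n, seed = seed + 1)
}

# simple Procrustes RMS after centering and optimal rotation/reflection
procrustes_rms <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(t(Y) %*% X)
  R <- s$u %*% t(s$v)
  Yr <- Y %*% R
  # allow global scale
  sc <- sum(Yr * X) / sum(Yr^2)
  sqrt(mean((X - sc * Yr)^2))
}

# equilibrium one-deme scenario template used in several tests
eq_scenario <- function(ne = "N", sample = 25L, name = "eq") {
  scenario(
    name,
    tibble::tibble(deme = "A", ne = ne, sample = sample),
    tibble::tibble(
      type = character(), time = character(), deme = character(),
      parent_a = character()
    )
  )
}

# well-separated fixed parameters for the catalog invasion topologies
separated_params <- function() {
  c(
    N1 = 5000, N2 = 300, N3 = 300, N4 = 300, N5 = 300,
    Nb2 = 10, Nb3 = 10, Nb4 = 10, Nb5 = 10,
    db1 = 10, db2 = 10, db3 = 10, db4 = 10,
    t4 = 120, t3 = 90, t2 = 60, t1 = 30, mu = 5e-4
  )
}
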