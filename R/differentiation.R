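# Per-locus inputs for Weir & Cockerham (1984) theta: for each population,
# the scored sample size n_i, allele frequencies p_i(A), and observed
# heterozygote frequencies h_i(A) (fraction of individuals heterozygous and
# carrying allele A).
wc_locus_input <- function(data, locus) {
  d <- tibble::as_tibble(data)
  d <- d[d$locus == locus & !is.na(d$a1), , drop = FALSE]
  pops <- intersect(ssr_pops(data), unique(d$pop))
  alleles <- sort(unique(c(d$a1, d$a2)))
  n <- vapply(pops, function(p) sum(d$pop == p), 1L)
  p <- matrix(0, length(alleles), length(pops), dimnames = list(alleles, pops))
  h <- matrix(0, length(alleles), length(pops), dimnames = list(alleles, pops))
  for (k in seq_along(pops)) {
    sub <- d[d$pop == pops[k], , drop = FALSE]
    cnt <- tabulate(match(c(sub$a1, sub$a2), alleles), length(alleles))
    p[, k] <- cnt / (2 * nrow(sub))
    hets <- sub[sub$a1 != sub$a2, , drop = FALSE]
    if (nrow(hets) > 0) {
      hc <- tabulate(match(c(hets$a1, hets$a2), alleles), length(alleles))
      h[, k] <- hc / nrow(sub)
    }
  }
  list(alleles = alleles, pops = pops, n = n, p = p, h = h)
}

# Weir & Cockerham (1984) variance components a (among populations),
# b (among individuals within populations), c (within individuals), per
# allele at one locus. Returns a matrix with columns a, b, c.
wc_abc <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  out <- matrix(NA_real_, nrow(p), 3, dimnames = list(rownames(p), c("a", "b", "c")))
  for (A in seq_len(nrow(p))) {
    pbar <- sum(n * p[A, ]) / (r * nbar)
    s2 <- sum(n * (p[A, ] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h[A, ]) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    out[A, ] <- c(a, b, cc)
  }
  out
}

# Multi-locus W&C theta over a set of populations: ratio of summed components.
wc_theta <- function(data, pops = NULL, per_locus = FALSE) {
  if (!is.null(pops)) {
    data <- ssr_subset_pops(data, pops)
  }
  loci <- ssr_loci(data)
  per <- lapply(loci, function(L) {
    inp <- wc_locus_input(data, L)
    if (length(inp$pops) < 2 || length(inp$alleles) < 1 || any(inp$n < 1)) {
      return(c(a = NA_real_, abc = NA_real_))
    }
    if (length(inp$alleles) == 1) {
      return(c(a = 0, abc = 0))
    }
    comp <- wc_abc(inp$n, inp$p, inp$h)
    c(a = sum(comp[, "a"]), abc = sum(comp))
  })
  m <- do.call(rbind, per)
  theta_loc <- ifelse(m[, "abc"] != 0, m[, "a"] / m[, "abc"], NA_real_)
  if (per_locus) {
    return(tibble::tibble(
      locus = loci, a = m[, "a"], abc = m[, "abc"],
      theta = theta_loc
    ))
  }
  sum(m[, "a"], na.rm = TRUE) / sum(m[, "abc"], na.rm = TRUE)
}

ssr_subset_pops <- function(data, pops) {
  out <- tibble::as_tibble(data)
  out <- out[out$pop %in% pops, , drop = FALSE]
  new_ssr_tbl(out, loci = ssr_loci(data), pops = pops)
}

#' Pairwise FST between populations
#'
#' Multi-locus Weir & Cockerham (1984) theta (ratio of variance-component
#' sums across loci and alleles), or Nei's Gst, for every population pair.
#' Negative estimates are reported as computed unless `truncate = TRUE`.
#'
#' @param data An `ssr_tbl` with >= 2 populations.
#' @param estimator `"weir_cockerham"` (default) or `"nei_gst"`.
#' @param truncate Truncate negative estimates at 0.
#' @return A symmetric [dist_matrix()] over populations; pairs with no shared
#'   scored locus are `NA`.
#' @export
pairwise_fst <- function(data, estimator = c("weir_cockerham", "nei_gst"),
                         truncate = FALSE) {
  estimator <- match.arg(estimator)
  pops <- ssr_pops(data)
  if (length(pops) < 2) stop("pairwise_fst needs >= 2 populations", call. = FALSE)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1)) {
      pr <- c(pops[j], pops[i])
      th <- if (estimator == "weir_cockerham") {
        wc_theta(data, pops = pr)
      } else {
        nei_gst_pair(data, pr)
      }
      if (truncate && is.finite(th)) th <- max(0, th)
      m[i, j] <- m[j, i] <- th
    }
  }
  diag(m) <- 0
  dist_matrix(m, labels = pops)
}

# Nei's Gst for a pair of populations, multi-locus (ratio of mean Ht-Hs).
nei_gst_pair <- function(data, pops) {
  fr <- allele_frequencies(ssr_subset_pops(data, pops))
  loci <- intersect(ssr_loci(data), unique(fr$locus))
  hts <- hss <- numeric(0)
  for (L in loci) {
    sub <- fr[fr$locus == L, ]
    if (length(unique(sub$pop)) < 2) next
    alleles <- sort(unique(sub$allele))
    pm <- matrix(0, length(alleles), 2, dimnames = list(alleles, pops))
    for (k in 1:2) {
      s <- sub[sub$pop == pops[k], ]
      pm[match(s$allele, alleles), k] <- s$freq
    }
    hs <- mean(1 - colSums(pm^2))
    ht <- 1 - sum(rowMeans(pm)^2)
    hts <- c(hts, ht)
    hss <- c(hss, hs)
  }
  if (length(hts) == 0 || mean(hts) == 0) {
    return(NA_real_)
  }
  (mean(hts) - mean(hss)) / mean(hts)
}

# Squared inter-individual distance matrix: number of allele mismatches
# (0/1/2) per locus, summed over loci scored in both individuals.
amova_distance <- function(data) {
  loci <- ssr_loci(data)
  ids <- unique(data$id)
  n <- length(ids)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(ids, loci))
  a2 <- a1
  idx <- cbind(match(data$id, ids), match(data$locus, loci))
  a1[idx] <- data$a1
  a2[idx] <- data$a2
  d2 <- matrix(0, n, n, dimnames = list(ids, ids))
  for (L in seq_along(loci)) {
    x1 <- a1[, L]
    x2 <- a2[, L]
    ok <- !is.na(x1)
    # shared-allele count between unordered pairs {x1,x2} and {y1,y2}
    for (i in which(ok)) {
      js <- which(ok & seq_len(n) > i)
      if (length(js) == 0) next
      s <- (x1[js] == x1[i]) + (x2[js] == x2[i])
      alt <- (x1[js] == x2[i]) + (x2[js] == x1[i])
      # homozygote/heterozygote cases: shared count is the best matching
      shared <- pmax(s, alt)
      # guard: {a,b} vs {a,a} must give 1, not 2
      hom_i <- x1[i] == x2[i]
      hom_j <- x1[js] == x2[js]
      shared[hom_i != hom_j & shared == 2] <- 1L
      mism <- 2L - shared
      d2[i, js] <- d2[i, js] + mism
      d2[js, i] <- d2[i, js]
    }
  }
  d2
}

amova_phi <- function(d2, pop_of) {
  pops <- unique(pop_of)
  N <- length(pop_of)
  P <- length(pops)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_wp <- 0
  for (p in pops) {
    idx <- which(pop_of == p)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_wp <- ss_wp + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_ap <- ss_total - ss_wp
  df_a <- P - 1
  df_w <- N - P
  ms_w <- ss_wp / df_w
  nprime <- (N - sum(table(pop_of)^2) / N) / df_a
  sigma_w <- ms_w
  sigma_a <- (ss_ap / df_a - ms_w) / nprime
  phi <- sigma_a / (sigma_a + sigma_w)
  list(
    ss = c(among = ss_ap, within = ss_wp, total = ss_total),
    df = c(among = df_a, within = df_w),
    sigma = c(among = sigma_a, within = sigma_w), phi_st = phi
  )
}

#' Analysis of molecular variance (AMOVA)
#'
#' One-level AMOVA on squared inter-individual distances (number of allele
#' differences per locus, 0/1/2, summed over loci — the standard codominant
#' distance), with method-of-moments variance components and a permutation
#' test that reassigns individuals to populations. The observed statistic is
#' included in both numerator and denominator of the p-value.
#'
#' @param data An `ssr_tbl` with >= 2 populations.
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @return An object of class `ssr_amova`: variance components (raw and
#'   truncated-at-zero), percentages of variation, Phi_ST, permutation
#'   p-value. Has [generics::tidy()] and [generics::glance()] methods.
#' @export
amova <- function(data, n_permutations = 999, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d2 <- amova_distance(data)
  ip <- dplyr::distinct(tibble::as_tibble(data), .data$id, .data$pop)
  pop_of <- ip$pop[match(rownames(d2), ip$id)]
  obs <- amova_phi(d2, pop_of)
  hits <- 1L # observed counts
  for (b in seq_len(n_permutations)) {
    perm <- amova_phi(d2, sample(pop_of))
    if (perm$phi_st >= obs$phi_st - 1e-12) hits <- hits + 1L
  }
  pval <- hits / (n_permutations + 1)
  sig_raw <- obs$sigma
  sig_tr <- pmax(sig_raw, 0)
  pct <- 100 * sig_tr / sum(sig_tr)
  structure(
    list(
      ss = obs$ss, df = obs$df, sigma_raw = sig_raw, sigma = sig_tr,
      percent = pct, phi_st = obs$phi_st, p_value = pval,
      n_permutations = n_permutations
    ),
    class = "ssr_amova"
  )
}

#' @export
print.ssr_amova <- function(x, ...) {
  cat("AMOVA (one level: among / within populations)\n")
  tab <- data.frame(
    df = c(x$df, sum(x$df)),
    SS = round(c(x$ss[c("among", "within")], x$ss["total"]), 3),
    sigma2 = c(round(x$sigma, 4), NA),
    percent = c(round(x$percent, 2), NA),
    row.names = c("Among populations", "Within populations", "Total")
  )
  print(tab)
  cat(sprintf(
    "Phi_ST = %.4f, p = %.4g (%d permutations)\n",
    x$phi_st, x$p_value, x$n_permutations
  ))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with significance
#' from permutations of the labels of one matrix. For `n <= 7` labels the
#' default `"auto"` mode enumerates all `n! - 1` non-identity permutations
#' exactly (4 labels give 23, the maximum possible for such a matrix);
#' otherwise random permutations are used.
#'
#' @param m1,m2 Symmetric matrices with identical labels (size >= 3).
#' @param mode `"auto"`, `"exact_enumeration"` or `"permutation"`.
#' @param n_perm Random permutation count for permutation mode.
#' @param alternative `"greater"` (default, the isolation-by-distance
#'   direction), `"less"` or `"two.sided"`.
#' @param seed Optional integer seed.
#' @return A tibble: `r`, `p_value`, `n_perm` (permutations other than the
#'   observed labelling), `mode`.
#' @export
mantel_test <- function(m1, m2, mode = c("auto", "exact_enumeration", "permutation"),
                        n_perm = 999, alternative = c("greater", "less", "two.sided"),
                        seed = NULL) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  m1 <- as.matrix(m1)
  m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrix size mismatch", call. = FALSE)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
    !identical(rownames(m1), rownames(m2))) {
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  if (n < 3) stop("Mantel test needs >= 3 labels", call. = FALSE)
  ut <- upper.tri(m1)
  if (stats::sd(m1[ut]) == 0 || stats::sd(m2[ut]) == 0) {
    return(tibble::tibble(
      r = NA_real_, p_value = NA_real_, n_perm = 0L,
      mode = "degenerate"
    ))
  }
  r_obs <- stats::cor(m1[ut], m2[ut])
  score <- function(r) {
    switch(alternative,
      greater = r,
      less = -r,
      two.sided = abs(r)
    )
  }
  if (mode == "auto") {
    mode <- if (n <= 7) "exact_enumeration" else "permutation"
  }
  if (mode == "exact_enumeration") {
    if (n > 7) stop("exact enumeration limited to <= 7 labels", call. = FALSE)
    perms <- all_permutations(n)
    rs <- vapply(perms, function(pm) {
      stats::cor(m1[ut], m2[pm, pm][ut])
    }, 1.0)
    # first permutation is the identity = observed
    r_perm <- rs[-1]
    p <- (sum(score(r_perm) >= score(r_obs) - 1e-12) + 1) / (length(r_perm) + 1)
    return(tibble::tibble(
      r = r_obs, p_value = p, n_perm = length(r_perm),
      mode = "exact_enumeration"
    ))
  }
  r_perm <- vapply(seq_len(n_perm), function(b) {
    pm <- sample.int(n)
    stats::cor(m1[ut], m2[pm, pm][ut])
  }, 1.0)
  p <- (sum(score(r_perm) >= score(r_obs) - 1e-12) + 1) / (n_perm + 1)
  tibble::tibble(r = r_obs, p_value = p, n_perm = n_perm, mode = "permutation")
}

# all permutations of 1..n, identity first
all_permutations <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  sub <- all_permutations(n - 1L)
  out <- list()
  for (s in sub) {
    for (pos in seq(0, n - 1)) {
      out[[length(out) + 1L]] <- append(s, n, after = pos)
    }
  }
  ident <- seq_len(n)
  idx <- which(vapply(out, function(p) all(p == ident), TRUE))
  c(out[idx], out[-idx])
}

#' Directional relative migration network
#'
#' Sundqvist-style directional method: for each population pair (i, j) a
#' hypothetical migrant pool is built with allele frequencies midway between
#' the two populations; the differentiation of each real population from the
#' pool is converted to a migration estimate (a population close to the pool
#' receives much gene flow), and the whole directed matrix is normalised by
#' its maximum so the strongest edge equals 1.
#'
#' @param data An `ssr_tbl` with >= 2 populations.
#' @param statistic `"nm"` (default), `"gst"` or `"d"` (Jost's D based).
#' @param n_bootstrap Bootstrap replicates over individuals within
#'   populations (0 = none) for edge stability.
#' @param seed Optional integer seed.
#' @return An object of class `ssr_migration`: `m` the directed matrix
#'   (`m[i, j]` = relative migration from i into j), `statistic`, and with
#'   bootstrapping a `boot` array of replicate networks.
#' @export
relative_migration <- function(data, statistic = c("nm", "gst", "d"),
                               n_bootstrap = 0, seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  m <- migration_matrix(data, statistic)
  boot <- NULL
  if (n_bootstrap > 0) {
    pops <- ssr_pops(data)
    boot <- array(NA_real_, c(length(pops), length(pops), n_bootstrap),
      dimnames = list(pops, pops, NULL)
    )
    ip <- dplyr::distinct(tibble::as_tibble(data), .data$id, .data$pop)
    for (b in seq_len(n_bootstrap)) {
      take <- unlist(lapply(pops, function(p) {
        ids <- ip$id[ip$pop == p]
        sample(ids, length(ids), replace = TRUE)
      }))
      rows <- lapply(seq_along(take), function(k) {
        sub <- data[data$id == take[k], , drop = FALSE]
        sub$id <- paste0("b", k)
        sub
      })
      bd <- ssr_dataset(dplyr::bind_rows(rows),
        loci = ssr_loci(data),
        pops = pops
      )
      boot[, , b] <- migration_matrix(bd, statistic)
    }
  }
  structure(list(m = m, statistic = statistic, boot = boot),
    class = "ssr_migration"
  )
}

migration_matrix <- function(data, statistic) {
  pops <- ssr_pops(data)
  fr <- allele_frequencies(data)
  loci <- ssr_loci(data)
  raw <- matrix(NA_real_, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_along(pops)) {
      if (i == j) next
      # migration from pops[i] into pops[j]: keyed to the SENDER's
      # differentiation from the hypothetical migrant pool — a population
      # that exports many migrants dominates the pool and sits close to it
      dstat <- pool_differentiation(fr, loci, pops[j], pops[i], statistic)
      raw[i, j] <- if (is.na(dstat) || dstat <= 0) {
        Inf
      } else {
        (1 - dstat) / (4 * dstat)
      }
    }
  }
  finite <- raw[is.finite(raw)]
  cap <- if (length(finite) > 0) max(finite) else 1
  raw[is.infinite(raw)] <- cap
  mx <- max(raw, na.rm = TRUE)
  out <- if (mx > 0) raw / mx else raw
  diag(out) <- 0
  out
}

# directional differentiation of population `to` from the hypothetical
# migrant pool of (from, to); the pool has the midpoint allele frequencies
# and the asymmetry enters through the within-population diversities.
pool_differentiation <- function(fr, loci, from, to, statistic) {
  hts <- hss <- numeric(0)
  for (L in loci) {
    sub <- fr[fr$locus == L & fr$pop %in% c(from, to), ]
    if (length(unique(sub$pop)) < 2) next
    alleles <- sort(unique(sub$allele))
    pf <- pt_ <- numeric(length(alleles))
    pf[match(sub$allele[sub$pop == from], alleles)] <- sub$freq[sub$pop == from]
    pt_[match(sub$allele[sub$pop == to], alleles)] <- sub$freq[sub$pop == to]
    pool <- (pf + pt_) / 2
    hs_to <- 1 - sum(pt_^2)
    hs_pool <- 1 - sum(pool^2)
    pair_mean <- (pt_ + pool) / 2
    ht <- 1 - sum(pair_mean^2)
    hts <- c(hts, ht)
    hss <- c(hss, (hs_to + hs_pool) / 2)
  }
  if (length(hts) == 0) {
    return(NA_real_)
  }
  ht <- mean(hts)
  hs <- mean(hss)
  if (statistic == "d") {
    if (hs >= 1) {
      return(NA_real_)
    }
    return(2 * (ht - hs) / (1 - hs)) # Jost D, n = 2 demes
  }
  if (ht == 0) {
    return(0)
  }
  (ht - hs) / ht # Gst; "nm" and "gst" share it, converted downstream
}

#' @export
print.ssr_migration <- function(x, ...) {
  cat(
    "Relative migration network (statistic:", x$statistic,
    "); m[i, j] = flow i -> j\n"
  )
  print(round(x$m, 3))
  invisible(x)
}
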