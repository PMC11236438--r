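# Conditional log-probability kernel of a genotype table given allele counts:
# log P = const + h*log(2) - sum_{i<=j} lfactorial(n_ij). Only the variable
# part is needed for comparisons between tables with the same allele counts.
hwe_log_kernel <- function(a1, a2) {
  h <- sum(a1 != a2)
  key <- paste(pmin(a1, a2), pmax(a1, a2))
  h * log(2) - sum(lfactorial(tabulate(factor(key))))
}

# One (locus, population) Guo-Thompson chain. The chain operates on the
# ordered vector of 2n allele slots; swapping two uniformly chosen slots is a
# symmetric proposal whose stationary distribution is uniform over orderings,
# which induces exactly the HWE conditional distribution on genotype tables.
# p = Pr(P(table) <= P(observed)), estimated as the fraction of visited
# states at or below the observed kernel, with a batch-mean standard error.
hwe_chain <- function(a1, a2, dememorization, batches, iterations) {
  slots <- as.vector(rbind(a1, a2))
  n2 <- length(slots)
  obs <- hwe_log_kernel(a1, a2)
  eps <- 1e-9
  kern <- function(s) {
    o <- seq(1, n2, by = 2)
    hwe_log_kernel(s[o], s[o + 1])
  }
  swap_many <- function(s, k) {
    for (i in seq_len(k)) {
      ij <- sample.int(n2, 2)
      s[ij] <- s[ij[2:1]]
    }
    s
  }
  slots <- swap_many(slots, dememorization)
  batch_means <- numeric(batches)
  for (b in seq_len(batches)) {
    hits <- 0L
    for (i in seq_len(iterations)) {
      ij <- sample.int(n2, 2)
      slots[ij] <- slots[ij[2:1]]
      if (kern(slots) <= obs + eps) hits <- hits + 1L
    }
    batch_means[b] <- hits / iterations
  }
  p <- mean(batch_means)
  se <- stats::sd(batch_means) / sqrt(batches)
  c(p = p, se = se)
}

#' Exact tests of Hardy-Weinberg equilibrium (probability test)
#'
#' Guo-Thompson Markov chain estimate of the exact probability test: the
#' p-value is the probability, under HWE conditional on the observed allele
#' counts, of a genotype table no more probable than the observed one. The
#' chain defaults mirror the classic Markov chain settings (dememorization
#' 1000, 100 batches of 1000 iterations) and a Monte Carlo standard error is
#' computed from batch means.
#'
#' @param data An `ssr_tbl`.
#' @param loci,pops Optional subsets; default all loci / populations.
#' @param pooled Test each locus on all populations pooled (one test per
#'   locus) instead of per (locus, population).
#' @param dememorization,batches,iterations Markov chain parameters.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with `locus` (, `pop`), `n_ind`, `n_alleles`, `p_hwe`,
#'   `se`, and a Bonferroni-adjusted column `p_bonferroni` (adjusted across
#'   the rows returned). Monomorphic or too-small combinations get `NA` with
#'   `note = "not applicable"`.
#' @export
hwe_test <- function(data, loci = NULL, pops = NULL, pooled = FALSE,
                     dememorization = 1000, batches = 100, iterations = 1000,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loci)) loci <- ssr_loci(data)
  d <- tibble::as_tibble(data)
  if (pooled) d$pop <- "(pooled)"
  if (is.null(pops)) pops <- unique(d$pop)
  combos <- expand.grid(locus = loci, pop = pops, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    sub <- d[d$locus == combos$locus[k] & d$pop == combos$pop[k] & !is.na(d$a1), ]
    n_all <- length(unique(c(sub$a1, sub$a2)))
    base <- tibble::tibble(
      locus = combos$locus[k], pop = combos$pop[k],
      n_ind = nrow(sub), n_alleles = n_all
    )
    if (nrow(sub) < 3 || n_all < 2) {
      return(dplyr::mutate(base,
        p_hwe = NA_real_, se = NA_real_,
        note = "not applicable"
      ))
    }
    est <- hwe_chain(sub$a1, sub$a2, dememorization, batches, iterations)
    dplyr::mutate(base, p_hwe = est[["p"]], se = est[["se"]], note = "")
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- stats::p.adjust(out$p_hwe, method = "bonferroni")
  if (pooled) out$pop <- NULL
  out
}
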