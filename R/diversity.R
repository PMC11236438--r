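#' Allele frequencies per population and locus
#'
#' Each non-missing diploid genotype contributes two gene copies. A
#' (population, locus) combination with zero scored genotypes is simply absent
#' from the table (never NaN-filled).
#'
#' @param data An `ssr_tbl`.
#' @param pooled If `TRUE`, pool all populations into a single table (the
#'   pooled frequency is the gene-count-weighted mean of population
#'   frequencies).
#' @return A tibble with columns `pop` (absent when `pooled`), `locus`,
#'   `allele`, `count`, `genes` (gene copies scored at that pop x locus) and
#'   `freq`.
#' @export
allele_frequencies <- function(data, pooled = FALSE) {
  d <- tibble::as_tibble(data)
  d <- d[!is.na(d$a1), , drop = FALSE]
  long <- tibble::tibble(
    pop = rep(d$pop, 2), locus = rep(d$locus, 2),
    allele = c(d$a1, d$a2)
  )
  if (pooled) long$pop <- "(pooled)"
  counts <- dplyr::count(long, .data$pop, .data$locus, .data$allele, name = "count")
  counts <- dplyr::mutate(dplyr::group_by(counts, .data$pop, .data$locus),
    genes = sum(.data$count), freq = .data$count / .data$genes
  )
  counts <- dplyr::ungroup(counts)
  counts <- counts[order(
    match(counts$pop, c(ssr_pops(data), "(pooled)")),
    match(counts$locus, ssr_loci(data)), counts$allele
  ), ]
  if (pooled) counts$pop <- NULL
  counts
}

# per (pop, locus): Ho, plain and unbiased He (Nei 1978), gene counts
per_pop_locus_h <- function(data) {
  d <- tibble::as_tibble(data)
  d <- d[!is.na(d$a1), , drop = FALSE]
  het <- dplyr::summarise(dplyr::group_by(d, .data$pop, .data$locus),
    n_ind = dplyr::n(), ho = mean(.data$a1 != .data$a2), .groups = "drop"
  )
  fr <- allele_frequencies(data)
  he <- dplyr::summarise(dplyr::group_by(fr, .data$pop, .data$locus),
    genes = .data$genes[1], na = dplyr::n(),
    he_plain = 1 - sum(.data$freq^2), .groups = "drop"
  )
  out <- dplyr::left_join(het, he, by = c("pop", "locus"))
  out$he_unbiased <- ifelse(out$genes > 1,
    out$genes / (out$genes - 1) * out$he_plain, 0
  )
  out
}

#' Observed and expected heterozygosity
#'
#' Ho is the fraction of heterozygous genotypes among scored individuals. He
#' (gene diversity) is \eqn{1 - \sum_k p_k^2}; with `unbiased = TRUE` the
#' small-sample correction \eqn{2n/(2n-1)} (Nei 1978) is applied, appropriate
#' for the small island samples this package targets.
#'
#' @param data An `ssr_tbl`.
#' @param level `"locus"` (pooled across populations, one row per locus),
#'   `"population"` (mean over loci of within-population values, one row per
#'   population) or `"global"`.
#' @param unbiased Apply the small-sample correction to He (default `TRUE`).
#' @return A tibble. At `level = "global"` a single row with `ho`, `he_pooled`
#'   (mean over loci of pooled-sample gene diversity) and `he_mean_pop` (mean
#'   over loci and populations of within-population gene diversity Hs) — two
#'   defensible readings of a "global He", both reported.
#' @export
heterozygosity <- function(data, level = c("population", "locus", "global"),
                           unbiased = TRUE) {
  level <- match.arg(level)
  ppl <- per_pop_locus_h(data)
  pick <- function(t) if (unbiased) t$he_unbiased else t$he_plain
  if (level == "population") {
    out <- dplyr::summarise(dplyr::group_by(ppl, .data$pop),
      n_loci = dplyr::n(), ho = mean(.data$ho),
      he = mean(if (unbiased) .data$he_unbiased else .data$he_plain),
      .groups = "drop"
    )
    out <- out[match(ssr_pops(data), out$pop), ]
    return(out)
  }
  # pooled-sample per-locus values
  d <- tibble::as_tibble(data)
  d <- d[!is.na(d$a1), , drop = FALSE]
  het <- dplyr::summarise(dplyr::group_by(d, .data$locus),
    n_ind = dplyr::n(), ho = mean(.data$a1 != .data$a2), .groups = "drop"
  )
  fr <- allele_frequencies(data, pooled = TRUE)
  he <- dplyr::summarise(dplyr::group_by(fr, .data$locus),
    genes = .data$genes[1], na = dplyr::n(),
    he_plain = 1 - sum(.data$freq^2), .groups = "drop"
  )
  loc <- dplyr::left_join(het, he, by = "locus")
  loc$he <- if (unbiased) {
    ifelse(loc$genes > 1, loc$genes / (loc$genes - 1) * loc$he_plain, 0)
  } else {
    loc$he_plain
  }
  loc <- loc[match(ssr_loci(data), loc$locus), c("locus", "n_ind", "na", "ho", "he")]
  if (level == "locus") {
    return(loc)
  }
  tibble::tibble(
    ho = mean(loc$ho), he_pooled = mean(loc$he),
    he_mean_pop = mean(pick(ppl))
  )
}

#' Within-population inbreeding coefficient FIS
#'
#' Per population, \eqn{F_{IS} = 1 - \bar{H}_o / \bar{H}_s} with the means
#' taken over loci and \eqn{H_s} the small-sample-corrected within-population
#' gene diversity (a ratio of averages, robust to near-monomorphic loci;
#' per-locus values are also returned when `detail = TRUE`).
#'
#' @param data An `ssr_tbl`.
#' @param detail Return per (population, locus) values instead of the
#'   population summary.
#' @return A tibble `pop`, `ho`, `hs`, `fis` plus a final `(mean)` row, or the
#'   per-locus detail. Populations where Hs = 0 at every locus get `NA`.
#' @export
fis <- function(data, detail = FALSE) {
  ppl <- per_pop_locus_h(data)
  ppl$fis <- ifelse(ppl$he_unbiased > 0, 1 - ppl$ho / ppl$he_unbiased, NA_real_)
  if (detail) {
    return(ppl[, c("pop", "locus", "ho", "he_unbiased", "fis")])
  }
  out <- dplyr::summarise(dplyr::group_by(ppl, .data$pop),
    ho = mean(.data$ho), hs = mean(.data$he_unbiased),
    fis = ifelse(mean(.data$he_unbiased) > 0,
      1 - mean(.data$ho) / mean(.data$he_unbiased), NA_real_
    ),
    .groups = "drop"
  )
  out <- out[match(ssr_pops(data), out$pop), ]
  dplyr::bind_rows(out, tibble::tibble(
    pop = "(mean)", ho = mean(out$ho), hs = mean(out$hs),
    fis = mean(out$fis, na.rm = TRUE)
  ))
}

#' Rarefied allelic richness
#'
#' Hypergeometric rarefaction to a common number of gene copies `g`:
#' \deqn{R_s = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]}
#' per (population, locus), averaged over loci for the population value.
#'
#' @param data An `ssr_tbl`.
#' @param g Rarefaction gene count; default the minimum gene count observed
#'   over all (population, locus) combinations, the largest g valid
#'   everywhere. Must be >= 2.
#' @return A tibble `pop`, `g`, `rs` (mean over loci); with `detail = TRUE`
#'   one row per (pop, locus).
#' @param detail Return per-locus values.
#' @export
allelic_richness <- function(data, g = NULL, detail = FALSE) {
  fr <- allele_frequencies(data)
  genes <- dplyr::summarise(dplyr::group_by(fr, .data$pop, .data$locus),
    genes = .data$genes[1], .groups = "drop"
  )
  gmin <- min(genes$genes)
  if (is.null(g)) g <- gmin
  if (g < 2) stop("rarefaction gene count g must be >= 2", call. = FALSE)
  if (g > gmin) {
    stop(
      "g = ", g, " exceeds the minimum gene count (", gmin,
      ") at some (population, locus)",
      call. = FALSE
    )
  }
  per <- dplyr::summarise(dplyr::group_by(fr, .data$pop, .data$locus),
    rs = sum(1 - exp(lchoose(.data$genes - .data$count, g) - lchoose(.data$genes, g))),
    .groups = "drop"
  )
  if (detail) {
    per$g <- g
    return(per)
  }
  out <- dplyr::summarise(dplyr::group_by(per, .data$pop),
    g = g, rs = mean(.data$rs), .groups = "drop"
  )
  out[match(ssr_pops(data), out$pop), ]
}

#' Private alleles per population
#'
#' An allele is private to a population when it is observed there and in no
#' other population. The fraction is relative to all distinct (locus, allele)
#' pairs observed in the whole dataset.
#'
#' @param data An `ssr_tbl` with >= 2 populations (a single population makes
#'   every allele trivially private; a warning is emitted).
#' @return A tibble `pop`, `n_private`, plus attributes `n_alleles_total` and
#'   `fraction_private` (also returned as columns of an attached summary row
#'   via `attr(, "summary")`).
#' @export
private_alleles <- function(data) {
  if (length(ssr_pops(data)) < 2) {
    warning("single population: every allele is trivially private")
  }
  fr <- allele_frequencies(data)
  key <- paste(fr$locus, fr$allele, sep = "\r")
  npop_per_allele <- table(key)[key]
  fr$private <- as.vector(npop_per_allele) == 1L
  out <- dplyr::summarise(dplyr::group_by(fr, .data$pop),
    n_private = sum(.data$private), .groups = "drop"
  )
  out <- out[match(ssr_pops(data), out$pop), ]
  total <- length(unique(key))
  attr(out, "n_alleles_total") <- total
  attr(out, "fraction_private") <- sum(out$n_private) / total
  out
}

#' Per-population diversity summary table
#'
#' Assembles the standard SSR diversity panel per population: number of
#' alleles (Na), observed/expected heterozygosity (Ho, He), inbreeding
#' coefficient (FIS), rarefied allelic richness (Rs) and private allele count
#' (Npa).
#'
#' @param data An `ssr_tbl`.
#' @param g Rarefaction gene count passed to [allelic_richness()].
#' @return A tibble, one row per population.
#' @export
diversity_summary <- function(data, g = NULL) {
  fr <- allele_frequencies(data)
  na <- dplyr::summarise(dplyr::group_by(fr, .data$pop),
    na = dplyr::n_distinct(paste(.data$locus, .data$allele)), .groups = "drop"
  )
  h <- heterozygosity(data, level = "population")
  f <- fis(data)
  f <- f[f$pop != "(mean)", c("pop", "fis")]
  rs <- allelic_richness(data, g = g)
  pa <- private_alleles(data)
  out <- Reduce(
    function(a, b) dplyr::left_join(a, b, by = "pop"),
    list(
      na, h[, c("pop", "ho", "he")], f, rs[, c("pop", "rs")],
      dplyr::rename(pa, npa = "n_private")
    )
  )
  out[match(ssr_pops(data), out$pop), ]
}
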