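# EM for null-allele frequency at one (locus, population).
# Model (Dempster EM as used for PCR null alleles): visible alleles V plus a
# null allele 0; observed classes are heterozygotes (i, j), visible
# homozygotes i (true homozygote ii or null heterozygote i0), and blanks
# (null homozygotes 00, when blanks_are_nulls). The E-step splits visible
# homozygotes between the two latent states, the M-step recounts gene copies.
null_em_one <- function(a1, a2, n_blank, blanks_are_nulls = TRUE,
                        tol = 1e-8, max_iter = 10000) {
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  n_obs <- length(a1)
  if (!blanks_are_nulls) n_blank <- 0L
  n_tot <- n_obs + n_blank
  if (k == 0 || n_tot == 0) {
    return(list(
      null_freq = NA_real_, freq = numeric(0), alleles = alleles,
      converged = NA, n_iter = 0L
    ))
  }
  i1 <- match(a1, alleles)
  i2 <- match(a2, alleles)
  is_hom <- i1 == i2
  het_counts <- tabulate(c(i1[!is_hom], i2[!is_hom]), k)
  hom_counts <- tabulate(i1[is_hom], k)
  p <- rep((1 - 0.05) / k, k)
  p0 <- 0.05
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step: posterior that an apparent homozygote ii is a true homozygote
    w <- ifelse(p + 2 * p0 > 0, p / (p + 2 * p0), 1)
    gene_v <- het_counts + hom_counts * (2 * w + (1 - w)) # = het + hom*(1 + w)
    gene_0 <- sum(hom_counts * (1 - w)) + 2 * n_blank
    tot <- sum(gene_v) + gene_0
    p_new <- gene_v / tot
    p0_new <- gene_0 / tot
    delta <- max(abs(c(p_new - p, p0_new - p0)))
    p <- p_new
    p0 <- p0_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    null_freq = p0, freq = stats::setNames(p, alleles), alleles = alleles,
    converged = converged, n_iter = it
  )
}

#' Null-allele frequency estimation by expectation-maximization
#'
#' Per (locus, population) EM estimate of the frequency of a non-amplifying
#' (null) allele, under the model that apparent homozygotes are a mixture of
#' true homozygotes and null heterozygotes. By default missing genotypes are
#' treated as candidate null homozygotes (blanks), the convention of
#' EM-based null estimation for SSR data; set `blanks_are_nulls = FALSE` to
#' attribute missingness to technical failure instead.
#'
#' @param data An `ssr_tbl`.
#' @param blanks_are_nulls Treat missing genotypes as null homozygotes.
#' @param tol,max_iter EM convergence tolerance on the largest frequency
#'   change, and iteration cap (non-convergence is flagged, not an error).
#' @return A tibble with `locus`, `pop`, `n_ind`, `n_blank`, `null_freq`,
#'   `converged`. The per-locus summary (mean and max over populations, both
#'   reported) is in `attr(, "by_locus")`; the EM-adjusted visible allele
#'   frequencies are in `attr(, "adjusted_freqs")` (columns `pop`, `locus`,
#'   `allele`, `freq`, summing to 1 - null_freq).
#' @export
null_allele_em <- function(data, blanks_are_nulls = TRUE, tol = 1e-8,
                           max_iter = 10000) {
  d <- tibble::as_tibble(data)
  combos <- expand.grid(
    locus = ssr_loci(data), pop = ssr_pops(data),
    stringsAsFactors = FALSE
  )
  rows <- list()
  freqs <- list()
  for (k in seq_len(nrow(combos))) {
    sub <- d[d$locus == combos$locus[k] & d$pop == combos$pop[k], , drop = FALSE]
    scored <- sub[!is.na(sub$a1), , drop = FALSE]
    n_blank <- sum(is.na(sub$a1))
    fit <- null_em_one(scored$a1, scored$a2, n_blank,
      blanks_are_nulls = blanks_are_nulls, tol = tol, max_iter = max_iter
    )
    rows[[k]] <- tibble::tibble(
      locus = combos$locus[k], pop = combos$pop[k],
      n_ind = nrow(scored), n_blank = n_blank,
      null_freq = fit$null_freq, converged = fit$converged
    )
    if (length(fit$freq) > 0) {
      freqs[[length(freqs) + 1]] <- tibble::tibble(
        pop = combos$pop[k], locus = combos$locus[k],
        allele = as.integer(names(fit$freq)), freq = unname(fit$freq)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  by_locus <- dplyr::summarise(dplyr::group_by(out, .data$locus),
    null_freq_mean = mean(.data$null_freq, na.rm = TRUE),
    null_freq_max = max(.data$null_freq, na.rm = TRUE),
    .groups = "drop"
  )
  attr(out, "by_locus") <- by_locus[match(ssr_loci(data), by_locus$locus), ]
  attr(out, "adjusted_freqs") <- dplyr::bind_rows(freqs)
  out
}

#' FST with and without the ENA null-allele correction
#'
#' Computes per-locus and global multi-locus Weir & Cockerham theta twice.
#' Uncorrected: straight from the observed genotypes. ENA-corrected: the
#' null-allele class estimated by the EM is excluded from the visible
#' system — allele frequencies are replaced by the EM-adjusted visible
#' frequencies (renormalized onto the visible simplex) and the
#' heterozygote-frequency term gets back the apparent-homozygote mass the
#' EM attributes to null heterozygotes, undoing the heterozygote deficit
#' that inflates theta. When the estimated null frequency is 0 everywhere
#' the two columns coincide exactly. A two-sided paired t-test across loci
#' compares the corrected and uncorrected per-locus values (a zero-variance
#' difference vector gives t = 0, p = 1 by convention).
#'
#' @param data An `ssr_tbl` with >= 2 populations.
#' @param blanks_are_nulls Passed to [null_allele_em()].
#' @return A list with `by_locus` (tibble: locus, fst, fst_ena), `global`
#'   (named vector), and `t_test` (tibble: t, df, p_value).
#' @export
fst_ena <- function(data, blanks_are_nulls = TRUE) {
  loci <- ssr_loci(data)
  pops <- ssr_pops(data)
  if (length(pops) < 2) stop("fst_ena needs >= 2 populations", call. = FALSE)
  em <- null_allele_em(data, blanks_are_nulls = blanks_are_nulls)
  adj <- attr(em, "adjusted_freqs")
  d <- tibble::as_tibble(data)
  per <- lapply(loci, function(L) {
    inp <- wc_locus_input(data, L)
    if (length(inp$pops) < 2 || length(inp$alleles) < 2) {
      return(c(a_u = NA, abc_u = NA, a_c = NA, abc_c = NA))
    }
    comp_u <- wc_abc(inp$n, inp$p, inp$h)
    p_adj <- inp$p
    h_adj <- inp$h
    for (pp in inp$pops) {
      s <- adj[adj$locus == L & adj$pop == pp, ]
      if (nrow(s) == 0 || sum(s$freq) <= 0) next
      p0 <- em$null_freq[em$locus == L & em$pop == pp]
      # visible-simplex frequencies
      p_adj[, pp] <- 0
      hit <- match(s$allele, inp$alleles)
      p_adj[hit[!is.na(hit)], pp] <- s$freq[!is.na(hit)] / sum(s$freq)
      # EM posterior share of apparent homozygotes that are null
      # heterozygotes, returned to the het-frequency term
      if (length(p0) == 1 && !is.na(p0) && p0 > 0) {
        sub <- d[d$locus == L & d$pop == pp & !is.na(d$a1), , drop = FALSE]
        hom <- sub[sub$a1 == sub$a2, , drop = FALSE]
        if (nrow(hom) > 0) {
          hom_freq <- tabulate(match(hom$a1, inp$alleles), length(inp$alleles)) /
            nrow(sub)
          pv <- rep(0, length(inp$alleles))
          pv[hit[!is.na(hit)]] <- s$freq[!is.na(hit)]
          w <- ifelse(pv + 2 * p0 > 0, pv / (pv + 2 * p0), 1)
          h_adj[, pp] <- inp$h[, pp] + hom_freq * (1 - w)
        }
      }
    }
    comp_c <- wc_abc(inp$n, p_adj, h_adj)
    c(
      a_u = sum(comp_u[, "a"]), abc_u = sum(comp_u),
      a_c = sum(comp_c[, "a"]), abc_c = sum(comp_c)
    )
  })
  m <- do.call(rbind, per)
  by_locus <- tibble::tibble(
    locus = loci,
    fst = ifelse(m[, "abc_u"] != 0, m[, "a_u"] / m[, "abc_u"], NA_real_),
    fst_ena = ifelse(m[, "abc_c"] != 0, m[, "a_c"] / m[, "abc_c"], NA_real_)
  )
  global <- c(
    fst = sum(m[, "a_u"], na.rm = TRUE) / sum(m[, "abc_u"], na.rm = TRUE),
    fst_ena = sum(m[, "a_c"], na.rm = TRUE) / sum(m[, "abc_c"], na.rm = TRUE)
  )
  ok <- stats::complete.cases(by_locus[, c("fst", "fst_ena")])
  diffs <- by_locus$fst_ena[ok] - by_locus$fst[ok]
  t_test <- if (length(diffs) < 2) {
    tibble::tibble(t = NA_real_, df = NA_real_, p_value = NA_real_)
  } else if (stats::sd(diffs) == 0 || max(abs(diffs)) < 1e-6) {
    # identical (to numerical noise) vectors: t = 0, p = 1 by convention
    tibble::tibble(t = 0, df = length(diffs) - 1, p_value = 1)
  } else {
    tt <- stats::t.test(diffs)
    tibble::tibble(
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }
  list(by_locus = by_locus, global = global, t_test = t_test)
}
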