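#' Generate genotypes from known allele frequencies
#'
#' Controlled-truth generator for estimator tests. Genotypes are drawn per
#' (population, locus) with within-population inbreeding coefficient `fis`
#' (one parental gene copy is duplicated with probability `fis`, giving
#' P(hom a) = p_a^2 + fis p_a (1 - p_a)). Null alleles, when requested, are
#' added to the allele pool at the given frequency: a null heterozygote is
#' recorded as an apparent homozygote for its visible allele and a null
#' homozygote as a missing genotype. Uniform missingness is applied last.
#'
#' @param freqs Tibble with columns `pop`, `locus`, `allele`, `freq`
#'   (frequencies summing to 1 per pop x locus).
#' @param n_per_pop Diploid individuals per population.
#' @param fis Within-population inbreeding coefficient in `[0, 1)`.
#' @param null_freqs Named numeric vector (by locus) of null-allele
#'   frequencies, or a single value applied to every locus; `NULL` for none.
#' @param missing_rate Probability a genotype is masked missing.
#' @param seed Integer seed; the generator is a pure function of
#'   `seed` + configuration.
#' @return An `ssr_tbl` with a `truth` attribute (the [truth_record()]).
#' @export
generate_from_frequencies <- function(freqs, n_per_pop, fis = 0,
                                      null_freqs = NULL, missing_rate = 0,
                                      seed = 1) {
  if (fis < 0 || fis >= 1) stop("fis must be in [0, 1)", call. = FALSE)
  freqs <- tibble::as_tibble(freqs)
  chk <- dplyr::summarise(dplyr::group_by(freqs, .data$pop, .data$locus),
    s = sum(.data$freq), .groups = "drop"
  )
  if (any(abs(chk$s - 1) > 1e-6)) {
    stop("allele frequencies must sum to 1 per (pop, locus)", call. = FALSE)
  }
  set.seed(seed)
  pops <- unique(freqs$pop)
  loci <- unique(freqs$locus)
  if (length(null_freqs) == 1 && is.null(names(null_freqs))) {
    null_freqs <- stats::setNames(rep(null_freqs, length(loci)), loci)
  }
  NULL_CODE <- -1L
  rows <- list()
  for (p in pops) {
    for (L in loci) {
      s <- freqs[freqs$pop == p & freqs$locus == L, ]
      alleles <- s$allele
      pr <- s$freq
      p0 <- unname(null_freqs[L])
      if (!is.null(null_freqs) && !is.na(p0) && p0 > 0) {
        alleles <- c(alleles, NULL_CODE)
        pr <- c(pr * (1 - p0), p0)
      }
      g1 <- alleles[sample.int(length(alleles), n_per_pop, replace = TRUE, prob = pr)]
      g2 <- alleles[sample.int(length(alleles), n_per_pop, replace = TRUE, prob = pr)]
      dup <- stats::runif(n_per_pop) < fis
      g2[dup] <- g1[dup]
      # null masking
      a1 <- g1
      a2 <- g2
      both_null <- a1 == NULL_CODE & a2 == NULL_CODE
      one_null <- xor(a1 == NULL_CODE, a2 == NULL_CODE)
      vis <- ifelse(a1 == NULL_CODE, a2, a1)
      a1[one_null] <- vis[one_null]
      a2[one_null] <- vis[one_null]
      a1[both_null] <- NA_integer_
      a2[both_null] <- NA_integer_
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = paste0(p, "_", seq_len(n_per_pop)), pop = p, locus = L,
        a1 = as.integer(a1), a2 = as.integer(a2)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (missing_rate > 0) {
    mask <- stats::runif(nrow(out)) < missing_rate
    out$a1[mask] <- NA_integer_
    out$a2[mask] <- NA_integer_
  }
  ds <- ssr_dataset(out, loci = loci, pops = pops)
  attr(ds, "truth") <- truth_record(
    generator = "from_frequencies",
    args = list(
      freqs = freqs, n_per_pop = n_per_pop, fis = fis,
      null_freqs = null_freqs, missing_rate = missing_rate, seed = seed
    )
  )
  ds
}

#' Four-island SSR fixture with hierarchical structure
#'
#' Emulates a small archipelago survey: 4 island populations x 10 diploid
#' individuals x 9 loci with 2-7 alleles per locus. Population allele
#' frequencies are Dirichlet perturbations of shared per-locus base
#' frequencies (concentration `theta`, chosen so realized pairwise
#' Weir-Cockerham FST falls in the moderate band around 0.05-0.25), with a
#' mild heterozygote deficit, one locus carrying null alleles, and ~3%
#' missing cells — the data pathologies the estimators in this package are
#' built to handle.
#'
#' @param seed Integer seed (pure function of seed).
#' @param n_pops,n_per_pop,n_loci Fixture dimensions.
#' @param theta Dirichlet concentration of island frequencies around the
#'   base (differentiation is roughly 1/(1 + theta)).
#' @param fis Within-population inbreeding coefficient.
#' @param null_locus_freq Null-allele frequency injected at the third locus.
#' @param missing_rate Uniform missingness.
#' @return An `ssr_tbl` with a `truth` attribute.
#' @export
generate_island_fixture <- function(seed = 1, n_pops = 4, n_per_pop = 10,
                                    n_loci = 9, theta = 7, fis = 0.1,
                                    null_locus_freq = 0.15,
                                    missing_rate = 0.03) {
  set.seed(seed)
  pops <- c("SantaCruz", "SanCristobal", "Isabela", "Floreana")[seq_len(min(n_pops, 4))]
  if (n_pops > 4) pops <- c(pops, paste0("Pop", seq(5, n_pops)))
  loci <- paste0("loc", seq_len(n_loci))
  freq_rows <- list()
  for (j in seq_len(n_loci)) {
    k <- sample(2:7, 1)
    alleles <- 100 + 10 * j + 2 * seq_len(k) # fragment-size-like codes
    base <- as.vector(rdirichlet1(rep(1.5, k)))
    for (p in pops) {
      f <- as.vector(rdirichlet1(theta * base))
      freq_rows[[length(freq_rows) + 1]] <- tibble::tibble(
        pop = p, locus = loci[j], allele = alleles, freq = f
      )
    }
  }
  freqs <- dplyr::bind_rows(freq_rows)
  nulls <- NULL
  if (!is.null(null_locus_freq) && null_locus_freq > 0 && n_loci >= 3) {
    nulls <- stats::setNames(null_locus_freq, loci[3])
  }
  geno_seed <- sample.int(.Machine$integer.max, 1)
  ds <- generate_from_frequencies(freqs, n_per_pop,
    fis = fis,
    null_freqs = nulls, missing_rate = missing_rate, seed = geno_seed
  )
  attr(ds, "truth") <- truth_record(
    generator = "island_fixture",
    args = list(
      seed = seed, n_pops = n_pops, n_per_pop = n_per_pop,
      n_loci = n_loci, theta = theta, fis = fis,
      null_locus_freq = null_locus_freq, missing_rate = missing_rate
    ),
    realized = list(freqs = freqs, null_freqs = nulls, geno_seed = geno_seed)
  )
  ds
}

# one Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-6))
  g / sum(g)
}

#' Generate pseudo-observed data under a catalog invasion scenario
#'
#' @param stage Catalog stage (1, 2 or 3), see [load_scenarios_stage()].
#' @param which Scenario index or name within the stage.
#' @param params Named parameter values, or `"draw"` to draw from
#'   [default_priors()].
#' @param seed Integer seed.
#' @param n_loci Loci to simulate.
#' @return An `ssr_tbl` with a `truth` attribute recording the scenario and
#'   the realized parameters.
#' @export
generate_under_scenario <- function(stage, which = 1, params = "draw",
                                    seed = 1, n_loci = 9) {
  cat_s <- load_scenarios_stage(stage)
  scn <- if (is.character(which) && !which %in% names(cat_s)) {
    stop("unknown scenario '", which, "' in stage ", stage, call. = FALSE)
  } else {
    cat_s[[which]]
  }
  set.seed(seed)
  realized <- if (identical(params, "draw")) {
    draw_scenario_params(scn)
  } else {
    unlist(params)
  }
  ds <- simulate_scenario(scn, params = realized, n_loci = n_loci)
  attr(ds, "truth") <- truth_record(
    generator = "under_scenario",
    args = list(
      stage = stage, which = which, params = params, seed = seed,
      n_loci = n_loci
    ),
    realized = list(scenario = scn$name, params = as.list(realized))
  )
  ds
}

#' Truth records for synthetic datasets
#'
#' Every generator attaches a truth record: the generator name and the
#' exact arguments needed to regenerate the dataset bit-identically, plus
#' realized internal quantities (drawn frequencies, parameters). Records
#' serialise to JSON.
#'
#' @param generator Generator name.
#' @param args Argument list sufficient for regeneration.
#' @param realized Realized internal quantities (informational).
#' @return An object of class `ssr_truth`.
#' @export
truth_record <- function(generator, args, realized = list()) {
  structure(list(generator = generator, args = args, realized = realized),
    class = "ssr_truth"
  )
}

#' @rdname truth_record
#' @param truth An `ssr_truth` (or the dataset carrying one).
#' @param path File path for JSON serialisation.
#' @export
write_truth <- function(truth, path) {
  if (inherits(truth, "ssr_tbl")) truth <- attr(truth, "truth")
  jsonlite::write_json(unclass(truth), path,
    auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  invisible(path)
}

#' @rdname truth_record
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$args$freqs)) x$args$freqs <- tibble::as_tibble(x$args$freqs)
  if (!is.null(x$args$null_freqs)) x$args$null_freqs <- unlist(x$args$null_freqs)
  structure(x, class = "ssr_truth")
}

#' @rdname truth_record
#' @export
regenerate_truth <- function(truth) {
  if (inherits(truth, "ssr_tbl")) truth <- attr(truth, "truth")
  args <- truth$args
  switch(truth$generator,
    from_frequencies = do.call(generate_from_frequencies, args),
    island_fixture = do.call(generate_island_fixture, args),
    under_scenario = do.call(generate_under_scenario, args),
    stop("unknown generator '", truth$generator, "'", call. = FALSE)
  )
}
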