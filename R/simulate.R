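#' Simulate an SSR dataset under a demographic scenario
#'
#' Backward-in-time coalescent of the sampled gene copies through the
#' scenario's deme graph (pairwise coalescence rate 1/(2N) per generation in
#' a deme of size N, continuous-time approximation), with lineage movement
#' at split/admixture events and piecewise-constant sizes for bottlenecks.
#' Mutations are dropped on branches as Poisson(mu x length), each one a
#' +/-1 repeat-unit step with equal probability (strict stepwise mutation
#' model); alleles are emitted as repeat counts around `base_allele`.
#'
#' @param scn An `ssr_scenario`; free parameters are resolved via `params`.
#' @param params Named parameter values (must include `mu` unless
#'   `mutation_rate` is given).
#' @param n_loci Number of independent loci.
#' @param mutation_rate Per-generation stepwise mutation rate; overrides
#'   `params[["mu"]]`.
#' @param seed Optional integer seed.
#' @param base_allele Repeat count the root carries (default 100). If a
#'   locus drifts to non-positive codes the whole locus is shifted up so the
#'   minimum is 1 (allele codes stay positive, within-locus differences are
#'   preserved).
#' @return An `ssr_tbl` over the sampled demes, with attribute `tmrca`
#'   (per-locus time to the most recent common ancestor, generations).
#' @export
simulate_scenario <- function(scn, params = NULL, n_loci = 9,
                              mutation_rate = NULL, seed = NULL,
                              base_allele = 100) {
  if (n_loci < 1) stop("n_loci must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pv <- unlist(params %||% list())
  mu <- mutation_rate %||% unname(pv["mu"])
  if (is.null(mu) || is.na(mu)) {
    stop("no mutation rate: give mutation_rate or params[['mu']]", call. = FALSE)
  }
  tpl <- compile_template(scn)
  vals <- tpl_resolve(tpl, pv)
  msg <- tpl_check(tpl, vals)
  if (!is.null(msg)) stop("invalid scenario '", scn$name, "': ", msg, call. = FALSE)
  sim <- tpl_simulate(tpl, vals, n_loci, mu)
  A <- sim$A + base_allele
  shift <- pmin(apply(A, 2, min) - 1L, 0L)
  A <- sweep(A, 2, shift)
  samp <- tpl$sample
  sampled <- tpl$demes[samp > 0]
  ids <- unlist(lapply(which(samp > 0), function(d) {
    paste0(tpl$demes[d], "_", seq_len(samp[d]))
  }))
  loci <- paste0("loc", seq_len(n_loci))
  odd <- seq(1, nrow(A), by = 2)
  out <- tibble::tibble(
    id = rep(ids, each = n_loci),
    pop = rep(tpl$demes[tpl$deme0[odd] + 1L], each = n_loci),
    locus = rep(loci, length(ids)),
    a1 = as.integer(t(A[odd, , drop = FALSE])),
    a2 = as.integer(t(A[odd + 1, , drop = FALSE]))
  )
  ds <- ssr_dataset(out, loci = loci, pops = sampled)
  attr(ds, "tmrca") <- sim$tmrca
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- compiled scenario templates -------------------------------------------
# A template pre-parses every numeric-or-parameter field of a scenario so
# that per-draw instantiation, validity checking and simulation are plain
# vector operations (the ABC loops run these millions of times).

# parse a character field vector into value/param(/derived "a-b") form
parse_spec <- function(x) {
  x <- as.character(x)
  val <- suppressWarnings(as.numeric(x))
  p1 <- p2 <- rep(NA_character_, length(x))
  free <- which(is.na(val) & !is.na(x))
  for (i in free) {
    parts <- strsplit(x[i], "-", fixed = TRUE)[[1]]
    n1 <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(n1)) p1[i] <- parts[1] else val[i] <- n1
    if (length(parts) > 1) p2[i] <- parts[2]
  }
  list(val = val, p1 = p1, p2 = p2)
}

resolve_spec <- function(spec, pv) {
  out <- spec$val
  need <- !is.na(spec$p1)
  out[need] <- pv[spec$p1[need]]
  minus <- !is.na(spec$p2)
  out[minus] <- out[minus] - pv[spec$p2[minus]]
  out
}

compile_template <- function(scn) {
  demes <- scn$demes$deme
  ev <- scn$events
  mv <- ev[ev$type %in% c("split", "admix"), , drop = FALSE]
  bn <- ev[ev$type == "bottleneck", , drop = FALSE]
  if (anyDuplicated(mv$deme)) {
    stop("a deme is removed (split/admix) more than once", call. = FALSE)
  }
  roots <- setdiff(demes, mv$deme)
  if (length(roots) != 1) {
    stop(length(roots), " root demes remain (need exactly 1)", call. = FALSE)
  }
  samp <- as.integer(scn$demes$sample)
  list(
    name = scn$name,
    demes = demes, sample = samp,
    deme0 = rep(seq_along(demes) - 1L, times = 2L * samp),
    ne = parse_spec(scn$demes$ne),
    mv_from = match(mv$deme, demes),
    mv_toa = match(mv$parent_a, demes),
    mv_tob = ifelse(is.na(mv$parent_b), -1L, match(mv$parent_b, demes)),
    mv_time = parse_spec(mv$time),
    mv_prop = parse_spec(ifelse(is.na(mv$prop), "1", as.character(mv$prop))),
    mv_is_admix = mv$type == "admix",
    bn_deme = match(bn$deme, demes),
    bn_start = parse_spec(bn$time),
    bn_dur = parse_spec(bn$duration),
    bn_size = parse_spec(bn$size)
  )
}

tpl_resolve <- function(tpl, pv) {
  list(
    ne = resolve_spec(tpl$ne, pv),
    mv_time = resolve_spec(tpl$mv_time, pv),
    mv_prop = resolve_spec(tpl$mv_prop, pv),
    bn_start = pmax(resolve_spec(tpl$bn_start, pv), 0),
    bn_dur = resolve_spec(tpl$bn_dur, pv),
    bn_size = resolve_spec(tpl$bn_size, pv)
  )
}

# NULL when valid, else a message; mirrors scenario_check() on resolved values
tpl_check <- function(tpl, v) {
  if (anyNA(c(v$ne, v$mv_time, v$mv_prop, v$bn_start, v$bn_dur, v$bn_size))) {
    return("unresolved parameter")
  }
  if (any(v$ne < 1)) {
    return("effective size < 1")
  }
  if (any(v$mv_time < 0)) {
    return("negative event time")
  }
  if (any(tpl$mv_is_admix & (v$mv_prop <= 0 | v$mv_prop >= 1))) {
    return("admixture proportion outside (0, 1)")
  }
  removal <- rep(Inf, length(tpl$demes))
  removal[tpl$mv_from] <- v$mv_time
  for (k in seq_along(tpl$mv_from)) {
    pars <- c(tpl$mv_toa[k], if (tpl$mv_tob[k] > 0) tpl$mv_tob[k])
    if (any(removal[pars] <= v$mv_time[k])) {
      return("a deme moves into a parent already removed")
    }
  }
  if (length(tpl$bn_deme) > 0) {
    if (any(v$bn_size < 1) || any(v$bn_dur <= 0)) {
      return("bottleneck with size < 1 or duration <= 0")
    }
    if (any(v$bn_start + v$bn_dur > removal[tpl$bn_deme] + 1e-9)) {
      return("bottleneck extends past the deme's removal time")
    }
  }
  NULL
}

# one simulated dataset as a gene-copy x locus allele-offset matrix
tpl_simulate <- function(tpl, v, n_loci, mu) {
  times <- sort(unique(c(0, v$mv_time, v$bn_start, v$bn_start + v$bn_dur)))
  E <- length(times)
  D <- length(tpl$demes)
  sizes <- matrix(rep(v$ne, each = E), E, D)
  for (k in seq_along(tpl$bn_deme)) {
    hit <- times >= v$bn_start[k] - 1e-12 &
      times < v$bn_start[k] + v$bn_dur[k] - 1e-12
    sizes[hit, tpl$bn_deme[k]] <- v$bn_size[k]
  }
  ord <- order(v$mv_time)
  mv_epoch <- as.integer(match(v$mv_time[ord], times) - 1L)
  mv_from <- as.integer(tpl$mv_from[ord] - 1L)
  mv_toa <- as.integer(tpl$mv_toa[ord] - 1L)
  mv_tob <- as.integer(ifelse(tpl$mv_tob[ord] > 0, tpl$mv_tob[ord] - 1L, -1L))
  mv_prob <- as.numeric(v$mv_prop[ord])
  n_copies <- length(tpl$deme0)
  A <- matrix(0L, n_copies, n_loci)
  tmrca <- numeric(n_loci)
  for (L in seq_len(n_loci)) {
    sim <- sim_locus_cpp(
      tpl$deme0, times, sizes, mv_epoch, mv_from, mv_toa,
      mv_tob, mv_prob, mu
    )
    A[, L] <- sim$state
    tmrca[L] <- sim$tmrca
  }
  list(A = A, tmrca = tmrca)
}

# fast prior draw against a template (vectorized, rejection on validity)
tpl_draw <- function(tpl, priors, max_tries = 1000) {
  lo <- priors$lo
  hi <- priors$hi
  is_log <- priors$dist == "logunif"
  llo <- ifelse(is_log, log(lo), lo)
  lhi <- ifelse(is_log, log(hi), hi)
  for (k in seq_len(max_tries)) {
    vals <- stats::runif(length(lo), llo, lhi)
    vals[is_log] <- exp(vals[is_log])
    names(vals) <- priors$param
    v <- tpl_resolve(tpl, vals)
    if (is.null(tpl_check(tpl, v))) {
      return(list(params = vals, resolved = v))
    }
  }
  stop("could not draw event-order-consistent parameters after ", max_tries,
    " tries for scenario '", tpl$name, "'",
    call. = FALSE
  )
}

# ---- summary statistics ----------------------------------------------------

#' ABC summary statistics of an SSR dataset
#'
#' The fixed-schema statistic vector used throughout the ABC engine: per
#' deme the mean number of alleles over loci (`na_*`) and the mean unbiased
#' gene diversity over loci (`gd_*`), plus every pairwise multi-locus
#' Weir-Cockerham FST (`fst_*_*`), in population order. Values are
#' numerically identical to [heterozygosity()] / [pairwise_fst()] on the
#' same data (same estimators, matrix fast path). An undefined FST
#' (monomorphic pair) is 0 by convention.
#'
#' @param data An `ssr_tbl`.
#' @param demes Expected population names; a deme absent from the data is a
#'   schema error. Default: the dataset's populations.
#' @return A named numeric vector.
#' @export
summary_stats <- function(data, demes = NULL) {
  pops <- ssr_pops(data)
  if (!is.null(demes)) {
    missing_d <- setdiff(demes, pops)
    if (length(missing_d) > 0) {
      stop("schema error: deme '", missing_d[1], "' absent from dataset",
        call. = FALSE
      )
    }
    pops <- demes
  }
  d <- tibble::as_tibble(data)
  d <- d[d$pop %in% pops, , drop = FALSE]
  loci <- ssr_loci(data)
  ids <- unique(d$id)
  A <- matrix(NA_integer_, 2 * length(ids), length(loci))
  row1 <- 2 * match(d$id, ids) - 1
  col <- match(d$locus, loci)
  A[cbind(row1, col)] <- d$a1
  A[cbind(row1 + 1, col)] <- d$a2
  ip <- dplyr::distinct(d, .data$id, .data$pop)
  pop_ind <- match(ip$pop[match(ids, ip$id)], pops)
  stats_core(A, pop_ind, pops)
}

# Core statistic engine on a gene-copy x locus allele matrix. Rows 2i-1, 2i
# are individual i's copies; pop_ind gives each individual's population
# index; NA = missing genotype (both copies).
stats_core <- function(A, pop_ind, pops) {
  P <- length(pops)
  n_loci <- ncol(A)
  pop_copy <- rep(pop_ind, each = 2)
  pair_i <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  npair <- nrow(pair_i)
  na_acc <- gd_acc <- nl_acc <- numeric(P)
  a_acc <- abc_acc <- numeric(npair)
  odd <- seq(1, nrow(A), by = 2)
  for (L in seq_len(n_loci)) {
    x <- A[, L]
    ok <- !is.na(x)
    alleles <- sort(unique(x[ok]))
    k <- length(alleles)
    if (k == 0) next
    code <- match(x, alleles)
    cnt <- matrix(
      tabulate(code[ok] + k * (pop_copy[ok] - 1L), k * P),
      k, P
    )
    n_i <- tabulate(pop_ind[!is.na(A[odd, L])], P)
    genes <- 2 * n_i
    scored <- genes > 0
    pmat <- sweep(cnt, 2, pmax(genes, 1), "/")
    na_acc[scored] <- na_acc[scored] + colSums(cnt[, scored, drop = FALSE] > 0)
    gd <- genes / pmax(genes - 1, 1) * (1 - colSums(pmat^2))
    gd_acc[scored] <- gd_acc[scored] + gd[scored]
    nl_acc[scored] <- nl_acc[scored] + 1
    if (k < 2) next
    # heterozygote allele counts per pop
    is_het <- A[odd, L] != A[odd + 1, L] & !is.na(A[odd, L])
    het_copies <- rep(is_het, each = 2)
    hcnt <- matrix(
      tabulate(code[het_copies] + k * (pop_copy[het_copies] - 1L), k * P),
      k, P
    )
    hmat <- sweep(hcnt, 2, pmax(n_i, 1), "/")
    for (pr in seq_len(npair)) {
      i <- pair_i[pr, 1]
      j <- pair_i[pr, 2]
      ni <- n_i[i]
      nj <- n_i[j]
      if (ni < 1 || nj < 1) next
      seen <- cnt[, i] + cnt[, j] > 0
      comp <- wc_abc_pair(
        ni, nj, pmat[seen, i], pmat[seen, j],
        hmat[seen, i], hmat[seen, j]
      )
      a_acc[pr] <- a_acc[pr] + comp[1]
      abc_acc[pr] <- abc_acc[pr] + comp[2]
    }
  }
  na_mean <- na_acc / pmax(nl_acc, 1)
  gd_mean <- gd_acc / pmax(nl_acc, 1)
  names(na_mean) <- paste0("na_", pops)
  names(gd_mean) <- paste0("gd_", pops)
  if (npair == 0) {
    return(c(na_mean, gd_mean))
  }
  fst <- ifelse(abc_acc != 0, a_acc / abc_acc, 0)
  names(fst) <- paste0("fst_", pops[pair_i[, 1]], "_", pops[pair_i[, 2]])
  c(na_mean, gd_mean, fst)
}

# vectorized two-population Weir-Cockerham components, summed over alleles;
# returns c(sum_a, sum_abc)
wc_abc_pair <- function(ni, nj, pi, pj, hi, hj) {
  r <- 2
  nbar <- (ni + nj) / 2
  if (nbar <= 1) {
    return(c(0, 0))
  }
  nc <- (r * nbar - (ni^2 + nj^2) / (r * nbar)) / (r - 1)
  pbar <- (ni * pi + nj * pj) / (r * nbar)
  s2 <- (ni * (pi - pbar)^2 + nj * (pj - pbar)^2) / ((r - 1) * nbar)
  hbar <- (ni * hi + nj * hj) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(sum(a), sum(a + b + cc))
}

# statistics straight from a simulation (no tibble round-trip); sampled
# demes only
tpl_stats <- function(tpl, sim) {
  samp <- tpl$sample
  sampled_idx <- which(samp > 0)
  pop_ind <- rep(seq_along(sampled_idx), times = samp[sampled_idx])
  stats_core(sim$A, pop_ind, tpl$demes[sampled_idx])
}
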