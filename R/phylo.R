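#' Nei's genetic distance between populations
#'
#' Standard Nei (1972) distance \eqn{D = -\ln I} with
#' \eqn{I = J_{xy} / \sqrt{J_x J_y}}, the J terms summed over loci; the
#' `nei78` variant replaces \eqn{J_x} and \eqn{J_y} by their
#' sample-size-unbiased estimates \eqn{(2n \sum x_i^2 - 1)/(2n - 1)}.
#' Population pairs sharing no alleles (I = 0) get an infinite-distance
#' sentinel; [upgma_tree()] caps such entries at twice the largest finite
#' distance with a warning.
#'
#' @param data An `ssr_tbl`, or an allele-frequency tibble from
#'   [allele_frequencies()] (columns pop, locus, allele, freq, genes).
#' @param variant `"nei72"` (default) or `"nei78"`.
#' @return A symmetric [dist_matrix()] over populations (may contain `Inf`).
#' @export
nei_distance <- function(data, variant = c("nei72", "nei78")) {
  variant <- match.arg(variant)
  if (inherits(data, "ssr_tbl")) {
    fr <- allele_frequencies(data)
    pops <- ssr_pops(data)
    loci <- ssr_loci(data)
  } else {
    fr <- tibble::as_tibble(data)
    pops <- unique(fr$pop)
    loci <- unique(fr$locus)
  }
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P)) {
    for (j in seq_len(i - 1)) {
      m[i, j] <- m[j, i] <- nei_d_pair(fr, loci, pops[j], pops[i], variant)
    }
  }
  dist_matrix(m, labels = pops, tol = Inf)
}

nei_d_pair <- function(fr, loci, px, py, variant) {
  jx <- jy <- jxy <- 0
  used <- 0L
  for (L in loci) {
    sx <- fr[fr$locus == L & fr$pop == px, ]
    sy <- fr[fr$locus == L & fr$pop == py, ]
    if (nrow(sx) == 0 || nrow(sy) == 0) next
    used <- used + 1L
    alleles <- sort(unique(c(sx$allele, sy$allele)))
    x <- y <- numeric(length(alleles))
    x[match(sx$allele, alleles)] <- sx$freq
    y[match(sy$allele, alleles)] <- sy$freq
    if (variant == "nei72") {
      jx <- jx + sum(x^2)
      jy <- jy + sum(y^2)
    } else {
      nx <- sx$genes[1]
      ny <- sy$genes[1]
      jx <- jx + (nx * sum(x^2) - 1) / (nx - 1)
      jy <- jy + (ny * sum(y^2) - 1) / (ny - 1)
    }
    jxy <- jxy + sum(x * y)
  }
  if (used == 0L) {
    return(NA_real_)
  }
  if (jxy <= 0) {
    return(Inf)
  }
  I <- jxy / sqrt(jx * jy)
  -log(min(I, 1)) # numerical guard: I can exceed 1 by rounding for identical pops
}

#' UPGMA tree from a distance matrix
#'
#' Agglomerative average linkage: the merged pair is always the one at the
#' smallest distance, ties broken deterministically by the lexicographically
#' smallest member label (so a label permutation of the input yields an
#' isomorphic tree). Node height is half the merge distance, making the tree
#' ultrametric. Infinite entries are capped at twice the largest finite
#' distance, with a warning.
#'
#' @param dist Symmetric distance matrix with labels.
#' @return An [ape::ape-package] `phylo` object (rooted, ultrametric), with
#'   `node.depth` attribute giving each internal node's height.
#' @export
upgma_tree <- function(dist) {
  m <- as.matrix(dist)
  if (any(is.na(m))) stop("UPGMA requires a complete distance matrix (NaN/NA found)", call. = FALSE)
  if (any(is.infinite(m))) {
    cap <- 2 * max(m[is.finite(m)])
    warning("infinite distances capped at ", signif(cap, 6), " for UPGMA")
    m[is.infinite(m)] <- cap
  }
  labels <- rownames(m)
  n <- nrow(m)
  if (n < 2) stop("UPGMA needs >= 2 labels", call. = FALSE)
  # active clusters: newick fragment, size, height, smallest member label
  nwk <- vapply(labels, quote_newick_label, "")
  size <- rep(1, n)
  height <- rep(0, n)
  minlab <- labels
  active <- rep(TRUE, n)
  d <- m
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1)) {
        i <- idx[ii]
        j <- idx[jj]
        key <- d[i, j]
        cand <- list(i = i, j = j, d = key)
        if (is.null(best) || key < best$d - 1e-12 ||
          (abs(key - best$d) <= 1e-12 &&
            min(minlab[i], minlab[j]) < min(minlab[best$i], minlab[best$j]))) {
          best <- cand
        }
      }
    }
    i <- best$i
    j <- best$j
    h <- best$d / 2
    # order children by smallest member label for a canonical form
    ord <- order(c(minlab[i], minlab[j]))
    ch <- c(i, j)[ord]
    frag <- paste0(
      "(", nwk[ch[1]], ":", fmt_bl(h - height[ch[1]]), ",",
      nwk[ch[2]], ":", fmt_bl(h - height[ch[2]]), ")"
    )
    # average linkage update into slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
    }
    nwk[i] <- frag
    size[i] <- size[i] + size[j]
    height[i] <- h
    minlab[i] <- min(minlab[i], minlab[j])
    active[j] <- FALSE
  }
  root <- which(active)
  txt <- paste0(nwk[root], ";")
  phy <- ape::read.tree(text = txt)
  phy$tip.label <- unquote_newick_label(phy$tip.label)
  phy
}

fmt_bl <- function(x) as.character(signif(max(x, 0), 12))

quote_newick_label <- function(x) {
  needs <- grepl("[][ \t,():;']", x)
  ifelse(needs, paste0("'", gsub("'", "''", x), "'"), x)
}

unquote_newick_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Nei-distance UPGMA tree with locus bootstrap
#'
#' Builds the full-data UPGMA tree on Nei's distance, then resamples loci
#' with replacement `n_boot` times, rebuilds the tree for each replicate, and
#' reports for every internal node of the full-data tree the percentage of
#' replicates containing that bipartition (node support, 0-100).
#'
#' @param data An `ssr_tbl` with >= 2 loci.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param variant Nei distance variant, see [nei_distance()].
#' @param seed Optional integer seed.
#' @param by_individual Treat every individual as a population of one
#'   (individual-level tree).
#' @return A `phylo` object with `node.label` set to bootstrap support
#'   percentages.
#' @export
bootstrap_tree <- function(data, n_boot = 1000, variant = "nei72", seed = NULL,
                           by_individual = FALSE) {
  loci <- ssr_loci(data)
  if (length(loci) < 2) stop("locus bootstrap needs >= 2 loci", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (by_individual) data <- individuals_as_pops(data)
  fr <- allele_frequencies(data)
  main <- suppressWarnings(upgma_tree(nei_distance(fr, variant)))
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    take <- sample(loci, length(loci), replace = TRUE)
    # duplicate sampled loci under unique names so each draw counts
    frb <- dplyr::bind_rows(lapply(seq_along(take), function(k) {
      s <- fr[fr$locus == take[k], ]
      s$locus <- paste0("L", k)
      s
    }))
    boots[[b]] <- suppressWarnings(upgma_tree(nei_distance(frb, variant)))
  }
  counts <- ape::prop.clades(main, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  main$node.label <- as.character(round(100 * counts / n_boot, 1))
  main
}

#' Treat each individual as a population of one
#'
#' @param data An `ssr_tbl`.
#' @return An `ssr_tbl` whose populations are the individual ids (used for
#'   individual-level trees).
#' @export
individuals_as_pops <- function(data) {
  d <- tibble::as_tibble(data)
  d$pop <- d$id
  ssr_dataset(d, loci = ssr_loci(data), pops = unique(d$id))
}

#' Write / read a tree in Newick format
#'
#' `write_newick()` serialises a `phylo` object with branch lengths and node
#' labels (bootstrap supports) as internal node labels, quoting any label
#' containing Newick-reserved characters (spaces, parentheses, commas,
#' colons, semicolons, quotes). `read_newick()` parses with
#' [ape::read.tree()] and strips the quoting, so the pair round-trips.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) {
      return(quote_newick_label(tree$tip.label[node]))
    }
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      paste0(rec(child), ":", fmt_bl(tree$edge.length[r]))
    }, "")
    lab <- if (!is.null(tree$node.label)) tree$node.label[node - n_tip] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  writeLines(paste0(rec(root), ";"), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  phy$tip.label <- unquote_newick_label(phy$tip.label)
  phy
}
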