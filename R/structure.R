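#' Individuals-by-allele dosage matrix
#'
#' Encodes the genotypes as a numeric matrix with one column per (locus,
#' allele) and one row per individual; each cell is the number of copies of
#' that allele carried (0, 1 or 2). Missing genotypes are handled per
#' `na_policy`: `"mean"` (default) imputes the locus-wide mean dosage (twice
#' the pooled allele frequency), `"zero"` sets 0, `"keep"` leaves `NA`.
#' Individuals missing at every locus are dropped with a warning.
#'
#' @param data An `ssr_tbl`.
#' @param na_policy `"mean"`, `"zero"` or `"keep"`.
#' @return A numeric matrix with rownames = individual ids, colnames =
#'   `locus.allele`, and attribute `pop` giving each row's population.
#' @export
genotypes_to_allele_matrix <- function(data, na_policy = c("mean", "zero", "keep")) {
  na_policy <- match.arg(na_policy)
  d <- tibble::as_tibble(data)
  ids <- unique(d$id)
  loci <- ssr_loci(data)
  cols <- list()
  for (L in loci) {
    sub <- d[d$locus == L, ]
    sub <- sub[match(ids, sub$id), ]
    alleles <- sort(unique(c(sub$a1, sub$a2)))
    alleles <- alleles[!is.na(alleles)]
    for (A in alleles) {
      dose <- (sub$a1 == A) + (sub$a2 == A)
      cols[[paste(L, A, sep = ".")]] <- as.numeric(dose)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  all_na <- apply(m, 1, function(r) all(is.na(r)))
  if (any(all_na)) {
    warning(
      "dropping ", sum(all_na),
      " individual(s) with no scored locus: ",
      paste(ids[all_na], collapse = ", ")
    )
    m <- m[!all_na, , drop = FALSE]
    ids <- ids[!all_na]
  }
  if (na_policy == "mean") {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    }
  } else if (na_policy == "zero") {
    m[is.na(m)] <- 0
  }
  ip <- dplyr::distinct(d, .data$id, .data$pop)
  attr(m, "pop") <- ip$pop[match(ids, ip$id)]
  m
}

#' K-means cluster inference with BIC model selection
#'
#' PCA of the (centred, scaled) allele-dosage matrix, then k-means for
#' K = 1..`max_K` on the retained principal components, each with multiple
#' random restarts keeping the best within-cluster sum of squares. Model
#' choice uses \deqn{BIC(K) = n \ln(WSS_K/n) + K \ln(n)} and the selected K
#' is the argmin (ties go to the smallest K).
#'
#' @param data An `ssr_tbl`.
#' @param max_K Largest number of clusters to try (>= 2).
#' @param n_pcs Number of principal components retained; default keeps
#'   components explaining >= 90% of variance.
#' @param n_restarts k-means restarts per K (default 10).
#' @param seed Optional integer seed.
#' @return An object of class `ssr_clusters`: `K` (selected), `assignments`
#'   (tibble id, pop, cluster), `bic` (tibble K, wss, bic), `n_pcs`, `pcs`
#'   (the retained component scores).
#' @export
find_clusters <- function(data, max_K = 8, n_pcs = NULL, n_restarts = 10,
                          seed = NULL) {
  if (max_K < 2) stop("max_K must be >= 2", call. = FALSE)
  if (n_restarts < 1) stop("n_restarts must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- genotypes_to_allele_matrix(data)
  pcs <- dosage_pca(m, n_pcs)
  x <- pcs$scores
  n <- nrow(x)
  max_K <- min(max_K, n - 1)
  n_distinct <- nrow(unique(round(x, 10)))
  res <- vector("list", max_K)
  wss <- rep(NA_real_, max_K)
  for (K in seq_len(max_K)) {
    if (K == 1) {
      wss[K] <- sum(scale(x, scale = FALSE)^2)
      res[[K]] <- rep(1L, n)
    } else if (K > n_distinct) {
      break # fewer distinct points than centers: K not fittable
    } else {
      km <- stats::kmeans(x, centers = K, nstart = n_restarts, iter.max = 100)
      wss[K] <- km$tot.withinss
      res[[K]] <- km$cluster
    }
  }
  bic <- n * log(pmax(wss, 1e-12) / n) + seq_len(max_K) * log(n)
  bic[is.na(wss)] <- Inf
  K_sel <- which.min(bic) # which.min takes the first (smallest K) on ties
  ip <- dplyr::distinct(tibble::as_tibble(data), .data$id, .data$pop)
  assignments <- tibble::tibble(
    id = rownames(m), pop = ip$pop[match(rownames(m), ip$id)],
    cluster = res[[K_sel]]
  )
  structure(
    list(
      K = K_sel, assignments = assignments,
      bic = tibble::tibble(K = seq_len(max_K), wss = wss, bic = bic),
      n_pcs = ncol(x), pcs = x
    ),
    class = "ssr_clusters"
  )
}

dosage_pca <- function(m, n_pcs = NULL, var_target = 0.9) {
  sds <- apply(m, 2, stats::sd)
  keep <- sds > 0
  pr <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  if (is.null(n_pcs)) {
    cum <- cumsum(ev) / sum(ev)
    n_pcs <- which(cum >= var_target)[1]
  }
  n_pcs <- min(n_pcs, ncol(pr$x), nrow(m) - 1)
  list(
    scores = pr$x[, seq_len(n_pcs), drop = FALSE],
    prop_var = ev[seq_len(n_pcs)] / sum(ev), rotation = pr$rotation,
    center = pr$center, scale = pr$scale, keep = keep
  )
}

#' @export
print.ssr_clusters <- function(x, ...) {
  cat(
    "k-means/BIC cluster solution: K =", x$K, "(", x$n_pcs,
    "PCs retained )\n"
  )
  print(x$bic, n = nrow(x$bic))
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant analysis on the principal components of the allele
#' dosage matrix, prioritising between-group over within-group variation.
#' Groups are either a cluster solution from [find_clusters()], an explicit
#' vector, or the population labels (default).
#'
#' @param data An `ssr_tbl`.
#' @param clusters `NULL` (use population labels), an `ssr_clusters` object,
#'   or a vector of group labels in individual order.
#' @param n_pcs Retained PCs; default keeps >= `var_target` of variance.
#' @param n_da Number of discriminant axes (capped at K - 1).
#' @param var_target Variance fraction targeted when `n_pcs` is `NULL`.
#' @return An object of class `ssr_dapc`: `coords` (tibble of individual
#'   discriminant coordinates), `centroids`, `prop_var` (per-axis share of
#'   discriminant variance), `posterior` (membership probabilities, rows sum
#'   to 1), `assigned`, `n_pcs`.
#' @export
dapc_fit <- function(data, clusters = NULL, n_pcs = NULL, n_da = NULL,
                     var_target = 0.9) {
  m <- genotypes_to_allele_matrix(data)
  grp <- if (is.null(clusters)) {
    attr(m, "pop")
  } else if (inherits(clusters, "ssr_clusters")) {
    as.character(clusters$assignments$cluster[
      match(rownames(m), clusters$assignments$id)
    ])
  } else {
    as.character(clusters)
  }
  grp <- factor(grp)
  K <- nlevels(grp)
  if (K < 2) stop("DAPC needs >= 2 groups (K = 1 has no discriminant axes)", call. = FALSE)
  pcs <- dosage_pca(m, n_pcs, var_target)
  x <- pcs$scores
  n_da <- if (is.null(n_da)) K - 1 else min(n_da, K - 1)
  fit <- MASS::lda(x, grouping = grp)
  pred <- stats::predict(fit, x)
  ld <- pred$x[, seq_len(n_da), drop = FALSE]
  svd2 <- fit$svd^2
  coords <- tibble::tibble(
    id = rownames(m), group = as.character(grp),
    as.data.frame(ld)
  )
  centroids <- dplyr::summarise(
    dplyr::group_by(coords, .data$group),
    dplyr::across(dplyr::starts_with("LD"), mean), .groups = "drop"
  )
  structure(
    list(
      coords = coords, centroids = centroids,
      prop_var = svd2[seq_len(n_da)] / sum(svd2),
      posterior = pred$posterior,
      assigned = as.character(pred$class),
      n_pcs = ncol(x), K = K, lda = fit
    ),
    class = "ssr_dapc"
  )
}

#' @export
print.ssr_dapc <- function(x, ...) {
  cat(
    "DAPC:", x$K, "groups,", x$n_pcs, "PCs,",
    length(x$prop_var), "discriminant axes\n"
  )
  cat(
    "Discriminant variance shares:",
    paste(sprintf("%.1f%%", 100 * x$prop_var), collapse = ", "), "\n"
  )
  acc <- mean(x$assigned == x$coords$group)
  cat(sprintf("Reassignment accuracy: %.1f%%\n", 100 * acc))
  invisible(x)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres \eqn{-\tfrac12 D^2}, eigendecomposes, and scales each axis
#' by the square root of its eigenvalue. Negative eigenvalues are reported
#' (their axes are dropped from the coordinates); axes are ordered by
#' eigenvalue.
#'
#' @param dist A symmetric distance matrix (labels in dimnames).
#' @return A list: `coords` (tibble label + `Axis1..k` for positive
#'   eigenvalues), `eigenvalues` (all, sorted decreasing),
#'   `prop_var` (share of positive inertia per retained axis).
#' @export
pcoa_dist <- function(dist) {
  m <- as.matrix(dist)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8)) {
    stop("pcoa_dist needs a symmetric square matrix", call. = FALSE)
  }
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (m^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(abs(e$values))
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
    nrow = sum(pos)
  )
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("P", seq_len(n))
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(
    coords = tibble::tibble(label = labels, as.data.frame(coords)),
    eigenvalues = e$values,
    prop_var = e$values[pos] / sum(e$values[pos])
  )
}
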