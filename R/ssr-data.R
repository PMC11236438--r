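#' Diploid SSR genotype tables
#'
#' The package stores codominant microsatellite genotypes as a long tibble of
#' class `ssr_tbl`: one row per individual x locus, with columns
#' \describe{
#'   \item{id}{individual identifier (character, unique per individual)}
#'   \item{pop}{population identifier (character)}
#'   \item{locus}{locus name (character)}
#'   \item{a1, a2}{the unordered diploid genotype as two positive integer
#'     allele codes (fragment sizes or arbitrary codes), stored sorted so that
#'     `a1 <= a2`; a missing genotype has `NA` in both columns.}
#' }
#' Population order and locus order are first-appearance order and are carried
#' in the `pops` and `loci` attributes; every downstream matrix (FST, Nei
#' distance, migration) uses that order.
#'
#' @param x A data frame with columns `id`, `pop`, `locus`, `a1`, `a2`.
#' @param loci,pops Optional character vectors fixing locus/population order;
#'   defaults to first-appearance order in `x`.
#' @return A validated `ssr_tbl`.
#' @examples
#' g <- tibble::tibble(
#'   id = rep(c("i1", "i2"), each = 2), pop = "A",
#'   locus = rep(c("L1", "L2"), 2),
#'   a1 = c(150L, 200L, 150L, 202L), a2 = c(154L, 200L, 150L, 204L)
#' )
#' ssr_dataset(g)
#' @export
ssr_dataset <- function(x, loci = NULL, pops = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("id", "pop", "locus", "a1", "a2")
  if (!all(need %in% names(x))) {
    stop("ssr_dataset() needs columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  x$id <- as.character(x$id)
  x$pop <- as.character(x$pop)
  x$locus <- as.character(x$locus)
  x$a1 <- as.integer(x$a1)
  x$a2 <- as.integer(x$a2)
  # half-missing cells are not representable genotypes
  half <- xor(is.na(x$a1), is.na(x$a2))
  if (any(half)) {
    stop("genotype with a single missing allele at id=", x$id[half][1],
      " locus=", x$locus[half][1], "; diploid cells are all-or-nothing",
      call. = FALSE
    )
  }
  bad <- !is.na(x$a1) & (x$a1 <= 0L | x$a2 <= 0L)
  if (any(bad)) {
    stop("allele codes must be positive integers (id=", x$id[bad][1],
      ", locus=", x$locus[bad][1], ")",
      call. = FALSE
    )
  }
  swap <- !is.na(x$a1) & x$a1 > x$a2
  if (any(swap)) {
    tmp <- x$a1[swap]
    x$a1[swap] <- x$a2[swap]
    x$a2[swap] <- tmp
  }
  if (is.null(loci)) loci <- unique(x$locus)
  if (is.null(pops)) pops <- unique(x$pop)
  # one population per individual
  ip <- dplyr::distinct(x, .data$id, .data$pop)
  if (anyDuplicated(ip$id)) {
    stop("individual ", ip$id[duplicated(ip$id)][1],
      " is assigned to more than one population",
      call. = FALSE
    )
  }
  miss <- setdiff(
    as.vector(outer(unique(x$id), loci, paste, sep = "\r")),
    paste(x$id, x$locus, sep = "\r")
  )
  if (length(miss) > 0) {
    # complete the grid with missing genotypes so every individual has a row
    # per locus
    add <- do.call(rbind, strsplit(miss, "\r", fixed = TRUE))
    pop_of <- stats::setNames(ip$pop, ip$id)
    x <- dplyr::bind_rows(x, tibble::tibble(
      id = add[, 1], pop = unname(pop_of[add[, 1]]), locus = add[, 2],
      a1 = NA_integer_, a2 = NA_integer_
    ))
  }
  x <- x[order(
    match(x$pop, pops), match(x$id, unique(x$id)),
    match(x$locus, loci)
  ), , drop = FALSE]
  new_ssr_tbl(x, loci = loci, pops = pops)
}

new_ssr_tbl <- function(x, loci, pops) {
  structure(
    tibble::as_tibble(x),
    loci = loci, pops = pops,
    class = c("ssr_tbl", class(tibble::tibble()))
  )
}

#' @export
print.ssr_tbl <- function(x, ...) {
  cat(
    "# SSR genotypes:", length(unique(x$id)), "individuals x",
    length(ssr_loci(x)), "loci in", length(ssr_pops(x)), "populations\n"
  )
  NextMethod()
}

#' Locus and population order of an SSR dataset
#'
#' @param x An `ssr_tbl` (or any long genotype data frame).
#' @return Character vector of locus (population) names in canonical order.
#' @export
ssr_loci <- function(x) {
  lv <- attr(x, "loci")
  if (is.null(lv)) unique(x$locus) else lv
}

#' @rdname ssr_loci
#' @export
ssr_pops <- function(x) {
  pv <- attr(x, "pops")
  if (is.null(pv)) unique(x$pop) else pv
}

#' Validate an SSR dataset
#'
#' Structural checks (reported, never raised): empty populations, loci with no
#' scored genotypes anywhere or within a population, duplicate ids. Also
#' reports missing-cell counts per locus and per population.
#'
#' @param data An `ssr_tbl`.
#' @return A list with `violations` (tibble: severity, message), and
#'   `missing_by_locus` / `missing_by_pop` count tibbles. An empty
#'   `violations` tibble means the dataset is clean.
#' @export
validate_ssr <- function(data) {
  v <- list()
  note <- function(severity, message) {
    v[[length(v) + 1]] <<- tibble::tibble(severity = severity, message = message)
  }
  for (p in ssr_pops(data)) {
    if (!any(data$pop == p)) note("error", paste0("population '", p, "' has no individuals"))
  }
  # haploid (half-scored) cells: representable in a raw data frame even though
  # ssr_dataset() refuses to construct them
  half <- xor(is.na(data$a1), is.na(data$a2))
  for (i in which(half)) {
    note("error", paste0(
      "haploid cell: individual '", data$id[i],
      "' at locus '", data$locus[i], "' has one scored allele"
    ))
  }
  dup <- duplicated(paste(data$id, data$locus, sep = "\r"))
  if (any(dup)) {
    note("error", paste0(
      "duplicate genotype rows for individual '",
      data$id[dup][1], "' at locus '", data$locus[dup][1], "'"
    ))
  }
  by_loc <- dplyr::summarise(dplyr::group_by(data, .data$locus),
    n_scored = sum(!is.na(.data$a1)), n_missing = sum(is.na(.data$a1)),
    .groups = "drop"
  )
  for (i in seq_len(nrow(by_loc))) {
    if (by_loc$n_scored[i] == 0) {
      note("warning", paste0("uninformative locus '", by_loc$locus[i], "': all cells missing"))
    }
  }
  by_pop <- dplyr::summarise(dplyr::group_by(data, .data$pop),
    n_scored = sum(!is.na(.data$a1)), n_missing = sum(is.na(.data$a1)),
    .groups = "drop"
  )
  violations <- if (length(v) > 0) {
    dplyr::bind_rows(v)
  } else {
    tibble::tibble(severity = character(), message = character())
  }
  list(
    violations = violations,
    missing_by_locus = by_loc,
    missing_by_pop = by_pop
  )
}

#' Symmetric labelled distance matrices
#'
#' Light wrapper used for FST, Nei distance and geographic distances: a square
#' numeric matrix with matching dimnames, symmetric within `tol`, zero
#' diagonal.
#'
#' @param m Square numeric matrix.
#' @param labels Optional labels (defaults to rownames).
#' @param tol Symmetry tolerance.
#' @return The matrix with dimnames set, validated.
#' @export
dist_matrix <- function(m, labels = NULL, tol = 1e-9) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("P", seq_len(nrow(m)))
  tm <- t(m)
  ok <- is.na(m) | is.na(tm) | (is.infinite(m) & is.infinite(tm)) |
    abs(m - tm) <= tol
  ok[is.na(ok)] <- FALSE
  if (!all(ok)) stop("distance matrix is not symmetric", call. = FALSE)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

#' Read/write a labelled square distance matrix as CSV
#'
#' First column holds labels, remaining columns the matrix values.
#'
#' @param path File path.
#' @param m Matrix for writing.
#' @return `read_dist_csv()` returns a validated symmetric matrix.
#' @export
read_dist_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  dist_matrix(m, labels = labels)
}

#' @rdname read_dist_csv
#' @export
write_dist_csv <- function(m, path) {
  d <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
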