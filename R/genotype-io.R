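#' Read a GenePop genotype file
#'
#' Parses the GenePop 4.x dialect: a title line, locus names (one per line or
#' comma-separated on one line), `Pop` separators, and per individual a label,
#' a comma, and one concatenated diploid cell per locus in 2- or 3-digit
#' allele coding. All-zero cells (`000`, `0000`, `000000`) are missing
#' genotypes. Allele width must be consistent across the whole file.
#'
#' @param path Path to a GenePop file.
#' @param pop_names Optional character vector overriding population names (one
#'   per `Pop` block, in file order). By default each block is named after its
#'   last individual label, the GenePop convention.
#' @return An [ssr_dataset()] (`ssr_tbl`).
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 4) stop("not a GenePop file: fewer than 4 lines", call. = FALSE)
  body <- lines[-1] # title line dropped
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GenePop file: no 'Pop' separator", call. = FALSE)
  loc_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicate locus names in GenePop header", call. = FALSE)

  blocks <- cumsum(is_pop)
  ind_lines <- which(!is_pop & seq_along(body) > first_pop - 1 & nzchar(trimws(body)))
  ind_lines <- ind_lines[ind_lines > first_pop]
  n_blocks <- max(blocks)
  if (!is.null(pop_names) && length(pop_names) != n_blocks) {
    stop("pop_names must have one name per Pop block (", n_blocks, ")", call. = FALSE)
  }

  allele_digits <- NA_integer_
  rows <- vector("list", length(ind_lines))
  labels_by_block <- vector("list", n_blocks)
  for (k in seq_along(ind_lines)) {
    li <- ind_lines[k]
    raw <- body[li]
    parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      stop("GenePop parse error at line ", li + 1, ": no comma after individual label", call. = FALSE)
    }
    label <- trimws(parts[1])
    cells <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(cells) != length(loci)) {
      stop(
        "GenePop parse error at line ", li + 1, ": ", length(cells),
        " genotype cells for ", length(loci), " loci",
        call. = FALSE
      )
    }
    a1 <- integer(length(loci))
    a2 <- integer(length(loci))
    for (j in seq_along(cells)) {
      cell <- cells[j]
      if (!grepl("^[0-9]+$", cell)) {
        stop("GenePop parse error at line ", li + 1, ": non-numeric cell '", cell, "'", call. = FALSE)
      }
      if (grepl("^0+$", cell) && nchar(cell) %in% c(3L, 4L, 6L)) {
        a1[j] <- NA_integer_
        a2[j] <- NA_integer_
        next
      }
      if (nchar(cell) %% 2L != 0L) {
        stop(
          "GenePop parse error at line ", li + 1, ": cell '", cell,
          "' has an odd number of digits",
          call. = FALSE
        )
      }
      w <- nchar(cell) %/% 2L
      if (!w %in% c(2L, 3L)) {
        stop(
          "GenePop parse error at line ", li + 1, ": allele width ", w,
          " (only 2- and 3-digit coding supported)",
          call. = FALSE
        )
      }
      if (is.na(allele_digits)) {
        allele_digits <- w
      } else if (w != allele_digits) {
        stop(
          "GenePop parse error at line ", li + 1, ": mixed allele widths (",
          allele_digits, " and ", w, " digits) in one file",
          call. = FALSE
        )
      }
      x1 <- as.integer(substr(cell, 1L, w))
      x2 <- as.integer(substr(cell, w + 1L, 2L * w))
      if (x1 == 0L || x2 == 0L) {
        stop(
          "GenePop parse error at line ", li + 1, ": half-missing cell '",
          cell, "'",
          call. = FALSE
        )
      }
      a1[j] <- x1
      a2[j] <- x2
    }
    b <- blocks[li]
    labels_by_block[[b]] <- c(labels_by_block[[b]], label)
    rows[[k]] <- tibble::tibble(
      id = label, block = b, locus = loci, a1 = a1, a2 = a2
    )
  }
  empty <- which(vapply(labels_by_block, length, 1L) == 0L)
  if (length(empty) > 0) {
    stop("GenePop validation error: empty Pop block (#", empty[1], ")", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  block_names <- if (is.null(pop_names)) {
    vapply(labels_by_block, function(l) l[length(l)], "")
  } else {
    pop_names
  }
  if (anyDuplicated(block_names)) {
    block_names <- make.unique(block_names, sep = "_")
  }
  out$pop <- block_names[out$block]
  out$block <- NULL
  # disambiguate duplicated individual labels across blocks
  if (anyDuplicated(dplyr::distinct(out, .data$id, .data$pop)$id)) {
    out$id <- paste(out$pop, out$id, sep = ":")
  }
  ssr_dataset(out, loci = loci, pops = block_names)
}

#' Write a GenePop genotype file
#'
#' @param data An `ssr_tbl`.
#' @param path Output path.
#' @param title Title line content.
#' @param allele_digits 2 or 3; alleles wider than this are an error.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(data, path, title = "ssrinvasion export", allele_digits = 3) {
  loci <- ssr_loci(data)
  pops <- ssr_pops(data)
  mx <- max(c(data$a1, data$a2), na.rm = TRUE)
  if (mx >= 10^allele_digits) {
    stop("allele code ", mx, " does not fit in ", allele_digits, "-digit coding", call. = FALSE)
  }
  fmt <- function(a) {
    ifelse(is.na(a), strrep("0", allele_digits),
      formatC(a, width = allele_digits, flag = "0")
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci, con)
  for (p in pops) {
    writeLines("Pop", con)
    sub <- data[data$pop == p, , drop = FALSE]
    for (ind in unique(sub$id)) {
      g <- sub[sub$id == ind, , drop = FALSE]
      g <- g[match(loci, g$locus), , drop = FALSE]
      cells <- paste0(fmt(g$a1), fmt(g$a2))
      writeLines(paste0(ind, " , ", paste(cells, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a delimited genotype table
#'
#' Expects a header row with an individual column, a population column, then
#' two columns per locus. Locus names are taken from the first column of each
#' pair, with a trailing pair index (`_1`, `.1`, `a`/`b`, ...) stripped when
#' present, so `Ced41_1,Ced41_2` and `Ced41,Ced41.1` both name locus `Ced41`.
#'
#' @param path File path.
#' @param delimiter Field delimiter (default `","`).
#' @param missing Tokens treated as missing alleles (any match makes the whole
#'   genotype missing).
#' @param id_col,pop_col Column positions of individual and population ids.
#' @return An [ssr_dataset()].
#' @export
read_ssr_table <- function(path, delimiter = ",", missing = c("NA", "", "0"),
                           id_col = 1, pop_col = 2) {
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"")
  if (length(unique(nf)) != 1) {
    stop(
      "table parse error: ragged rows (fields per line: ",
      paste(unique(nf), collapse = ", "), ")",
      call. = FALSE
    )
  }
  d <- utils::read.table(path,
    sep = delimiter, header = TRUE, check.names = FALSE,
    colClasses = "character", quote = "\""
  )
  geno_cols <- setdiff(seq_len(ncol(d)), c(id_col, pop_col))
  if (length(geno_cols) %% 2 != 0 || length(geno_cols) == 0) {
    stop("table parse error: need two allele columns per locus", call. = FALSE)
  }
  first_of_pair <- geno_cols[seq(1, length(geno_cols), by = 2)]
  loci <- sub("[._-]?(1|a|A)$", "", names(d)[first_of_pair])
  if (anyDuplicated(loci)) loci <- make.unique(loci, sep = "_")
  parse_allele <- function(tok) {
    tok <- trimws(tok)
    out <- rep(NA_integer_, length(tok))
    is_miss <- is.na(tok) | tok %in% missing
    bad <- !is_miss & !grepl("^[0-9]+$", tok)
    if (any(bad)) {
      stop("table parse error: non-integer allele token '", tok[bad][1], "'", call. = FALSE)
    }
    out[!is_miss] <- as.integer(tok[!is_miss])
    out[!is.na(out) & out == 0L] <- NA_integer_
    out
  }
  rows <- lapply(seq_along(loci), function(j) {
    c1 <- geno_cols[2 * j - 1]
    c2 <- geno_cols[2 * j]
    a1 <- parse_allele(d[[c1]])
    a2 <- parse_allele(d[[c2]])
    half <- xor(is.na(a1), is.na(a2))
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
    tibble::tibble(
      id = as.character(d[[id_col]]), pop = as.character(d[[pop_col]]),
      locus = loci[j], a1 = a1, a2 = a2
    )
  })
  ssr_dataset(dplyr::bind_rows(rows), loci = loci)
}

#' Write a delimited genotype table (two columns per locus)
#'
#' @inheritParams write_genepop
#' @param delimiter Field delimiter.
#' @param missing Token written for missing alleles.
#' @export
write_ssr_table <- function(data, path, delimiter = ",", missing = "NA") {
  loci <- ssr_loci(data)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(data),
    id_cols = c("id", "pop"), names_from = "locus",
    values_from = c("a1", "a2"),
    names_glue = "{locus}_{ifelse(.value == 'a1', 1, 2)}"
  )
  ord <- c("id", "pop", as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))
  wide <- wide[, ord]
  for (j in seq(3, ncol(wide))) {
    wide[[j]] <- ifelse(is.na(wide[[j]]), missing, as.character(wide[[j]]))
  }
  utils::write.table(wide, path,
    sep = delimiter, row.names = FALSE,
    quote = FALSE
  )
  invisible(path)
}
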