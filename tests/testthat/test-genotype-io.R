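strip_geno <- function(x) {
  x <- as.data.frame(tibble::as_tibble(x)[, c("id", "pop", "locus", "a1", "a2")])
  x[order(x$id, x$locus), ]
}

test_that("GenePop parser handles minimal files, missing codes and pop naming", {
  tf <- withr::local_tempfile(fileext = ".gen")
  writeLines(c(
    "two pops one locus",
    "L1",
    "Pop",
    "a1 , 001002",
    "a2 , 001001",
    "Pop",
    "b1 , 002002",
    "b2 , 000000"
  ), tf)
  ds <- read_genepop(tf)
  expect_s3_class(ds, "ssr_tbl")
  expect_equal(ssr_loci(ds), "L1")
  expect_equal(ssr_pops(ds), c("a2", "b2")) # last label of each block
  expect_equal(sort(unique(c(ds$a1, ds$a2))), c(1L, 2L))
  expect_true(is.na(ds$a1[ds$id == "b2"])) # all-zero cell is missing
  ds2 <- read_genepop(tf, pop_names = c("North", "South"))
  expect_equal(ssr_pops(ds2), c("North", "South"))
})

test_that("GenePop parser rejects malformed input with informative errors", {
  bad <- function(lines) {
    tf <- tempfile(fileext = ".gen")
    writeLines(lines, tf)
    tf
  }
  # odd digit count
  expect_error(
    read_genepop(bad(c("t", "L1", "Pop", "x , 00102"))),
    "odd number of digits"
  )
  # mixed 2- and 3-digit widths
  expect_error(
    read_genepop(bad(c("t", "L1", "L2", "Pop", "x , 0102 001002"))),
    "mixed allele widths"
  )
  # empty Pop block
  expect_error(
    read_genepop(bad(c("t", "L1", "Pop", "x , 0102", "Pop"))),
    "empty Pop block"
  )
})

test_that("GenePop write/read round-trips genotypes, populations and loci", {
  ds <- generate_island_fixture(seed = 7)
  tf <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds, tf)
  back <- read_genepop(tf, pop_names = ssr_pops(ds))
  expect_equal(ssr_loci(back), ssr_loci(ds))
  expect_equal(ssr_pops(back), ssr_pops(ds))
  expect_equal(strip_geno(back), strip_geno(ds), ignore_attr = TRUE)
})

test_that("delimited table reader parses genotypes and agrees with GenePop", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ind,pop,Ced41_1,Ced41_2",
    "i1,A,150,154",
    "i2,A,NA,NA"
  ), tf)
  ds <- read_ssr_table(tf)
  expect_equal(ssr_loci(ds), "Ced41")
  expect_equal(ds$a1[ds$id == "i1"], 150L)
  expect_equal(ds$a2[ds$id == "i1"], 154L)
  expect_true(is.na(ds$a1[ds$id == "i2"]))

  # dual encoding of the same dataset produces equal objects
  full <- generate_island_fixture(seed = 3)
  tg <- withr::local_tempfile(fileext = ".gen")
  tt <- withr::local_tempfile(fileext = ".csv")
  write_genepop(full, tg)
  write_ssr_table(full, tt)
  via_gen <- read_genepop(tg, pop_names = ssr_pops(full))
  via_tab <- read_ssr_table(tt)
  expect_equal(strip_geno(via_gen), strip_geno(via_tab), ignore_attr = TRUE)
})

test_that("table reader rejects ragged rows and non-integer tokens", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ind,pop,L1_1,L1_2", "i1,A,150,154", "i2,A,150"), tf)
  expect_error(read_ssr_table(tf), "ragged")
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ind,pop,L1_1,L1_2", "i1,A,15x,154"), tf2)
  expect_error(read_ssr_table(tf2), "non-integer")
})

test_that("validate_ssr reports rather than raises", {
  ds <- generate_island_fixture(seed = 5)
  rep_ok <- validate_ssr(ds)
  expect_equal(nrow(rep_ok$violations), 0)
  expect_true(all(c("locus", "n_missing") %in% names(rep_ok$missing_by_locus)))

  # uninformative locus (all missing)
  d <- tibble::as_tibble(ds)
  d$a1[d$locus == "loc1"] <- NA_integer_
  d$a2[d$locus == "loc1"] <- NA_integer_
  rep_warn <- validate_ssr(ssr_dataset(d))
  expect_true(any(grepl("uninformative locus", rep_warn$violations$message)))

  # haploid cell injected into a raw frame
  raw <- tibble::as_tibble(ds)
  raw$a2[3] <- NA_integer_
  rep_bad <- validate_ssr(raw)
  expect_true(any(grepl("haploid cell", rep_bad$violations$message)))
  expect_true(any(grepl(raw$id[3], rep_bad$violations$message, fixed = TRUE)))
})

test_that("ssr_dataset enforces structural invariants", {
  base <- tibble::tibble(
    id = "i1", pop = "A", locus = "L1", a1 = 2L, a2 = 1L
  )
  ds <- ssr_dataset(base)
  expect_equal(ds$a1, 1L) # stored sorted
  expect_equal(ds$a2, 2L)
  expect_error(
    ssr_dataset(dplyr::mutate(base, a1 = 0L)),
    "positive"
  )
  expect_error(
    ssr_dataset(dplyr::mutate(base, a2 = NA_integer_)),
    "single missing allele"
  )
  two_pop <- dplyr::bind_rows(base, dplyr::mutate(base, pop = "B"))
  expect_error(ssr_dataset(two_pop), "more than one population")
})

test_that("the shipped synthetic example survey loads and regenerates", {
  gen <- system.file("extdata", "synthetic_island_survey.gen",
    package = "ssrinvasion"
  )
  tru <- system.file("extdata", "synthetic_island_survey_truth.json",
    package = "ssrinvasion"
  )
  ds <- read_genepop(gen, pop_names = c(
    "SantaCruz", "SanCristobal", "Isabela", "Floreana"
  ))
  expect_equal(length(unique(ds$id)), 40)
  expect_equal(length(ssr_loci(ds)), 9)
  re <- regenerate_truth(read_truth(tru))
  expect_equal(
    as.data.frame(tibble::as_tibble(re)[, c("pop", "locus", "a1", "a2")]),
    as.data.frame(tibble::as_tibble(ds)[, c("pop", "locus", "a1", "a2")]),
    ignore_attr = TRUE
  )
})

test_that("distance matrix CSV round-trips labels and values", {
  m <- dist_matrix(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3),
    labels = c("Santa Cruz", "Isabela", "Floreana")
  )
  tf <- withr::local_tempfile(fileext = ".csv")
  write_dist_csv(m, tf)
  back <- read_dist_csv(tf)
  expect_equal(back, m)
  expect_error(dist_matrix(matrix(c(0, 1, 2, 0), 2)), "not symmetric")
})
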