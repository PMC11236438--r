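#' Run the full SSR analysis pipeline
#'
#' Orchestrates diversity -> differentiation -> structure -> tree -> ABC on
#' one genotype dataset and writes per-stage artifacts (CSV / Newick) plus a
#' single JSON manifest holding every statistic and every seed. Stages are
#' individually skippable; a failing stage is recorded as partial completion
#' and the run continues.
#'
#' @param input An `ssr_tbl`, or a path to a GenePop / delimited genotype
#'   file.
#' @param format `"genepop"` or `"table"` when `input` is a path.
#' @param output_dir Directory for artifacts (created if needed); `NULL`
#'   writes nothing and only returns the manifest.
#' @param seed Integer master seed; each stage gets a derived seed, all
#'   recorded in the manifest.
#' @param skip Character vector of stages to skip, out of
#'   `c("diversity", "differentiation", "structure", "tree", "abc")`.
#' @param permutations AMOVA permutation count.
#' @param n_boot Tree bootstrap replicates.
#' @param hwe_iterations Markov chain iterations per batch for the HWE test
#'   (with 100 batches).
#' @param geo_dist Optional geographic distance matrix (labels =
#'   populations) enabling the Mantel test.
#' @param abc_stage Catalog stage for the ABC block.
#' @param abc_sims Simulations per scenario for the reference table.
#' @param abc_scenarios Optional named scenario list overriding the catalog.
#' @param max_K Largest K for cluster search.
#' @param verbose Log stage timings to stderr.
#' @return The manifest (list), invisibly classed `ssr_manifest`. Exit
#'   semantics for scripting: `attr(, "status")` is `"ok"` or `"partial"`.
#' @export
run_ssr_pipeline <- function(input, format = c("genepop", "table"),
                             output_dir = NULL, seed = 1,
                             skip = character(),
                             permutations = 999, n_boot = 200,
                             hwe_iterations = 200, geo_dist = NULL,
                             abc_stage = 1, abc_sims = 300,
                             abc_scenarios = NULL, max_K = 8,
                             verbose = TRUE) {
  format <- match.arg(format)
  data <- if (inherits(input, "ssr_tbl")) {
    input
  } else if (format == "genepop") {
    read_genepop(input)
  } else {
    read_ssr_table(input)
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  stages <- c("diversity", "differentiation", "structure", "tree", "abc")
  seeds <- stats::setNames(seed + seq_along(stages), stages)
  log_msg <- function(...) if (verbose) message("[ssrinvasion] ", ...)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ssrinvasion")),
    seed = seed, stage_seeds = as.list(seeds),
    n_individuals = length(unique(data$id)),
    n_loci = length(ssr_loci(data)),
    populations = ssr_pops(data),
    stages = list()
  )
  run_stage <- function(name, fun) {
    if (name %in% skip) {
      log_msg("stage ", name, ": skipped")
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    t0 <- Sys.time()
    res <- tryCatch(fun(seeds[[name]]),
      error = function(e) structure(list(error = conditionMessage(e)), failed = TRUE)
    )
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    if (isTRUE(attr(res, "failed"))) {
      log_msg("stage ", name, " FAILED: ", res$error)
      manifest$stages[[name]] <<- list(
        status = "failed", error = res$error,
        runtime_s = dt
      )
    } else {
      log_msg("stage ", name, " done in ", dt, "s")
      manifest$stages[[name]] <<- c(
        list(status = "ok", runtime_s = dt),
        res
      )
    }
  }

  run_stage("diversity", function(sd) {
    set.seed(sd)
    summ <- diversity_summary(data)
    per_locus <- heterozygosity(data, level = "locus")
    glob <- heterozygosity(data, level = "global")
    hwe <- hwe_test(data,
      pooled = TRUE, dememorization = 1000, batches = 100,
      iterations = hwe_iterations, seed = sd
    )
    em <- null_allele_em(data)
    ena <- fst_ena(data)
    pa <- private_alleles(data)
    if (!is.null(output_dir)) {
      readr::write_csv(summ, file.path(output_dir, "diversity_by_population.csv"))
      readr::write_csv(
        dplyr::left_join(
          dplyr::left_join(per_locus, attr(em, "by_locus"), by = "locus"),
          hwe[, c("locus", "p_hwe", "p_bonferroni")],
          by = "locus"
        ),
        file.path(output_dir, "diversity_by_locus.csv")
      )
    }
    list(
      by_population = summ, by_locus = per_locus, global = glob,
      hwe = hwe, null_alleles = attr(em, "by_locus"),
      fst_ena = list(
        global = as.list(ena$global),
        t_test = ena$t_test
      ),
      private_fraction = attr(pa, "fraction_private")
    )
  })

  run_stage("differentiation", function(sd) {
    set.seed(sd)
    fst <- pairwise_fst(data)
    am <- amova(data, n_permutations = permutations, seed = sd)
    mig <- relative_migration(data, seed = sd + 1)
    mant <- if (!is.null(geo_dist)) {
      mantel_test(fst, geo_dist, seed = sd + 2)
    } else {
      NULL
    }
    if (!is.null(output_dir)) {
      write_dist_csv(fst, file.path(output_dir, "pairwise_fst.csv"))
      readr::write_csv(tidy(mig), file.path(output_dir, "migration_network.csv"))
    }
    c(
      list(
        fst = as.data.frame(fst), amova = c(
          as.list(glance(am)),
          list(table = tidy(am))
        ),
        migration = tidy(mig)
      ),
      if (!is.null(mant)) list(mantel = mant)
    )
  })

  run_stage("structure", function(sd) {
    set.seed(sd)
    cl <- find_clusters(data, max_K = max_K, seed = sd)
    dp <- dapc_fit(data, clusters = cl)
    pc <- pcoa_dist(pairwise_fst(data, truncate = TRUE))
    if (!is.null(output_dir)) {
      readr::write_csv(cl$bic, file.path(output_dir, "bic_curve.csv"))
      readr::write_csv(tidy(dp), file.path(output_dir, "dapc_coords.csv"))
      readr::write_csv(pc$coords, file.path(output_dir, "pcoa_coords.csv"))
    }
    list(
      K = cl$K, bic = cl$bic, assignments = cl$assignments,
      dapc = as.list(glance(dp)), pcoa_eigenvalues = pc$eigenvalues
    )
  })

  run_stage("tree", function(sd) {
    tr <- bootstrap_tree(data, n_boot = n_boot, seed = sd)
    path <- NULL
    if (!is.null(output_dir)) {
      path <- file.path(output_dir, "upgma_tree.nwk")
      write_newick(tr, path)
    }
    list(
      newick = capture_newick(tr),
      supports = tr$node.label, n_boot = n_boot
    )
  })

  run_stage("abc", function(sd) {
    scns <- abc_scenarios %||% load_scenarios_stage(abc_stage)
    tab <- build_reference_table(scns,
      n_sims_per_scenario = abc_sims,
      n_loci = length(ssr_loci(data)), seed = sd
    )
    obs <- observed_stats_for_abc(data, scns[[1]])
    post <- suppressWarnings(scenario_posterior(tab, obs))
    best <- post$scenario[which.max(post$posterior)]
    pars <- estimate_parameters(tab, obs, best)
    if (!is.null(output_dir)) {
      readr::write_csv(post, file.path(output_dir, "abc_scenario_posterior.csv"))
      readr::write_csv(pars, file.path(output_dir, "abc_parameters.csv"))
    }
    list(
      stage = abc_stage, n_sims = abc_sims, posterior = post,
      best_scenario = best, parameters = pars
    )
  })

  failed <- any(vapply(
    manifest$stages,
    function(s) identical(s$status, "failed"), TRUE
  ))
  manifest$status <- if (failed) "partial" else "ok"
  if (!is.null(output_dir)) {
    jsonlite::write_json(
      manifest_serializable(manifest),
      file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
    )
  }
  structure(manifest, class = "ssr_manifest", status = manifest$status)
}

capture_newick <- function(tree) {
  tf <- tempfile(fileext = ".nwk")
  on.exit(unlink(tf))
  write_newick(tree, tf)
  readLines(tf)[1]
}

manifest_serializable <- function(m) {
  rapply(m, function(x) {
    if (inherits(x, "phylo")) capture_newick(x) else x
  }, how = "replace", classes = c("phylo", "ANY"))
}

# map the dataset's populations onto the scenario's sampled demes by name
# when they match, else by order, so observed stats share the ABC schema
observed_stats_for_abc <- function(data, scn) {
  sampled <- scn$demes$deme[scn$demes$sample > 0]
  pops <- ssr_pops(data)
  if (all(sampled %in% pops)) {
    return(summary_stats(data, demes = sampled))
  }
  if (length(pops) != length(sampled)) {
    stop(
      "dataset has ", length(pops), " populations but the scenario samples ",
      length(sampled), " demes; supply matching scenarios",
      call. = FALSE
    )
  }
  d <- tibble::as_tibble(data)
  d$pop <- sampled[match(d$pop, pops)]
  summary_stats(
    ssr_dataset(d, loci = ssr_loci(data), pops = sampled),
    demes = sampled
  )
}

#' Human-readable report from a pipeline manifest
#'
#' Formats the manifest's key results as plain-text tables: a symmetric
#' pairwise-FST matrix (em-dash diagonal), the per-population diversity
#' panel, AMOVA, and the ABC scenario posterior table. Values are printed at
#' 2 decimals for diversity statistics and FST; the manifest keeps full
#' precision.
#'
#' @param manifest An `ssr_manifest` from [run_ssr_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
report_tables <- function(manifest) {
  out <- c("=== SSR pipeline report ===", "")
  st <- manifest$stages
  fmt2 <- function(x) formatC(round(x, 2), format = "f", digits = 2)
  if (!is.null(st$differentiation) && st$differentiation$status == "ok") {
    fstm <- as.matrix(st$differentiation$fst)
    lab <- colnames(fstm)
    body <- matrix(fmt2(fstm), nrow(fstm))
    diag(body) <- "—"
    wid <- max(nchar(c(lab, body)))
    pad <- function(x) formatC(x, width = wid)
    out <- c(
      out, "Pairwise FST:",
      paste(c(pad(""), pad(lab)), collapse = " ")
    )
    for (i in seq_along(lab)) {
      out <- c(out, paste(c(pad(lab[i]), pad(body[i, ])), collapse = " "))
    }
    out <- c(out, "")
  }
  if (!is.null(st$diversity) && st$diversity$status == "ok") {
    bp <- st$diversity$by_population
    out <- c(out, "Diversity by population (Na, Ho, He, FIS, Rs, Npa):")
    for (i in seq_len(nrow(bp))) {
      out <- c(out, sprintf(
        "  %-14s Na=%d Ho=%s He=%s FIS=%s Rs=%s Npa=%d",
        bp$pop[i], bp$na[i], fmt2(bp$ho[i]), fmt2(bp$he[i]),
        fmt2(bp$fis[i]), fmt2(bp$rs[i]), bp$npa[i]
      ))
    }
    out <- c(out, "")
  }
  if (!is.null(st$differentiation) && st$differentiation$status == "ok") {
    am <- st$differentiation$amova
    out <- c(out, sprintf(
      "AMOVA: %.2f%% among / %.2f%% within populations; Phi_ST=%.3f, p=%.4g",
      am$table$percent[1], am$table$percent[2], am$phi_st, am$p_value
    ), "")
  }
  if (!is.null(st$abc) && st$abc$status == "ok") {
    out <- c(out, "ABC scenario posteriors:")
    po <- st$abc$posterior
    for (i in order(-po$posterior)) {
      out <- c(out, sprintf(
        "  %-28s %.4f%s", po$scenario[i], po$posterior[i],
        if (po$scenario[i] == st$abc$best_scenario) "  <- best" else ""
      ))
    }
    out <- c(out, "")
  }
  skipped <- names(st)[vapply(st, function(s) identical(s$status, "skipped"), TRUE)]
  failed <- names(st)[vapply(st, function(s) identical(s$status, "failed"), TRUE)]
  if (length(skipped) > 0) out <- c(out, paste("Skipped stages:", paste(skipped, collapse = ", ")))
  if (length(failed) > 0) out <- c(out, paste("FAILED stages:", paste(failed, collapse = ", ")))
  cat(out, sep = "\n")
  invisible(out)
}
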