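#' Demographic invasion scenarios
#'
#' A scenario is a backward-in-time event list over named demes, the
#' currency of the ABC engine. Numeric fields (effective sizes, event times,
#' bottleneck sizes/durations, admixture proportions, the mutation rate) may
#' be given as numbers or as parameter names (e.g. `"N2"`, `"t1"`) to be
#' drawn from priors at simulation time.
#'
#' Event semantics (times in generations before present):
#' \describe{
#'   \item{split}{at `time`, lineages of `deme` move into `parent_a` — the
#'     forward-time introduction of `deme` from `parent_a`.}
#'   \item{admix}{at `time`, each lineage of `deme` moves to `parent_a` with
#'     probability `prop`, else to `parent_b` — a forward-time admixed
#'     founding.}
#'   \item{bottleneck}{`deme` has size `size` during
#'     `[time, time + duration)` — a founder bottleneck directly after an
#'     introduction ends at the introduction (split) time.}
#' }
#'
#' @param name Scenario identifier.
#' @param demes Tibble/data frame with columns `deme`, `ne` (number or
#'   parameter name) and `sample` (diploid individuals sampled; 0 = ghost).
#' @param events Tibble with columns `type`, `time`, `deme`, `parent_a`,
#'   `parent_b`, `prop`, `size`, `duration` (unused fields `NA`).
#' @return An object of class `ssr_scenario`.
#' @export
scenario <- function(name, demes, events) {
  demes <- tibble::as_tibble(demes)
  if (!"sample" %in% names(demes)) demes$sample <- 0L
  events <- tibble::as_tibble(events)
  for (col in c("parent_b", "prop", "size", "duration")) {
    if (!col %in% names(events)) events[[col]] <- NA
  }
  events <- events[, c(
    "type", "time", "deme", "parent_a", "parent_b",
    "prop", "size", "duration"
  )]
  bad <- !events$type %in% c("split", "admix", "bottleneck")
  if (any(bad)) stop("unknown event type: ", events$type[bad][1], call. = FALSE)
  refs <- c(events$deme, events$parent_a, events$parent_b)
  miss <- setdiff(unique(refs[!is.na(refs)]), demes$deme)
  if (length(miss) > 0) stop("event references unknown deme: ", miss[1], call. = FALSE)
  structure(list(name = name, demes = demes, events = events),
    class = "ssr_scenario"
  )
}

#' @export
print.ssr_scenario <- function(x, ...) {
  cat("Scenario", x$name, "-", nrow(x$demes), "demes,", nrow(x$events), "events\n")
  print(x$demes)
  print(x$events)
  invisible(x)
}

#' Parameters named in a scenario template
#'
#' @param scn An `ssr_scenario`.
#' @return Character vector of free parameter names (fields given as
#'   non-numeric strings), always including `"mu"`.
#' @export
scenario_params <- function(scn) {
  vals <- c(
    scn$demes$ne, scn$events$time, scn$events$prop, scn$events$size,
    scn$events$duration
  )
  vals <- as.character(vals[!is.na(vals)])
  # derived expressions like "t4-db4" contribute their component names
  vals <- unlist(strsplit(vals, "-", fixed = TRUE))
  free <- vals[is.na(suppressWarnings(as.numeric(vals)))]
  unique(c(free, "mu"))
}

num_or_param <- function(x, params) {
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  need <- is.na(out) & !is.na(x)
  if (any(need)) {
    missing_p <- setdiff(x[need], names(params))
    if (length(missing_p) > 0) {
      stop("no value for scenario parameter '", missing_p[1], "'", call. = FALSE)
    }
    out[need] <- unlist(params)[x[need]]
  }
  out
}

#' Instantiate a scenario with concrete parameter values
#'
#' @param scn An `ssr_scenario` (possibly with named free parameters).
#' @param params Named list/vector of parameter values.
#' @param check Validate event-order invariants (default `TRUE`).
#' @return An `ssr_scenario` with all numeric fields resolved.
#' @export
instantiate_scenario <- function(scn, params = list(), check = TRUE) {
  out <- resolve_derived(scn, params)
  out$demes$ne <- num_or_param(out$demes$ne, params)
  out$events$time <- num_or_param(out$events$time, params)
  out$events$prop <- num_or_param(out$events$prop, params)
  out$events$size <- num_or_param(out$events$size, params)
  out$events$duration <- num_or_param(out$events$duration, params)
  if (check) {
    msg <- scenario_check(out)
    if (!is.null(msg)) stop("invalid scenario '", scn$name, "': ", msg, call. = FALSE)
  }
  out
}

# NULL when valid, else a message. Works on instantiated scenarios.
scenario_check <- function(scn) {
  d <- scn$demes
  ev <- scn$events
  if (any(d$ne < 1)) {
    return("effective size < 1")
  }
  moves <- ev[ev$type %in% c("split", "admix"), ]
  if (anyDuplicated(moves$deme)) {
    return("a deme is removed (split/admix) more than once")
  }
  # exactly one root: demes never removed
  removed <- moves$deme
  roots <- setdiff(d$deme, removed)
  if (length(roots) != 1) {
    return(paste0(length(roots), " root demes remain (need exactly 1)"))
  }
  removal_time <- stats::setNames(rep(Inf, nrow(d)), d$deme)
  removal_time[moves$deme] <- moves$time
  for (k in seq_len(nrow(moves))) {
    pars <- c(moves$parent_a[k], moves$parent_b[k])
    pars <- pars[!is.na(pars)]
    if (any(removal_time[pars] <= moves$time[k])) {
      return(paste0(
        "deme '", moves$deme[k], "' moves at t=", moves$time[k],
        " into a parent already removed"
      ))
    }
  }
  adm <- ev[ev$type == "admix", ]
  if (nrow(adm) > 0 && (any(adm$prop <= 0) || any(adm$prop >= 1))) {
    return("admixture proportion outside (0, 1)")
  }
  bns <- ev[ev$type == "bottleneck", ]
  if (nrow(bns) > 0) {
    if (any(bns$size < 1) || any(bns$duration <= 0) || any(bns$time < 0)) {
      return("bottleneck with size < 1, duration <= 0 or negative start")
    }
    if (any(bns$time + bns$duration > removal_time[bns$deme] + 1e-9)) {
      return("bottleneck extends past the deme's removal time")
    }
  }
  if (any(ev$time < 0)) {
    return("negative event time")
  }
  NULL
}

#' Default priors for a scenario's free parameters
#'
#' Parameter-name conventions drive the defaults: names starting with `N`
#' get log-uniform effective sizes on `[10, 1e5]` (`Nb`/bottleneck sizes
#' log-uniform on `[2, 1e3]`), names starting with `t` uniform times on
#' `[1, 500]` generations (a recent-introduction window), `db` uniform
#' bottleneck durations on `[1, 50]`, `r` uniform admixture proportions on
#' `[0.1, 0.9]`, and `mu` log-uniform on `[1e-4, 1e-3]` per generation.
#' These are package defaults, fully overridable.
#'
#' @param scn An `ssr_scenario`.
#' @return A tibble `param`, `dist` (`"unif"`/`"logunif"`), `lo`, `hi`.
#' @export
default_priors <- function(scn) {
  p <- scenario_params(scn)
  row <- function(param) {
    if (param == "mu") {
      return(c("logunif", 1e-4, 1e-3))
    }
    if (grepl("^Nb", param)) {
      return(c("logunif", 2, 1e3))
    }
    if (grepl("^N", param)) {
      return(c("logunif", 10, 1e5))
    }
    if (grepl("^db", param)) {
      return(c("unif", 1, 50))
    }
    if (grepl("^t", param)) {
      return(c("unif", 1, 500))
    }
    if (grepl("^r", param)) {
      return(c("unif", 0.1, 0.9))
    }
    c("unif", 0, 1)
  }
  m <- t(vapply(p, row, character(3)))
  tibble::tibble(
    param = p, dist = m[, 1],
    lo = as.numeric(m[, 2]), hi = as.numeric(m[, 3])
  )
}

#' Draw scenario parameters from priors
#'
#' iid draws from the per-parameter priors, rejecting draws that violate the
#' scenario's event-order invariants (up to `max_tries` redraws, then an
#' error).
#'
#' @param scn An `ssr_scenario`.
#' @param priors Prior tibble as from [default_priors()].
#' @param max_tries Redraw cap for event-order rejection.
#' @return Named numeric vector of parameter values (a valid draw).
#' @export
draw_scenario_params <- function(scn, priors = default_priors(scn),
                                 max_tries = 1000) {
  for (k in seq_len(max_tries)) {
    vals <- mapply(function(dist, lo, hi) {
      if (dist == "logunif") {
        exp(stats::runif(1, log(lo), log(hi)))
      } else {
        stats::runif(1, lo, hi)
      }
    }, priors$dist, priors$lo, priors$hi)
    names(vals) <- priors$param
    ok <- tryCatch(
      {
        instantiate_scenario(scn, as.list(vals))
        TRUE
      },
      error = function(e) FALSE
    )
    if (ok) {
      return(vals)
    }
  }
  stop("could not draw event-order-consistent parameters after ", max_tries,
    " tries for scenario '", scn$name, "'",
    call. = FALSE
  )
}

# -- built-in catalog ---------------------------------------------------------

galapagos_demes <- function(origin = "Mainland", origin_sample = 0L) {
  tibble::tibble(
    deme = c(origin, "SantaCruz", "SanCristobal", "Isabela", "Floreana"),
    ne = c("N1", "N2", "N3", "N4", "N5"),
    sample = c(origin_sample, 10L, 10L, 10L, 10L)
  )
}

intro_events <- function(chains) {
  # chains: list of c(child, parent, t_name, nb_name, db_name)
  ev <- lapply(chains, function(ch) {
    tibble::tibble(
      type = c("split", "bottleneck"),
      time = c(ch[3], paste0(ch[3], "-", ch[5])),
      deme = ch[1], parent_a = c(ch[2], NA),
      parent_b = NA, prop = NA,
      size = c(NA, ch[4]), duration = c(NA, ch[5])
    )
  })
  dplyr::bind_rows(ev)
}

# bottleneck start times are "t - db"; resolve the arithmetic at
# instantiation by rewriting them as derived expressions
resolve_derived <- function(scn, params) {
  ev <- scn$events
  der <- grepl("-", as.character(ev$time), fixed = TRUE) &
    is.na(suppressWarnings(as.numeric(ev$time)))
  if (any(der)) {
    parts <- strsplit(as.character(ev$time[der]), "-", fixed = TRUE)
    vals <- vapply(parts, function(p) {
      num_or_param(p[1], params) - num_or_param(p[2], params)
    }, 1.0)
    ev$time[der] <- as.character(pmax(vals, 0))
  }
  scn$events <- ev
  scn
}

#' Built-in invasion scenario catalog
#'
#' Returns the scenario set for one of three analysis stages of an
#' archipelago invasion, each containing the published best-supported
#' topology plus contrasting alternatives (serial stepping-stone and
#' independent-introduction topologies):
#' \describe{
#'   \item{stage 1}{only island samples; the unsampled mainland origin has
#'     unknown size. Winner: mainland to Floreana and Santa Cruz, Floreana
#'     to San Cristobal, San Cristobal to Isabela.}
#'   \item{stage 2}{mainland samples included as the origin. Winner: two
#'     independent mainland introductions (to Santa Cruz and San Cristobal),
#'     then San Cristobal to Isabela and Santa Cruz to Floreana.}
#'   \item{stage 3}{coastal-region samples as the origin. Winner: Coast to
#'     San Cristobal, then San Cristobal to the other three islands.}
#' }
#' Every introduction is followed (forward in time) by a founder bottleneck.
#' User-defined scenario sets of any size can be supplied through
#' [read_scenarios()].
#'
#' @param stage 1, 2 or 3.
#' @return A named list of `ssr_scenario` templates; the published topology
#'   carries the attribute `published = TRUE`.
#' @export
load_scenarios_stage <- function(stage) {
  if (!stage %in% 1:3) stop("unknown stage: ", stage, call. = FALSE)
  origin_sample <- if (stage == 1) 0L else 20L
  origin <- if (stage == 3) "Coast" else "Mainland"
  demes <- galapagos_demes(origin, origin_sample)
  mk <- function(name, chains, published = FALSE) {
    s <- scenario(name, demes, intro_events(chains))
    attr(s, "published") <- published
    s
  }
  # time ordering: t4 > t3 > t2 > t1 ensures children split before parents
  if (stage == 1) {
    out <- list(
      winner_floreana_first = mk("winner_floreana_first", list(
        c("Floreana", origin, "t4", "Nb5", "db4"),
        c("SantaCruz", origin, "t3", "Nb2", "db3"),
        c("SanCristobal", "Floreana", "t2", "Nb3", "db2"),
        c("Isabela", "SanCristobal", "t1", "Nb4", "db1")
      ), published = TRUE),
      serial_chain = mk("serial_chain", list(
        c("SantaCruz", origin, "t4", "Nb2", "db4"),
        c("SanCristobal", "SantaCruz", "t3", "Nb3", "db3"),
        c("Isabela", "SanCristobal", "t2", "Nb4", "db2"),
        c("Floreana", "Isabela", "t1", "Nb5", "db1")
      )),
      all_independent = mk("all_independent", list(
        c("SantaCruz", origin, "t4", "Nb2", "db4"),
        c("SanCristobal", origin, "t3", "Nb3", "db3"),
        c("Isabela", origin, "t2", "Nb4", "db2"),
        c("Floreana", origin, "t1", "Nb5", "db1")
      ))
    )
  } else if (stage == 2) {
    out <- list(
      winner_two_mainland_intros = mk("winner_two_mainland_intros", list(
        c("SantaCruz", origin, "t4", "Nb2", "db4"),
        c("SanCristobal", origin, "t3", "Nb3", "db3"),
        c("Isabela", "SanCristobal", "t2", "Nb4", "db2"),
        c("Floreana", "SantaCruz", "t1", "Nb5", "db1")
      ), published = TRUE),
      floreana_first = mk("floreana_first", list(
        c("Floreana", origin, "t4", "Nb5", "db4"),
        c("SantaCruz", origin, "t3", "Nb2", "db3"),
        c("SanCristobal", "Floreana", "t2", "Nb3", "db2"),
        c("Isabela", "SanCristobal", "t1", "Nb4", "db1")
      )),
      serial_chain = mk("serial_chain", list(
        c("SantaCruz", origin, "t4", "Nb2", "db4"),
        c("SanCristobal", "SantaCruz", "t3", "Nb3", "db3"),
        c("Isabela", "SanCristobal", "t2", "Nb4", "db2"),
        c("Floreana", "Isabela", "t1", "Nb5", "db1")
      ))
    )
  } else {
    out <- list(
      winner_sancristobal_hub = mk("winner_sancristobal_hub", list(
        c("SanCristobal", origin, "t4", "Nb3", "db4"),
        c("SantaCruz", "SanCristobal", "t3", "Nb2", "db3"),
        c("Isabela", "SanCristobal", "t2", "Nb4", "db2"),
        c("Floreana", "SanCristobal", "t1", "Nb5", "db1")
      ), published = TRUE),
      santacruz_hub = mk("santacruz_hub", list(
        c("SantaCruz", origin, "t4", "Nb2", "db4"),
        c("SanCristobal", "SantaCruz", "t3", "Nb3", "db3"),
        c("Isabela", "SantaCruz", "t2", "Nb4", "db2"),
        c("Floreana", "SantaCruz", "t1", "Nb5", "db1")
      )),
      all_independent = mk("all_independent", list(
        c("SantaCruz", origin, "t4", "Nb2", "db4"),
        c("SanCristobal", origin, "t3", "Nb3", "db3"),
        c("Isabela", origin, "t2", "Nb4", "db2"),
        c("Floreana", origin, "t1", "Nb5", "db1")
      ))
    )
  }
  out
}

#' The three published invasion topologies in one comparable frame
#'
#' The best-supported topology of each catalog stage (Floreana-first,
#' two-independent-mainland-introductions, San-Cristobal-hub), all with the
#' same demes and the same sampling scheme so they can compete in a single
#' reference table — the setting for scenario-recovery experiments.
#'
#' @param origin_sampled Sample the origin deme (20 individuals) or leave it
#'   as an unsampled ghost.
#' @return Named list of three `ssr_scenario` templates.
#' @export
invasion_topologies <- function(origin_sampled = FALSE) {
  demes <- galapagos_demes("Mainland", if (origin_sampled) 20L else 0L)
  mk <- function(name, chains) {
    scenario(name, demes, intro_events(chains))
  }
  list(
    floreana_first = mk("floreana_first", list(
      c("Floreana", "Mainland", "t4", "Nb5", "db4"),
      c("SantaCruz", "Mainland", "t3", "Nb2", "db3"),
      c("SanCristobal", "Floreana", "t2", "Nb3", "db2"),
      c("Isabela", "SanCristobal", "t1", "Nb4", "db1")
    )),
    two_mainland_intros = mk("two_mainland_intros", list(
      c("SantaCruz", "Mainland", "t4", "Nb2", "db4"),
      c("SanCristobal", "Mainland", "t3", "Nb3", "db3"),
      c("Isabela", "SanCristobal", "t2", "Nb4", "db2"),
      c("Floreana", "SantaCruz", "t1", "Nb5", "db1")
    )),
    sancristobal_hub = mk("sancristobal_hub", list(
      c("SanCristobal", "Mainland", "t4", "Nb3", "db4"),
      c("SantaCruz", "SanCristobal", "t3", "Nb2", "db3"),
      c("Isabela", "SanCristobal", "t2", "Nb4", "db2"),
      c("Floreana", "SanCristobal", "t1", "Nb5", "db1")
    ))
  )
}

# -- plain-text scenario format ----------------------------------------------

#' Read / write scenario files
#'
#' A line-based plain-text format, one or more scenarios per file:
#' \preformatted{
#' scenario <name>
#' deme <name> <ne> [sample=<n>]
#' split <time> <child> <parent>
#' admix <time> <child> <parentA> <parentB> <prop>
#' bottleneck <deme> <start> <duration> <size>
#' }
#' Numeric fields may be parameter names; blank lines and `#` comments are
#' ignored.
#'
#' @param path File path.
#' @param scenarios A list of `ssr_scenario` for writing.
#' @return `read_scenarios()`: a named list of `ssr_scenario`.
#' @export
read_scenarios <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur_name <- NULL
  demes <- events <- NULL
  flush <- function() {
    if (!is.null(cur_name)) {
      out[[cur_name]] <<- scenario(cur_name, dplyr::bind_rows(demes),
        events = if (length(events) > 0) {
          dplyr::bind_rows(events)
        } else {
          tibble::tibble(
            type = character(), time = character(), deme = character(),
            parent_a = character()
          )
        }
      )
    }
  }
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    kw <- tok[1]
    if (kw == "scenario") {
      flush()
      cur_name <- tok[2]
      demes <- list()
      events <- list()
    } else if (kw == "deme") {
      samp <- 0L
      sv <- grep("^sample=", tok, value = TRUE)
      if (length(sv) > 0) samp <- as.integer(sub("^sample=", "", sv[1]))
      demes[[length(demes) + 1]] <- tibble::tibble(
        deme = tok[2], ne = tok[3], sample = samp
      )
    } else if (kw == "split") {
      events[[length(events) + 1]] <- tibble::tibble(
        type = "split", time = tok[2], deme = tok[3], parent_a = tok[4]
      )
    } else if (kw == "admix") {
      events[[length(events) + 1]] <- tibble::tibble(
        type = "admix", time = tok[2], deme = tok[3], parent_a = tok[4],
        parent_b = tok[5], prop = tok[6]
      )
    } else if (kw == "bottleneck") {
      events[[length(events) + 1]] <- tibble::tibble(
        type = "bottleneck", time = tok[3], deme = tok[2],
        parent_a = NA_character_, duration = tok[4], size = tok[5]
      )
    } else {
      stop("scenario file parse error: unknown keyword '", kw, "'", call. = FALSE)
    }
  }
  flush()
  out
}

#' @rdname read_scenarios
#' @export
write_scenarios <- function(scenarios, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in scenarios) {
    writeLines(paste("scenario", s$name), con)
    for (i in seq_len(nrow(s$demes))) {
      writeLines(paste0(
        "deme ", s$demes$deme[i], " ", s$demes$ne[i],
        " sample=", s$demes$sample[i]
      ), con)
    }
    for (i in seq_len(nrow(s$events))) {
      e <- s$events[i, ]
      line <- switch(e$type,
        split = paste("split", e$time, e$deme, e$parent_a),
        admix = paste("admix", e$time, e$deme, e$parent_a, e$parent_b, e$prop),
        bottleneck = paste("bottleneck", e$deme, e$time, e$duration, e$size)
      )
      writeLines(line, con)
    }
    writeLines("", con)
  }
  invisible(path)
}
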