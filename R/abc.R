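#' Build an ABC reference table
#'
#' For each scenario: iid prior draws, coalescent simulation, summary
#' statistics. All scenarios must sample the same demes so the statistic
#' schema is fixed across rows.
#'
#' @param scenarios Named list of `ssr_scenario` templates.
#' @param n_sims_per_scenario Simulations per scenario.
#' @param priors Optional named list (by scenario name) of prior tibbles;
#'   defaults to [default_priors()] per scenario.
#' @param n_loci Loci per simulated dataset.
#' @param seed Optional integer seed.
#' @return A tibble: `scenario`, one column per parameter (NA where a
#'   parameter does not belong to a row's scenario), and the summary-stat
#'   columns (attribute `stat_names`).
#' @export
build_reference_table <- function(scenarios, n_sims_per_scenario,
                                  priors = NULL, n_loci = 9, seed = NULL) {
  if (length(scenarios) < 2) stop("need >= 2 scenarios", call. = FALSE)
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, function(s) s$name, "")
  }
  if (!is.null(seed)) set.seed(seed)
  blocks <- vector("list", length(scenarios))
  stat_names <- NULL
  all_params <- character(0)
  for (nm in names(scenarios)) {
    all_params <- union(all_params, unique(c(
      default_priors(scenarios[[nm]])$param,
      priors[[nm]]$param
    )))
  }
  mu_loc <- match("mu", all_params)
  for (b in seq_along(scenarios)) {
    nm <- names(scenarios)[b]
    tpl <- compile_template(scenarios[[nm]])
    pr <- priors[[nm]] %||% default_priors(scenarios[[nm]])
    pm <- matrix(NA_real_, n_sims_per_scenario, length(all_params),
      dimnames = list(NULL, all_params)
    )
    sm <- NULL
    for (s in seq_len(n_sims_per_scenario)) {
      draw <- tpl_draw(tpl, pr)
      sim <- tpl_simulate(tpl, draw$resolved, n_loci, draw$params[["mu"]])
      st <- tpl_stats(tpl, sim)
      if (is.null(sm)) {
        if (is.null(stat_names)) {
          stat_names <- names(st)
        } else if (!identical(names(st), stat_names)) {
          stop("scenario '", nm, "' produces a different statistic schema",
            call. = FALSE
          )
        }
        sm <- matrix(NA_real_, n_sims_per_scenario, length(st),
          dimnames = list(NULL, stat_names)
        )
      }
      pm[s, names(draw$params)] <- draw$params
      sm[s, ] <- st
    }
    blocks[[b]] <- dplyr::bind_cols(
      tibble::tibble(scenario = nm),
      tibble::as_tibble(pm), tibble::as_tibble(sm)
    )
  }
  out <- dplyr::bind_rows(blocks)
  attr(out, "stat_names") <- stat_names
  out
}

# robust per-statistic scales from the reference table (MAD, falling back to
# SD, dropping zero-scale statistics)
stat_scales <- function(stats_mat, robust = TRUE) {
  sc <- apply(stats_mat, 2, if (robust) stats::mad else stats::sd)
  zero <- sc <= 0
  if (any(zero)) sc[zero] <- apply(stats_mat[, zero, drop = FALSE], 2, stats::sd)
  sc
}

abc_accept <- function(table, observed, n_closest, robust = TRUE) {
  stat_names <- attr(table, "stat_names") %||%
    intersect(names(observed), names(table))
  sm <- as.matrix(table[, stat_names, drop = FALSE])
  obs <- observed[stat_names]
  sc <- stat_scales(sm, robust)
  keep <- sc > 0
  z <- sweep(sm[, keep, drop = FALSE], 2, sc[keep], "/")
  zo <- obs[keep] / sc[keep]
  dist <- sqrt(rowSums(sweep(z, 2, zo, "-")^2))
  ord <- order(dist)
  idx <- ord[seq_len(min(n_closest, length(ord)))]
  dmax <- max(dist[idx])
  w <- if (dmax > 0) 1 - (dist[idx] / dmax)^2 else rep(1, length(idx))
  w[w <= 0] <- min(w[w > 0], 1e-6)
  list(
    idx = idx, weights = w, dist = dist,
    diffs = sweep(z[idx, , drop = FALSE], 2, zo, "-"),
    stat_names = stat_names[keep]
  )
}

#' Scenario posterior probabilities
#'
#' Standardises the reference-table statistics (median absolute deviation by
#' default), ranks rows by Euclidean distance to the observed vector, keeps
#' the `n_closest` rows, and estimates each scenario's posterior either as
#' its frequency among them (`rejection`) or by weighted multinomial
#' logistic regression of the scenario indicator on the statistic
#' differences, evaluated at zero difference (`logistic`, the default).
#'
#' @param table Reference table from [build_reference_table()].
#' @param observed Named statistic vector ([summary_stats()] of the data).
#' @param n_closest Accepted rows; default 1% of the table (min 50).
#' @param method `"logistic"` or `"rejection"`.
#' @return A tibble `scenario`, `posterior`, `se` (binomial, rejection
#'   only), `n_accepted`, `method`; posteriors sum to 1. Scenarios absent
#'   from the accepted set get probability 0 with a warning.
#' @export
scenario_posterior <- function(table, observed,
                               n_closest = max(50, round(0.01 * nrow(table))),
                               method = c("logistic", "rejection")) {
  method <- match.arg(method)
  if (n_closest > nrow(table)) {
    stop("n_closest exceeds the reference table size", call. = FALSE)
  }
  all_scn <- unique(table$scenario)
  acc <- abc_accept(table, observed, n_closest)
  scn_acc <- table$scenario[acc$idx]
  present <- unique(scn_acc)
  if (length(setdiff(all_scn, present)) > 0) {
    warning(
      "scenario(s) absent from the accepted set: ",
      paste(setdiff(all_scn, present), collapse = ", ")
    )
  }
  if (method == "rejection" || length(present) == 1) {
    w <- acc$weights
    p <- vapply(all_scn, function(s) sum(w[scn_acc == s]) / sum(w), 1.0)
    n_eff <- length(scn_acc)
    se <- sqrt(p * (1 - p) / n_eff)
    return(tibble::tibble(
      scenario = all_scn, posterior = unname(p), se = unname(se),
      n_accepted = n_eff,
      method = if (length(present) == 1 && method == "logistic") {
        "rejection (single scenario accepted)"
      } else {
        "rejection"
      }
    ))
  }
  df <- data.frame(scn = factor(scn_acc, levels = present), acc$diffs)
  fit <- nnet::multinom(scn ~ ., data = df, weights = acc$weights, trace = FALSE)
  zero <- as.data.frame(matrix(0, 1, ncol(acc$diffs)))
  names(zero) <- colnames(acc$diffs)
  pr <- stats::predict(fit, newdata = zero, type = "probs")
  if (length(present) == 2) pr <- c(1 - pr, pr) # binomial case returns P(level2)
  names(pr) <- present
  p <- stats::setNames(rep(0, length(all_scn)), all_scn)
  p[present] <- pr
  p <- p / sum(p)
  tibble::tibble(
    scenario = all_scn, posterior = unname(p[all_scn]), se = NA_real_,
    n_accepted = length(scn_acc), method = "logistic"
  )
}

# weighted quantiles (type-7-like linear interpolation on the weighted ECDF)
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2)$y
}

#' Posterior parameter estimates for one scenario
#'
#' Beaumont local-linear regression adjustment: among the accepted rows of
#' the chosen scenario, each parameter is regressed (Epanechnikov-weighted)
#' on the standardised statistic differences and adjusted to zero
#' difference. Positive parameters are adjusted on the log scale,
#' proportions on the logit scale. A singular regression falls back to the
#' unadjusted rejection posterior with a warning.
#'
#' @param table Reference table.
#' @param observed Named statistic vector.
#' @param scenario Scenario name.
#' @param n_closest Accepted rows among that scenario's simulations.
#' @return A tibble `param`, `q025`, `median`, `q975`, `n_accepted`,
#'   `adjusted`.
#' @export
estimate_parameters <- function(table, observed, scenario,
                                n_closest = max(50, round(0.01 * sum(table$scenario == scenario)))) {
  sub <- table[table$scenario == scenario, , drop = FALSE]
  if (nrow(sub) < n_closest) {
    stop("fewer scenario rows than n_closest", call. = FALSE)
  }
  attr(sub, "stat_names") <- attr(table, "stat_names")
  acc <- abc_accept(sub, observed, n_closest)
  stat_cols <- attr(table, "stat_names") %||% character(0)
  par_cols <- setdiff(names(sub), c("scenario", stat_cols))
  par_cols <- par_cols[vapply(
    par_cols,
    function(pc) !all(is.na(sub[[pc]])), TRUE
  )]
  X <- acc$diffs
  w <- acc$weights
  rows <- lapply(par_cols, function(pc) {
    y <- sub[[pc]][acc$idx]
    if (all(y > 0) && any(y != y[1])) {
      trans <- log
      inv <- exp
      if (all(y < 1)) { # proportion-like
        trans <- function(v) stats::qlogis(v)
        inv <- function(v) stats::plogis(v)
      }
    } else {
      trans <- identity
      inv <- identity
    }
    ty <- trans(y)
    adj <- TRUE
    ty_adj <- tryCatch(
      {
        fit <- stats::lm.wfit(cbind(1, X), ty, w)
        if (any(is.na(fit$coefficients))) stop("singular")
        ty - X %*% fit$coefficients[-1]
      },
      error = function(e) {
        warning("singular local-linear regression for '", pc,
          "'; using unadjusted rejection posterior",
          call. = FALSE
        )
        adj <<- FALSE
        ty
      }
    )
    q <- weighted_quantile(inv(as.vector(ty_adj)), w, c(0.025, 0.5, 0.975))
    tibble::tibble(
      param = pc, q025 = q[1], median = q[2], q975 = q[3],
      n_accepted = length(y), adjusted = adj
    )
  })
  dplyr::bind_rows(rows)
}

#' Posterior-predictive model checking
#'
#' PCA of the reference-table statistics with the observed vector and
#' posterior-predictive simulations projected into it, plus a per-statistic
#' two-sided tail probability of the observed value among the predictions.
#'
#' @param table Reference table.
#' @param observed Named statistic vector.
#' @param scenario The fitted scenario (an `ssr_scenario` or its name, in
#'   which case `scenarios` must contain it).
#' @param scenarios Named scenario list (templates), needed to re-simulate.
#' @param n_closest Accepted rows defining the posterior.
#' @param n_pred Posterior-predictive simulations.
#' @param n_loci Loci per simulated dataset.
#' @param seed Optional integer seed.
#' @return A list: `pca` (tibble `type` in reference/observed/predictive +
#'   coordinates), `tail` (tibble `stat`, `tail_prob`), `prop_var`.
#' @export
model_check <- function(table, observed, scenario, scenarios = NULL,
                        n_closest = max(50, round(0.01 * nrow(table))),
                        n_pred = 100, n_loci = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scn <- if (inherits(scenario, "ssr_scenario")) scenario else scenarios[[scenario]]
  nm <- scn$name
  sub <- table[table$scenario == nm, , drop = FALSE]
  attr(sub, "stat_names") <- attr(table, "stat_names")
  acc <- abc_accept(sub, observed, min(n_closest, nrow(sub)))
  stat_cols <- attr(table, "stat_names")
  par_cols <- setdiff(names(sub), c("scenario", stat_cols))
  par_cols <- par_cols[vapply(par_cols, function(pc) !all(is.na(sub[[pc]])), TRUE)]
  draw_rows <- sample(acc$idx, n_pred, replace = TRUE, prob = acc$weights)
  pred <- matrix(NA_real_, n_pred, length(stat_cols),
    dimnames = list(NULL, stat_cols)
  )
  tpl <- compile_template(scn)
  for (k in seq_len(n_pred)) {
    pars <- as.numeric(sub[draw_rows[k], par_cols])
    names(pars) <- par_cols
    v <- tpl_resolve(tpl, pars)
    sim <- tpl_simulate(tpl, v, n_loci, pars[["mu"]])
    pred[k, ] <- tpl_stats(tpl, sim)[stat_cols]
  }
  ref <- as.matrix(sub[, stat_cols, drop = FALSE])
  keep <- apply(ref, 2, stats::sd) > 0
  pr <- stats::prcomp(ref[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k_axes <- min(2, ncol(pr$x))
  proj <- function(m, type) {
    sc <- stats::predict(pr, newdata = as.data.frame(m[, keep, drop = FALSE]))
    tibble::tibble(type = type, as.data.frame(sc[, seq_len(k_axes), drop = FALSE]))
  }
  pca <- dplyr::bind_rows(
    proj(ref, "reference"),
    proj(matrix(observed[stat_cols],
      nrow = 1,
      dimnames = list(NULL, stat_cols)
    ), "observed"),
    proj(pred, "predictive")
  )
  tail_probs <- vapply(stat_cols, function(s) {
    F <- mean(pred[, s] <= observed[[s]])
    min(1, 2 * min(F, 1 - F))
  }, 1.0)
  list(
    pca = pca,
    tail = tibble::tibble(stat = stat_cols, tail_prob = unname(tail_probs)),
    prop_var = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k_axes)]
  )
}

#' Confidence in scenario choice: type I and type II error rates
#'
#' Simulates pseudo-observed datasets under every scenario (prior-drawn
#' parameters), classifies each with [scenario_posterior()] against the
#' reference table, and reports per focal scenario its type-I error (its
#' own pseudo-datasets not assigned to it) and the mean type-II error with
#' range (other scenarios' pseudo-datasets assigned to it).
#'
#' @param scenarios Named scenario list.
#' @param table Reference table.
#' @param n_pseudo_per_scenario Pseudo-observed datasets per scenario
#'   (< 10 triggers an instability warning).
#' @param priors Optional named list of prior tibbles.
#' @param n_closest,method Passed to [scenario_posterior()].
#' @param n_loci Loci per pseudo-dataset.
#' @param seed Optional integer seed.
#' @return A tibble `scenario`, `type1`, `type2_mean`, `type2_min`,
#'   `type2_max`, `n_pseudo`, plus a formatted `type2_label` like
#'   `"0.08 [0.03-0.16]"`.
#' @export
confidence_errors <- function(scenarios, table, n_pseudo_per_scenario = 50,
                              priors = NULL,
                              n_closest = max(50, round(0.01 * nrow(table))),
                              method = "rejection", n_loci = 9, seed = NULL) {
  if (n_pseudo_per_scenario < 10) {
    warning("n_pseudo_per_scenario < 10: error estimates will be unstable")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, function(s) s$name, "")
  }
  nms <- names(scenarios)
  assigned <- matrix(0L, length(nms), length(nms), dimnames = list(nms, nms))
  for (truth in nms) {
    tpl <- compile_template(scenarios[[truth]])
    pr <- priors[[truth]] %||% default_priors(scenarios[[truth]])
    for (k in seq_len(n_pseudo_per_scenario)) {
      draw <- tpl_draw(tpl, pr)
      sim <- tpl_simulate(tpl, draw$resolved, n_loci, draw$params[["mu"]])
      post <- suppressWarnings(scenario_posterior(
        table, tpl_stats(tpl, sim),
        n_closest = n_closest, method = method
      ))
      best <- post$scenario[which.max(post$posterior)]
      assigned[truth, best] <- assigned[truth, best] + 1L
    }
  }
  rows <- lapply(nms, function(f) {
    type1 <- 1 - assigned[f, f] / n_pseudo_per_scenario
    others <- setdiff(nms, f)
    t2 <- assigned[others, f] / n_pseudo_per_scenario
    tibble::tibble(
      scenario = f, type1 = type1, type2_mean = mean(t2),
      type2_min = min(t2), type2_max = max(t2),
      n_pseudo = n_pseudo_per_scenario,
      type2_label = sprintf(
        "%.2f [%.2f-%.2f]", mean(t2), min(t2), max(t2)
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "assignment_matrix") <- assigned
  out
}
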