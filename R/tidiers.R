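#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an AMOVA fit
#'
#' @param x An `ssr_amova` from [amova()].
#' @param ... Unused.
#' @return One row per variance stratum: `term`, `df`, `SS`, `sigma2`
#'   (truncated at 0), `sigma2_raw`, `percent`.
#' @export
tidy.ssr_amova <- function(x, ...) {
  tibble::tibble(
    term = c("among populations", "within populations"),
    df = unname(x$df),
    SS = unname(x$ss[c("among", "within")]),
    sigma2 = unname(x$sigma),
    sigma2_raw = unname(x$sigma_raw),
    percent = unname(x$percent)
  )
}

#' @rdname tidy.ssr_amova
#' @export
glance.ssr_amova <- function(x, ...) {
  tibble::tibble(
    phi_st = x$phi_st, p_value = x$p_value,
    n_permutations = x$n_permutations
  )
}

#' Tidy a cluster solution
#'
#' @param x An `ssr_clusters` from [find_clusters()].
#' @param ... Unused.
#' @return The per-individual assignments tibble.
#' @export
tidy.ssr_clusters <- function(x, ...) x$assignments

#' @rdname tidy.ssr_clusters
#' @export
glance.ssr_clusters <- function(x, ...) {
  tibble::tibble(
    K = x$K, n_pcs = x$n_pcs,
    bic_min = min(x$bic$bic), max_K = max(x$bic$K)
  )
}

#' Tidy a DAPC fit
#'
#' @param x An `ssr_dapc` from [dapc_fit()].
#' @param ... Unused.
#' @return Per-individual discriminant coordinates with group, assigned
#'   cluster and maximum posterior membership.
#' @export
tidy.ssr_dapc <- function(x, ...) {
  out <- x$coords
  out$assigned <- x$assigned
  out$posterior_max <- apply(x$posterior, 1, max)
  out
}

#' @rdname tidy.ssr_dapc
#' @export
glance.ssr_dapc <- function(x, ...) {
  tibble::tibble(
    K = x$K, n_pcs = x$n_pcs, n_axes = length(x$prop_var),
    var_axis1 = x$prop_var[1],
    reassignment = mean(x$assigned == x$coords$group)
  )
}

#' Tidy a migration network
#'
#' @param x An `ssr_migration` from [relative_migration()].
#' @param ... Unused.
#' @return One row per directed pair: `from`, `to`, `migration`, plus
#'   bootstrap 2.5/97.5% quantiles when available.
#' @export
tidy.ssr_migration <- function(x, ...) {
  pops <- rownames(x$m)
  idx <- which(row(x$m) != col(x$m), arr.ind = TRUE)
  out <- tibble::tibble(
    from = pops[idx[, 1]], to = pops[idx[, 2]],
    migration = x$m[idx]
  )
  if (!is.null(x$boot)) {
    q <- apply(x$boot, c(1, 2), stats::quantile,
      probs = c(0.025, 0.975),
      na.rm = TRUE
    )
    out$lo <- q[1, , ][idx]
    out$hi <- q[2, , ][idx]
  }
  out
}
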