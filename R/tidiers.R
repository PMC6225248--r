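#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PMF profile into its per-bin table
#'
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @return A tibble with `x` (nm), `G` (kJ/mol) and `sigma`.
#' @export
tidy.pmf_profile <- function(x, ...) as_tibble(x$profile)

#' One-row summary of a PMF fit
#'
#' @inheritParams tidy.pmf_profile
#' @return A tibble with `dg_binding`, `dg_sigma` (NA without bootstrap),
#'   `n_windows`, `n_bins`, `temperature`, `iterations`, `converged`.
#' @export
glance.pmf_profile <- function(x, ...) {
  tibble(dg_binding = x$dg_binding,
         dg_sigma = x$dg_sigma %||% NA_real_,
         n_windows = x$n_windows, n_bins = nrow(x$profile),
         temperature = x$temperature,
         iterations = x$iterations, converged = x$converged)
}

#' Tidy a cluster assignment into its per-cluster table
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return A tibble with `cluster`, `n`, `population`, `center_frame`.
#' @export
tidy.cluster_assignment <- function(x, ...) as_tibble(x$clusters)

#' One-row summary of a clustering
#'
#' @inheritParams tidy.cluster_assignment
#' @return A tibble with `n_frames`, `n_clusters`, `cutoff`, `p1`.
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(n_frames = nrow(x$assignment), n_clusters = nrow(x$clusters),
         cutoff = x$cutoff, p1 = x$clusters$population[1])
}
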