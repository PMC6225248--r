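#' Ensemble-average an energy table over a cluster's frames
#'
#' Computes the arithmetic mean of every (moiety, term) column over the
#' frames selected by `frames` — typically the members of one conformational
#' cluster, so that each binding estimate refers to a single conformation's
#' ensemble. Per-term uncertainties come from block averaging
#' ([block_average_sigma()]) over the masked series.
#'
#' @param table An `energy_series` tibble (see [energy_table()]).
#' @param frames Integer frame numbers to keep (e.g. from
#'   [cluster_frames()]); NULL keeps all frames.
#' @return An `energy_decomposition` tibble: `moiety`, `term`, `mean`,
#'   `sigma` (kJ/mol) and `n_frames`.
#' @export
ensemble_average <- function(table, frames = NULL) {
  stopifnot(inherits(table, "energy_series"))
  tab <- as_tibble(table)
  if (!is.null(frames)) {
    tab <- filter(tab, .data$frame %in% frames)
    if (!nrow(tab)) abort("frame mask selects no frames.")
  }
  out <- tab |>
    group_by(.data$moiety, .data$term) |>
    summarise(
      mean = mean(.data$value),
      sigma = if (n() >= 16) block_average_sigma(.data$value)$sigma else
        if (n() < 2 || sd(.data$value) == 0) 0 else sd(.data$value) / sqrt(n()),
      n_frames = n(), .groups = "drop")
  class(out) <- c("energy_decomposition", class(tibble()))
  out
}

#' Assemble an energy decomposition directly from term means
#'
#' Convenience constructor for hand-built decompositions (e.g. for checking
#' estimator arithmetic): one row per (moiety, term) with known means and
#' optional uncertainties.
#'
#' @param df Data frame with `moiety`, `term`, `mean` and optionally
#'   `sigma`, `n_frames`.
#' @return An `energy_decomposition` tibble.
#' @export
energy_decomposition <- function(df) {
  df <- as_tibble(df)
  need <- c("moiety", "term", "mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("decomposition lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!"sigma" %in% names(df)) df$sigma <- 0
  if (!"n_frames" %in% names(df)) df$n_frames <- NA_integer_
  badt <- setdiff(unique(df$term), .energy_terms)
  if (length(badt)) abort(paste0("unknown energy term(s): ", paste(badt, collapse = ", ")))
  badm <- setdiff(unique(df$moiety), .energy_moieties)
  if (length(badm)) abort(paste0("unknown moiety label(s): ", paste(badm, collapse = ", ")))
  if (!all(is.finite(df$mean))) abort("term means must be finite.")
  if (any(df$sigma < 0)) abort("term sigmas must be >= 0.")
  df <- df[, c("moiety", "term", "mean", "sigma", "n_frames")]
  class(df) <- c("energy_decomposition", class(tibble()))
  df
}

# look up one (term, moiety) mean / sigma; error names the missing symbol
.decomp_get <- function(decomp, term, moiety, what = c("mean", "sigma")) {
  what <- match.arg(what)
  hit <- decomp$term == term & decomp$moiety == moiety
  if (sum(hit) != 1)
    abort(sprintf("decomposition is missing the term V_%s(%s) required by this estimator.",
                  term, moiety))
  decomp[[what]][hit]
}

.decomp_has <- function(decomp, term, moiety) {
  sum(decomp$term == term & decomp$moiety == moiety) == 1
}
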