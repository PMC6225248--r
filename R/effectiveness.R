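# Effective aggregation-disruption free energy:
#   PP-PP + R-R -> 2 R-PP,  dG_eff = 2 dG_R-PP - dG_RR - dG_PP-PP.
# Negative dG_eff predicts that the pseudo-peptide dissociates the R-R
# dimer at 1:1 stoichiometry.

#' Effective aggregation-disruption free energy
#'
#' `dG_eff = 2 dG_R-PP - dG_RR - dG_PP-PP`, the free-energy change of
#' replacing an R homodimer and a pseudo-peptide homodimer with two R-PP
#' heterodimers. When uncertainties are supplied the result's sigma is the
#' quadrature `sqrt(4 s_rpp^2 + s_rr^2 + s_pppp^2)`.
#'
#' @param dg_rpp,dg_rr,dg_pppp Binding free energies, kJ/mol (heterodimer,
#'   R homodimer, PP homodimer).
#' @param sigma_rpp,sigma_rr,sigma_pppp Optional 1-sigma uncertainties.
#' @return kJ/mol; with sigmas supplied, a named list `value`, `sigma`.
#' @examples
#' delta_g_eff(-57, -53, -45)   # -16
#' @export
delta_g_eff <- function(dg_rpp, dg_rr, dg_pppp,
                        sigma_rpp = NULL, sigma_rr = NULL, sigma_pppp = NULL) {
  if (!all(is.finite(c(dg_rpp, dg_rr, dg_pppp))))
    abort("all three binding free energies must be finite.")
  v <- 2 * dg_rpp - dg_rr - dg_pppp
  if (is.null(sigma_rpp) && is.null(sigma_rr) && is.null(sigma_pppp)) return(v)
  s <- sqrt(4 * (sigma_rpp %||% 0)^2 + (sigma_rr %||% 0)^2 + (sigma_pppp %||% 0)^2)
  list(value = v, sigma = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate effectiveness records for a set of complexes
#'
#' Applies [delta_g_eff()] row-wise to a table of binding free energies and,
#' when a printed/reference `dg_eff_reported` column is present, flags rows
#' whose reported value disagrees with the recomputed arithmetic by more
#' than `flag_tol` — such discrepancies are reported, never silently
#' matched.
#'
#' @param df Data frame with columns `complex` (or `pp` + `edge`),
#'   `dg_rpp`, `dg_rr`, `dg_pppp`, optionally `sigma_*` and
#'   `dg_eff_reported` (kJ/mol).
#' @param flag_tol Tolerance (kJ/mol) for the discrepancy flag.
#' @return The input as a tibble with `dg_eff` (and `dg_eff_sigma` when
#'   sigmas are present), plus `discrepant` when a reported column exists.
#' @export
dgeff_table <- function(df, flag_tol = 0.5) {
  df <- as_tibble(df)
  need <- c("dg_rpp", "dg_rr", "dg_pppp")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("dgeff table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  df$dg_eff <- 2 * df$dg_rpp - df$dg_rr - df$dg_pppp
  if (all(c("sigma_rpp", "sigma_rr", "sigma_pppp") %in% names(df)))
    df$dg_eff_sigma <- sqrt(4 * df$sigma_rpp^2 + df$sigma_rr^2 + df$sigma_pppp^2)
  if ("dg_eff_reported" %in% names(df)) {
    df$discrepant <- abs(df$dg_eff - df$dg_eff_reported) > flag_tol
    if (any(df$discrepant)) {
      lab <- if ("complex" %in% names(df)) df$complex[df$discrepant]
             else which(df$discrepant)
      warn(paste0("reported dG_eff disagrees with 2 dG_R-PP - dG_RR - dG_PP-PP for: ",
                  paste(lab, collapse = ", "),
                  " (recomputed values are reported; the discrepancy is flagged)."))
    }
  }
  df
}

#' Rank pseudo-peptide candidates by predicted disruption effectiveness
#'
#' Sorts ascending by `dg_eff` (more negative = more effective at
#' disrupting beta-sheet formation); ties are broken by pseudo-peptide
#' name, then edge, so the order is a deterministic total order.
#'
#' @param records Data frame with `dg_eff` and identifying columns
#'   (`complex`, or `pp` and `edge`).
#' @return The records sorted, with a `rank` column prepended.
#' @export
rank_candidates <- function(records) {
  records <- as_tibble(records)
  if (!nrow(records)) abort("need at least one record to rank.")
  if (!"dg_eff" %in% names(records)) abort("records lack a `dg_eff` column.")
  key2 <- if ("pp" %in% names(records)) records$pp
          else if ("complex" %in% names(records)) records$complex
          else rep("", nrow(records))
  key3 <- if ("edge" %in% names(records)) records$edge else rep("", nrow(records))
  ord <- order(records$dg_eff, key2, key3)
  out <- records[ord, ]
  out <- mutate(out, rank = row_number())
  out[, c("rank", setdiff(names(out), "rank"))]
}
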