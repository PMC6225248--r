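#' Read a whitespace-delimited numeric table in the xvg dialect
#'
#' Lines beginning with `#` or `@` (comments and plotting directives) are
#' ignored; the remaining rows must be whitespace-delimited numbers with a
#' consistent column count.
#'
#' @param path File path.
#' @return A tibble of numeric columns named `V1`, `V2`, ...
#' @export
read_xvg_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) abort(paste0("no numeric rows in ", path))
  toks <- strsplit(trimws(lines[rows]), "\\s+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1)
    abort(sprintf("inconsistent column count at line %d of %s (%d vs %d).",
                  rows[which(ncols != ncols[1])[1]], path,
                  ncols[which(ncols != ncols[1])[1]], ncols[1]))
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad))
    abort(sprintf("non-numeric token at line %d of %s.", rows[bad[1]], path))
  m <- do.call(rbind, vals)
  colnames(m) <- paste0("V", seq_len(ncol(m)))
  as_tibble(m)
}

# Controlled vocabulary for per-frame energy tables ---------------------------

.energy_terms <- c("gas_es", "gas_vdw", "sol_es", "sol_vdw",
                   "int_es", "int_vdw", "pbsa")
.energy_moieties <- c("PP", "Abeta", "PP_complex", "Abeta_complex", "complex")

#' Assemble a long-form per-frame energy table
#'
#' Energy tables are long tibbles with columns `frame`, `time` (ns), `moiety`,
#' `term` and `value` (kJ/mol). `term` is one of `gas_es`, `gas_vdw`,
#' `sol_es`, `sol_vdw`, `int_es`, `int_vdw`, `pbsa`; `moiety` one of `PP`
#' and `Abeta` (individually equilibrated, unbound), `PP_complex` and
#' `Abeta_complex` (the starred moieties inside the complex), or `complex`
#' (the pair; interaction terms always carry this moiety).
#'
#' @param df Data frame with those columns (a missing `time` is filled from
#'   `frame`).
#' @return A validated `energy_series` tibble.
#' @export
energy_table <- function(df) {
  df <- as_tibble(df)
  need <- c("frame", "moiety", "term", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("energy table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!"time" %in% names(df)) df$time <- as.numeric(df$frame)
  badt <- setdiff(unique(df$term), .energy_terms)
  if (length(badt)) abort(paste0("unknown energy term(s): ", paste(badt, collapse = ", "),
                                 "; allowed: ", paste(.energy_terms, collapse = ", ")))
  badm <- setdiff(unique(df$moiety), .energy_moieties)
  if (length(badm)) abort(paste0("unknown moiety label(s): ", paste(badm, collapse = ", ")))
  if (!all(is.finite(df$value))) abort("energy values must be finite.")
  cnt <- dplyr::count(df, .data$moiety, .data$term)
  if (length(unique(cnt$n)) != 1)
    abort("all (moiety, term) columns must cover the same frames.")
  df <- df[, c("frame", "time", "moiety", "term", "value")]
  class(df) <- c("energy_series", class(tibble()))
  df
}

#' Generate a full synthetic energy table with known term means
#'
#' Convenience wrapper around [gen_energy_series()]: one AR(1) series per
#' (moiety, term) pair in `means`, sharing `sd`, `phi` and frame count.
#' Used to exercise the endpoint estimators against analytic expectations.
#'
#' @param means Data frame with columns `moiety`, `term`, `mean` (kJ/mol).
#' @param sd,phi,n_frames,seed Passed per series; seeds are offset per row
#'   so series are independent.
#' @return An `energy_series` tibble.
#' @export
gen_energy_table <- function(means, sd = 1, phi = 0, n_frames = 1000, seed = 1) {
  means <- as_tibble(means)
  rows <- lapply(seq_len(nrow(means)), function(i) {
    s <- gen_energy_series(mean = means$mean[i], sd = sd, phi = phi,
                           n_frames = n_frames, seed = seed + i)
    tibble(frame = s$frame, time = s$time,
           moiety = means$moiety[i], term = means$term[i], value = s$value)
  })
  energy_table(bind_rows(rows))
}
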