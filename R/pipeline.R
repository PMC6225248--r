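#' Run the full analysis pipeline from a configuration
#'
#' Executes the configured stages in order — umbrella-sampling WHAM (with
#' bootstrap errors) for each listed window set, LIE / Gas-PBSA estimates
#' for each energy table, and the effectiveness ranking when a dimer
#' binding-energy table is given — and writes every artifact (TSV tables,
#' a JSON machine report, a run log) to `out_dir`. The configuration and
#' seed are echoed into the report for provenance.
#'
#' @param config A YAML file path or an equivalent nested list with any of:
#'   * `wham`: list of entries with `meta` (window metadata TSV),
#'     `discard_time` (ps), `bin_width`, `n_boot`;
#'   * `lie`: list of entries with `energies` (long TSV with columns
#'     frame, moiety, term, value), `variant` ("S"/"D"/"DR"), optional
#'     `mask` (JSON cluster report + cluster id);
#'   * `dgeff`: a TSV with the [dgeff_table()] columns.
#' @param out_dir Output directory.
#' @param seed Integer seed used for every stochastic stage.
#' @return Invisibly, the report list.
#' @export
pipeline_run <- function(config, out_dir = ".", seed = 1) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("pmflie pipeline | seed %d | %s", seed, format(Sys.time(), "%Y-%m-%d"))
  report <- list(seed = seed, config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }

  if (!is.null(cfg$wham)) {
    report$wham <- list()
    for (entry in cfg$wham) {
      nm <- entry$name %||% basename(dirname(entry$meta))
      res <- stage(paste0("wham:", nm), {
        uw <- read_umbrella_windows(entry$meta)
        if (!is.null(entry$discard_time))
          uw <- equilibration_split(uw, entry$discard_time)
        bw <- entry$bin_width %||% 0.01
        pmf <- bayesian_bootstrap_errors(uw, n_boot = entry$n_boot %||% 100,
                                         seed = seed, bin_width = bw)
        readr::write_tsv(pmf$profile, file.path(out_dir, paste0("pmf_", nm, ".tsv")))
        list(dg_binding = pmf$dg_binding, dg_sigma = pmf$dg_sigma,
             n_windows = pmf$n_windows, iterations = pmf$iterations)
      })
      logf("wham %s: dG_binding = %.2f +/- %.2f kJ/mol", nm,
           res$dg_binding, res$dg_sigma)
      report$wham[[nm]] <- res
    }
  }

  if (!is.null(cfg$lie)) {
    rows <- list()
    for (entry in cfg$lie) {
      nm <- entry$name %||% basename(entry$energies)
      est <- stage(paste0("lie:", nm), {
        tab <- energy_table(readr::read_tsv(entry$energies, show_col_types = FALSE))
        frames <- NULL
        cl_id <- NA_integer_; pop <- NA_real_
        if (!is.null(entry$mask)) {
          mk <- jsonlite::read_json(entry$mask, simplifyVector = TRUE)
          cl_id <- entry$cluster %||% 1L
          frames <- mk$assignment$frame[mk$assignment$cluster == cl_id]
          pop <- mk$clusters$population[mk$clusters$cluster == cl_id]
        }
        dec <- ensemble_average(tab, frames)
        variant <- entry$variant %||% "D"
        fn <- switch(variant, S = lie_s_dg, D = lie_d_dg, DR = lie_dr_dg,
                     PBSA = gas_pbsa_dg)
        if (variant == "PBSA") fn(dec, cluster = cl_id, population = pop)
        else fn(dec, lie_params(variant), cluster = cl_id, population = pop)
      })
      est$name <- nm
      logf("lie %s: %s dG = %.2f +/- %.2f kJ/mol", nm, est$method, est$dg, est$sigma)
      rows[[length(rows) + 1L]] <- est
    }
    lie_tab <- bind_rows(rows)
    readr::write_tsv(lie_tab, file.path(out_dir, "binding_estimates.tsv"))
    report$lie <- lie_tab
  }

  if (!is.null(cfg$dgeff)) {
    res <- stage("dgeff", {
      df <- readr::read_tsv(cfg$dgeff, show_col_types = FALSE)
      if (!all(c("dg_rpp", "dg_rr", "dg_pppp") %in% names(df))) {
        warn("dgeff stage skipped: table lacks homodimer binding energies.")
        NULL
      } else {
        out <- rank_candidates(dgeff_table(df))
        readr::write_tsv(out, file.path(out_dir, "effectiveness.tsv"))
        out
      }
    })
    if (!is.null(res)) {
      logf("dgeff: top candidate %s (dG_eff = %.1f kJ/mol)",
           res$complex[1] %||% res$pp[1], res$dg_eff[1])
      report$dgeff <- res
    }
  } else if (!is.null(cfg$lie) || !is.null(cfg$wham)) {
    logf("dgeff: no homodimer table configured; stage skipped.")
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Write a cluster assignment as a JSON report
#'
#' @param assignment A `cluster_assignment`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_cluster_json <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  jsonlite::write_json(
    list(cutoff = assignment$cutoff,
         clusters = assignment$clusters,
         assignment = assignment$assignment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
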