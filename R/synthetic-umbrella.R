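#' Generate harmonically biased umbrella-sampling windows
#'
#' Draws reaction-coordinate samples for a set of umbrella windows from a
#' known one-dimensional potential. Window `w` samples the biased Boltzmann
#' density proportional to `exp(-(U(x) + k/2 (x - c_w)^2) / kB T)`.
#' Sampling is by inverse-CDF lookup on a fine grid (independence sampling
#' rather than Markov-chain Monte Carlo), so the draws are exact up to grid
#' resolution and carry no equilibration transient.
#'
#' The defaults mirror a common umbrella-sampling protocol for peptide
#' dimer dissociation: harmonic force constant 1000 kJ/(mol nm^2), windows
#' 0.1 nm apart, 310 K.
#'
#' @param potential A [potential_spec()].
#' @param centers Numeric, bias centres in nm; all must lie inside the
#'   potential domain.
#' @param k Harmonic bias force constant, kJ/(mol nm^2); > 0.
#' @param n_per_window Samples per window; >= 1.
#' @param temperature Kelvin; > 0.
#' @param seed Integer seed; the same spec and seed reproduce the samples.
#' @param dt Time spacing between recorded samples, ps (metadata only).
#' @param n_grid Grid resolution for the inverse-CDF sampler.
#' @return An `umbrella_windows` tibble with one row per window and columns
#'   `window`, `center` (nm), `k`, `temperature`, `samples` (list of numeric
#'   vectors, nm) and `times` (list, ps).
#' @examples
#' pot <- potential_spec("flat", domain = c(0.5, 1.5))
#' uw <- gen_umbrella_windows(pot, centers = 1.0, k = 1000,
#'                            n_per_window = 1000, seed = 1)
#' sd(uw$samples[[1]])  # ~ sqrt(kB * 310 / 1000) = 0.0508 nm
#' @export
gen_umbrella_windows <- function(potential, centers, k = 1000,
                                 n_per_window = 20000,
                                 temperature = 310, seed = 1,
                                 dt = 1, n_grid = 6000) {
  stopifnot(inherits(potential, "potential_spec"))
  if (!is.finite(k) || k <= 0) abort("bias force constant `k` must be > 0.")
  if (!is.finite(temperature) || temperature <= 0) abort("`temperature` must be > 0 K.")
  if (n_per_window < 1) abort("`n_per_window` must be >= 1.")
  dom <- potential$domain
  if (any(centers < dom[1] | centers > dom[2]))
    abort("all bias `centers` must lie inside the potential domain.")

  beta <- 1 / (kB * temperature)
  xg <- seq(dom[1], dom[2], length.out = n_grid)
  Ug <- potential$U(xg)
  if (!all(is.finite(Ug))) abort("potential evaluates to non-finite energies on the domain.")

  set.seed(as.integer(seed))
  out <- map(seq_along(centers), function(i) {
    w <- Ug + 0.5 * k * (xg - centers[i])^2
    logp <- -beta * (w - min(w))
    p <- exp(logp)
    # piecewise-linear CDF on the grid; inverse by interpolation
    cdf <- cumsum((p[-1] + p[-n_grid]) / 2 * diff(xg))
    cdf <- c(0, cdf) / cdf[n_grid - 1]
    u <- runif(n_per_window)
    approx(cdf, xg, xout = u, ties = "ordered")$y
  })

  structure(
    tibble(
      window = seq_along(centers),
      center = as.numeric(centers),
      k = k,
      temperature = temperature,
      samples = out,
      times = map(out, ~ seq_along(.x) * dt)
    ),
    class = c("umbrella_windows", class(tibble())))
}

#' Generate a stationary AR(1) energy-component series
#'
#' Emulates a per-frame force-field energy term as a Gaussian AR(1) process
#' with given marginal mean and standard deviation and lag-1 autocorrelation
#' `phi`. The innovation variance is scaled so the marginal (stationary)
#' standard deviation equals `sd` for every `phi`; the initial state is drawn
#' from the stationary distribution.
#'
#' @param mean Marginal mean, kJ/mol.
#' @param sd Marginal standard deviation, kJ/mol; >= 0.
#' @param phi Lag-1 autocorrelation; |phi| < 1.
#' @param n_frames Number of frames; > 0.
#' @param seed Integer seed.
#' @param dt Frame spacing in ns (metadata).
#' @return A tibble with columns `frame`, `time` (ns) and `value` (kJ/mol).
#' @examples
#' es <- gen_energy_series(mean = -100, sd = 5, phi = 0.8,
#'                         n_frames = 1000, seed = 7)
#' mean(es$value)
#' @export
gen_energy_series <- function(mean = 0, sd = 1, phi = 0, n_frames = 1000,
                              seed = 1, dt = 0.01) {
  if (!is.finite(sd) || sd < 0) abort("`sd` must be >= 0.")
  if (!is.finite(phi) || abs(phi) >= 1) abort("|phi| must be < 1 for stationarity.")
  if (n_frames < 1) abort("`n_frames` must be > 0.")
  set.seed(as.integer(seed))
  if (sd == 0) {
    v <- rep(mean, n_frames)
  } else {
    innov_sd <- sd * sqrt(1 - phi^2)
    z <- numeric(n_frames)
    z[1] <- rnorm(1, 0, sd)
    if (n_frames > 1) {
      eps <- rnorm(n_frames - 1, 0, innov_sd)
      for (t in 2:n_frames) z[t] <- phi * z[t - 1] + eps[t - 1]
    }
    v <- mean + z
  }
  tibble(frame = seq_len(n_frames), time = seq_len(n_frames) * dt, value = v)
}

#' Write umbrella windows to xvg-dialect files plus a metadata table
#'
#' One two-column file per window (time ps, coordinate nm) in the layout of
#' standard pull-code output, and a `windows.tsv` metadata table with columns
#' `file`, `center`, `k`, `temperature` — the same shape [read_umbrella_windows()]
#' consumes.
#'
#' @param windows An `umbrella_windows` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the metadata table.
#' @export
write_umbrella_windows <- function(windows, dir) {
  stopifnot(inherits(windows, "umbrella_windows"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%03d.xvg", windows$window)
  for (i in seq_len(nrow(windows))) {
    con <- file.path(dir, files[i])
    hdr <- c("# umbrella window reaction-coordinate samples",
             sprintf("@ subtitle \"center %.4f nm, k %.1f kJ/(mol nm^2)\"",
                     windows$center[i], windows$k[i]),
             "@ xaxis label \"Time (ps)\"",
             "@ yaxis label \"COM separation (nm)\"")
    dat <- sprintf("%.4f %.6f", windows$times[[i]], windows$samples[[i]])
    writeLines(c(hdr, dat), con)
  }
  meta <- tibble(file = files, center = windows$center, k = windows$k,
                 temperature = windows$temperature)
  meta_path <- file.path(dir, "windows.tsv")
  readr::write_tsv(meta, meta_path)
  invisible(meta_path)
}

#' Read umbrella windows from a metadata table and per-window sample files
#'
#' @param meta_path Path to a TSV with columns `file`, `center`, `k` and
#'   optionally `temperature`; `file` paths are resolved relative to the
#'   table's directory.
#' @param temperature Fallback temperature (K) when the table has no column.
#' @return An `umbrella_windows` tibble (see [gen_umbrella_windows()]).
#' @export
read_umbrella_windows <- function(meta_path, temperature = 310) {
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  if (!all(c("file", "center", "k") %in% names(meta)))
    abort("window metadata table needs columns `file`, `center`, `k`.")
  if (!"temperature" %in% names(meta)) meta$temperature <- temperature
  base <- dirname(meta_path)
  parsed <- map(meta$file, function(f) read_xvg_table(file.path(base, f)))
  structure(
    tibble(
      window = seq_len(nrow(meta)),
      center = meta$center, k = meta$k, temperature = meta$temperature,
      samples = map(parsed, ~ .x[[2]]),
      times = map(parsed, ~ .x[[1]])
    ),
    class = c("umbrella_windows", class(tibble())))
}
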