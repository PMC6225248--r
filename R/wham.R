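# WHAM reconstruction of the potential of mean force from umbrella windows.
#
# Unbiased probability per bin:
#   p(x_b) = sum_w n_w(b) / sum_w N_w exp[(f_w - U_w(x_b)) / kBT]
#   f_w    = -kBT ln sum_b p(x_b) exp[-U_w(x_b) / kBT]
# iterated to self-consistency; G(x) = -kBT ln p(x), minimum shifted to 0.

.wham_prepare <- function(windows, bin_width = 0.01, domain = NULL) {
  stopifnot(inherits(windows, "umbrella_windows"))
  if (!nrow(windows)) abort("need at least one umbrella window.")
  if (length(unique(windows$temperature)) != 1)
    abort("all windows must share one temperature (no multi-temperature WHAM).")
  if (any(windows$k <= 0)) abort("window force constants must be > 0.")
  if (any(lengths(windows$samples) == 0)) abort("every window needs samples.")
  if (is.null(domain)) domain <- range(unlist(windows$samples))
  if (diff(domain) < bin_width) domain <- mean(domain) + c(-0.5, 0.5) * bin_width
  edges <- seq(domain[1], domain[2] + bin_width * 1e-9, by = bin_width)
  if (tail(edges, 1) < domain[2]) edges <- c(edges, tail(edges, 1) + bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  B <- length(centers)
  W <- nrow(windows)
  bin_of <- lapply(windows$samples, function(s) {
    i <- findInterval(s, edges, rightmost.closed = TRUE, all.inside = TRUE)
    i
  })
  counts <- do.call(rbind, lapply(bin_of, function(i) tabulate(i, nbins = B)))
  beta <- 1 / (kB * windows$temperature[1])
  U <- 0.5 * outer(windows$k * 1, rep(1, B)) *
    (outer(windows$center, centers, function(c, x) (x - c)^2))
  bias_boltz <- exp(-beta * U)                      # W x B
  list(windows = windows, edges = edges, centers = centers, B = B, W = W,
       bin_of = bin_of, counts = counts, beta = beta, bias_boltz = bias_boltz)
}

.wham_core <- function(prep, counts, tol = 1e-7, max_iter = 1e5, f_init = NULL) {
  N_w <- rowSums(counts)
  c_b <- colSums(counts)
  occ <- c_b > 0
  kT <- 1 / prep$beta
  f <- if (is.null(f_init)) numeric(prep$W) else f_init
  A <- prep$bias_boltz                              # W x B
  iter <- 0L
  repeat {
    iter <- iter + 1L
    a_w <- N_w * exp(prep$beta * f)
    denom <- colSums(A * a_w)
    p <- ifelse(occ & denom > 0, c_b / denom, 0)
    z <- as.vector(A %*% p)
    f_new <- -kT * log(z)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol || iter >= max_iter) break
  }
  p <- p / sum(p)
  list(p = p, f = f, occ = occ, iter = iter, resid = resid,
       converged = resid < tol)
}

.check_window_overlap <- function(prep) {
  ord <- order(prep$windows$center)
  occ <- prep$counts[ord, , drop = FALSE] > 0
  if (length(ord) < 2) return(invisible(TRUE))
  for (i in 1:(length(ord) - 1)) {
    if (!any(occ[i, ] & occ[i + 1, ]))
      abort(sprintf(paste0("windows centred at %.3f and %.3f nm share no occupied ",
                           "bins: coverage gap; add intermediate windows."),
                    prep$windows$center[ord[i]], prep$windows$center[ord[i + 1]]))
  }
  invisible(TRUE)
}

#' Reconstruct a potential of mean force by WHAM
#'
#' Solves the WHAM equations self-consistently over histogram bins for a
#' set of harmonically biased umbrella windows and returns the free-energy
#' profile `G(x) = -kBT ln p(x)`, shifted so its minimum is 0, together
#' with the window free-energy offsets `f_w` and the binding free energy
#' (minus the span between the highest and lowest points of the profile).
#'
#' @param windows An `umbrella_windows` tibble (see
#'   [gen_umbrella_windows()] / [read_umbrella_windows()]).
#' @param bin_width Histogram bin width, nm (default 0.01).
#' @param domain Optional (min, max) of the profile; defaults to the sampled
#'   range.
#' @param tol Convergence tolerance on the offsets, kJ/mol.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return A `pmf_profile`: list with `profile` (tibble `x`, `G`, `sigma`;
#'   `sigma` is NA until [bayesian_bootstrap_errors()] is attached),
#'   `f` (window offsets), `dg_binding`, `temperature`, convergence info.
#' @examples
#' pot <- potential_spec("flat", domain = c(0.7, 1.3))
#' uw <- gen_umbrella_windows(pot, centers = c(0.9, 1.0, 1.1), k = 1000,
#'                            n_per_window = 4000, seed = 2)
#' pmf <- wham(uw)
#' pmf$dg_binding
#' @export
wham <- function(windows, bin_width = 0.01, domain = NULL,
                 tol = 1e-7, max_iter = 1e5) {
  prep <- .wham_prepare(windows, bin_width, domain)
  .check_window_overlap(prep)
  fit <- .wham_core(prep, prep$counts, tol, max_iter)
  if (!fit$converged)
    abort(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol).",
                  as.integer(max_iter), fit$resid))
  kT <- 1 / prep$beta
  G <- rep(Inf, prep$B)
  G[fit$occ] <- -kT * log(fit$p[fit$occ])
  mask <- .contiguous_mask(fit$occ)
  G <- G - min(G[mask])
  prof <- tibble(x = prep$centers, G = G, sigma = NA_real_)[mask, ]
  structure(list(
    profile = prof, f = fit$f,
    dg_binding = -(max(prof$G) - min(prof$G)),
    temperature = prep$windows$temperature[1],
    bin_width = bin_width, n_windows = prep$W,
    iterations = fit$iter, residual = fit$resid, converged = TRUE),
    class = "pmf_profile")
}

# largest contiguous run of occupied bins (tail bins can straggle)
.contiguous_mask <- function(occ) {
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) abort("no occupied bins.")
  best <- runs[which.max(r$lengths[runs])]
  mask <- logical(length(occ))
  mask[starts[best]:ends[best]] <- TRUE
  mask
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d bins (width %.3g nm), %d windows, T = %g K\n",
              nrow(x$profile), x$bin_width, x$n_windows, x$temperature))
  cat(sprintf("  dG_binding = %.2f kJ/mol; converged in %d iterations\n",
              x$dg_binding, x$iterations))
  invisible(x)
}

#' Binding free energy from a PMF profile
#'
#' Returns minus the difference between the highest and lowest points of
#' the profile, so a deeper well gives a more negative binding free energy.
#'
#' @param pmf A `pmf_profile`, or a numeric vector of free energies.
#' @return kJ/mol (<= 0).
#' @export
binding_dg <- function(pmf) {
  G <- if (inherits(pmf, "pmf_profile")) pmf$profile$G else as.numeric(pmf)
  G <- G[is.finite(G)]
  if (!length(G)) abort("empty profile.")
  -(max(G) - min(G))
}

#' Discard the equilibration portion of each window
#'
#' Removes samples recorded before `discard_time` (same time unit as the
#' windows' `times`, ps by convention) from every window; the common
#' protocol discards the first 10 ns of each 50 ns window.
#'
#' @param windows An `umbrella_windows` tibble.
#' @param discard_time Time before which samples are dropped.
#' @param total_time Optional declared window length; `discard_time` must
#'   be smaller.
#' @return The trimmed `umbrella_windows`.
#' @export
equilibration_split <- function(windows, discard_time, total_time = NULL) {
  stopifnot(inherits(windows, "umbrella_windows"))
  if (!is.null(total_time) && discard_time >= total_time)
    abort("`discard_time` must be smaller than `total_time`.")
  out <- windows
  for (i in seq_len(nrow(out))) {
    keep <- out$times[[i]] > discard_time
    if (!any(keep))
      abort(sprintf("window %d has no samples after discarding %g.",
                    out$window[i], discard_time))
    out$samples[[i]] <- out$samples[[i]][keep]
    out$times[[i]] <- out$times[[i]][keep]
  }
  out
}

#' Histogram-overlap diagnostics between adjacent windows
#'
#' Overlap between two windows is the shared mass of their normalized
#' reaction-coordinate histograms on common bins,
#' `sum_b min(h1_b, h2_b)`. Adjacent pairs (by bias centre) falling below
#' `threshold` are flagged as coverage gaps that would need intermediate
#' windows.
#'
#' @param windows An `umbrella_windows` tibble (>= 2 windows).
#' @param bin_width Histogram bin width, nm.
#' @param threshold Flagging threshold on adjacent overlap (default 0.05).
#' @return A list: `overlap` (W x W matrix), `adjacent` (tibble with
#'   `window_a`, `window_b`, `overlap`, `flagged`).
#' @export
overlap_report <- function(windows, bin_width = 0.01, threshold = 0.05) {
  if (nrow(windows) < 2) abort("overlap report needs >= 2 windows.")
  prep <- .wham_prepare(windows, bin_width)
  h <- prep$counts / rowSums(prep$counts)
  W <- prep$W
  ov <- matrix(1, W, W)
  for (i in 1:(W - 1)) for (j in (i + 1):W)
    ov[i, j] <- ov[j, i] <- sum(pmin(h[i, ], h[j, ]))
  ord <- order(windows$center)
  adj <- tibble(
    window_a = windows$window[ord[-W]],
    window_b = windows$window[ord[-1]],
    overlap = vapply(seq_len(W - 1),
                     function(i) ov[ord[i], ord[i + 1]], numeric(1)))
  adj$flagged <- adj$overlap < threshold
  list(overlap = ov, adjacent = adj)
}
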