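# Atom selections -------------------------------------------------------------

#' Build an atom selection
#'
#' Selections filter a conformer's atom records by any combination of chain,
#' residue number, residue name, atom name and backbone flag. A bare
#' character vector passed where a selection is expected is shorthand for
#' `sel(atoms = ...)`, and the string `"backbone"` for `sel(backbone = TRUE)`.
#'
#' @param chain,resid,resname,atoms Values to keep (NULL = no constraint).
#' @param backbone If TRUE keep only backbone atoms (N, CA, C, O, amide H).
#' @return A `pmflie_sel` list usable by [kabsch_rmsd()], [hbond_count()],
#'   [cluster_rmsd_cutoff()] and friends.
#' @export
sel <- function(chain = NULL, resid = NULL, resname = NULL, atoms = NULL,
                backbone = NULL) {
  structure(list(chain = chain, resid = resid, resname = resname,
                 atoms = atoms, backbone = backbone), class = "pmflie_sel")
}

.as_sel <- function(x) {
  if (is.null(x)) return(sel())
  if (inherits(x, "pmflie_sel")) return(x)
  if (is.character(x)) {
    if (length(x) == 1 && x == "backbone") return(sel(backbone = TRUE))
    return(sel(atoms = x))
  }
  abort("selection must be NULL, a pmflie_sel, atom names, or \"backbone\".")
}

.sel_idx <- function(conf, selection) {
  s <- .as_sel(selection)
  keep <- rep(TRUE, nrow(conf))
  if (!is.null(s$chain)) keep <- keep & conf$chain %in% s$chain
  if (!is.null(s$resid)) keep <- keep & conf$resid %in% s$resid
  if (!is.null(s$resname)) keep <- keep & conf$resname %in% s$resname
  if (!is.null(s$atoms)) keep <- keep & conf$atom %in% s$atoms
  if (isTRUE(s$backbone)) keep <- keep & conf$backbone
  which(keep)
}

# Kabsch superposition ---------------------------------------------------------

.kabsch_fit <- function(P, Q) {
  # returns Q rotated+translated onto P (both n x 3), least squares
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(Q0, P0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(Q0 %*% t(R), 2, cp, FUN = "+")
}

.rmsd_fitted <- function(P, Q) {
  Qf <- .kabsch_fit(P, Q)
  sqrt(mean(rowSums((P - Qf)^2)))
}

#' Root-mean-square deviation after optimal superposition
#'
#' Applies the closed-form least-squares (SVD, Kabsch) rotation and
#' translation of `b` onto `a` over the selected atoms, then returns the
#' RMSD in nm. Mass-unweighted by default, matching common practice;
#' set `mass_weighted = TRUE` to weight the fit and the deviation by atom
#' mass.
#'
#' @param a,b Conformers; the selection must map to equal atom counts.
#' @param selection An atom selection (see [sel()]); default all atoms.
#' @param mass_weighted Use atom masses as weights.
#' @return RMSD in nm (symmetric in `a`, `b`; >= 0).
#' @export
kabsch_rmsd <- function(a, b, selection = NULL, mass_weighted = FALSE) {
  stopifnot(inherits(a, "conformer"), inherits(b, "conformer"))
  ia <- .sel_idx(a, selection); ib <- .sel_idx(b, selection)
  if (!length(ia) || !length(ib)) abort("empty atom selection.")
  if (length(ia) != length(ib))
    abort(sprintf("selection maps to %d atoms in `a` but %d in `b`.",
                  length(ia), length(ib)))
  P <- .xyz(a)[ia, , drop = FALSE]
  Q <- .xyz(b)[ib, , drop = FALSE]
  if (!mass_weighted) return(.rmsd_fitted(P, Q))
  w <- a$mass[ia] / sum(a$mass[ia])
  cp <- colSums(P * w); cq <- colSums(Q * w)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(Q0 * w, P0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(sum(w * rowSums((P0 - Q0 %*% t(R))^2)))
}

# GROMOS-style RMSD-cutoff clustering ------------------------------------------

.ensemble_coords <- function(ensemble, selection = NULL) {
  f1 <- ensemble_frame(ensemble, unique(ensemble$frame)[1])
  idx <- .sel_idx(f1, selection)
  if (!length(idx)) abort("empty atom selection.")
  frames <- sort(unique(ensemble$frame))
  lapply(frames, function(fr) .xyz(ensemble_frame(ensemble, fr))[idx, , drop = FALSE])
}

#' Pairwise RMSD matrix over ensemble frames
#'
#' @param ensemble A `conformer_ensemble`.
#' @param selection Atom selection (see [sel()]).
#' @return A symmetric matrix of superposed RMSDs (nm).
#' @export
rmsd_matrix <- function(ensemble, selection = NULL) {
  xs <- .ensemble_coords(ensemble, selection)
  nf <- length(xs)
  m <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      m[i, j] <- m[j, i] <- .rmsd_fitted(xs[[i]], xs[[j]])
    }
  }
  m
}

#' GROMOS-style conformational clustering with an RMSD cutoff
#'
#' Repeatedly takes the frame with the most neighbours within `cutoff`
#' (superposed RMSD over the selection) as a cluster centre, assigns it and
#' its neighbours to that cluster, removes them, and repeats on the
#' remainder. Ties in neighbour count are broken toward the lowest frame
#' index, so the result is deterministic. Clusters are finally relabelled
#' 1..K by descending population.
#'
#' Typical cutoffs for peptide dimer work: 0.25 nm over all atoms for small
#' rigid complexes, 0.35 nm over backbone atoms for flexible full-length
#' complexes.
#'
#' @param ensemble A `conformer_ensemble` (>= 1 frame).
#' @param cutoff RMSD cutoff in nm; > 0.
#' @param selection Atom selection; default `"backbone"`.
#' @return A `cluster_assignment`: list with `assignment` (tibble `frame`,
#'   `cluster`), `clusters` (tibble `cluster`, `n`, `population`,
#'   `center_frame`), `cutoff` and `selection`.
#' @export
cluster_rmsd_cutoff <- function(ensemble, cutoff, selection = "backbone") {
  if (!is.finite(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0 nm.")
  m <- rmsd_matrix(ensemble, selection)
  nf <- nrow(m)
  frames <- sort(unique(ensemble$frame))
  neigh <- m <= cutoff           # includes self
  alive <- rep(TRUE, nf)
  cl <- integer(nf)
  centers <- integer(0)
  k <- 0
  while (any(alive)) {
    counts <- colSums(neigh[alive, , drop = FALSE]) * alive
    c_idx <- which.max(counts)   # ties -> lowest index
    members <- which(alive & neigh[, c_idx])
    k <- k + 1
    cl[members] <- k
    centers[k] <- c_idx
    alive[members] <- FALSE
  }
  tab <- tibble(cluster = seq_len(k),
                n = as.integer(table(factor(cl, levels = seq_len(k)))),
                center_frame = frames[centers])
  ord <- order(-tab$n, tab$cluster)   # descending population, stable
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  tab <- tab[ord, ]
  tab$cluster <- seq_len(k)
  tab$population <- tab$n / nf
  structure(list(
    assignment = tibble(frame = frames, cluster = relabel[cl]),
    clusters = tab[, c("cluster", "n", "population", "center_frame")],
    cutoff = cutoff,
    selection = .as_sel(selection)),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d frames, %d clusters, cutoff %.3g nm\n",
              nrow(x$assignment), nrow(x$clusters), x$cutoff))
  print(x$clusters)
  invisible(x)
}

#' Frame mask for one cluster
#'
#' @param assignment A `cluster_assignment`.
#' @param cluster Cluster id (1 = most populated).
#' @return Integer frame numbers belonging to the cluster.
#' @export
cluster_frames <- function(assignment, cluster = 1) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  assignment$assignment$frame[assignment$assignment$cluster == cluster]
}
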