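# Intermolecular contacts: hydrogen bonds, salt bridges, COM separation,
# beta-sheet registry.

#' Side-chain charged-group atom names by residue type
#'
#' Atom names carrying the formal charge for the standard charged residues
#' and for the non-standard ornithine (ORN) and diaminobutyric acid (DAB)
#' of the pseudo-peptides. Used by [salt_bridge_series()] defaults; extend
#' or override by passing your own table.
#'
#' @return A tibble with columns `resname`, `atom`, `charge_sign`.
#' @export
charged_group_atoms <- function() {
  tibble(
    resname = c("LYS", "ARG", "ARG", "ARG", "ORN", "DAB",
                "GLU", "GLU", "ASP", "ASP"),
    atom = c("NZ", "NH1", "NH2", "NE", "NZ", "NG",
             "OE1", "OE2", "OD1", "OD2"),
    charge_sign = c(1, 1, 1, 1, 1, 1, -1, -1, -1, -1))
}

.pairdist_min <- function(P, Q) {
  # minimum inter-point distance between two coordinate sets
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
  sqrt(max(0, min(d2)))
}

.as_ensemble <- function(x) {
  if (inherits(x, "conformer_ensemble")) return(x)
  if (inherits(x, "conformer")) return(conformer_ensemble(list(x)))
  abort("expected a conformer or conformer_ensemble.")
}

# hydrogen bonds ---------------------------------------------------------------

.hbonds_one_dir <- function(conf, don_idx, acc_idx, d_cut, angle_cut) {
  # donors: N (or O/S) atoms with an attached hydrogen; a hydrogen is
  # "attached" when within 0.12 nm of the donor heavy atom
  X <- .xyz(conf)
  don <- don_idx[conf$element[don_idx] %in% c("N", "O", "S")]
  hyd <- which(conf$element == "H")
  if (!length(don)) return(0L)
  count <- 0L
  for (d in don) {
    hd <- hyd[sqrt(rowSums((X[hyd, , drop = FALSE] -
                              matrix(X[d, ], length(hyd), 3, byrow = TRUE))^2)) <= 0.12]
    if (!length(hd)) next
    for (a in acc_idx) {
      if (a == d) next
      rda <- X[a, ] - X[d, ]
      dda <- sqrt(sum(rda^2))
      if (dda > d_cut || dda == 0) next
      for (h in hd) {
        rdh <- X[h, ] - X[d, ]
        ang <- acos(pmin(1, pmax(-1, sum(rdh * rda) /
                                   (sqrt(sum(rdh^2)) * dda)))) * 180 / pi
        if (ang <= angle_cut) { count <- count + 1L; break }
      }
    }
  }
  count
}

#' Count intermolecular hydrogen bonds per frame
#'
#' A hydrogen bond is counted when the donor--acceptor heavy-atom distance
#' is at most `d_cut` and the hydrogen--donor--acceptor angle at most
#' `angle_cut` (defaults 0.35 nm and 30 degrees, the era's GROMACS
#' convention). Bonds are counted in both directions: donors of group A to
#' acceptors of group B, plus donors of B to acceptors of A. Donors are
#' N/O/S atoms carrying a hydrogen within bonding distance; acceptors are
#' the N/O atoms of the partner selection.
#'
#' @param x A `conformer` or `conformer_ensemble`.
#' @param group_A,group_B Atom selections (see [sel()]) defining the two
#'   molecules, e.g. `sel(chain = "A")`.
#' @param d_cut Donor-acceptor distance cutoff, nm.
#' @param angle_cut Hydrogen-donor-acceptor angle cutoff, degrees.
#' @return A tibble with `frame`, `time`, `n_hbonds`, carrying the ensemble
#'   mean as attribute `"mean"` (also via `mean(result$n_hbonds)`).
#' @export
hbond_count <- function(x, group_A, group_B, d_cut = 0.35, angle_cut = 30) {
  ens <- .as_ensemble(x)
  frames <- sort(unique(ens$frame))
  res <- map(frames, function(fr) {
    conf <- ensemble_frame(ens, fr)
    ia <- .sel_idx(conf, group_A); ib <- .sel_idx(conf, group_B)
    if (!length(ia) || !length(ib)) abort("empty hydrogen-bond selection.")
    acc_a <- ia[conf$element[ia] %in% c("N", "O")]
    acc_b <- ib[conf$element[ib] %in% c("N", "O")]
    .hbonds_one_dir(conf, ia, acc_b, d_cut, angle_cut) +
      .hbonds_one_dir(conf, ib, acc_a, d_cut, angle_cut)
  })
  times <- vapply(frames, function(fr) ens$time[ens$frame == fr][1], numeric(1))
  out <- tibble(frame = frames, time = times, n_hbonds = unlist(res))
  attr(out, "mean") <- mean(out$n_hbonds)
  out
}

# salt bridges -----------------------------------------------------------------

#' Monitor salt-bridge distances between labelled charged-residue pairs
#'
#' For each labelled pair of residue groups, reports the per-frame minimum
#' distance between their side-chain charged-group atoms and a
#' salt-bridge-exists flag. A salt bridge is considered to exist when the
#' separation is below 1 nm.
#'
#' @param x A `conformer` or `conformer_ensemble`.
#' @param group_pairs Named list; each element is a list of two selections
#'   (see [sel()]), e.g.
#'   `list("Lys16-glu8" = list(sel(chain="A", resid=16), sel(chain="B", resid=8)))`.
#'   Selections are restricted to charged-group atoms per `charged_atoms`
#'   when those residues appear there; otherwise all selected atoms count.
#' @param exist_cut Existence threshold, nm (default 1.0).
#' @param charged_atoms Charged-group atom table (see [charged_group_atoms()]).
#' @return A `contact_series` tibble: `frame`, `time`, `pair`,
#'   `min_distance` (nm), `exists` (flag), with per-pair means available via
#'   [summarise_contacts()].
#' @export
salt_bridge_series <- function(x, group_pairs, exist_cut = 1.0,
                               charged_atoms = charged_group_atoms()) {
  ens <- .as_ensemble(x)
  if (!length(group_pairs)) abort("`group_pairs` must name at least one pair.")
  if (is.null(names(group_pairs)))
    names(group_pairs) <- paste0("pair", seq_along(group_pairs))
  frames <- sort(unique(ens$frame))
  rows <- list()
  for (fr in frames) {
    conf <- ensemble_frame(ens, fr)
    tm <- ens$time[ens$frame == fr][1]
    for (nm in names(group_pairs)) {
      gp <- group_pairs[[nm]]
      idx <- lapply(gp, function(s) {
        i <- .sel_idx(conf, s)
        if (!length(i)) abort(sprintf("empty group in pair '%s'.", nm))
        ch <- i[paste(conf$resname[i], conf$atom[i]) %in%
                  paste(charged_atoms$resname, charged_atoms$atom)]
        if (length(ch)) ch else i
      })
      d <- .pairdist_min(.xyz(conf)[idx[[1]], , drop = FALSE],
                         .xyz(conf)[idx[[2]], , drop = FALSE])
      rows[[length(rows) + 1L]] <-
        tibble(frame = fr, time = tm, pair = nm,
               min_distance = d, exists = d < exist_cut)
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("contact_series", class(tibble()))
  out
}

#' Per-pair averages of a contact series
#'
#' @param series A `contact_series` from [salt_bridge_series()].
#' @return A tibble with `pair`, `mean_distance`, `fraction_exists`.
#' @export
summarise_contacts <- function(series) {
  series |>
    as_tibble() |>
    group_by(.data$pair) |>
    summarise(mean_distance = mean(.data$min_distance),
              fraction_exists = mean(.data$exists), .groups = "drop")
}

# centre-of-mass separation ----------------------------------------------------

#' Mass-weighted centre-of-mass separation of two parts
#'
#' @param conf A `conformer` with masses.
#' @param part_A,part_B Atom selections (see [sel()]).
#' @return Euclidean distance between the two mass-weighted centroids, nm.
#' @export
com_separation <- function(conf, part_A, part_B) {
  stopifnot(inherits(conf, "conformer"))
  com <- function(s) {
    i <- .sel_idx(conf, s)
    if (!length(i)) abort("empty COM selection.")
    m <- conf$mass[i]
    if (!all(is.finite(m)) || sum(m) <= 0) abort("part has zero total mass.")
    colSums(.xyz(conf)[i, , drop = FALSE] * m) / sum(m)
  }
  sqrt(sum((com(part_A) - com(part_B))^2))
}

# beta-sheet registry ----------------------------------------------------------

#' Determine the beta-sheet registry of a residue pairing
#'
#' For an antiparallel sheet between the R fragment (amyloid-beta numbering,
#' `i`) and a pseudo-peptide (natural numbering, `j`), the registry is the
#' constant value of `i + j` across all paired residues. For parallel
#' sheets the registry does not apply and `NA` is returned with the pairing
#' retained.
#'
#' @param pairing Data frame with columns `i` and `j` (non-empty), e.g. the
#'   `pairing` element of [gen_beta_sheet_pair()] or the output of
#'   [pairing_from_hbonds()].
#' @param mode `"antiparallel"` or `"parallel"`.
#' @return A `registry_result` list: `mode`, `registry` (integer or NA),
#'   `pairing`.
#' @export
sheet_registry <- function(pairing, mode = c("antiparallel", "parallel")) {
  mode <- match.arg(mode)
  pairing <- as_tibble(pairing)
  if (!nrow(pairing) || !all(c("i", "j") %in% names(pairing)))
    abort("`pairing` must be a non-empty data frame with columns `i`, `j`.")
  if (mode == "parallel") {
    return(structure(list(mode = mode, registry = NA_integer_, pairing = pairing),
                     class = "registry_result"))
  }
  s <- pairing$i + pairing$j
  if (length(unique(s)) != 1) {
    off <- pairing[s != s[1], , drop = FALSE]
    abort(paste0("inconsistent antiparallel registry: i + j differs at pair(s) ",
                 paste(sprintf("(%d,%d)", off$i, off$j), collapse = ", "),
                 " vs ", s[1], "."))
  }
  structure(list(mode = mode, registry = as.integer(s[1]), pairing = pairing),
            class = "registry_result")
}

#' @export
print.registry_result <- function(x, ...) {
  cat("<registry_result>", x$mode,
      if (is.na(x$registry)) "registry: not applicable"
      else paste0("registry i + j = ", x$registry), "\n")
  invisible(x)
}

#' Derive a residue pairing from backbone-backbone hydrogen bonds
#'
#' Residues of chain A and chain B are considered paired when they share at
#' least one backbone-backbone hydrogen bond (either direction) under the
#' geometric criterion of [hbond_count()].
#'
#' @param conf A two-chain `conformer`.
#' @param chain_A,chain_B Chain ids of the two strands.
#' @inheritParams hbond_count
#' @return A tibble of paired residue numbers `i` (chain A), `j` (chain B).
#' @export
pairing_from_hbonds <- function(conf, chain_A = "A", chain_B = "B",
                                d_cut = 0.35, angle_cut = 30) {
  stopifnot(inherits(conf, "conformer"))
  X <- .xyz(conf)
  bb <- which(conf$backbone)
  ia <- bb[conf$chain[bb] == chain_A]
  ib <- bb[conf$chain[bb] == chain_B]
  if (!length(ia) || !length(ib)) abort("chains not found or have no backbone atoms.")
  pairs <- list()
  add_dir <- function(don_side, acc_side) {
    don <- don_side[conf$atom[don_side] == "N"]
    for (d in don) {
      h <- don_side[conf$atom[don_side] == "H" &
                      conf$resid[don_side] == conf$resid[d]]
      if (!length(h)) next
      acc <- acc_side[conf$atom[acc_side] == "O"]
      for (a in acc) {
        rda <- X[a, ] - X[d, ]
        dda <- sqrt(sum(rda^2))
        if (dda > d_cut) next
        rdh <- X[h[1], ] - X[d, ]
        ang <- acos(pmin(1, pmax(-1, sum(rdh * rda) /
                                   (sqrt(sum(rdh^2)) * dda)))) * 180 / pi
        if (ang <= angle_cut)
          pairs[[length(pairs) + 1L]] <<-
            c(i = conf$resid[if (conf$chain[d] == chain_A) d else a],
              j = conf$resid[if (conf$chain[d] == chain_A) a else d])
      }
    }
  }
  add_dir(ia, ib)
  add_dir(ib, ia)
  if (!length(pairs)) return(tibble(i = integer(0), j = integer(0)))
  distinct(arrange(as_tibble(do.call(rbind, pairs)), .data$i, .data$j))
}
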