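# Idealized two-strand beta-sheet builder. The template is deliberately
# schematic: extended strands with a 0.35 nm rise per residue and amide
# geometry arranged so every paired residue forms the two canonical
# backbone-backbone hydrogen bonds under the 0.35 nm / 30 degree criterion
# at zero noise. It carries no side chains and no claim of stereochemical
# realism.

.r_sequence <- c("HIS", "HIS", "GLY", "LYS", "LEU", "VAL", "PHE", "PHE",
                 "ALA", "GLU", "ASP")           # Abeta 13..23 (HHGKLVFFAED)
.pp_sequence <- c("DAB", "ORN", "LEU", "MPH", "PHE", "MPH", "LEU", "GLU")

.resname_A <- function(i) ifelse(i >= 13 & i <= 23, .r_sequence[i - 12], "ALA")
.resname_B <- function(j) ifelse(j >= 1 & j <= 8, .pp_sequence[j], "ALA")

.rise <- 0.35  # nm Calpha-Calpha rise per residue along the strand

# backbone atom offsets within one x-slot; strand A at y ~ 0, strand B above
.slot_atoms_A <- function(s) {
  tibble(atom = c("N", "H", "CA", "C", "O"),
         x = s + c(0, 0, 0.117, 0.233, 0.233),
         y = c(0, 0.10, -0.09, 0, 0.10),
         z = 0)
}
.slot_atoms_B <- function(s) {
  tibble(atom = c("N", "H", "CA", "C", "O"),
         x = s + c(0.233, 0.233, 0.117, 0, 0),
         y = c(0.40, 0.30, 0.49, 0.423, 0.30),
         z = 0)
}

#' Generate an idealized antiparallel or parallel beta-sheet strand pair
#'
#' Builds two extended backbone strands (atoms N, H, CA, C, O): strand A
#' carries the numbering of the amyloid-beta recognition fragment R
#' (residues 13 onward, sequence HHGKLVFFAED within 13-23) and strand B the
#' natural 1-based numbering of an eight-residue pseudo-peptide. Residues
#' are paired so that in antiparallel mode `i + j` equals `registry` for
#' every pair; in parallel mode `registry` is interpreted as the constant
#' offset `i - j` (a sheet registry proper does not apply). At
#' `rmsd_noise = 0` every emitted pair satisfies the hydrogen-bond
#' criterion of [hbond_count()] in both donor directions.
#'
#' @param n_res Residues per strand; >= 2.
#' @param mode `"antiparallel"` or `"parallel"`.
#' @param registry Pairing constant: `i + j` (antiparallel, default
#'   `13 + n_res`, full overlap) or `i - j` (parallel, default 12).
#' @param rmsd_noise Isotropic Gaussian atom displacement, nm; the
#'   per-coordinate sd is `rmsd_noise / sqrt(3)` so the expected RMSD from
#'   the template is about `rmsd_noise`.
#' @param seed Integer seed for the noise.
#' @return A `beta_sheet_pair` list: `strand_A`, `strand_B` (conformers,
#'   chains "A" and "B"), `pairing` (tibble of `i`, `j`), `mode`, `registry`.
#' @examples
#' sh <- gen_beta_sheet_pair(n_res = 7, mode = "antiparallel", registry = 23)
#' sh$pairing
#' @export
gen_beta_sheet_pair <- function(n_res, mode = c("antiparallel", "parallel"),
                                registry = NULL, rmsd_noise = 0, seed = 1) {
  mode <- match.arg(mode)
  if (n_res < 2) abort("`n_res` must be >= 2.")
  if (rmsd_noise < 0) abort("`rmsd_noise` must be >= 0.")
  i_res <- 13:(12 + n_res)
  j_res <- 1:n_res
  if (is.null(registry)) registry <- if (mode == "antiparallel") 13 + n_res else 12
  partner_j <- if (mode == "antiparallel") registry - i_res else i_res - registry
  keep <- partner_j %in% j_res
  if (!any(keep))
    abort(sprintf("registry %d pairs no residues of strands 13..%d and 1..%d.",
                  registry, max(i_res), n_res))
  pairing <- tibble(i = i_res[keep], j = partner_j[keep])

  # x-slot of residue i on A; B residues inherit the slot of their partner
  i_ref <- i_res[1]
  slot_A <- function(i) (i - i_ref) * .rise
  slot_B <- function(j) {
    i_part <- if (mode == "antiparallel") registry - j else j + registry
    slot_A(i_part)
  }

  build <- function(res_ids, slot_fun, atoms_fun, resname_fun, chain) {
    rows <- lapply(res_ids, function(r) {
      a <- atoms_fun(slot_fun(r))
      mutate(a, resname = resname_fun(r), resid = r, chain = chain)
    })
    df <- bind_rows(rows)
    df <- df[order(df$resid), ]
    conformer(df)
  }
  A <- build(i_res, slot_A, .slot_atoms_A, .resname_A, "A")
  B <- build(sort(j_res), slot_B, .slot_atoms_B, .resname_B, "B")

  if (rmsd_noise > 0) {
    set.seed(as.integer(seed))
    s <- rmsd_noise / sqrt(3)
    jitter <- function(conf) {
      conf$x <- conf$x + rnorm(nrow(conf), 0, s)
      conf$y <- conf$y + rnorm(nrow(conf), 0, s)
      conf$z <- conf$z + rnorm(nrow(conf), 0, s)
      conf
    }
    A <- jitter(A); B <- jitter(B)
  }

  structure(list(strand_A = A, strand_B = B, pairing = pairing,
                 mode = mode, registry = registry),
            class = "beta_sheet_pair")
}

#' Concatenate two conformers into one multi-chain conformer
#'
#' @param a,b Conformers with distinct chain ids.
#' @return A single `conformer` with the atoms of `a` followed by `b`.
#' @export
combine_conformers <- function(a, b) {
  stopifnot(inherits(a, "conformer"), inherits(b, "conformer"))
  conformer(bind_rows(as_tibble(a), as_tibble(b)))
}
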