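# Shared coordinate data model: a conformer is a tibble of atom records with
# coordinates in nm. All internal units are nm / kJ/mol; Angstrom appears only
# at the PDB boundary.

.backbone_names <- c("N", "CA", "C", "O", "H")

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

.guess_element <- function(atom) {
  # first alphabetic character of the atom name; covers the backbone and the
  # side-chain atoms used by the contact analyses
  toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", atom))
}

#' Build a conformer from atom records
#'
#' A conformer is a tibble with one row per atom: `atom` (name), `resname`,
#' `resid` (1-based, preserved verbatim from input), `chain`, `element`,
#' `backbone` (flag, set for N, CA, C, O and the amide H), `x`, `y`, `z`
#' in nm and `mass` in amu. Missing `chain`, `element`, `backbone` and
#' `mass` are filled from the atom names.
#'
#' @param df Data frame with at least `atom`, `resname`, `resid`, `x`, `y`, `z`.
#' @return A `conformer` tibble.
#' @export
conformer <- function(df) {
  df <- as_tibble(df)
  need <- c("atom", "resname", "resid", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("conformer records lack column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    abort("conformer coordinates must be finite.")
  if (!"chain" %in% names(df)) df$chain <- "A"
  if (!"element" %in% names(df)) df$element <- .guess_element(df$atom)
  if (!"backbone" %in% names(df)) df$backbone <- df$atom %in% .backbone_names
  if (!"mass" %in% names(df)) {
    df$mass <- unname(.atomic_masses[df$element])
    df$mass[is.na(df$mass)] <- 12.011
  }
  if (any(df$mass <= 0, na.rm = TRUE)) abort("atom masses must be > 0.")
  for (ch in unique(df$chain)) {
    r <- df$resid[df$chain == ch]
    if (is.unsorted(r)) abort("residue numbers must be non-decreasing within a chain.")
  }
  df <- df[, c("atom", "resname", "resid", "chain", "element", "backbone",
               "x", "y", "z", "mass")]
  class(df) <- c("conformer", class(tibble()))
  df
}

.xyz <- function(conf) cbind(conf$x, conf$y, conf$z)

#' Read a molecular structure file into a conformer
#'
#' Supports PDB (fixed-column ATOM/HETATM records, parsed through bio3d,
#' coordinates converted from Angstrom to nm) and GRO (GROMACS fixed-width,
#' already in nm). For multi-model PDB files the first model is returned;
#' see [read_ensemble_pdb()] for trajectories.
#'
#' @param path File path.
#' @param format `"pdb"` or `"gro"`; default guessed from the extension.
#' @return A `conformer` tibble with coordinates in nm.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  switch(format, pdb = .read_pdb(path), gro = .read_gro(path))
}

.check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    abort(sprintf("malformed PDB record at line %d of %s (truncated before coordinates).",
                  bad[1], path))
  if (!any(rec)) abort(paste0("no ATOM/HETATM records in ", path))
  invisible(lines)
}

.read_pdb <- function(path) {
  .check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  conformer(tibble(
    atom = a$elety, resname = a$resid, resid = a$resno,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    x = a$x / 10, y = a$y / 10, z = a$z / 10))
}

.read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) abort(paste0("not a GRO file (too short): ", path))
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat) || length(lines) < nat + 3)
    abort(paste0("malformed GRO atom count in ", path))
  rec <- lines[3:(2 + nat)]
  bad <- which(nchar(rec) < 44)
  if (length(bad))
    abort(sprintf("malformed GRO record at line %d of %s.", bad[1] + 2, path))
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) abort(paste0("non-numeric GRO field in ", path))
    v
  }
  conformer(tibble(
    atom = trimws(substr(rec, 11, 15)),
    resname = trimws(substr(rec, 6, 10)),
    resid = as.integer(num(substr(rec, 1, 5))),
    x = num(substr(rec, 21, 28)),
    y = num(substr(rec, 29, 36)),
    z = num(substr(rec, 37, 44))))
}

#' Write a conformer to PDB or GRO
#'
#' The inverse of [read_structure()]: `read(write(x))` reproduces `x` up to
#' the format's coordinate precision (1e-4 nm for PDB, 1e-3 nm for GRO).
#' PDB output is written through bio3d with nm converted to Angstrom.
#'
#' @param conf A `conformer`.
#' @param path Output path.
#' @param format `"pdb"` or `"gro"`; default guessed from the extension.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(conf, path, format = c("auto", "pdb", "gro")) {
  stopifnot(inherits(conf, "conformer"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(.xyz(conf))) * 10,
                     resno = conf$resid, resid = conf$resname,
                     chain = conf$chain, elety = conf$atom,
                     elesy = conf$element)
  } else {
    rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   conf$resid, conf$resname, conf$atom,
                   seq_len(nrow(conf)) %% 100000,
                   conf$x, conf$y, conf$z)
    writeLines(c("written by pmflie", sprintf("%5d", nrow(conf)), rec,
                 sprintf("%10.5f%10.5f%10.5f", 10, 10, 10)), path)
  }
  invisible(path)
}

#' Assemble an ordered ensemble of conformers sharing one topology
#'
#' @param frames List of `conformer` objects with identical atom count and
#'   ordering.
#' @param times Frame times in ns, strictly increasing; defaults to
#'   `seq_along(frames)`.
#' @return A `conformer_ensemble` tibble in long form: columns `frame`,
#'   `time` plus the conformer columns.
#' @export
conformer_ensemble <- function(frames, times = NULL) {
  if (!length(frames)) abort("ensemble needs at least one frame.")
  if (is.null(times)) times <- as.numeric(seq_along(frames))
  if (length(times) != length(frames) || any(diff(times) <= 0))
    abort("frame times must be strictly increasing, one per frame.")
  ref <- frames[[1]]
  for (f in frames) {
    stopifnot(inherits(f, "conformer"))
    if (nrow(f) != nrow(ref) || !all(f$atom == ref$atom) ||
        !all(f$resid == ref$resid))
      abort("all frames must share atom count and ordering.")
  }
  out <- bind_rows(lapply(seq_along(frames), function(i)
    mutate(as_tibble(frames[[i]]), frame = i, time = times[i])))
  out <- out[, c("frame", "time", setdiff(names(out), c("frame", "time")))]
  class(out) <- c("conformer_ensemble", class(tibble()))
  out
}

#' @export
#' @rdname conformer_ensemble
#' @param ensemble A `conformer_ensemble`.
#' @param i Frame index.
ensemble_frame <- function(ensemble, i) {
  f <- filter(as_tibble(ensemble), .data$frame == i)
  if (!nrow(f)) abort(sprintf("no frame %s in ensemble.", i))
  conformer(select(f, -"frame", -"time"))
}

#' Read a multi-model PDB file as a conformer ensemble
#'
#' Frames are the MODEL records, in file order; times default to the frame
#' index in ns.
#'
#' @inheritParams read_structure
#' @param times Optional frame times (ns).
#' @return A `conformer_ensemble`.
#' @export
read_ensemble_pdb <- function(path, times = NULL) {
  .check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  topo <- tibble(
    atom = a$elety, resname = a$resid, resid = a$resno,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain))
  nfr <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nfr), function(i) {
    m <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
    conformer(mutate(topo, x = m[, 1], y = m[, 2], z = m[, 3]))
  })
  conformer_ensemble(frames, times)
}

#' Number of frames in an ensemble
#' @param ensemble A `conformer_ensemble`.
#' @export
n_frames <- function(ensemble) length(unique(ensemble$frame))
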