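#' Build a structure object from an atom table
#'
#' A `clamp_structure` is a flat atom table: one row per atom with chain,
#' 1-based residue number, residue name, atom name, element, coordinates in
#' Angstrom and a van der Waals radius. Radii default to a per-element
#' consolidated (Bondi-style) table via [vdw_radius()].
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`,
#'   `atom_name`, `element`, `x`, `y`, `z` and optionally `radius`.
#' @return An object of class `clamp_structure`.
#' @export
clamp_structure <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resname", "atom_name", "element",
            "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("'atoms' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates", call. = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius(atoms$element)
  if (any(!is.finite(atoms$radius) | atoms$radius <= 0))
    stop("radii must be positive", call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "clamp_structure")
}

#' @export
print.clamp_structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, chains %s\n", nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Van der Waals radii by element
#'
#' Consolidated per-element van der Waals radii (Angstrom): H 1.20, C 1.70,
#' N 1.55, O 1.52, S 1.80, P 1.80, F 1.47, Cl 1.75, Br 1.85, I 1.98,
#' Se 1.90. Unknown elements fall back to 1.70 with a warning.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  key <- toupper(trimws(element))
  r <- tab[key]
  if (anyNA(r)) {
    warning("unknown element(s) ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using default radius 1.7 A", call. = FALSE)
    r[is.na(r)] <- 1.70
  }
  unname(r)
}

#' Coordinate trajectory over a fixed atom roster
#'
#' Frames are stored as a 3-dimensional array `n_frames x n_atoms x 3`
#' (Angstrom) over a fixed atom table; `times` are strictly increasing
#' frame times in picoseconds.
#'
#' @param coords Array `n_frames x n_atoms x 3`, or list of `n_atoms x 3`
#'   matrices.
#' @param atoms Atom table as in [clamp_structure()] (coordinates ignored).
#' @param times Numeric vector of frame times (ps); defaults to
#'   `0, 1, 2, ...`.
#' @return An object of class `clamp_trajectory`.
#' @export
clamp_trajectory <- function(coords, atoms, times = NULL) {
  if (is.list(coords)) {
    n <- length(coords)
    na <- nrow(coords[[1L]])
    arr <- array(NA_real_, c(n, na, 3L))
    for (i in seq_len(n)) {
      if (!identical(dim(coords[[i]]), c(na, 3L)))
        stop("all frames must share the atom roster", call. = FALSE)
      arr[i, , ] <- coords[[i]]
    }
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) != dim(coords)[2L])
    stop("atom table does not match coordinate array", call. = FALSE)
  if (is.null(times)) times <- seq_len(dim(coords)[1L]) - 1
  if (length(times) != dim(coords)[1L] || any(diff(times) <= 0))
    stop("'times' must be strictly increasing, one per frame", call. = FALSE)
  structure(list(coords = coords, atoms = atoms, times = as.numeric(times)),
            class = "clamp_trajectory")
}

#' @export
print.clamp_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, %g-%g ps\n",
              dim(x$coords)[1L], dim(x$coords)[2L],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A [clamp_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[1L]

#' Write a trajectory as a multi-MODEL PDB file
#'
#' Emits one `MODEL`/`ENDMDL` block per frame in fixed-width PDB format.
#' (Written by hand because the installed structure packages write only
#' single-model files; reading goes through `bio3d`.)
#'
#' @param trajectory A [clamp_trajectory()] or [clamp_structure()] (single
#'   model).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(trajectory, path) {
  if (inherits(trajectory, "clamp_structure")) {
    trajectory <- clamp_trajectory(
      array(as.matrix(trajectory$atoms[, c("x", "y", "z")]),
            c(1L, nrow(trajectory$atoms), 3L)),
      trajectory$atoms, times = 0)
  }
  stopifnot(inherits(trajectory, "clamp_trajectory"))
  atoms <- trajectory$atoms
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(trajectory)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- trajectory$coords[f, , , drop = FALSE]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(atoms)),
      ifelse(nchar(atoms$atom_name) < 4L, paste0(" ", atoms$atom_name),
             atoms$atom_name),
      atoms$resname, atoms$chain, atoms$resno,
      xyz[1L, , 1L], xyz[1L, , 2L], xyz[1L, , 3L],
      1, 0, toupper(atoms$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-MODEL) PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning either a
#' [clamp_structure()] (single model) or a [clamp_trajectory()]
#' (several `MODEL` blocks). Frame times default to `frame_interval`
#' picoseconds apart.
#'
#' @param path PDB file path.
#' @param frame_interval Time between models in ps (default 1).
#' @return A `clamp_structure` or `clamp_trajectory`.
#' @export
read_pdb_models <- function(path, frame_interval = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1L, 1L)
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      resname = as.character(at$resid),
                      atom_name = trimws(as.character(at$elety)),
                      element = trimws(as.character(elem)),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  nf <- if (is.matrix(xyz)) nrow(xyz) else 1L
  if (nf == 1L) return(clamp_structure(atoms))
  arr <- array(NA_real_, c(nf, nrow(atoms), 3L))
  for (f in seq_len(nf)) {
    m <- matrix(if (is.matrix(xyz)) xyz[f, ] else xyz, ncol = 3L, byrow = TRUE)
    arr[f, , ] <- m
  }
  clamp_trajectory(arr, atoms, times = (seq_len(nf) - 1) * frame_interval)
}
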