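#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`, computed by singular value decomposition of the
#' weighted covariance matrix with the determinant sign fixed so the
#' returned matrix is a proper rotation (det = +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`
#'   non-collinear points.
#' @param weights Optional non-negative per-point weights.
#' @return List with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% t(rotation) + translation` approximates `reference`, and
#'   the post-fit `rmsd` (Angstrom, weighted when weights are given).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L ||
      nrow(mobile) != nrow(reference))
    stop("'mobile' and 'reference' must be n x 3 with equal n", call. = FALSE)
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("'weights' must be non-negative with positive sum", call. = FALSE)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  a <- sweep(mobile, 2L, cm)
  b <- sweep(reference, 2L, cr)
  h <- t(a * w) %*% b
  sv <- svd(h)
  if (min(sv$d) < 1e-12 && sum(sv$d > 1e-12) < 2L)
    stop("degenerate (collinear or coincident) geometry", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% t(rot)),
       rmsd = rmsd)
}

apply_fit <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2L, -fit$translation)
}

resolve_window <- function(trajectory, window) {
  if (is.null(window)) return(seq_len(n_frames(trajectory)))
  if (length(window) == 2L && is.numeric(window)) {
    idx <- which(trajectory$times >= window[1L] &
                 trajectory$times < window[2L])
  } else idx <- as.integer(window)
  if (length(idx) == 0L) stop("window contains no frames", call. = FALSE)
  if (any(idx < 1L | idx > n_frames(trajectory)))
    stop("window frame index out of range", call. = FALSE)
  idx
}

#' Parse a residue selection string
#'
#' Selections use `"chain:resstart-resend"` (e.g. `"L:10-31"`); a bare
#' chain id selects the whole chain; `NULL` selects everything.
#'
#' @param atoms Atom table (`chain`, `resno`, ...).
#' @param selection Selection string or `NULL`.
#' @return Integer vector of atom-row indices.
#' @export
parse_selection <- function(atoms, selection = NULL) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  m <- regmatches(selection,
                  regexec("^([^:]+)(?::(\\d+)-(\\d+))?$", selection))[[1L]]
  if (length(m) == 0L)
    stop("cannot parse selection '", selection,
         "'; expected \"chain:start-end\"", call. = FALSE)
  idx <- which(atoms$chain == m[2L])
  if (nzchar(m[3L]))
    idx <- idx[atoms$resno[idx] >= as.integer(m[3L]) &
               atoms$resno[idx] <= as.integer(m[4L])]
  if (length(idx) == 0L)
    stop("selection '", selection, "' matches no atoms", call. = FALSE)
  idx
}

#' Window-averaged structure from a trajectory
#'
#' Superposes every frame of the window onto the window's first frame
#' (Kabsch) and returns the per-atom mean coordinates, as when one averaged
#' structure is generated from each 300 K equilibration phase.
#'
#' @param trajectory A [clamp_trajectory()].
#' @param window `c(start, end)` time window in ps (half-open), an integer
#'   frame-index vector, or `NULL` for all frames.
#' @return A [clamp_structure()] of mean coordinates.
#' @export
average_structure <- function(trajectory, window = NULL) {
  stopifnot(inherits(trajectory, "clamp_trajectory"))
  idx <- resolve_window(trajectory, window)
  ref <- trajectory$coords[idx[1L], , ]
  acc <- matrix(0, nrow(ref), 3L)
  for (f in idx) {
    xyz <- trajectory$coords[f, , ]
    fit <- kabsch_superpose(xyz, ref)
    acc <- acc + apply_fit(xyz, fit)
  }
  mean_xyz <- acc / length(idx)
  atoms <- trajectory$atoms
  atoms$x <- mean_xyz[, 1L]; atoms$y <- mean_xyz[, 2L]
  atoms$z <- mean_xyz[, 3L]
  clamp_structure(atoms)
}

superpose_window <- function(trajectory, idx, sel) {
  # rigid-fit every window frame on the full atom roster, onto the window
  # mean (one re-fit iteration from the first frame); then restrict to the
  # measured selection
  frames <- lapply(idx, function(f)
    trajectory$coords[f, , , drop = TRUE])
  ref <- frames[[1L]]
  fitted <- lapply(frames, function(x) apply_fit(x, kabsch_superpose(x, ref)))
  mean1 <- Reduce(`+`, fitted) / length(fitted)
  lapply(frames, function(x)
    apply_fit(x, kabsch_superpose(x, mean1))[sel, , drop = FALSE])
}

#' Per-residue root-mean-square fluctuation
#'
#' For each selected residue, the square root of the mean (over window
#' frames) squared deviation of its atom from its time-mean position, after
#' rigid-body superposition of all window frames onto the window mean
#' structure (one re-fit iteration from the first frame). When several
#' windows are given (e.g. the cooling, equilibration and subsequent
#' heating segments around one averaged conformation), each window is
#' superposed independently and fluctuations are pooled across windows.
#'
#' @param trajectory A [clamp_trajectory()].
#' @param selection Selection string (see [parse_selection()]); should
#'   resolve to one atom per residue (C-alpha).
#' @param windows A single window or list of windows as in
#'   [average_structure()]; default all frames.
#' @param superpose Superpose frames onto the window mean before measuring
#'   fluctuations (default). Set `FALSE` for frames already expressed in a
#'   common reference frame (no global motion), e.g. selections too small
#'   for a meaningful rigid fit.
#' @return Named numeric vector of RMSF values (Angstrom) per residue.
#' @export
rmsf <- function(trajectory, selection = NULL, windows = NULL,
                 superpose = TRUE) {
  stopifnot(inherits(trajectory, "clamp_trajectory"))
  sel <- parse_selection(trajectory$atoms, selection)
  if (!is.null(windows) && !is.list(windows)) windows <- list(windows)
  if (is.null(windows)) windows <- list(NULL)
  total_frames <- 0L
  sumsq <- numeric(length(sel))
  for (w in windows) {
    idx <- resolve_window(trajectory, w)
    fitted <- if (superpose) superpose_window(trajectory, idx, sel)
      else lapply(idx, function(f)
        matrix(trajectory$coords[f, sel, ], ncol = 3L))
    mean_xyz <- Reduce(`+`, fitted) / length(fitted)
    for (x in fitted) sumsq <- sumsq + rowSums((x - mean_xyz)^2)
    total_frames <- total_frames + length(fitted)
  }
  out <- sqrt(sumsq / total_frames)
  names(out) <- paste0(trajectory$atoms$chain[sel], ":",
                       trajectory$atoms$resno[sel])
  out
}

#' Cluster-wise mean and standard deviation of per-conformation RMSF
#'
#' Averages RMSF profiles across all conformations within each cluster and
#' reports mean and sample standard deviation (denominator n-1) per residue,
#' as plotted with thick (mean) and thin (sd) bars. A cluster of size one
#' gets sd 0 and is flagged.
#'
#' @param per_conformation_rmsf Matrix (conformations x residues) or list of
#'   congruent named vectors.
#' @param labels Cluster labels, one per conformation.
#' @return List of per-cluster data frames (`residue`, `mean`, `sd`) with a
#'   logical attribute `"singleton"` per cluster.
#' @export
rmsf_cluster_stats <- function(per_conformation_rmsf, labels) {
  if (is.list(per_conformation_rmsf))
    per_conformation_rmsf <- do.call(rbind, per_conformation_rmsf)
  m <- as.matrix(per_conformation_rmsf)
  if (nrow(m) != length(labels))
    stop("one label per conformation required", call. = FALSE)
  res <- colnames(m)
  if (is.null(res)) res <- as.character(seq_len(ncol(m)))
  out <- lapply(split(seq_len(nrow(m)), labels), function(rows) {
    sub <- m[rows, , drop = FALSE]
    d <- data.frame(residue = res,
                    mean = colMeans(sub),
                    sd = if (nrow(sub) > 1L) apply(sub, 2L, stats::sd)
                         else rep(0, ncol(sub)),
                    stringsAsFactors = FALSE)
    attr(d, "singleton") <- nrow(sub) == 1L
    d
  })
  out
}

golden_spiral_points <- function(n) {
  # deterministic quasi-uniform points on the unit sphere (no RNG)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic point-counting SASA: each atom's sphere of radius
#' `radius + probe` is sampled with a deterministic golden-spiral point set;
#' a point is accessible when it lies outside every neighbouring atom's
#' extended sphere. Per-atom area is the accessible fraction times
#' `4*pi*(radius + probe)^2`.
#'
#' @param structure A [clamp_structure()], or an atom data frame accepted by
#'   it.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Numeric vector of per-atom areas (squared Angstrom) with the
#'   total as attribute `"total"`; see also [buried_interface_area()].
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960L) {
  if (!inherits(structure, "clamp_structure"))
    structure <- clamp_structure(structure)
  at <- structure$atoms
  n <- nrow(at)
  if (n == 0L) {
    warning("zero atoms; SASA is 0", call. = FALSE)
    out <- numeric(0)
    attr(out, "total") <- 0
    return(out)
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ext <- at$radius + probe
  pts <- golden_spiral_points(n_points)
  areas <- numeric(n)
  # pairwise distances once; neighbours are atoms whose extended spheres
  # can intersect
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (ext[i] + ext)^2 & seq_len(n) != i)
    sphere <- pts * ext[i] +
      matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- sweep(sphere, 2L, xyz[j, ])
        buried <- buried | (rowSums(dj * dj) < ext[j]^2)
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    areas[i] <- acc / n_points * 4 * pi * ext[i]^2
  }
  names(areas) <- paste0(at$chain, ":", at$resno, ":", at$atom_name)
  attr(areas, "total") <- sum(areas)
  areas
}

#' Buried interface area between two chain sets of a complex
#'
#' `SASA(A alone) + SASA(B alone) - SASA(complex)`: the surface each partner
#' buries on forming the interface. Reported unhalved (divide by two for the
#' per-side convention).
#'
#' @param complex A [clamp_structure()] containing both chain sets.
#' @param chains_a,chains_b Disjoint character vectors of chain ids whose
#'   union covers the complex.
#' @param probe,n_points As in [sasa()].
#' @return Buried area in squared Angstrom (non-negative up to point
#'   sampling tolerance).
#' @export
buried_interface_area <- function(complex, chains_a, chains_b,
                                  probe = 1.4, n_points = 960L) {
  stopifnot(inherits(complex, "clamp_structure"))
  if (length(intersect(chains_a, chains_b)) > 0L)
    stop("chain sets must be disjoint", call. = FALSE)
  present <- unique(complex$atoms$chain)
  if (!setequal(union(chains_a, chains_b), present))
    stop("chain sets must cover the complex exactly (complex has ",
         paste(present, collapse = ", "), ")", call. = FALSE)
  sub <- function(chains)
    clamp_structure(complex$atoms[complex$atoms$chain %in% chains, ,
                                  drop = FALSE])
  sa <- attr(sasa(sub(chains_a), probe, n_points), "total")
  sb <- attr(sasa(sub(chains_b), probe, n_points), "total")
  sab <- attr(sasa(complex, probe, n_points), "total")
  sa + sb - sab
}
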