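#' Specification for a cluster-structured synthetic PIE ensemble
#'
#' Defines the ground truth of a synthetic ensemble: `k` planted clusters
#' with distinct mean PIE matrices, i.i.d. Gaussian cell noise, and one
#' planted lowest-energy ("stable") cluster. The generator stands in for the
#' simulated-annealing sampling plus quantum-chemistry energy engine so the
#' downstream clustering, selection and decomposition stages are testable
#' with known truth.
#'
#' Each generated cell's total PIE is split into PIEDA components by fixed
#' fractions; the last component (`Gsol`) is computed as the remainder so
#' the five components always close on the total to machine precision.
#'
#' @param n_ligand,n_receptor Residue counts of the two axes.
#' @param cluster_sizes Integer vector; its sum is the ensemble size.
#' @param cluster_means List of `n_ligand x n_receptor` mean matrices
#'   (kJ/mol), one per cluster.
#' @param noise_sd Gaussian cell noise, kJ/mol, `>= 0`.
#' @param stable_cluster_index Index of the planted lowest-energy cluster.
#' @param component_split Named fractions for `Ees`, `Eex`, `Ect`, `Edisp`
#'   (summing with the implied `Gsol` remainder to 1). The default
#'   (0.55/0/0/0.30, leaving 0.15 for `Gsol`) sends the total to
#'   electrostatics, dispersion and solvation with zero exchange and charge
#'   transfer, mirroring the three components reported for residue-level
#'   decompositions, with electrostatics dominant so the generated profiles
#'   have an unambiguous interaction character.
#' @param ligand_chain,receptor_chain Chain ids used on the residue axes.
#' @param seed Integer seed; identical seeds give bit-identical ensembles.
#' @return An object of class `pie_ensemble_spec`.
#' @export
pie_ensemble_spec <- function(n_ligand, n_receptor, cluster_sizes,
                              cluster_means, noise_sd,
                              stable_cluster_index,
                              component_split = c(Ees = 0.55, Eex = 0,
                                                  Ect = 0, Edisp = 0.30),
                              ligand_chain = "L", receptor_chain = "R",
                              seed = 1L) {
  cluster_sizes <- as.integer(cluster_sizes)
  if (length(cluster_sizes) == 0L || any(cluster_sizes < 1L))
    stop("'cluster_sizes' must be positive counts", call. = FALSE)
  if (!is.list(cluster_means) || length(cluster_means) != length(cluster_sizes))
    stop("'cluster_means' must be one mean matrix per cluster", call. = FALSE)
  cluster_means <- lapply(cluster_means, as.matrix)
  for (m in cluster_means)
    if (!identical(dim(m), c(as.integer(n_ligand), as.integer(n_receptor))))
      stop(sprintf("cluster mean matrices must be %d x %d",
                   n_ligand, n_receptor), call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  stable_cluster_index <- as.integer(stable_cluster_index)
  if (stable_cluster_index < 1L ||
      stable_cluster_index > length(cluster_sizes))
    stop("'stable_cluster_index' out of range", call. = FALSE)
  need <- c("Ees", "Eex", "Ect", "Edisp")
  if (!all(need %in% names(component_split)))
    stop("'component_split' needs fractions for ",
         paste(need, collapse = ", "), " (Gsol is the remainder)",
         call. = FALSE)
  structure(list(n_ligand = as.integer(n_ligand),
                 n_receptor = as.integer(n_receptor),
                 cluster_sizes = cluster_sizes,
                 cluster_means = cluster_means,
                 noise_sd = noise_sd,
                 stable_cluster_index = stable_cluster_index,
                 component_split = component_split[need],
                 ligand_chain = ligand_chain,
                 receptor_chain = receptor_chain,
                 seed = as.integer(seed)),
            class = "pie_ensemble_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic PIE ensemble with planted clusters
#'
#' Draws `sum(cluster_sizes)` PIE matrices; a matrix in cluster `c` is
#' `cluster_means[[c]]` plus i.i.d. Gaussian noise of standard deviation
#' `noise_sd` per cell. The planted labels are recorded as
#' `ground_truth` on the returned ensemble and round-trip through
#' [write_pie_table()] / [read_pie_table()].
#'
#' @param spec A [pie_ensemble_spec()].
#' @return A [pie_ensemble()] with ground-truth labels.
#' @export
generate_pie_ensemble <- function(spec) {
  stopifnot(inherits(spec, "pie_ensemble_spec"))
  ligand <- data.frame(chain = spec$ligand_chain,
                       resno = seq_len(spec$n_ligand),
                       resname = "ALA", stringsAsFactors = FALSE)
  receptor <- data.frame(chain = spec$receptor_chain,
                         resno = seq_len(spec$n_receptor),
                         resname = "GLY", stringsAsFactors = FALSE)
  labels <- rep(seq_along(spec$cluster_sizes), times = spec$cluster_sizes)
  fr <- spec$component_split
  with_seed(spec$seed, {
    mats <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      total <- spec$cluster_means[[labels[i]]]
      if (spec$noise_sd > 0)
        total <- total + matrix(stats::rnorm(length(total), 0, spec$noise_sd),
                                nrow(total), ncol(total))
      comps <- list(Ees = total * fr[["Ees"]], Eex = total * fr[["Eex"]],
                    Ect = total * fr[["Ect"]], Edisp = total * fr[["Edisp"]])
      comps$Gsol <- total - comps$Ees - comps$Eex - comps$Ect - comps$Edisp
      mats[[i]] <- pie_matrix(sprintf("conf%04d", i), ligand, receptor,
                              total, components = comps, tol = 1e-9)
    }
    pie_ensemble(mats, provenance = sprintf("synthetic seed=%d", spec$seed),
                 ground_truth = labels)
  })
}

#' Specification for a synthetic coordinate trajectory
#'
#' Residues (one pseudo-atom each, named CA) sit at fixed mean positions
#' 3.8 Angstrom apart along x; each frame displaces residue `r`
#' isotropically with per-axis standard deviation `per_residue_sd[r]/sqrt(3)`,
#' so the closed-form RMSF of residue `r` is exactly `per_residue_sd[r]`.
#' Optionally a random global rigid motion (proper rotation + translation)
#' is composed onto every frame, which superposition-based analyses must
#' remove.
#'
#' @param n_residues Residue count.
#' @param n_frames Frame count, `>= 2`.
#' @param per_residue_sd Numeric vector of target RMSF values (Angstrom),
#'   recycled to `n_residues`, all `>= 0`.
#' @param frame_interval Time between frames, ps.
#' @param rigid_motion Logical; compose a random rigid motion per frame.
#' @param chain Chain id.
#' @param seed Integer seed.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_residues, n_frames, per_residue_sd,
                            frame_interval = 1, rigid_motion = FALSE,
                            chain = "L", seed = 1L) {
  n_residues <- as.integer(n_residues)
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("'n_frames' must be >= 2", call. = FALSE)
  per_residue_sd <- rep_len(as.numeric(per_residue_sd), n_residues)
  if (any(per_residue_sd < 0)) stop("'per_residue_sd' must be >= 0",
                                    call. = FALSE)
  structure(list(n_residues = n_residues, n_frames = n_frames,
                 per_residue_sd = per_residue_sd,
                 frame_interval = frame_interval,
                 rigid_motion = isTRUE(rigid_motion),
                 chain = chain, seed = as.integer(seed)),
            class = "trajectory_spec")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Mean C-alpha positions of an idealized helical trace
#'
#' Residues sit on an alpha-helix-like spiral (2.3 Angstrom radius, 1.5
#' Angstrom rise, 100 degrees per residue), giving a non-collinear mean
#' structure suitable for rigid-body superposition.
#'
#' @param n Residue count.
#' @return `n x 3` coordinate matrix (Angstrom).
#' @export
helical_trace <- function(n) {
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
}

#' Generate a synthetic trajectory with prescribed fluctuations
#'
#' @param spec A [trajectory_spec()].
#' @return A [clamp_trajectory()]; the planted mean coordinates are attached
#'   as attribute `"mean_coords"` and the planted RMSF as `"true_rmsf"`.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  mean_xyz <- helical_trace(spec$n_residues)
  axis_sd <- spec$per_residue_sd / sqrt(3)
  with_seed(spec$seed, {
    arr <- array(NA_real_, c(spec$n_frames, spec$n_residues, 3L))
    for (f in seq_len(spec$n_frames)) {
      xyz <- mean_xyz +
        matrix(stats::rnorm(3L * spec$n_residues), ncol = 3L) * axis_sd
      if (spec$rigid_motion)
        xyz <- xyz %*% t(random_rotation()) +
          matrix(stats::rnorm(3L, 0, 10), spec$n_residues, 3L, byrow = TRUE)
      arr[f, , ] <- xyz
    }
    atoms <- data.frame(chain = spec$chain, resno = seq_len(spec$n_residues),
                        resname = "ALA", atom_name = "CA", element = "C",
                        x = mean_xyz[, 1L], y = mean_xyz[, 2L],
                        z = mean_xyz[, 3L], stringsAsFactors = FALSE)
    tr <- clamp_trajectory(arr, atoms,
                           times = (seq_len(spec$n_frames) - 1) *
                             spec$frame_interval)
    attr(tr, "mean_coords") <- mean_xyz
    attr(tr, "true_rmsf") <- spec$per_residue_sd
    tr
  })
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate random sequences with a planted motif
#'
#' Draws `n` sequences of i.i.d. background composition and plants the given
#' motif at a uniformly chosen position in a recorded subset of them;
#' returns the sequences together with the planted positions so scanner
#' recovery can be scored.
#'
#' @param n Number of sequences.
#' @param motif Residue string of length `>= 5` over the 20-letter alphabet.
#' @param length Background sequence length (0 means the motif alone).
#' @param background Named composition over the 20 amino acids (need not be
#'   normalized); default uniform.
#' @param plant_fraction Fraction of sequences carrying the motif.
#' @param seed Integer seed.
#' @return List with `sequences` (character vector), `positions` (1-based
#'   planted start, `NA` where unplanted) and `planted` (logical).
#' @export
generate_motif_sequences <- function(n, motif, length = 200,
                                     background = NULL,
                                     plant_fraction = 1, seed = 1L) {
  stopifnot(n >= 1L)
  motif_chars <- strsplit(toupper(motif), "")[[1L]]
  if (base::length(motif_chars) < 5L)
    stop("'motif' must have length >= 5", call. = FALSE)
  if (!all(motif_chars %in% AA_ALPHABET))
    stop("'motif' contains non-amino-acid letters: ",
         paste(unique(setdiff(motif_chars, AA_ALPHABET)), collapse = ", "),
         call. = FALSE)
  if (is.null(background))
    background <- stats::setNames(rep(1, 20L), AA_ALPHABET)
  bg <- background[AA_ALPHABET]
  bg[is.na(bg)] <- 0
  bg <- bg / sum(bg)
  L <- as.integer(length)
  mlen <- base::length(motif_chars)
  with_seed(seed, {
    planted <- seq_len(n) <= ceiling(plant_fraction * n)
    seqs <- character(n)
    pos <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (L == 0L) {
        seqs[i] <- paste(motif_chars, collapse = "")
        pos[i] <- 1L
        next
      }
      s <- sample(AA_ALPHABET, L, replace = TRUE, prob = bg)
      if (planted[i]) {
        p <- sample.int(L - mlen + 1L, 1L)
        s[p:(p + mlen - 1L)] <- motif_chars
        pos[i] <- p
      }
      seqs[i] <- paste(s, collapse = "")
    }
    list(sequences = seqs, positions = pos, planted = planted)
  })
}
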