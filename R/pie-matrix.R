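#' Residue-pair interaction energy matrix for one conformation
#'
#' A `pie_matrix` holds the pair-interaction energies (PIE, kJ/mol) between
#' every ligand residue and every receptor residue of a single sampled
#' conformation, optionally decomposed into the five PIEDA components:
#' electrostatic (`Ees`), exchange (`Eex`), charge transfer (`Ect`),
#' dispersion (`Edisp`) and solvation (`Gsol`). When all five components are
#' present their cellwise sum must equal the total within `tol`.
#'
#' Residue axes are data frames with columns `chain`, `resno` (1-based PDB
#' numbering) and `resname`; rows of `total` are ligand residues, columns are
#' receptor residues.
#'
#' @param conformation_id Character scalar, unique within an ensemble.
#' @param ligand,receptor Residue axis data frames (`chain`, `resno`,
#'   `resname`).
#' @param total Numeric matrix, `nrow(ligand) x nrow(receptor)`, kJ/mol.
#' @param components Optional named list of matrices `Ees`, `Eex`, `Ect`,
#'   `Edisp`, `Gsol`, each the same shape as `total`.
#' @param tol Closure tolerance in kJ/mol for `sum(components) == total`.
#'   Parsed quantum-chemistry output is checked at 0.5 kJ/mol by default;
#'   synthetic data is generated to close at 1e-9.
#' @return An object of class `pie_matrix`.
#' @export
pie_matrix <- function(conformation_id, ligand, receptor, total,
                       components = NULL, tol = 0.5) {
  stopifnot(is.character(conformation_id), length(conformation_id) == 1L)
  ligand <- validate_axis(ligand, "ligand")
  receptor <- validate_axis(receptor, "receptor")
  total <- as.matrix(total)
  if (!is.numeric(total) || any(!is.finite(total)))
    stop("'total' must be a finite numeric matrix", call. = FALSE)
  if (nrow(total) != nrow(ligand) || ncol(total) != nrow(receptor))
    stop(sprintf("'total' must be %d x %d (ligand x receptor), got %d x %d",
                 nrow(ligand), nrow(receptor), nrow(total), ncol(total)),
         call. = FALSE)
  if (!is.null(components)) {
    comp_names <- c("Ees", "Eex", "Ect", "Edisp", "Gsol")
    if (!all(names(components) %in% comp_names))
      stop("components must be named among: ", paste(comp_names, collapse = ", "),
           call. = FALSE)
    components <- lapply(components, as.matrix)
    for (nm in names(components)) {
      if (!identical(dim(components[[nm]]), dim(total)))
        stop("component '", nm, "' does not match the shape of 'total'",
             call. = FALSE)
    }
    if (all(comp_names %in% names(components))) {
      csum <- Reduce(`+`, components[comp_names])
      bad <- which(abs(csum - total) > tol, arr.ind = TRUE)
      if (nrow(bad) > 0L) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        stop(sprintf(paste0(
          "PIEDA components do not sum to total within %g kJ/mol in ",
          "conformation '%s' at cell ligand %s%d / receptor %s%d ",
          "(total %.4f, component sum %.4f)"),
          tol, conformation_id, ligand$chain[i], ligand$resno[i],
          receptor$chain[j], receptor$resno[j], total[i, j], csum[i, j]),
          call. = FALSE)
      }
    }
  }
  structure(list(conformation_id = conformation_id,
                 ligand = ligand, receptor = receptor,
                 total = total, components = components),
            class = "pie_matrix")
}

validate_axis <- function(axis, what) {
  axis <- as.data.frame(axis, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resname")
  if (!all(need %in% names(axis)))
    stop("'", what, "' axis needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  axis$chain <- as.character(axis$chain)
  axis$resno <- as.integer(axis$resno)
  axis$resname <- as.character(axis$resname)
  if (anyNA(axis$resno)) stop("'", what, "' axis has non-integer resno",
                              call. = FALSE)
  rownames(axis) <- NULL
  axis[, need]
}

#' @export
print.pie_matrix <- function(x, ...) {
  cat(sprintf("PIE matrix '%s': %d ligand x %d receptor residues%s\n",
              x$conformation_id, nrow(x$ligand), nrow(x$receptor),
              if (is.null(x$components)) "" else
                paste0(" (+", paste(names(x$components), collapse = ","), ")")))
  cat(sprintf("  total PIE: %.2f kJ/mol\n", sum(x$total)))
  invisible(x)
}

#' Ordered collection of PIE matrices with provenance metadata
#'
#' An `pie_ensemble` is an ordered list of [pie_matrix()] objects that share
#' identical residue axes, together with optional cluster-lineage metadata
#' (a string of round-wise cluster ids joined by `-`, e.g. `"6-7-2-6"`), the
#' sampling round, free-text provenance, and optional ground-truth cluster
#' labels carried by the synthetic-data generator.
#'
#' @param matrices List of [pie_matrix()] objects with unique
#'   `conformation_id`s and identical residue axes.
#' @param lineage Optional cluster-lineage string.
#' @param round Integer sampling round (default 1).
#' @param provenance Free text.
#' @param ground_truth Optional integer vector of planted cluster labels,
#'   one per conformation.
#' @return An object of class `pie_ensemble`.
#' @export
pie_ensemble <- function(matrices, lineage = NULL, round = 1L,
                         provenance = "", ground_truth = NULL) {
  stopifnot(is.list(matrices))
  if (!all(vapply(matrices, inherits, logical(1), "pie_matrix")))
    stop("'matrices' must be a list of pie_matrix objects", call. = FALSE)
  ids <- vapply(matrices, `[[`, character(1), "conformation_id")
  if (anyDuplicated(ids))
    stop("duplicate conformation_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (length(matrices) > 1L) {
    ref <- matrices[[1L]]
    for (m in matrices[-1L]) {
      if (!identical(m$ligand, ref$ligand) ||
          !identical(m$receptor, ref$receptor))
        stop("all matrices in an ensemble must share residue axes ",
             "(mismatch at conformation '", m$conformation_id, "')",
             call. = FALSE)
    }
  }
  if (!is.null(ground_truth)) {
    ground_truth <- as.integer(ground_truth)
    if (length(ground_truth) != length(matrices))
      stop("'ground_truth' must have one label per conformation",
           call. = FALSE)
  }
  structure(list(matrices = matrices, lineage = lineage,
                 round = as.integer(round), provenance = provenance,
                 ground_truth = ground_truth),
            class = "pie_ensemble")
}

#' @export
length.pie_ensemble <- function(x) length(x$matrices)

#' @export
print.pie_ensemble <- function(x, ...) {
  cat(sprintf("PIE ensemble: %d conformations", length(x)))
  if (length(x) > 0L) {
    m <- x$matrices[[1L]]
    cat(sprintf(", %d ligand x %d receptor residues",
                nrow(m$ligand), nrow(m$receptor)))
  }
  cat("\n")
  if (!is.null(x$lineage)) cat("  lineage:", x$lineage, "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  if (!is.null(x$ground_truth))
    cat("  ground truth:", length(unique(x$ground_truth)),
        "planted clusters\n")
  invisible(x)
}

#' Conformation ids of an ensemble
#' @param ensemble A [pie_ensemble()].
#' @return Character vector of conformation ids, in ensemble order.
#' @export
conformation_ids <- function(ensemble) {
  stopifnot(inherits(ensemble, "pie_ensemble"))
  vapply(ensemble$matrices, `[[`, character(1), "conformation_id")
}

#' Merge PIE ensembles sharing residue axes
#'
#' Concatenates ensembles in the given order (the first ensemble's
#' conformations come first), as when PIE datasets from consecutive sampling
#' rounds are pooled before re-clustering (e.g. merging a 300- and a
#' 180-conformation sampling into one 480-conformation dataset).
#'
#' @param ensembles List of [pie_ensemble()] objects with identical residue
#'   axes and pairwise-disjoint conformation ids.
#' @param provenance Provenance string for the merged ensemble.
#' @return A [pie_ensemble()] of size equal to the sum of the input sizes.
#' @export
merge_ensembles <- function(ensembles, provenance = "merged") {
  stopifnot(is.list(ensembles), length(ensembles) >= 1L)
  if (!all(vapply(ensembles, inherits, logical(1), "pie_ensemble")))
    stop("'ensembles' must be a list of pie_ensemble objects", call. = FALSE)
  mats <- do.call(c, lapply(ensembles, `[[`, "matrices"))
  gt <- lapply(ensembles, `[[`, "ground_truth")
  gt <- if (any(vapply(gt, is.null, logical(1)))) NULL else do.call(c, gt)
  pie_ensemble(mats, round = max(vapply(ensembles, `[[`, integer(1), "round")),
               provenance = provenance, ground_truth = gt)
}
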