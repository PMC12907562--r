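#' Write a PIE ensemble to a long-form tab-separated table
#'
#' The exchange format is long-form: one row per (conformation, ligand
#' residue, receptor residue) with columns for the total PIE and the five
#' PIEDA components (empty when absent). Ensemble metadata (lineage, round,
#' provenance, ground-truth labels) is carried in `#`-prefixed header lines,
#' so a written file round-trips losslessly through [read_pie_table()].
#'
#' @param ensemble A [pie_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_pie_table()]
#' @export
write_pie_table <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pie_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# clampconf PIE table v1", con)
  if (!is.null(ensemble$lineage))
    writeLines(paste0("# lineage: ", ensemble$lineage), con)
  writeLines(paste0("# round: ", ensemble$round), con)
  if (nzchar(ensemble$provenance))
    writeLines(paste0("# provenance: ", ensemble$provenance), con)
  if (!is.null(ensemble$ground_truth))
    writeLines(paste0("# ground_truth: ",
                      paste(conformation_ids(ensemble), ensemble$ground_truth,
                            sep = "=", collapse = ",")), con)
  cols <- c("conformation_id", "ligand_chain", "ligand_resno",
            "ligand_resname", "receptor_chain", "receptor_resno",
            "receptor_resname", "total", "Ees", "Eex", "Ect", "Edisp", "Gsol")
  writeLines(paste(cols, collapse = "\t"), con)
  comp_names <- c("Ees", "Eex", "Ect", "Edisp", "Gsol")
  for (m in ensemble$matrices) {
    nl <- nrow(m$ligand); nr <- nrow(m$receptor)
    li <- rep(seq_len(nl), times = nr)  # column-major flatten matches c(total)
    rj <- rep(seq_len(nr), each = nl)
    df <- data.frame(
      conformation_id = m$conformation_id,
      ligand_chain = m$ligand$chain[li],
      ligand_resno = m$ligand$resno[li],
      ligand_resname = m$ligand$resname[li],
      receptor_chain = m$receptor$chain[rj],
      receptor_resno = m$receptor$resno[rj],
      receptor_resname = m$receptor$resname[rj],
      total = format_energy(c(m$total)),
      stringsAsFactors = FALSE)
    for (nm in comp_names) {
      df[[nm]] <- if (!is.null(m$components) && nm %in% names(m$components))
        format_energy(c(m$components[[nm]])) else ""
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

format_energy <- function(x) formatC(x, format = "g", digits = 17)

#' Read a PIE ensemble from a long-form table
#'
#' Parses the tab-separated format written by [write_pie_table()].
#' Conformation and residue order is taken from first appearance in the
#' file; nothing is silently reordered. Rows whose five PIEDA components do
#' not sum to the total within `tol` raise an error naming the offending
#' cell and line.
#'
#' @param path File path.
#' @param tol Component-closure tolerance in kJ/mol (default 0.5, suitable
#'   for parsed quantum-chemistry engine output).
#' @return A [pie_ensemble()].
#' @export
read_pie_table <- function(path, tol = 0.5) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list(lineage = NULL, round = 1L, provenance = "",
               ground_truth = NULL)
  for (h in lines[hdr]) {
    kv <- sub("^#\\s*", "", h)
    if (grepl("^lineage:", kv)) meta$lineage <- trimws(sub("^lineage:", "", kv))
    if (grepl("^round:", kv)) meta$round <- as.integer(trimws(sub("^round:", "", kv)))
    if (grepl("^provenance:", kv))
      meta$provenance <- trimws(sub("^provenance:", "", kv))
    if (grepl("^ground_truth:", kv)) {
      pairs <- strsplit(trimws(sub("^ground_truth:", "", kv)), ",")[[1L]]
      kvp <- strsplit(pairs, "=")
      meta$ground_truth <- stats::setNames(
        as.integer(vapply(kvp, `[`, character(1), 2L)),
        vapply(kvp, `[`, character(1), 1L))
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  if (length(body) == 0L || !nzchar(body[1L]))
    stop("no header row found in '", path, "'", call. = FALSE)
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("conformation_id", "ligand_chain", "ligand_resno",
            "ligand_resname", "receptor_chain", "receptor_resno",
            "receptor_resname", "total")
  if (!all(need %in% cols))
    stop("PIE table '", path, "' is missing columns: ",
         paste(setdiff(need, cols), collapse = ", "), call. = FALSE)
  if (length(body) == 1L)
    return(pie_ensemble(list(), lineage = meta$lineage, round = meta$round,
                        provenance = meta$provenance))
  df <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  # line numbers in the original file, for error messages
  body_line_of <- setdiff(seq_along(lines), hdr)[-1L]
  num <- function(col, required) {
    if (!col %in% names(df)) return(NULL)
    x <- df[[col]]
    if (!required && all(!nzchar(x))) return(NULL)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.finite(v) & nzchar(x) | (!nzchar(x) & required))
    if (length(bad) > 0L)
      stop(sprintf("unparseable %s value '%s' at line %d of '%s'",
                   col, x[bad[1L]], body_line_of[bad[1L]], path),
           call. = FALSE)
    v
  }
  df$total_num <- num("total", TRUE)
  comp_names <- c("Ees", "Eex", "Ect", "Edisp", "Gsol")
  comp_cols <- list()
  for (nm in comp_names) comp_cols[[nm]] <- num(nm, FALSE)
  have_comps <- !vapply(comp_cols, is.null, logical(1))

  ids <- unique(df$conformation_id)
  lig_key <- paste(df$ligand_chain, df$ligand_resno, df$ligand_resname,
                   sep = "\r")
  rec_key <- paste(df$receptor_chain, df$receptor_resno, df$receptor_resname,
                   sep = "\r")
  first <- df$conformation_id == ids[1L]
  lig_levels <- unique(lig_key[first])
  rec_levels <- unique(rec_key[first])
  unkey <- function(k) {
    parts <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    data.frame(chain = parts[, 1L], resno = as.integer(parts[, 2L]),
               resname = parts[, 3L], stringsAsFactors = FALSE)
  }
  ligand <- unkey(lig_levels)
  receptor <- unkey(rec_levels)
  nl <- nrow(ligand); nr <- nrow(receptor)
  li <- match(lig_key, lig_levels)
  rj <- match(rec_key, rec_levels)
  if (anyNA(li) || anyNA(rj)) {
    bad <- which(is.na(li) | is.na(rj))[1L]
    stop(sprintf("residue axes differ between conformations at line %d of '%s'",
                 body_line_of[bad], path), call. = FALSE)
  }
  mats <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sel <- which(df$conformation_id == ids[k])
    if (length(sel) != nl * nr)
      stop(sprintf("conformation '%s' has %d rows, expected %d (%d x %d)",
                   ids[k], length(sel), nl * nr, nl, nr), call. = FALSE)
    idx <- cbind(li[sel], rj[sel])
    if (anyDuplicated(idx) > 0L)
      stop(sprintf("duplicate cell for conformation '%s' near line %d of '%s'",
                   ids[k], body_line_of[sel[anyDuplicated(idx)]], path),
           call. = FALSE)
    total <- matrix(NA_real_, nl, nr)
    total[idx] <- df$total_num[sel]
    comps <- NULL
    if (all(have_comps)) {
      comps <- lapply(comp_names, function(nm) {
        m <- matrix(NA_real_, nl, nr); m[idx] <- comp_cols[[nm]][sel]; m
      })
      names(comps) <- comp_names
      csum <- Reduce(`+`, comps)
      off <- abs(csum - total) > tol
      if (any(off)) {
        cell <- which(off, arr.ind = TRUE)[1L, ]
        row_in_sel <- sel[which(li[sel] == cell[1L] & rj[sel] == cell[2L])]
        stop(sprintf(paste0(
          "PIEDA components sum to %.4f but total is %.4f (tolerance %g ",
          "kJ/mol) for conformation '%s', ligand %s%d / receptor %s%d, ",
          "line %d of '%s'"),
          csum[cell[1L], cell[2L]], total[cell[1L], cell[2L]], tol, ids[k],
          ligand$chain[cell[1L]], ligand$resno[cell[1L]],
          receptor$chain[cell[2L]], receptor$resno[cell[2L]],
          body_line_of[row_in_sel], path), call. = FALSE)
      }
    } else if (any(have_comps)) {
      comps <- lapply(comp_cols[have_comps], function(v) {
        m <- matrix(NA_real_, nl, nr); m[idx] <- v[sel]; m
      })
    }
    mats[[k]] <- pie_matrix(ids[k], ligand, receptor, total,
                            components = comps, tol = tol)
  }
  gt <- NULL
  if (!is.null(meta$ground_truth)) gt <- unname(meta$ground_truth[ids])
  pie_ensemble(mats, lineage = meta$lineage, round = meta$round,
               provenance = meta$provenance, ground_truth = gt)
}

#' Load a table of binding free energies
#'
#' Reads a CSV with columns `ligand_label`, `receptor_label`, `dg_bind`
#' (kJ/mol), optional `buried_area` (squared Angstrom) and `source`. The
#' packaged fixture [dg_table()] mirrors the published 13-row summary of
#' ligand-peptide binding free energies on the 9-1-1 core ring.
#'
#' @param path CSV file path.
#' @return A data frame, one row per ligand-receptor interface.
#' @export
load_dg_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(df)
  need <- c("ligand_label", "receptor_label", "dg_bind")
  if (!all(need %in% names(df)))
    stop("ΔG table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$dg_bind) || anyNA(df$dg_bind))
    stop("non-numeric dg_bind value in '", path, "'", call. = FALSE)
  df
}

#' Packaged binding-free-energy fixture
#'
#' The 13 published ligand/receptor interfaces on the 9-1-1 core-ring
#' structure with their FMO3-derived binding free energies (kJ/mol) and
#' buried surface areas; used as the input to the state-transition ledger
#' ([build_state_ledger()]).
#'
#' @return Data frame with 13 rows.
#' @export
dg_table <- function() {
  load_dg_table(system.file("extdata", "table12_dg.csv",
                            package = "clampconf", mustWork = TRUE))
}
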