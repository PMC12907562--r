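#' Per-residue energy decomposition over a cluster
#'
#' For each ligand residue `i`, sums the PIE (and the PIEDA components Ees,
#' Edisp, Gsol when present) over all receptor residues `j` in each cluster
#' member, then reports mean and sample standard deviation across members:
#' the contribution of each ligand residue to the overall interaction.
#'
#' @param ensemble A [pie_ensemble()].
#' @param members Conformation ids or indices belonging to the cluster.
#' @param ligand_range,receptor_range Range strings as in
#'   [build_features()].
#' @return Data frame, one row per ligand residue, with `chain`, `resno`,
#'   `resname` and `<comp>_mean` / `<comp>_sd` columns for `total`, `Ees`,
#'   `Edisp`, `Gsol`. A warning is raised when components are present but do
#'   not close on the total.
#' @export
residue_profile <- function(ensemble, members = NULL,
                            ligand_range = NULL, receptor_range = NULL) {
  stopifnot(inherits(ensemble, "pie_ensemble"))
  ids <- conformation_ids(ensemble)
  if (is.null(members)) members <- ids
  idx <- if (is.numeric(members)) as.integer(members)
         else match(members, ids)
  if (anyNA(idx) || length(idx) == 0L)
    stop("cluster members not found in the ensemble", call. = FALSE)
  ax <- ensemble$matrices[[1L]]
  li <- range_indices(ax$ligand, ligand_range, "ligand")
  rj <- range_indices(ax$receptor, receptor_range, "receptor")
  comps <- c("total", "Ees", "Edisp", "Gsol")
  rows <- function(m, comp) {
    mat <- if (comp == "total") m$total else m$components[[comp]]
    if (is.null(mat)) return(rep(NA_real_, length(li)))
    rowSums(mat[li, rj, drop = FALSE])
  }
  out <- data.frame(chain = ax$ligand$chain[li],
                    resno = ax$ligand$resno[li],
                    resname = ax$ligand$resname[li],
                    stringsAsFactors = FALSE)
  for (comp in comps) {
    per_conf <- vapply(ensemble$matrices[idx], rows, numeric(length(li)),
                       comp = comp)
    per_conf <- matrix(per_conf, nrow = length(li))
    out[[paste0(comp, "_mean")]] <- rowMeans(per_conf)
    out[[paste0(comp, "_sd")]] <- if (length(idx) > 1L)
      apply(per_conf, 1L, stats::sd) else rep(0, length(li))
  }
  has_comp <- !anyNA(out$Ees_mean) && !anyNA(out$Edisp_mean) &&
    !anyNA(out$Gsol_mean)
  if (has_comp) {
    m1 <- ensemble$matrices[[idx[1L]]]
    full <- all(c("Ees", "Eex", "Ect", "Edisp", "Gsol") %in%
                names(m1$components))
    zero_xt <- full &&
      all(abs(m1$components$Eex[li, rj]) < 1e-9) &&
      all(abs(m1$components$Ect[li, rj]) < 1e-9)
    if (zero_xt) {
      gap <- abs(out$Ees_mean + out$Edisp_mean + out$Gsol_mean -
                 out$total_mean)
      if (any(gap > 1e-6))
        warning("component profile does not close on the total profile ",
                "(max gap ", format(max(gap)), " kJ/mol)", call. = FALSE)
    }
  }
  out
}

#' Classify a residue's interaction character from PIEDA components
#'
#' Labels each ligand residue `"electrostatic"`, `"dispersion/solvation"` or
#' `"indeterminate"` from its summed component energies (kJ/mol). The net
#' electrostatic contribution is `Ees` plus any positive (unfavourable)
#' `Gsol` — the desolvation penalty that screens a charge-charge contact —
#' while the dispersion/solvation side is `Edisp` plus any negative
#' (favourable) `Gsol`. Whichever net term is negative and more favourable
#' wins; ties and cases where neither net term is attractive are
#' indeterminate. With the published component sums this reproduces the
#' qualitative calls: e.g. a lysine with Ees -220, Edisp -12, Gsol +107 is
#' electrostatic, and a leucine with Ees -6, Edisp -13, Gsol -10 is
#' dispersion/solvation.
#'
#' @param ees,edisp,gsol Component energies, kJ/mol (vectorized).
#' @return Character vector of labels.
#' @export
classify_interaction <- function(ees, edisp, gsol) {
  n <- max(length(ees), length(edisp), length(gsol))
  ees <- rep_len(ees, n); edisp <- rep_len(edisp, n)
  gsol <- rep_len(gsol, n)
  electro_net <- ees + pmax(gsol, 0)
  disp_net <- edisp + pmin(gsol, 0)
  out <- rep("indeterminate", n)
  out[electro_net < 0 & electro_net < disp_net] <- "electrostatic"
  out[disp_net < 0 & disp_net < electro_net] <- "dispersion/solvation"
  out
}

#' Identify anchoring residues from RMSF and energy profiles
#'
#' Anchoring residues are conformationally stable and energetically
#' engaged: RMSF at or below the segment's `rmsf_quantile` quantile
#' (degenerate all-equal profiles pass every residue) and absolute mean
#' summed PIE at or above `energy_floor`.
#'
#' @param rmsf_profile Named numeric vector of per-residue RMSF (Angstrom).
#' @param energy_profile Numeric vector of per-residue mean summed PIE
#'   (kJ/mol) on the same residue axis, or a [residue_profile()] data frame
#'   (its `total_mean` column is used).
#' @param rmsf_quantile Quantile cut for "low RMSF" (default 0.25).
#' @param energy_floor Minimum |mean PIE| in kJ/mol (default 10).
#' @return Character vector of anchoring residue names (or indices as
#'   names when unnamed).
#' @export
anchor_residues <- function(rmsf_profile, energy_profile,
                            rmsf_quantile = 0.25, energy_floor = 10) {
  if (is.data.frame(energy_profile)) {
    nm <- paste0(energy_profile$chain, ":", energy_profile$resno)
    energy_profile <- stats::setNames(energy_profile$total_mean, nm)
  }
  if (length(energy_profile) == 0L) return(character(0))
  if (length(rmsf_profile) != length(energy_profile))
    stop("RMSF and energy profiles must share the residue axis",
         call. = FALSE)
  if (!is.null(names(rmsf_profile)) && !is.null(names(energy_profile)) &&
      !identical(names(rmsf_profile), names(energy_profile)))
    stop("RMSF and energy profiles must share the residue axis",
         call. = FALSE)
  cut <- stats::quantile(rmsf_profile, rmsf_quantile, names = FALSE)
  low <- rmsf_profile <= cut
  energetic <- abs(energy_profile) >= energy_floor
  nm <- names(energy_profile)
  if (is.null(nm)) nm <- as.character(seq_along(energy_profile))
  nm[low & energetic]
}

#' Binding free energy from component free energies
#'
#' `dG_bind = G_complex - (G_receptor + G_ligand)`, all in kJ/mol.
#'
#' @param g_complex,g_receptor,g_ligand Free energies, kJ/mol (vectorized).
#' @return Binding free energy, kJ/mol.
#' @export
delta_g_bind <- function(g_complex, g_receptor, g_ligand) {
  g_complex - (g_receptor + g_ligand)
}

#' A named checkpoint state of the clamp's ligand occupancies
#'
#' One intermediate of the checkpoint cycle: a set of occupancies, each a
#' ligand segment bound to one receptor surface (Rad9 front pocket, Hus1
#' groove, or Rad1 surface) with its binding free energy. A surface may
#' carry several segments of the same ligand (e.g. two Rhino segments on
#' Rad1) but never two different ligands.
#'
#' @param name State name (e.g. `"A"`, `"C"`, `"F"`).
#' @param occupancies Data frame with columns `ligand_label`, `surface`,
#'   `dg_bind` (kJ/mol); zero rows allowed.
#' @param description Free text.
#' @param hypothetical Logical; the state's total is bookkeeping only (its
#'   simultaneous occupancies may be sterically impossible).
#' @param partially_specified Logical; the occupancy set is reconstructed
#'   from narrative rather than fully printed values.
#' @return Object of class `interface_state`.
#' @export
interface_state <- function(name, occupancies, description = "",
                            hypothetical = FALSE,
                            partially_specified = FALSE) {
  occupancies <- as.data.frame(occupancies, stringsAsFactors = FALSE)
  if (nrow(occupancies) > 0L) {
    need <- c("ligand_label", "surface", "dg_bind")
    if (!all(need %in% names(occupancies)))
      stop("occupancies need columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(!is.finite(occupancies$dg_bind)))
      stop("non-finite dg_bind in state ", name, call. = FALSE)
    per_surface <- tapply(occupancies$ligand_label, occupancies$surface,
                          function(x) length(unique(x)))
    if (any(per_surface > 1L))
      stop("state ", name, ": more than one ligand on surface ",
           paste(names(per_surface)[per_surface > 1L], collapse = ", "),
           call. = FALSE)
  }
  structure(list(name = name, occupancies = occupancies,
                 description = description,
                 hypothetical = isTRUE(hypothetical),
                 partially_specified = isTRUE(partially_specified)),
            class = "interface_state")
}

#' @export
print.interface_state <- function(x, ...) {
  cat(sprintf("State %s%s: total %.0f kJ/mol\n", x$name,
              if (x$hypothetical) " (hypothetical)" else "",
              state_total(x)))
  if (nrow(x$occupancies) > 0L)
    print(x$occupancies, row.names = FALSE)
  invisible(x)
}

#' Total binding free energy of a checkpoint state
#'
#' Sum of the state's occupancy binding free energies across all interfaces
#' (e.g. the three Rhino interfaces -610, -482, -381 kJ/mol sum to -1473).
#' An empty state totals 0.
#'
#' @param state An [interface_state()].
#' @return Total, kJ/mol.
#' @export
state_total <- function(state) {
  stopifnot(inherits(state, "interface_state"))
  if (nrow(state$occupancies) == 0L) return(0)
  sum(state$occupancies$dg_bind)
}

#' Binding-energy change of a state transition
#'
#' `state_total(to) - state_total(from)`. When a `reference` state is given
#' both totals are first expressed relative to it; the reference cancels, so
#' the result is identical either way (asserted).
#'
#' @param from,to [interface_state()] objects sharing the same free-energy
#'   table.
#' @param reference Optional [interface_state()].
#' @return Energy change, kJ/mol.
#' @export
transition_delta <- function(from, to, reference = NULL) {
  raw <- state_total(to) - state_total(from)
  if (!is.null(reference)) {
    ref <- state_total(reference)
    rel <- (state_total(to) - ref) - (state_total(from) - ref)
    stopifnot(isTRUE(all.equal(rel, raw)))
  }
  raw
}

#' Build the checkpoint-cycle state ledger
#'
#' Constructs the ordered interface states A-H of the checkpoint cycle
#' (default / Rad17 recruitment / Rad17-bound / Rhino insertion /
#' Rhino-bound / polymerized / depolymerized) from the packaged occupancy
#' map and a binding-free-energy table, and reports each state's absolute
#' total and its total relative to state A. States whose occupancies are
#' not fully determined by printed interface energies are flagged
#' `partially_specified`; the insertion state E is additionally flagged
#' `hypothetical` (its simultaneous occupancies may clash sterically) and
#' should not be used for quantitative comparisons.
#'
#' @param dg Data frame from [load_dg_table()] / [dg_table()], with an
#'   `interface` key column matching the occupancy map.
#' @param occupancy_path Path to the occupancy-map CSV; defaults to the
#'   packaged map.
#' @return Object of class `state_ledger`: `states` (named list of
#'   [interface_state()]), `table` (data frame with `state`, `total`,
#'   `relative_total`, `hypothetical`, `partially_specified`).
#' @export
build_state_ledger <- function(dg = dg_table(), occupancy_path = NULL) {
  if (is.null(occupancy_path))
    occupancy_path <- system.file("extdata", "table13_occupancy.csv",
                                  package = "clampconf", mustWork = TRUE)
  occ <- utils::read.csv(occupancy_path, stringsAsFactors = FALSE)
  need <- c("state", "surface", "ligand_label", "interface")
  if (!all(need %in% names(occ)))
    stop("occupancy map needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"interface" %in% names(dg))
    dg$interface <- paste(dg$ligand_label, dg$receptor_label, sep = " & ")
  hit <- match(occ$interface, dg$interface)
  if (anyNA(hit))
    stop("free-energy table has no entry for interface(s): ",
         paste(unique(occ$interface[is.na(hit)]), collapse = "; "),
         call. = FALSE)
  occ$dg_bind <- dg$dg_bind[hit]
  states <- lapply(split(occ, occ$state), function(s) {
    interface_state(s$state[1L],
                    s[, c("ligand_label", "surface", "dg_bind")],
                    description = if ("description" %in% names(s))
                      s$description[1L] else "",
                    hypothetical = isTRUE(any(s$hypothetical == 1)),
                    partially_specified =
                      isTRUE(any(s$partially_specified == 1)))
  })
  states <- states[order(names(states))]
  totals <- vapply(states, state_total, numeric(1))
  if (!"A" %in% names(states))
    stop("occupancy map must define reference state A", call. = FALSE)
  tab <- data.frame(state = names(states),
                    total = unname(totals),
                    relative_total = unname(totals - totals[["A"]]),
                    hypothetical = vapply(states, `[[`, logical(1),
                                          "hypothetical"),
                    partially_specified = vapply(states, `[[`, logical(1),
                                                 "partially_specified"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(states = states, table = tab), class = "state_ledger")
}

#' @export
print.state_ledger <- function(x, ...) {
  cat("Checkpoint interface-state ledger (kJ/mol):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
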