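test_that("residue profiles reduce to row sums with zero sd for one conformation", {
  ax <- data.frame(chain = "L", resno = 1:2, resname = "ALA")
  rx <- data.frame(chain = "R", resno = 1:3, resname = "GLY")
  total <- rbind(c(-1, -2, -2), c(-3, -2, -2))
  m <- pie_matrix("only", ax, rx, total)
  ens <- pie_ensemble(list(m))
  prof <- residue_profile(ens)
  expect_equal(prof$total_mean, c(-5, -7))
  expect_equal(prof$total_sd, c(0, 0))
})

test_that("residue profiles match a loop-summation oracle and close on totals", {
  ens <- generate_pie_ensemble(make_spec(sizes = c(8L, 8L), seed = 81L,
                                         totals = c(-200, -80)))
  members <- conformation_ids(ens)[ens$ground_truth == 1L]
  prof <- residue_profile(ens, members)
  # loop oracle
  for (comp in c("total", "Ees", "Edisp", "Gsol")) {
    for (li in seq_len(nrow(prof))) {
      vals <- vapply(members, function(id) {
        m <- ens$matrices[[match(id, conformation_ids(ens))]]
        mat <- if (comp == "total") m$total else m$components[[comp]]
        acc <- 0
        for (rj in seq_len(ncol(mat))) acc <- acc + mat[li, rj]
        acc
      }, numeric(1))
      expect_equal(prof[[paste0(comp, "_mean")]][li], mean(vals),
                   tolerance = 1e-12)
      expect_equal(prof[[paste0(comp, "_sd")]][li], stats::sd(vals),
                   tolerance = 1e-12)
    }
  }
  # closure: sum of per-residue total means = cluster mean of total PIE
  totals <- total_pie(ens)[members]
  expect_equal(sum(prof$total_mean), mean(totals), tolerance = 1e-9)
  # and the component profile closes on the total profile
  expect_equal(prof$Ees_mean + prof$Edisp_mean + prof$Gsol_mean,
               prof$total_mean, tolerance = 1e-9)
})

test_that("interaction classification follows net electrostatic vs dispersion/solvation dominance", {
  # lysine-like salt bridge: huge Ees paying a desolvation penalty
  expect_equal(classify_interaction(-220, -12, 107), "electrostatic")
  # leucine-like hydrophobic anchor
  expect_equal(classify_interaction(-6, -13, -10), "dispersion/solvation")
  expect_equal(classify_interaction(0, 0, 0), "indeterminate")
  # acidic residue with repulsive Ees rescued by favourable solvation
  expect_equal(classify_interaction(51, -7, -63), "dispersion/solvation")
  expect_equal(classify_interaction(10, 2, 5), "indeterminate")
  # vectorized
  expect_equal(classify_interaction(c(-220, -6), c(-12, -13), c(107, -10)),
               c("electrostatic", "dispersion/solvation"))
})

test_that("anchor residues are the low-RMSF, energetically engaged ones", {
  r <- c(a = 0.2, b = 1.5, c = 0.25, d = 2.0)
  e <- c(a = -80, b = -90, c = -4, d = -2)
  # a and c pass the 25% RMSF quantile; only a clears the energy floor
  expect_equal(anchor_residues(r, e), "a")
  # planted two low-RMSF energetic residues
  r2 <- c(a = 0.2, b = 1.5, c = 0.21, d = 2.0, e = 1.4, f = 1.9, g = 2.2,
          h = 1.8)
  e2 <- c(a = -80, b = -5, c = -55, d = -2, e = -3, f = -1, g = -2, h = -4)
  expect_equal(anchor_residues(r2, e2), c("a", "c"))
  # degenerate tie: flat RMSF passes every residue
  flat <- rep(1, 4); names(flat) <- letters[1:4]
  e3 <- c(a = -1, b = -50, c = -2, d = -3); names(e3) <- letters[1:4]
  expect_equal(anchor_residues(flat, e3), "b")
  expect_equal(anchor_residues(numeric(0), numeric(0)), character(0))
  expect_error(anchor_residues(r, e2), "share the residue axis")
})

test_that("binding free energy arithmetic is g_complex minus parts", {
  expect_equal(delta_g_bind(-10, -4, -3), -3)
  expect_equal(delta_g_bind(5, 5, 0), 0)
  set.seed(82)
  g <- matrix(rnorm(30), ncol = 3)
  expect_equal(delta_g_bind(g[, 1], g[, 2], g[, 3]),
               g[, 1] - g[, 2] - g[, 3])
})

test_that("interface states enforce one ligand per surface and sum their energies", {
  empty <- interface_state("X", data.frame(ligand_label = character(0),
                                           surface = character(0),
                                           dg_bind = numeric(0)))
  expect_equal(state_total(empty), 0)

  two_segments <- interface_state("F", data.frame(
    ligand_label = "Rhino", surface = c("Rad1 surface", "Rad1 surface"),
    dg_bind = c(-482, -381)))
  expect_equal(state_total(two_segments), -863)

  expect_error(interface_state("bad", data.frame(
    ligand_label = c("Rhino", "Rad17"),
    surface = c("Rad1 surface", "Rad1 surface"),
    dg_bind = c(-482, -293))), "more than one ligand")
})

test_that("transition deltas are antisymmetric and reference-independent", {
  a <- interface_state("A", data.frame(ligand_label = "x", surface = "s1",
                                       dg_bind = -100))
  b <- interface_state("B", data.frame(ligand_label = "y", surface = "s1",
                                       dg_bind = -250))
  expect_equal(transition_delta(a, b), -150)
  expect_equal(transition_delta(b, a), 150)
  expect_equal(transition_delta(a, a), 0)
  ref <- interface_state("R", data.frame(ligand_label = "z", surface = "s2",
                                         dg_bind = -40))
  expect_equal(transition_delta(a, b, reference = ref),
               transition_delta(a, b))
})

test_that("the checkpoint-state ledger reproduces the printed bookkeeping", {
  led <- build_state_ledger()
  tab <- led$table
  expect_setequal(tab$state, LETTERS[1:8])
  # reference state: the clamp's own tail occupies Rad9 and Hus1
  expect_equal(state_total(led$states$A), -461 + -635)
  expect_equal(tab$relative_total[tab$state == "A"], 0)
  # relative totals are absolute totals shifted by state A
  expect_equal(tab$relative_total, tab$total - tab$total[tab$state == "A"])
  # the insertion state is bookkeeping only
  expect_true(tab$hypothetical[tab$state == "E"])
  expect_true(all(tab$partially_specified[tab$state %in% c("B", "D", "E")]))
  expect_false(any(tab$partially_specified[tab$state %in%
                                           c("A", "C", "F", "G", "H")]))
  # a missing interface label is reported by name
  dg_short <- dg_table()
  dg_short <- dg_short[dg_short$ligand_label != "Rad17-iVERGE", ]
  expect_error(build_state_ledger(dg_short), "Rad17-iVERGE")
})
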