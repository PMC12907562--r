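---
title: "Identifying stable peptide-binding conformations from interaction-energy ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying stable peptide-binding conformations from interaction-energy ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampconf)
```

## The problem

Short, largely disordered peptide segments — the Rad17 KYxxL motif, the two
KYxxL+ motifs of Rhino, the Rad9 C-terminal tail, the p21 C-terminus — bind
the 9-1-1 DNA-damage clamp (Rad9-Hus1-Rad1) at a small number of surfaces:
the Rad9 front pocket, a basic/hydrophobic groove on Hus1, and the Rad1
outer surface. Molecular-dynamics sampling of such a peptide on the clamp
produces hundreds of candidate bound conformations; fragment-based quantum
chemistry then assigns each conformation a matrix of residue-residue
pair-interaction energies (PIE, kJ/mol) between the peptide and the
receptor, optionally decomposed (PIEDA) into electrostatic (Ees), exchange
(Eex), charge-transfer (Ect), dispersion (Edisp) and solvation (Gsol)
components. `clampconf` takes these matrices as its input and answers:
which sampled conformations form a reproducible, energetically stable
binding mode, which peptide residues anchor it, and how the clamp's ligand
occupancies trade off energetically as the checkpoint cycle progresses.

The MD engine and the quantum-chemistry engine are deliberately out of
scope: their outputs are consumed as data, and a synthetic-data module with
known ground truth stands in for them so that every stage of the pipeline
is testable.

## Conformational fingerprints and clustering

Each conformation's PIE matrix, restricted to declared ligand and receptor
residue ranges, is flattened ligand-major into a feature vector
(`build_features()`); raw kJ/mol values are used without standardization so
that strongly interacting cells dominate the geometry, which is the
intended behaviour. Conformations are grouped by agglomerative hierarchical
clustering (`pie_cluster()`), by default the Ward criterion on Euclidean
distances (`stats::hclust(method = "ward.D2")` on unsquared distances).
Neither the linkage nor the metric is forced by the underlying science, so
both are configuration inputs recorded in every report; the defaults were
chosen once to match the common default of the clustering implementations
used in this field. The cluster count `k` is always a user input, never
auto-selected: the analyses this package supports use widely different `k`
(from 10 to 60) depending on how finely a binding surface is being
dissected.

Cluster labels are integers `1..k` in `stats::cutree()` order. Lineage
strings produced by iterative refinement join the per-round selected
cluster ids with `-` (e.g. `"6-7-2-6"`), naming the path of re-seeded
sampling rounds that produced a conformation family.

## Stability ranking and multiple comparison

For each conformation the total interaction energy is the double sum over
matrix cells, `sum_i sum_j PIE[i, j]` (`total_pie()`); per-cluster
summaries report n, mean, median, sample sd and the 25th/75th percentiles
(`summarize_clusters()`). The most stable cluster is the one with the
lowest mean (or, configurably, median) total PIE.

Whether the lowest cluster is *distinguishably* lowest is decided by the
Tukey-Kramer all-pairs procedure (`tukey_kramer()`): for groups a, b the
studentized-range statistic

    q_ab = |mean_a - mean_b| / sqrt( MSW/2 * (1/n_a + 1/n_b) )

is compared against the studentized-range quantile `qtukey(1 - alpha, k,
N - k)` with the pooled within-cluster mean square MSW. Base R's
`qtukey()`/`ptukey()` evaluate the studentized-range distribution by
numerical integration; the unit tests additionally check the critical
value against a 200,000-draw Monte-Carlo oracle, and the acceptance suite
verifies that the procedure's family-wise error under a null of five
groups of ten standard normals is the nominal 5% (within Monte-Carlo
tolerance). Group letters come from an insert-and-absorb compact-letter
display (`compact_letters()`): clusters sharing no letter differ
significantly; clusters sharing a letter do not.

`select_stable()` returns the argmin cluster plus every cluster not
significantly different from it — binding modes the data cannot rank. An
optional `top_m` pre-selection by lowest median supports the workflow
where only the few lowest clusters are carried into testing. Ties on the
rank statistic break by lower median, then lower cluster id, so selection
is fully deterministic. A per-cluster comparison against a reference
cluster (`compare_to_reference()`) implements the two-sample alternative
used when many small clusters make the all-pairs procedure inappropriate:
two-sided t-test, choosing Welch over Student when an F-test rejects
variance equality at 0.05 (the "auto" policy; both variants can be
forced).

Iterative refinement (`iterative_refine()`) alternates sampling and
selection: each round clusters a freshly sampled ensemble, selects the
stable cluster, and seeds the next round from that cluster's
minimum-total-PIE conformation. It stops after the configured number of
rounds or when the selected cluster's mean total PIE improves by less than
`tol` (default 1 kJ/mol — well under the kT-scale differences that matter
here).

## Per-residue decomposition and interaction character

Within a stable cluster, `residue_profile()` reports for each ligand
residue i the mean and sample sd (over cluster members) of the row sums
`sum_j PIE[i, j]` and of the corresponding Ees, Edisp and Gsol sums. The
per-residue totals close on the cluster mean of the total PIE, which the
tests assert to 1e-9 on synthetic data.

`classify_interaction()` turns a residue's component sums into a
qualitative character. The rule is this package's formalization of how
such decompositions are read in practice:

* net electrostatic contribution: `Ees + max(Gsol, 0)` — a charge-charge
  contact pays its desolvation penalty, so unfavourable solvation screens
  Ees;
* net dispersion/solvation contribution: `Edisp + min(Gsol, 0)` —
  favourable solvation accompanies hydrophobic burial and is credited to
  this side;
* the more negative net term wins; if neither is negative, or they tie,
  the residue is `indeterminate`.

A magnitude-only comparison of |Ees| against |Edisp| (ignoring the sign of
Gsol on the electrostatic side) was considered and rejected: it mislabels
hydrophobic anchors whose raw Ees is moderately negative but fully
cancelled by desolvation (an isoleucine with Ees -17, Edisp -12, Gsol +6
is a hydrophobic-groove residue, not a salt bridge). The net-component
rule reproduces the published qualitative calls for all the clamp-ligand
decompositions the package's acceptance suite encodes — lysine/arginine
salt bridges into the acidic subpocket as electrostatic, the
leucine/phenylalanine anchors of the hydrophobic subpocket as
dispersion/solvation.

Anchoring residues (`anchor_residues()`) are those both conformationally
quiet and energetically engaged: RMSF at or below the segment's 0.25
quantile and |mean row-sum PIE| of at least 10 kJ/mol. Both thresholds are
configurable; the defaults were fixed once against synthetic look-alike
profiles. A degenerate all-equal RMSF profile passes every residue, so the
energy floor alone decides.

## Geometry: superposition, RMSF, SASA, buried area

`kabsch_superpose()` computes the least-squares rigid transform by SVD of
the weighted covariance matrix, with the determinant correction that
guarantees a proper rotation; fewer than three points or collinear
geometry is an error. `average_structure()` superposes every frame of a
window onto the window's first frame and averages coordinates — the
standard construction of one averaged conformation per annealing-cycle
equilibration phase.

`rmsf()` measures, per residue, the root-mean-square deviation from the
time-mean position over one or more trajectory windows. Frames are rigid-fit
on the full atom roster onto the window mean (one re-fit iteration starting
from the first frame) and the fluctuation is then read off the selected
C-alpha atoms; `superpose = FALSE` skips the fit for trajectories already
expressed in a common frame, where the closed form of the synthetic
generator (RMSF exactly equal to the planted per-residue amplitude) holds
exactly. Windows are the half-open time intervals produced by
`segment_windows()` — the cooling, equilibration and subsequent heating
segments around an averaged conformation — and fluctuations are pooled
across windows. Cluster-wise RMSF statistics (`rmsf_cluster_stats()`)
report mean and sample sd per residue, flagging singleton clusters.

`sasa()` is a Shrake-Rupley implementation with a deterministic
golden-spiral point set (no random number generation, hence bit-identical
results) of 960 points per atom by default, probe radius 1.4 Angstrom, and
a consolidated per-element van der Waals radius table (H 1.20, C 1.70,
N 1.55, O 1.52, S 1.80, ...; unknown elements fall back to 1.70 with a
warning). Against closed forms, the defaults give better than 1% accuracy
on single spheres and two-sphere intersections, and global
rotation/translation moves the total by well under 0.5%.

`buried_interface_area()` is `SASA(A) + SASA(B) - SASA(AB)` for two
disjoint chain sets covering the complex. The value is reported
**unhalved**: that sum is the direct quantity defined by the formula, and
published "buried surface area" columns do not state a halving convention,
so the package leaves the factor of two to the user rather than guessing.
For the same reason — and because reported areas depend on whichever
engine, radius table and probe convention produced them — numerical
agreement with printed buried-area columns is documented as out of scope.

## Annealing-schedule bookkeeping

`annealing_schedule()` models one cycle of the ligand-group temperature
profile as piecewise linear: ramp from 300 K to the peak over 0-500 ps,
hold to 1000 ps, cool back to 2000 ps, equilibrate at 300 K to 2500 ps;
the receptor group follows the same shape rescaled to 300-350 K,
synchronized. (The exact low-group waveform is not printed anywhere; the
synchronized-shape assumption is exactly that, an assumption, and is only
used for bookkeeping.) One averaged conformation is emitted per completed
cycle, so a sampling plan of runs yields
`sum(n_runs * floor(duration_ps / 2500))` conformations — partial cycles
emit nothing, which is what makes the printed ensemble sizes
(400, 420, 300, 200, 180, 100) come out exactly. `select_best_model()`
implements the structure-prediction bookkeeping of choosing the
highest-confidence (ipTM+pTM) candidate from a 5-model x 5-conformation
pool, with a documented lexical tie-break.

## The state-transition ledger

Binding free energies of the individual peptide-receptor interfaces,
`dG_bind = G_complex - (G_receptor + G_ligand)`, enter as a packaged
13-row table (`dg_table()`). The checkpoint cycle is modelled as ordered
occupancy states A-H of the three clamp surfaces (`build_state_ledger()`):
A, the resting clamp with its own Rad9 tail occupying the front pocket and
the Hus1 groove; C, the fully Rad17-engaged clamp; F, Rhino having
replaced Rad17 on Rad9 and Rad1 with the iVERGE still on Hus1; G, the
polymerized state bridged by the second KYxxL+ motif; H, the
depolymerized, tail-reclaimed state. Each state's total is the sum of its
occupancy energies and is also reported relative to state A. Transitions
are plain differences of state totals (`transition_delta()`),
antisymmetric and independent of any reference shift.

States B, D and E are not fully determined by printed interface energies;
they are reconstructed from the narrative of the transition mechanism
(initial Rad17 contact through its N-terminus on Rad1; initial Rhino
contact through T52-F61; the T38-I48 insertion intermediate) and carry
`partially_specified = TRUE`. State E is additionally flagged
`hypothetical` — its simultaneous occupancies may clash sterically — and
its total should never be used quantitatively. Only A, C, F, G, H feed the
package's checks.

## The KYxxL+ motif profile

The motif model is a fixed-length, ungapped 7-position
position-frequency matrix (`build_profile()`) built from an alignment
block with every sequence carrying equal weight, Laplace-style
pseudocounts (default 0.5), gaps excluded from counts, and per-column
information content `log2(20) - H` in bits as simplified logo heights. A
full profile HMM with insert/delete states adds nothing here: the motif is
a fixed 7-mer in its alignment. Scanning (`scan_motif()`) supports the two
consensus patterns — Group 1 `[KR]-[YFK]-x-x-L-x-Phi` and Group 2
`R-x-L-x-Phi` anchored at positions +3..+7 — and a log-odds mode scoring
`sum(log2(f/bg))` per window. The hydrophobic set Phi is fixed to
{A, V, L, I, M, F, W, Y}; "hydrophobic" is not otherwise parameterized, so
this is a recorded decision. An optional relaxed rule accepts the
hydrophobic anchor at +6 instead of +7, the substitution observed in the
Rad9 tail. The packaged alignment block
(`inst/extdata/kyxxl_block_synthetic.fasta`) is a synthetic stand-in: only
the human residue identities of the motif instances are printed anywhere,
so orthologue rows are conservative variants, and the file says so in its
name and headers.

## What the synthetic generator does and does not emulate

`generate_pie_ensemble()` plants k clusters with prescribed mean PIE
matrices and adds i.i.d. Gaussian cell noise; one cluster is designated
the energy minimum. Components are fixed fractions of each total (default
Ees 0.55, Edisp 0.30, Gsol the 0.15 remainder, Eex = Ect = 0), with the
last component computed as the remainder so the five close on the total to
machine precision. `generate_trajectory()` puts residues on an idealized
helical trace and displaces each isotropically with per-axis sd
`amplitude/sqrt(3)`, so the planted per-residue RMSF is recovered in
closed form; an optional random rigid motion per frame exercises the
superposition machinery. `generate_motif_sequences()` plants motif
instances at recorded positions in i.i.d. background sequence.

Real ensembles are not i.i.d. Gaussian around cluster means: conformations
are autocorrelated along a trajectory, energy distributions are skewed,
cluster sizes are wildly unequal, and PIEDA components are not fixed
fractions of the total. Nothing published characterizes the
between-conformation variance of PIE values, so the Gaussian choice is a
modelling stand-in, chosen because it makes cluster recovery and the
multiple-comparison calibration well-posed. Passing the recovery tests
therefore demonstrates that the pipeline's inference machinery is correct
and deterministic, not that it will resolve any particular real system's
binding modes.

## Numerical choices and problem sizes

* Studentized-range p-values and critical values via `ptukey`/`qtukey`
  (numerical integration in base R); all-pairs q statistics and the
  compact-letter display are computed in this package.
* SASA point set: deterministic golden spiral, 960 points; probe 1.4 A.
* Superposition reference for RMSF: the window mean, reached by one
  re-fit iteration from the first frame.
* Selection and refinement tie-breaks: lower median, then lower cluster
  id; best-model ties: lexical (model id, conformation id).
* Energies are kJ/mol, lengths Angstrom, times ps throughout; durations
  given in ns are converted exactly.
* Test problem sizes: synthetic ensembles of 30-120 conformations on
  4 x 6 residue axes; trajectories of up to 5000 frames for the RMSF
  closed-form check; 10,000 simulated families for the family-wise error
  calibration; 200 sequences of length 200 for scanner recovery. These
  sizes give comfortable Monte-Carlo margins for every asserted tolerance
  while keeping the full suite fast on a single CPU.

## Known limitations

* The clustering defaults (Ward, Euclidean, unscaled features) are
  recorded choices, not inferences; published analyses do not state them.
* Buried areas are unhalved and engine conventions differ; do not compare
  them numerically with published tables.
* The ledger's states B, D, E are narrative reconstructions
  (`partially_specified`), and E is bookkeeping only.
* The motif model is ungapped and fixed-length; it cannot represent
  insertions within the motif.
* `rmsf()` requires at least three atoms for superposition; smaller
  selections must use `superpose = FALSE`.
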