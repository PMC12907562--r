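# Shared fixtures: small synthetic specs with known ground truth.

make_cluster_means <- function(totals, n_ligand = 4L, n_receptor = 6L) {
  lapply(totals, function(tt)
    matrix(tt / (n_ligand * n_receptor), n_ligand, n_receptor))
}

make_spec <- function(totals = c(-500, -300, -100), sizes = c(20L, 20L, 20L),
                      noise_sd = 5, n_ligand = 4L, n_receptor = 6L,
                      seed = 42L) {
  pie_ensemble_spec(
    n_ligand = n_ligand, n_receptor = n_receptor,
    cluster_sizes = sizes,
    cluster_means = make_cluster_means(totals, n_ligand, n_receptor),
    noise_sd = noise_sd,
    stable_cluster_index = which.min(totals),
    seed = seed)
}

# Adjusted Rand index, written out from the pair-counting definition so it
# stays independent of any clustering machinery under test.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Analytic SASA of two intersecting spheres with extended radii r1, r2 at
# centre distance d: each sphere loses the spherical cap cut off by the
# radical plane.
two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h1 + 4 * pi * r2^2 - 2 * pi * r2 * h2
}

two_atom_structure <- function(d, element = "C", chains = c("A", "B")) {
  clamp_structure(data.frame(
    chain = chains, resno = 1L, resname = "ALA", atom_name = "CA",
    element = element, x = c(0, d), y = 0, z = 0,
    stringsAsFactors = FALSE))
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L, byrow = TRUE)
}
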