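test_that("feature matrices flatten PIE cells ligand-major with correct shape", {
  ens <- generate_pie_ensemble(make_spec(sizes = c(1L, 1L), seed = 41L,
                                         totals = c(-120, -60),
                                         n_ligand = 3L, n_receptor = 4L))
  feat <- build_features(ens)
  expect_equal(dim(feat), c(2L, 12L))
  expect_equal(colnames(feat)[1:4], c("LL1|RR1", "LL1|RR2", "LL1|RR3",
                                      "LL1|RR4"))
  # single-pair restriction reproduces that PIE series
  one <- build_features(ens, "L:2-2", "R:3-3")
  expect_equal(unname(one[, 1L]),
               vapply(ens$matrices, function(m) m$total[2L, 3L], numeric(1)))
  # row sums equal the restricted total (loop oracle)
  sub <- build_features(ens, "L:1-2", "R:2-4")
  for (i in 1:2) {
    acc <- 0
    for (li in 1:2) for (rj in 2:4) acc <- acc + ens$matrices[[i]]$total[li, rj]
    expect_equal(unname(rowSums(sub))[i], acc)
  }
  expect_error(build_features(ens, "L:1-9"), "outside the declared axis")
  expect_error(build_features(ens, "Q"), "chain 'Q'")
})

test_that("total PIE is the double sum over (restricted) cells", {
  ax <- data.frame(chain = "L", resno = 1:2, resname = "ALA")
  rx <- data.frame(chain = "R", resno = 1:2, resname = "GLY")
  zero <- pie_matrix("z", ax, rx, matrix(0, 2, 2))
  expect_equal(total_pie(zero), 0)
  m <- pie_matrix("m", ax, rx, matrix(c(-1, -3, -2, -4), 2, 2))
  expect_equal(total_pie(m), -10)
  set.seed(44)
  rm_ <- matrix(rnorm(4), 2, 2)
  mm <- pie_matrix("r", ax, rx, rm_)
  acc <- 0
  for (i in 1:2) for (j in 1:2) acc <- acc + rm_[i, j]
  expect_equal(total_pie(mm), acc)
})

test_that("agglomerative clustering recovers planted structure deterministically", {
  ens <- generate_pie_ensemble(make_spec(c(-500, -300, -100),
                                         sizes = c(15L, 15L, 15L),
                                         noise_sd = 2, seed = 45L))
  feat <- build_features(ens)
  all_one <- pie_cluster(feat, k = 1L)
  expect_true(all(all_one$labels == 1L))

  cl <- pie_cluster(feat, k = 3L)
  expect_equal(ari(cl$labels, ens$ground_truth), 1)
  cl2 <- pie_cluster(feat, k = 3L)
  expect_identical(cl$labels, cl2$labels)
  expect_error(pie_cluster(feat, k = 99L), "between 1")
})

test_that("cluster summaries match hand arithmetic and a sort-based quartile oracle", {
  s <- summarize_clusters(c(1, 1), c(-1, -3))
  expect_equal(s$mean, -2)
  expect_equal(s$median, -2)
  single <- summarize_clusters(c(1, 2, 2), c(-5, -1, -2))
  expect_true(single$singleton[single$cluster == 1])
  expect_equal(single$sd[single$cluster == 1], 0)

  set.seed(46)
  x <- rnorm(23)
  s2 <- summarize_clusters(rep(1, 23), x)
  # type-7 quantile oracle from sorted order statistics
  xs <- sort(x)
  q_oracle <- function(p) {
    h <- (length(xs) - 1) * p
    lo <- floor(h)
    xs[lo + 1] + (h - lo) * (xs[lo + 2 - (h == lo)] - xs[lo + 1 - (h == lo)])
  }
  expect_equal(s2$q25, q_oracle(0.25), tolerance = 1e-12)
  expect_equal(s2$q75, q_oracle(0.75), tolerance = 1e-12)
})

test_that("Tukey-Kramer separates shifted groups and letters identical ones together", {
  set.seed(47)
  base <- rnorm(10)
  same <- tukey_kramer(list(a = base, b = base + 1e-12, c = rnorm(10)))
  expect_false(same$pairs$significant[same$pairs$group_a == "a" &
                                      same$pairs$group_b == "b"])
  ab <- same$letters[c("a", "b")]
  expect_true(any(strsplit(ab[1], "")[[1]] %in% strsplit(ab[2], "")[[1]]))

  shifted <- tukey_kramer(list(a = rnorm(10), b = rnorm(10),
                               c = rnorm(10) + 100))
  pc <- shifted$pairs[shifted$pairs$group_a == "c" |
                      shifted$pairs$group_b == "c", ]
  expect_true(all(pc$significant))
  others <- unlist(strsplit(shifted$letters[c("a", "b")], ""))
  expect_false(any(strsplit(shifted$letters[["c"]], "")[[1]] %in% others))

  expect_error(tukey_kramer(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("the studentized-range critical value matches a Monte-Carlo oracle", {
  # balanced null: q = range(means) / sqrt(MSW/n), 5 groups of n = 10
  set.seed(48)
  k <- 5L; n <- 10L; reps <- 200000L
  qs <- numeric(reps)
  chunk <- 20000L
  done <- 0L
  while (done < reps) {
    m <- matrix(rnorm(chunk * k * n), nrow = chunk)
    idx <- rep(seq_len(k), each = n)
    means <- sapply(seq_len(k), function(g)
      rowMeans(m[, idx == g, drop = FALSE]))
    ssw <- rowSums((m - means[, idx])^2)
    msw <- ssw / (k * n - k)
    qs[(done + 1):(done + chunk)] <-
      (apply(means, 1L, max) - apply(means, 1L, min)) / sqrt(msw / n)
    done <- done + chunk
  }
  crit_mc <- unname(stats::quantile(qs, 0.95))
  crit_pkg <- tukey_kramer(split(rnorm(k * n), rep(1:k, each = n)))$critical
  expect_equal(crit_pkg, stats::qtukey(0.95, k, k * n - k))
  expect_lt(abs(crit_mc - crit_pkg) / crit_pkg, 0.01)
})

test_that("compact letters are always consistent with pairwise significance", {
  set.seed(49)
  for (trial in 1:25) {
    k <- sample(3:8, 1)
    sig <- matrix(FALSE, k, k, dimnames = list(paste0("g", 1:k),
                                               paste0("g", 1:k)))
    pairs <- which(upper.tri(sig))
    on <- sample(pairs, size = rbinom(1, length(pairs), 0.4))
    sig[on] <- TRUE
    sig <- sig | t(sig)
    lt <- compact_letters(sig)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      shared <- any(strsplit(lt[a], "")[[1]] %in% strsplit(lt[b], "")[[1]])
      if (sig[a, b]) expect_false(shared) else expect_true(shared)
    }
  }
})

test_that("reference comparisons pick the right t-test and match a permutation oracle", {
  x <- c(1, 2, 3, 4)
  same <- compare_to_reference(x, x)
  expect_equal(same$p, 1)
  expect_equal(same$statistic, 0)

  set.seed(50)
  far <- compare_to_reference(rnorm(20), rnorm(20) + 50)
  expect_lt(far$p, 1e-10)

  expect_match(compare_to_reference(x, x + 0.5, policy = "welch")$test,
               "Welch")
  expect_match(compare_to_reference(x, x + 0.5, policy = "student")$test,
               "Student")

  # exhaustive permutation oracle at small n
  set.seed(51)
  a <- rnorm(6); b <- rnorm(6) + 1.2
  p_student <- compare_to_reference(a, b, policy = "student")$p
  pool <- c(a, b)
  combos <- utils::combn(12L, 6L)
  t_obs <- abs(stats::t.test(a, b, var.equal = TRUE)$statistic)
  t_perm <- apply(combos, 2L, function(ix)
    abs(stats::t.test(pool[ix], pool[-ix], var.equal = TRUE)$statistic))
  p_perm <- mean(t_perm >= t_obs - 1e-12)
  expect_lt(abs(p_student - p_perm), 0.05)
})

test_that("stable-cluster selection returns the argmin plus its statistical ties", {
  ens <- generate_pie_ensemble(make_spec(c(-500, -300, -100),
                                         sizes = c(15L, 15L, 15L),
                                         noise_sd = 2, seed = 52L))
  feat <- build_features(ens)
  cl <- pie_cluster(feat, k = 3L)
  totals <- rowSums(feat)
  summ <- summarize_clusters(cl, totals)
  tk <- tukey_kramer(split(totals, cl$labels))
  sel <- select_stable(summ, tk)
  planted <- cl$labels[which(ens$ground_truth ==
                             which.min(c(-500, -300, -100)))][1L]
  expect_identical(unname(sel), unname(planted))

  # two indistinguishable lowest clusters are both returned
  ens2 <- generate_pie_ensemble(make_spec(c(-500, -498, -100),
                                          sizes = c(15L, 15L, 15L),
                                          noise_sd = 40, seed = 53L))
  totals2 <- total_pie(ens2)
  labels2 <- ens2$ground_truth          # use truth labels to isolate selection
  summ2 <- summarize_clusters(labels2, totals2)
  tk2 <- tukey_kramer(split(totals2, labels2))
  sel2 <- select_stable(summ2, tk2)
  expect_setequal(sel2, c(1L, 2L))

  # single cluster: returned as-is
  expect_equal(select_stable(summarize_clusters(rep(1L, 4), rnorm(4)), NULL),
               1L)
  # top_m pre-selection by median keeps only the m lowest-median clusters
  sel3 <- select_stable(summ2, tk2, top_m = 1L)
  expect_equal(length(sel3), 1L)
})

test_that("select_stable always contains the argmin-mean cluster", {
  set.seed(54)
  for (trial in 1:10) {
    g <- lapply(1:4, function(i) rnorm(8, mean = sample(-5:0, 1)))
    names(g) <- 1:4
    totals <- unlist(g)
    labels <- rep(1:4, each = 8)
    summ <- summarize_clusters(labels, totals)
    tk <- tukey_kramer(g)
    sel <- select_stable(summ, tk)
    expect_true(summ$cluster[which.min(summ$mean)] %in% sel)
  }
})

test_that("iterative refinement builds lineage strings and improves monotonically", {
  # sampler plants the stable cluster at a prescribed index per round;
  # block-ordered generation makes cutree label = planted index
  plant <- c(2L, 3L, 1L)
  stable_means <- c(-500, -800, -1100)
  sampler <- function(seed_conf, round) {
    totals <- rep(-100, 3)
    totals[plant[round]] <- stable_means[round]
    generate_pie_ensemble(make_spec(totals, sizes = c(10L, 10L, 10L),
                                    noise_sd = 1, seed = 60L + round))
  }
  res <- iterative_refine(sampler, rounds = 3L, k = 3L, tol = 1)
  # lineage is the per-round selected cluster ids joined by "-"
  picked <- vapply(res$rounds, function(r) r$selected[1L], integer(1))
  expect_equal(res$lineage, paste(picked, collapse = "-"))
  expect_equal(length(res$rounds), 3L)
  # each round's selected cluster is exactly the planted stable block
  for (r in 1:3) {
    cl <- res$rounds[[r]]$cluster
    members <- cl$labels == picked[r]
    planted_block <- rep(seq_len(3L), each = 10L) == plant[r]
    expect_equal(unname(members), planted_block)
    expect_equal(res$rounds[[r]]$mean_total_pie, stable_means[r],
                 tolerance = 0.01)
  }
  means <- vapply(res$rounds, `[[`, numeric(1), "mean_total_pie")
  expect_true(all(diff(means) < 0))
  expect_equal(res$final_mean, means[length(means)])

  one <- iterative_refine(sampler, rounds = 1L, k = 3L)
  expect_equal(one$lineage, as.character(one$rounds[[1L]]$selected[1L]))

  # improvement below tol stops early
  flat_sampler <- function(seed_conf, round)
    generate_pie_ensemble(make_spec(c(-500, -100, -100),
                                    sizes = c(10L, 10L, 10L),
                                    noise_sd = 1, seed = 70L))
  res2 <- iterative_refine(flat_sampler, rounds = 4L, k = 3L, tol = 1)
  expect_lt(length(res2$rounds), 4L)

  bad_sampler <- function(seed_conf, round) stop("engine exploded")
  expect_error(iterative_refine(bad_sampler, rounds = 2L, k = 2L),
               "round 1.*engine exploded")
})
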