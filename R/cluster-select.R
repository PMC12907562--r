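range_indices <- function(axis, range, what) {
  if (is.null(range)) return(seq_len(nrow(axis)))
  m <- regmatches(range, regexec("^([^:]+)(?::(\\d+)-(\\d+))?$", range))[[1L]]
  if (length(m) == 0L)
    stop("cannot parse ", what, " range '", range,
         "'; expected \"chain:start-end\"", call. = FALSE)
  idx <- which(axis$chain == m[2L])
  if (length(idx) == 0L)
    stop(what, " range '", range, "': chain '", m[2L],
         "' is not on the axis", call. = FALSE)
  if (nzchar(m[3L])) {
    lo <- as.integer(m[3L]); hi <- as.integer(m[4L])
    span <- range(axis$resno[idx])
    if (lo < span[1L] || hi > span[2L])
      stop(what, " range '", range, "': residue ",
           if (lo < span[1L]) lo else hi, " is outside the declared axis (",
           m[2L], ":", span[1L], "-", span[2L], ")", call. = FALSE)
    idx <- idx[axis$resno[idx] >= lo & axis$resno[idx] <= hi]
  }
  idx
}

#' Flatten a PIE ensemble into a conformation-by-cell feature matrix
#'
#' Each conformation becomes one row; columns are the flattened
#' (ligand residue, receptor residue) PIE cells restricted to the declared
#' ranges, in ligand-major order (all receptor cells of ligand residue 1,
#' then of residue 2, ...). Values are raw kJ/mol; no standardization.
#'
#' @param ensemble A [pie_ensemble()].
#' @param ligand_range,receptor_range Residue range strings
#'   (`"chain:start-end"`, bare chain, or `NULL` for all).
#' @return Numeric matrix with conformation ids as row names and
#'   `L<chain><resno>|R<chain><resno>` column labels.
#' @export
build_features <- function(ensemble, ligand_range = NULL,
                           receptor_range = NULL) {
  stopifnot(inherits(ensemble, "pie_ensemble"), length(ensemble) > 0L)
  ax <- ensemble$matrices[[1L]]
  li <- range_indices(ax$ligand, ligand_range, "ligand")
  rj <- range_indices(ax$receptor, receptor_range, "receptor")
  cells <- expand.grid(r = rj, l = li)   # ligand-major: l varies slowest
  cells <- cells[order(match(cells$l, li)), ]
  feat <- vapply(ensemble$matrices,
                 function(m) m$total[cbind(cells$l, cells$r)],
                 numeric(nrow(cells)))
  feat <- if (is.matrix(feat)) t(feat) else matrix(feat, ncol = 1L)
  rownames(feat) <- conformation_ids(ensemble)
  colnames(feat) <- paste0("L", ax$ligand$chain[cells$l],
                           ax$ligand$resno[cells$l], "|R",
                           ax$receptor$chain[cells$r],
                           ax$receptor$resno[cells$r])
  feat
}

#' Total pair-interaction energy of a conformation
#'
#' The double sum of PIE over the (optionally range-restricted) ligand and
#' receptor residues of one matrix, or of every matrix in an ensemble.
#'
#' @param x A [pie_matrix()] or [pie_ensemble()].
#' @param ligand_range,receptor_range Range strings as in
#'   [build_features()].
#' @return Scalar (matrix) or named vector (ensemble) of total PIE, kJ/mol.
#' @export
total_pie <- function(x, ligand_range = NULL, receptor_range = NULL) {
  if (inherits(x, "pie_ensemble")) {
    out <- vapply(x$matrices, total_pie, numeric(1),
                  ligand_range = ligand_range,
                  receptor_range = receptor_range)
    names(out) <- conformation_ids(x)
    return(out)
  }
  stopifnot(inherits(x, "pie_matrix"))
  li <- range_indices(x$ligand, ligand_range, "ligand")
  rj <- range_indices(x$receptor, receptor_range, "receptor")
  if (length(li) == 0L || length(rj) == 0L) {
    warning("empty range restriction; total PIE is 0", call. = FALSE)
    return(0)
  }
  sum(x$total[li, rj, drop = FALSE])
}

#' Agglomerative hierarchical clustering of PIE fingerprints
#'
#' Deterministic agglomerative clustering of the feature matrix with the
#' chosen linkage (default Ward on Euclidean distances, via
#' `stats::hclust(method = "ward.D2")`, the Ward criterion on unsquared
#' Euclidean distances) and labels from cutting the merge tree at `k`.
#'
#' @param features Feature matrix from [build_features()].
#' @param k Number of clusters, `1 <= k <= nrow(features)`.
#' @param linkage `hclust` linkage method (default `"ward.D2"`).
#' @param metric `dist` metric (default `"euclidean"`).
#' @return Object of class `cluster_result`: `k`, `labels` (1..k, named by
#'   conformation), `merge_tree` (the `hclust` object), `linkage`, `metric`.
#' @export
pie_cluster <- function(features, k, linkage = "ward.D2",
                        metric = "euclidean") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1L || k > n)
    stop("'k' must be between 1 and the number of conformations (", n, ")",
         call. = FALSE)
  if (n == 1L) {
    labels <- stats::setNames(1L, rownames(features))
    return(structure(list(k = 1L, labels = labels, merge_tree = NULL,
                          linkage = linkage, metric = metric),
                     class = "cluster_result"))
  }
  hc <- stats::hclust(stats::dist(features, method = metric),
                      method = linkage)
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(features)
  structure(list(k = as.integer(k), labels = labels, merge_tree = hc,
                 linkage = linkage, metric = metric),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result: %d conformations in k = %d clusters (%s/%s)\n",
              length(x$labels), x$k, x$linkage, x$metric))
  print(table(x$labels))
  invisible(x)
}

#' Per-cluster summaries of total PIE
#'
#' Count, mean, median, sample standard deviation and the 25th/75th
#' percentiles (box-plot boundaries, type-7 quantiles) of the total PIE in
#' each cluster. Singleton clusters get sd 0 and `singleton = TRUE`.
#'
#' @param labels Cluster labels (vector or a `cluster_result`).
#' @param totals Per-conformation total PIE aligned with `labels`.
#' @return Data frame with one row per cluster, ordered by cluster id.
#' @export
summarize_clusters <- function(labels, totals) {
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  if (length(labels) != length(totals))
    stop("'totals' must align with 'labels'", call. = FALSE)
  groups <- split(as.numeric(totals), labels)
  out <- data.frame(
    cluster = as.integer(names(groups)),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    median = vapply(groups, stats::median, numeric(1)),
    sd = vapply(groups, function(g)
      if (length(g) > 1L) stats::sd(g) else 0, numeric(1)),
    q25 = vapply(groups, stats::quantile, numeric(1), probs = 0.25,
                 names = FALSE),
    q75 = vapply(groups, stats::quantile, numeric(1), probs = 0.75,
                 names = FALSE),
    stringsAsFactors = FALSE)
  out$singleton <- out$n == 1L
  rownames(out) <- NULL
  out[order(out$cluster), ]
}

#' Tukey-Kramer all-pairs comparison with compact-letter display
#'
#' For every pair of groups computes the studentized-range statistic
#' `q = |mean_a - mean_b| / sqrt(MSW/2 * (1/n_a + 1/n_b))` with the pooled
#' within-group mean square `MSW` on `N - k` degrees of freedom, and
#' compares it with the studentized-range critical value
#' `qtukey(1 - alpha, k, N - k)` (base R's numerical integration of the
#' studentized-range distribution). Groups are then lettered so that any
#' two groups sharing no letter differ significantly at family-wise level
#' `alpha` (insert-and-absorb compact-letter display).
#'
#' @param groups Named list of numeric vectors, each of length `>= 2`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Object of class `tukey_kramer`: `pairs` (data frame with
#'   `group_a`, `group_b`, `diff`, `q`, `p`, `significant`), `letters`
#'   (named character vector), `alpha`, `df`, `msw`, `critical`.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L))
    stop("every group needs n >= 2 (group ",
         paste(names(groups)[ns < 2L], collapse = ", "), ")", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  k <- length(groups)
  n_total <- sum(ns)
  df <- n_total - k
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msw <- ssw / df
  idx <- utils::combn(k, 2L)
  ga <- idx[1L, ]; gb <- idx[2L, ]
  se <- sqrt(msw / 2 * (1 / ns[ga] + 1 / ns[gb]))
  diffs <- means[ga] - means[gb]
  q <- abs(diffs) / se
  q[se == 0] <- ifelse(diffs[se == 0] == 0, 0, Inf)
  crit <- stats::qtukey(1 - alpha, nmeans = k, df = df)
  p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  p[is.infinite(q)] <- 0
  pairs <- data.frame(group_a = names(groups)[ga],
                      group_b = names(groups)[gb],
                      diff = unname(diffs), q = unname(q), p = unname(p),
                      significant = unname(q > crit),
                      stringsAsFactors = FALSE)
  sig <- matrix(FALSE, k, k, dimnames = list(names(groups), names(groups)))
  sig[cbind(ga, gb)] <- pairs$significant
  sig[cbind(gb, ga)] <- pairs$significant
  structure(list(pairs = pairs,
                 letters = compact_letters(sig),
                 alpha = alpha, df = df, msw = msw, critical = crit,
                 means = means, n = ns),
            class = "tukey_kramer")
}

#' @export
print.tukey_kramer <- function(x, ...) {
  cat(sprintf("Tukey-Kramer: %d groups, df = %d, q_crit(%.2f) = %.3f\n",
              length(x$letters), x$df, x$alpha, x$critical))
  print(data.frame(mean = x$means, n = x$n, letters = x$letters))
  invisible(x)
}

#' Compact-letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: starts with one letter covering all groups;
#' every significant pair splits the letters containing both members into
#' two, and letters subsumed by another are absorbed. Groups sharing a
#' letter are pairwise non-significant; groups sharing none differ
#' significantly.
#'
#' @param significant Symmetric logical matrix with group names as
#'   dimnames; `TRUE` where the pair differs significantly.
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(significant) {
  groups <- rownames(significant)
  k <- length(groups)
  sets <- list(rep(TRUE, k))   # each set = logical membership vector
  pairs <- which(significant & upper.tri(significant), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    nxt <- list()
    for (s in sets) {
      if (s[a] && s[b]) {
        s1 <- s; s1[a] <- FALSE
        s2 <- s; s2[b] <- FALSE
        nxt <- c(nxt, list(s1), list(s2))
      } else nxt <- c(nxt, list(s))
    }
    # absorb sets contained in (or equal to) an earlier/larger set
    keep <- rep(TRUE, length(nxt))
    for (i in seq_along(nxt)) {
      if (!keep[i]) next
      for (j in seq_along(nxt)) {
        if (i == j || !keep[j]) next
        if (all(nxt[[i]] >= nxt[[j]]) &&
            (sum(nxt[[i]]) > sum(nxt[[j]]) || i < j))
          keep[j] <- FALSE
      }
    }
    sets <- nxt[keep]
  }
  # stable letter order: by first member
  ord <- order(vapply(sets, function(s) which(s)[1L], integer(1)))
  sets <- sets[ord]
  letters_pool <- c(letters, paste0(rep(letters, each = 26L), letters))
  out <- vapply(seq_len(k), function(g)
    paste(letters_pool[which(vapply(sets, function(s) s[g], logical(1)))],
          collapse = ""),
    character(1))
  stats::setNames(out, groups)
}

#' Two-sample comparison against a reference cluster
#'
#' Two-sided t-test of a group against the reference (most stable) cluster.
#' Policy `"auto"` runs Welch's t-test when an F-test of variance equality
#' rejects at 0.05 and Student's otherwise; `"student"`/`"welch"` force the
#' variant.
#'
#' @param group,reference Numeric vectors, each `n >= 2`.
#' @param policy `"auto"`, `"student"` or `"welch"`.
#' @return List with `p`, `statistic`, `test` (test name) and `policy`.
#' @export
compare_to_reference <- function(group, reference,
                                 policy = c("auto", "student", "welch")) {
  policy <- match.arg(policy)
  if (length(group) < 2L || length(reference) < 2L)
    stop("both samples need n >= 2", call. = FALSE)
  if (stats::var(group) == 0 && stats::var(reference) == 0) {
    if (mean(group) == mean(reference))
      return(list(p = 1, statistic = 0, test = "degenerate (zero variance)",
                  policy = policy))
  }
  welch <- switch(policy,
    student = FALSE,
    welch = TRUE,
    auto = {
      f <- stats::var.test(group, reference)
      is.finite(f$p.value) && f$p.value < 0.05
    })
  tt <- stats::t.test(group, reference, var.equal = !welch)
  list(p = tt$p.value, statistic = unname(tt$statistic),
       test = if (welch) "Welch's t-test" else "Student's t-test",
       policy = policy)
}

#' Select the most stable cluster(s)
#'
#' Returns the cluster with the lowest `rank_by` statistic of total PIE plus
#' every cluster not significantly different from it in the Tukey-Kramer
#' table; when `top_m` is given, only the `top_m` clusters with the lowest
#' medians are considered at all (pre-selection before testing). Ties on the
#' rank statistic break by lower median, then lower cluster id.
#'
#' @param summaries Data frame from [summarize_clusters()].
#' @param significance A [tukey_kramer()] result whose group names are
#'   cluster ids, or `NULL` (then only the argmin cluster is returned).
#' @param rank_by `"mean"` or `"median"` total PIE.
#' @param top_m Optional pre-selection size by lowest median.
#' @return Integer vector of stable cluster ids, the argmin first.
#' @export
select_stable <- function(summaries, significance = NULL,
                          rank_by = c("mean", "median"), top_m = NULL) {
  rank_by <- match.arg(rank_by)
  s <- summaries
  if (!is.null(top_m)) {
    top_m <- min(top_m, nrow(s))
    s <- s[order(s$median, s$cluster), ][seq_len(top_m), ]
  }
  ord <- order(s[[rank_by]], s$median, s$cluster)
  best <- s$cluster[ord[1L]]
  if (is.null(significance)) return(best)
  pr <- significance$pairs
  others <- setdiff(s$cluster, best)
  ns <- others[vapply(others, function(cl) {
    row <- pr[(pr$group_a == as.character(best) &
               pr$group_b == as.character(cl)) |
              (pr$group_b == as.character(best) &
               pr$group_a == as.character(cl)), ]
    nrow(row) == 1L && !row$significant
  }, logical(1))]
  c(best, sort(ns))
}

#' Iterative re-seeded conformational refinement with lineage naming
#'
#' Per round: sample an ensemble, cluster its PIE fingerprints, select the
#' most stable cluster, and seed the next round from that cluster's
#' minimum-total-PIE conformation. Cluster ids selected per round are
#' joined with `-` into the lineage string (e.g. `"6-7-2-6"`). Refinement
#' stops after `rounds` rounds or when the selected cluster's mean total
#' PIE improves by less than `tol` kJ/mol.
#'
#' @param sampler Function `(seed_conformation, round)` returning a
#'   [pie_ensemble()]; `seed_conformation` is `NULL` in round 1 and a
#'   [pie_matrix()] afterwards.
#' @param rounds Maximum number of rounds.
#' @param k Cluster count per round (scalar or vector per round).
#' @param ligand_range,receptor_range Feature ranges as in
#'   [build_features()].
#' @param rank_by Rank statistic for [select_stable()].
#' @param alpha Tukey-Kramer family-wise level.
#' @param tol Minimum mean-total-PIE improvement (kJ/mol) to continue.
#' @return Object of class `refinement_result`: `lineage` (string),
#'   `rounds` (list of per-round records: cluster result, summaries,
#'   selected ids, seed conformation id, mean total PIE of the selected
#'   cluster) and `final_mean`.
#' @export
iterative_refine <- function(sampler, rounds, k,
                             ligand_range = NULL, receptor_range = NULL,
                             rank_by = "mean", alpha = 0.05, tol = 1) {
  stopifnot(is.function(sampler), rounds >= 1L)
  k <- rep_len(as.integer(k), rounds)
  lineage <- integer(0)
  seed_conf <- NULL
  records <- list()
  prev_mean <- Inf
  for (r in seq_len(rounds)) {
    ens <- tryCatch(sampler(seed_conf, r), error = function(e)
      stop("sampler failed in round ", r, ": ", conditionMessage(e),
           call. = FALSE))
    feat <- build_features(ens, ligand_range, receptor_range)
    cl <- pie_cluster(feat, k = min(k[r], nrow(feat)))
    totals <- rowSums(feat)
    summ <- summarize_clusters(cl, totals)
    tk <- NULL
    eligible <- summ$cluster[summ$n >= 2L]
    if (length(eligible) >= 2L) {
      groups <- split(totals, cl$labels)[as.character(eligible)]
      tk <- tukey_kramer(groups, alpha = alpha)
    }
    sel <- select_stable(summ[summ$cluster %in% eligible | summ$n < 2L, ],
                         significance = tk, rank_by = rank_by)
    primary <- sel[1L]
    lineage <- c(lineage, primary)
    members <- which(cl$labels == primary)
    seed_idx <- members[which.min(totals[members])]
    seed_conf <- ens$matrices[[seed_idx]]
    mean_sel <- summ$mean[summ$cluster == primary]
    records[[r]] <- list(cluster = cl, summaries = summ, tukey = tk,
                         selected = sel,
                         seed_conformation = seed_conf$conformation_id,
                         mean_total_pie = mean_sel)
    if (prev_mean - mean_sel < tol && r > 1L) break
    prev_mean <- mean_sel
  }
  structure(list(lineage = paste(lineage, collapse = "-"),
                 rounds = records,
                 final_mean = records[[length(records)]]$mean_total_pie),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("Refinement: lineage %s over %d round(s), final mean total PIE %.2f kJ/mol\n",
              x$lineage, length(x$rounds), x$final_mean))
  invisible(x)
}
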