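PHI_SET <- c("A", "V", "L", "I", "M", "F", "W", "Y")

group1_sets <- function(phi = PHI_SET) {
  list(`+1` = c("K", "R"), `+2` = c("Y", "F", "K"), `+3` = AA_ALPHABET,
       `+4` = AA_ALPHABET, `+5` = "L", `+6` = AA_ALPHABET, `+7` = phi)
}

group2_sets <- function(phi = PHI_SET) {
  # anchored at +3..+7; +1/+2 unconstrained
  list(`+1` = AA_ALPHABET, `+2` = AA_ALPHABET, `+3` = "R",
       `+4` = AA_ALPHABET, `+5` = "L", `+6` = AA_ALPHABET, `+7` = phi)
}

#' Build a position-frequency profile of the KYxxL+ motif
#'
#' From an ungapped alignment block of the 7-position Rad9-front-pocket
#' binding motif (positions +1..+7), with every sequence carrying equal
#' weight. Per-position amino-acid frequencies are maximum-likelihood
#' counts regularized by a Laplace-style pseudocount; gap characters
#' (`-`, `.`) are excluded from the counts. Information content per column
#' is `log2(20) - H(column)` bits (simplified logo heights), and the
#' profile carries the two consensus patterns: Group 1
#' `[KR]-[YFK]-x-x-L-x-Phi` and Group 2 `R-x-L-x-Phi` anchored at +3..+7,
#' with Phi the hydrophobic set {A,V,L,I,M,F,W,Y}.
#'
#' @param msa Character vector of aligned sequences of equal length (7 for
#'   the canonical block), or a named list as returned by FASTA readers.
#' @param pseudocount Pseudocount per amino acid (default 0.5).
#' @param background Named background composition (default uniform).
#' @return Object of class `motif_profile`: `frequencies` (20 x L matrix),
#'   `info_content` (bits per position), `background`, `length`,
#'   `group1_pattern`, `group2_pattern`, `phi`.
#' @export
build_profile <- function(msa, pseudocount = 0.5, background = NULL) {
  if (is.list(msa)) msa <- vapply(msa, function(s)
    paste(toupper(as.character(s)), collapse = ""), character(1))
  msa <- toupper(msa)
  if (length(msa) == 0L) stop("empty alignment", call. = FALSE)
  L <- unique(nchar(msa))
  if (length(L) != 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  chars <- do.call(rbind, strsplit(msa, ""))
  bad <- setdiff(unique(c(chars)), c(AA_ALPHABET, "-", "."))
  if (length(bad) > 0L)
    stop("alignment contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  bg <- background[AA_ALPHABET]; bg[is.na(bg)] <- 0; bg <- bg / sum(bg)
  freq <- matrix(NA_real_, 20L, L,
                 dimnames = list(AA_ALPHABET, paste0("+", seq_len(L))))
  for (p in seq_len(L)) {
    col <- chars[, p]
    col <- col[col %in% AA_ALPHABET]
    counts <- table(factor(col, levels = AA_ALPHABET))
    freq[, p] <- (as.numeric(counts) + pseudocount) /
      (sum(counts) + 20 * pseudocount)
  }
  h <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  structure(list(frequencies = freq, info_content = log2(20) - h,
                 background = bg, length = L,
                 group1_pattern = group1_sets(),
                 group2_pattern = group2_sets(),
                 phi = PHI_SET),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cons <- rownames(x$frequencies)[apply(x$frequencies, 2L, which.max)]
  cat(sprintf("Motif profile: %d positions, consensus %s\n", x$length,
              paste(cons, collapse = "")))
  cat("  information content (bits):",
      paste(sprintf("%.2f", x$info_content), collapse = " "), "\n")
  invisible(x)
}

match_sets <- function(window, sets, relaxed_phi = FALSE) {
  ok <- all(mapply(function(ch, set) ch %in% set, window, sets))
  if (ok || !relaxed_phi) return(ok)
  # relaxed hydrophobic rule: Phi may sit at +6 instead of +7
  swapped <- sets
  swapped[["+6"]] <- sets[["+7"]]
  swapped[["+7"]] <- AA_ALPHABET
  all(mapply(function(ch, set) ch %in% set, window, swapped))
}

#' Scan a sequence for KYxxL+ motif matches
#'
#' In `pattern` mode, every 7-residue window satisfying the Group-1 or
#' Group-2 consensus sets is reported (Group 2 constrains only its five
#' anchored positions +3..+7). In `logodds` mode, each window is scored
#' `sum(log2(f_pos(aa) / bg(aa)))` against the profile and windows scoring
#' at or above `threshold` are reported. Positions are 1-based. The
#' `relaxed_phi` flag accepts the hydrophobic anchor at +6 in place of +7
#' (the substitution observed for the Rad9 tail).
#'
#' @param sequence Protein sequence (string over the 20-letter alphabet).
#' @param profile A [motif_profile()].
#' @param mode `"pattern"` or `"logodds"`.
#' @param threshold Log-odds reporting threshold in bits (default 0).
#' @param relaxed_phi Accept Phi at +6 or +7 in pattern mode.
#' @return Data frame with `position`, `group` (`"1"`, `"2"`, `"1+2"` or
#'   `NA` in logodds mode), `score` (log-odds bits) and `window`.
#' @export
scan_motif <- function(sequence, profile, mode = c("pattern", "logodds"),
                       threshold = 0, relaxed_phi = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "motif_profile"))
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L)
    stop("sequence contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  L <- profile$length
  n_win <- length(chars) - L + 1L
  empty <- data.frame(position = integer(0), group = character(0),
                      score = numeric(0), window = character(0),
                      stringsAsFactors = FALSE)
  if (n_win < 1L) return(empty)
  score_window <- function(w) {
    rows <- match(w, AA_ALPHABET)
    sum(log2(profile$frequencies[cbind(rows, seq_len(L))] /
             profile$background[rows]))
  }
  out <- vector("list", n_win)
  for (p in seq_len(n_win)) {
    w <- chars[p:(p + L - 1L)]
    sc <- score_window(w)
    if (mode == "pattern") {
      g1 <- match_sets(w, profile$group1_pattern, relaxed_phi)
      g2 <- match_sets(w, profile$group2_pattern, relaxed_phi)
      if (g1 || g2)
        out[[p]] <- data.frame(position = p,
                               group = if (g1 && g2) "1+2"
                                       else if (g1) "1" else "2",
                               score = sc,
                               window = paste(w, collapse = ""),
                               stringsAsFactors = FALSE)
    } else if (sc >= threshold) {
      out[[p]] <- data.frame(position = p, group = NA_character_,
                             score = sc, window = paste(w, collapse = ""),
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Packaged KYxxL+ alignment block (synthetic stand-in)
#'
#' A 7-column ungapped alignment of KYxxL+ motif instances assembled from
#' the residue identities reported for the human Rad9-binding segments
#' (Rhino Q12-F18 and K90-F96, Rad17 K194-M200, Rad9 K360-F366, p21
#' S153-F159) plus conservative variants standing in for the orthologue
#' rows of the published alignment figure, which is not reproduced here.
#'
#' @return Named character vector of aligned 7-mers.
#' @export
kyxxl_alignment <- function() {
  path <- system.file("extdata", "kyxxl_block_synthetic.fasta",
                      package = "clampconf", mustWork = TRUE)
  lines <- readLines(path)
  heads <- grep("^>", lines)
  seqs <- vapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    paste(lines[from:to], collapse = "")
  }, character(1))
  stats::setNames(seqs, sub("^>\\s*", "", lines[heads]))
}
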