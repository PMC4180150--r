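# Gene-conversion and recombination detection among paralogs: a Sawyer-style
# fragment statistic with a permutation null (GENECONV-like "inner" pairwise
# fragments) and a MaxChi sliding-window chi-square breakpoint scan.

.alignment_matrix <- function(alignment) {
  alignment <- unlist(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  m
}

# polymorphic (informative) columns: more than one character state among the
# gap-free rows; columns with any gap are excluded
.polymorphic_columns <- function(m) {
  no_gap <- colSums(m == "-") == 0L
  poly <- apply(m, 2L, function(col) length(unique(col)) > 1L)
  which(no_gap & poly)
}

#' GENECONV-style pairwise gene-conversion scan
#'
#' For every sequence pair, scores the maximal run of consecutive polymorphic
#' columns at which the pair agrees (with `mismatch_penalty > 0`, maximal
#' positive-scoring segments where a disagreement costs the penalty). The
#' null distribution of the maximal score is obtained by permuting the order
#' of polymorphic columns; p-values are Bonferroni-corrected over all pairs
#' (global test).
#'
#' @param alignment Named character vector of aligned DNA rows (>= 3).
#' @param n_perm Permutation replicates.
#' @param seed Integer seed.
#' @param mismatch_penalty 0 (default) restricts fragments to exact runs.
#' @param report_threshold Only fragments with Bonferroni-corrected p at or
#'   below this are returned (all pairs are kept in the `all_pairs`
#'   attribute).
#' @return Data frame of significant fragments: `seq1`, `seq2`, `score`
#'   (fragment score in polymorphic sites), `frag_start_site`/`frag_end_site`
#'   (1-based indices over polymorphic sites), `frag_start_col`/`frag_end_col`
#'   (alignment columns), `sim_p`, `bonferroni_p`.
#' @export
geneconv_scan <- function(alignment, n_perm = 10000L, seed = 1L,
                          mismatch_penalty = 0, report_threshold = 0.05) {
  m <- .alignment_matrix(alignment)
  if (nrow(m) < 3L)
    stop("need more than two sequences to detect conversion signals")
  poly <- .polymorphic_columns(m)
  empty <- data.frame(seq1 = character(), seq2 = character(), score = numeric(),
                      frag_start_site = integer(), frag_end_site = integer(),
                      frag_start_col = integer(), frag_end_col = integer(),
                      sim_p = numeric(), bonferroni_p = numeric())
  if (length(poly) == 0L) {
    message("no polymorphic columns; nothing to scan")
    return(empty)
  }
  ids <- rownames(m)
  n <- nrow(m)
  n_pairs <- n * (n - 1L) / 2L
  rows <- list()
  pair_idx <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pair_idx <- pair_idx + 1L
    agree <- as.integer(m[i, poly] == m[j, poly])
    res <- cpp_fragment_null(agree, mismatch_penalty, n_perm,
                             seed + pair_idx)
    sim_p <- (1 + sum(res$null >= res$observed)) / (n_perm + 1)
    bon_p <- min(1, sim_p * n_pairs)
    # locate the maximal fragment (first run achieving the observed score)
    fs <- fe <- NA_integer_
    if (res$observed > 0) {
      best <- -Inf; cur <- 0; cur_start <- 1L
      for (s in seq_along(agree)) {
        if (agree[s]) {
          if (cur == 0) cur_start <- s
          cur <- cur + 1
        } else if (mismatch_penalty <= 0) cur <- 0
        else { cur <- max(0, cur - mismatch_penalty); if (cur == 0) cur_start <- s + 1L }
        if (cur > best) { best <- cur; fs <- cur_start; fe <- s }
      }
    }
    rows[[pair_idx]] <- data.frame(
      seq1 = ids[i], seq2 = ids[j], score = res$observed,
      frag_start_site = fs, frag_end_site = fe,
      frag_start_col = if (is.na(fs)) NA_integer_ else poly[fs],
      frag_end_col = if (is.na(fe)) NA_integer_ else poly[fe],
      sim_p = sim_p, bonferroni_p = bon_p, stringsAsFactors = FALSE)
  }
  all_pairs <- do.call(rbind, rows)
  out <- all_pairs[all_pairs$bonferroni_p <= report_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_pairs") <- all_pairs
  attr(out, "n_polymorphic") <- length(poly)
  out
}

#' MaxChi recombination breakpoint scan
#'
#' For every sequence pair and every candidate breakpoint over the polymorphic
#' columns, a 2x2 chi-square compares the match/mismatch counts in the two
#' flanking half-windows (`window`/2 polymorphic sites each). The per-pair
#' maximum chi-square is tested against a permutation null (shuffling
#' polymorphic column order) and Bonferroni-corrected over pairs.
#'
#' @param alignment Named character vector of aligned DNA rows (>= 3).
#' @param window Full window size in polymorphic sites (half each side).
#' @param n_perm Permutation replicates.
#' @param seed Integer seed.
#' @param alpha Reporting threshold on the corrected p-value.
#' @return Data frame of signals: `seq1`, `seq2`, `breakpoint_col` (alignment
#'   column), `chi_sq`, `sim_p`, `bonferroni_p`. The `all_pairs` attribute
#'   keeps every pair's maximum.
#' @export
maxchi_scan <- function(alignment, window = 30L, n_perm = 1000L, seed = 1L,
                        alpha = 0.01) {
  m <- .alignment_matrix(alignment)
  if (nrow(m) < 3L)
    stop("need more than two sequences to detect recombination signals")
  poly <- .polymorphic_columns(m)
  if (window > length(poly))
    stop("window larger than the number of polymorphic sites")
  half <- max(1L, window %/% 2L)
  chi_max <- function(agree) {
    L <- length(agree)
    if (L < 2L * half) return(c(0, NA))
    cums <- c(0L, cumsum(agree))
    ks <- seq.int(half, L - half)
    mL <- cums[ks + 1L] - cums[ks - half + 1L]       # matches left
    mR <- cums[ks + half + 1L] - cums[ks + 1L]       # matches right
    a <- mL; b <- half - mL; c_ <- mR; d <- half - mR
    tot <- 2L * half
    num <- tot * (a * d - b * c_)^2
    den <- as.numeric(a + b) * (c_ + d) * (a + c_) * (b + d)
    chi <- ifelse(den > 0, num / den, 0)
    k <- which.max(chi)
    c(chi[k], ks[k])
  }
  ids <- rownames(m)
  n <- nrow(m)
  n_pairs <- n * (n - 1L) / 2L
  rows <- list()
  pair_idx <- 0L
  set.seed(seed)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pair_idx <- pair_idx + 1L
    agree <- as.integer(m[i, poly] == m[j, poly])
    obs <- chi_max(agree)
    nullv <- vapply(seq_len(n_perm), function(p)
      chi_max(sample(agree))[1L], 0)
    sim_p <- (1 + sum(nullv >= obs[1L])) / (n_perm + 1)
    bon_p <- min(1, sim_p * n_pairs)
    rows[[pair_idx]] <- data.frame(
      seq1 = ids[i], seq2 = ids[j],
      breakpoint_col = if (is.na(obs[2L])) NA_integer_ else poly[obs[2L]],
      chi_sq = obs[1L], sim_p = sim_p, bonferroni_p = bon_p,
      stringsAsFactors = FALSE)
  }
  all_pairs <- do.call(rbind, rows)
  out <- all_pairs[all_pairs$bonferroni_p <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_pairs") <- all_pairs
  attr(out, "n_polymorphic") <- length(poly)
  out
}
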