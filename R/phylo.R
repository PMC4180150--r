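# Protein alignment and NJ phylogenies: progressive profile alignment with
# BLOSUM62, p-distances, neighbor joining (via ape) and bootstrap support for
# interior branches.

# frequency profile of an alignment block over the BLOSUM alphabet; gap
# columns carry zero weight (gaps score 0 against anything)
.profile_matrix <- function(rows, alpha) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  P <- matrix(0, length(alpha), L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tb <- table(factor(col, levels = alpha))
      P[, j] <- as.numeric(tb) / nrow(mat)
    }
  }
  P
}

.merge_profiles <- function(rows_a, rows_b, B, gap_open, gap_extend) {
  alpha <- rownames(B)
  Pa <- .profile_matrix(rows_a, alpha)
  Pb <- .profile_matrix(rows_b, alpha)
  S <- t(Pa) %*% B %*% Pb
  al <- cpp_global_affine(S, gap_open, gap_extend)
  expand <- function(rows, cols) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "", fixed = TRUE)[[1L]]
      paste(ifelse(cols == 0L, "-", ch[pmax(cols, 1L)]), collapse = "")
    }, "", USE.NAMES = TRUE)
  }
  c(expand(rows_a, al$a_cols), expand(rows_b, al$b_cols))
}

#' Progressive multiple protein alignment
#'
#' Builds a guide tree from k-mer distances by neighbor joining, then merges
#' sequences and profiles along the guide tree with global profile-profile
#' alignment (BLOSUM62, affine gaps). Deterministic.
#'
#' @param records Named character vector of protein sequences (>= 2).
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @param k K-mer size for guide-tree distances.
#' @return Named character vector of aligned rows (equal length, `-` gaps),
#'   in input order, of class `multiple_alignment` with attribute
#'   `alphabet = "aa"`.
#' @export
progressive_align <- function(records, gap_open = -10, gap_extend = -1, k = 3L) {
  records <- unlist(records)
  n <- length(records)
  if (n < 2L) stop("need at least 2 sequences to align")
  B <- aa_alphabet()
  if (n == 2L) {
    out <- .merge_profiles(records[1L], records[2L], B, gap_open, gap_extend)
    names(out) <- names(records)
    return(structure(out[names(records)], class = "multiple_alignment",
                     alphabet = "aa"))
  }
  # k-mer guide distances
  kmer_set <- function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  }
  sets <- lapply(records, kmer_set)
  D <- matrix(0, n, n, dimnames = list(names(records), names(records)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    D[i, j] <- D[j, i] <- 1 - shared / min(length(sets[[i]]), length(sets[[j]]))
  }
  guide <- ape::nj(as.dist(D))
  guide <- ape::root(guide, outgroup = guide$tip.label[1L], resolve.root = TRUE)
  guide <- ape::reorder.phylo(guide, "postorder")
  ntip <- length(guide$tip.label)
  blocks <- vector("list", ntip + guide$Nnode)
  for (i in seq_len(ntip))
    blocks[[i]] <- stats::setNames(records[guide$tip.label[i]],
                                   guide$tip.label[i])
  children <- split(guide$edge[, 2L], guide$edge[, 1L])
  for (node in unique(guide$edge[, 1L])) {      # postorder: children first
    kids <- children[[as.character(node)]]
    acc <- blocks[[kids[1L]]]
    for (kid in kids[-1L])
      acc <- .merge_profiles(acc, blocks[[kid]], B, gap_open, gap_extend)
    blocks[[node]] <- acc
  }
  out <- blocks[[ntip + 1L]]
  structure(out[names(records)], class = "multiple_alignment", alphabet = "aa")
}

#' Pairwise p-distance matrix
#'
#' Fraction of differing sites per pair. Under `"pairwise"` deletion, sites
#' where either row has a gap are skipped per pair; under `"complete"`
#' deletion, only gap-free columns are used for all pairs.
#'
#' @param alignment Named character vector of equal-length rows.
#' @param gap_mode `"pairwise"` (default) or `"complete"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment, gap_mode = c("pairwise", "complete")) {
  gap_mode <- match.arg(gap_mode)
  alignment <- unlist(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  if (gap_mode == "complete") {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  n <- length(alignment)
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok))
      stop(sprintf("no comparable sites between '%s' and '%s'",
                   names(alignment)[i], names(alignment)[j]))
    D[i, j] <- D[j, i] <- mean(mat[i, ok] != mat[j, ok])
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via ape). Negative branch-length
#' estimates are clamped to zero and flagged in the returned tree's
#' `clamped_branches` attribute. Two taxa give a single edge of total length
#' equal to their distance.
#'
#' @param dist Symmetric distance matrix with zero diagonal.
#' @return An `ape::phylo` tree (unrooted for >= 3 taxa).
#' @export
neighbor_joining <- function(dist) {
  dist <- as.matrix(dist)
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(dist)
  ids <- rownames(dist)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                        ids[1L], dist[1L, 2L] / 2,
                                        ids[2L], dist[1L, 2L] / 2))
    attr(tr, "clamped_branches") <- 0L
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(dist))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped_branches") <- sum(neg)
  tr
}

#' NJ tree with bootstrap interior-branch support
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance NJ
#' tree per replicate, and reports for every interior branch the percentage of
#' replicates containing the same bipartition (stored in `$node.label`).
#'
#' @param alignment Named character vector of aligned rows (>= 4).
#' @param reps Bootstrap replications.
#' @param seed Integer seed.
#' @param gap_mode Passed to [p_distance_matrix()].
#' @return The NJ tree with integer support values (0-100) as node labels.
#' @export
interior_branch_support <- function(alignment, reps = 1000L, seed = 1L,
                                    gap_mode = "pairwise") {
  alignment <- unlist(alignment)
  if (length(alignment) < 4L) stop("need >= 4 rows for interior branches")
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  pdist_safe <- function(m) {
    n <- nrow(m)
    D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      D[i, j] <- D[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 1
    }
    D
  }
  if (gap_mode == "complete") {
    keep <- colSums(mat == "-") == 0L
    mat <- mat[, keep, drop = FALSE]
  }
  main <- neighbor_joining(pdist_safe(mat))
  set.seed(seed)
  boots <- vector("list", reps)
  for (b in seq_len(reps)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    boots[[b]] <- neighbor_joining(pdist_safe(mat[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.integer(round(100 * counts / reps))
  main
}
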