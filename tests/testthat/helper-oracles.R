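# Independent oracles used by the tests. These deliberately re-derive results
# by brute force / enumeration, structured differently from the package code.

# --- simple affine-gap Smith-Waterman (local) on two DNA strings -------------
oracle_local_align <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(0, n + 1, m + 1)
  X[1, ] <- Y[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- exhaustive modified Nei-Gojobori oracle ---------------------------------
# Uses Biostrings' genetic code directly and enumerates mutations and paths
# explicitly, with the same conventions as the package documents: transition
# weight R in site counting, stop mutations nonsynonymous, stop-crossing paths
# excluded from difference averaging.
oracle_ng <- function(cds1, cds2, R = 2) {
  gc <- Biostrings::GENETIC_CODE
  transl <- function(codon) unname(gc[codon])
  is_ti <- function(x, y) paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT")
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(codon) {
    s <- 0
    for (p in 1:3) {
      wt <- 0; ws <- 0
      for (bb in setdiff(bases, substr(codon, p, p))) {
        mut <- codon; substr(mut, p, p) <- bb
        w <- if (is_ti(substr(codon, p, p), bb)) R else 1
        wt <- wt + w
        if (transl(mut) != "*" && transl(mut) == transl(codon)) ws <- ws + w
      }
      s <- s + ws / wt
    }
    s
  }
  path_diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    perms <- if (length(pos) == 1) list(pos) else
      if (length(pos) == 2) list(pos, rev(pos)) else {
        out <- list()
        for (x in pos) for (y in setdiff(pos, x))
          out[[length(out) + 1]] <- c(x, y, setdiff(pos, c(x, y)))
        out
      }
    walk <- function(ord, allow_stop) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (!allow_stop && transl(nxt) == "*") return(NULL)
        if (transl(nxt) != "*" && transl(nxt) == transl(cur)) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
    if (!length(res)) res <- lapply(perms, walk, allow_stop = TRUE)
    colMeans(do.call(rbind, res))
  }
  co1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  co2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  keep <- grepl("^[ACGT]{3}$", co1) & grepl("^[ACGT]{3}$", co2)
  co1 <- co1[keep]; co2 <- co2[keep]
  S <- (sum(sapply(co1, syn_sites)) + sum(sapply(co2, syn_sites))) / 2
  N <- 3 * length(co1) - S
  d <- rowSums(sapply(seq_along(co1), function(i) path_diffs(co1[i], co2[i])))
  list(dS = d[1] / S, dN = d[2] / N, S = S, N = N, Sd = d[1], Nd = d[2])
}

# --- least-squares branch lengths for a fixed 4-taxon topology ---------------
# topology given as split list(c(1,2), c(3,4)) etc.; returns the LS fit of the
# 5 branch lengths and the residual sum of squares.
oracle_ls_quartet <- function(D, split) {
  # unrooted quartet: tips a,b | c,d with internal edge e
  a <- split[[1]][1]; b <- split[[1]][2]; c_ <- split[[2]][1]; d <- split[[2]][2]
  # path matrix rows: ab, ac, ad, bc, bd, cd ; cols: ta, tb, tc, td, te
  A <- rbind(c(1,1,0,0,0), c(1,0,1,0,1), c(1,0,0,1,1),
             c(0,1,1,0,1), c(0,1,0,1,1), c(0,0,1,1,0))
  y <- c(D[a,b], D[a,c_], D[a,d], D[b,c_], D[b,d], D[c_,d])
  fit <- qr.solve(A, y)
  rss <- sum((A %*% fit - y)^2)
  list(lengths = fit, rss = rss)
}

# --- brute-force mixture likelihood on a star tree over 61 codon states ------
oracle_star_lnl <- function(cds, branch_lengths, kappa, omega, pi = NULL) {
  codons <- kapkit:::sense_codons()
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  eig <- kapkit:::.gy_eig(kappa, omega, pi)
  Ps <- lapply(branch_lengths / eig$rate, function(t) kapkit:::.p_matrix(eig, t))
  n <- length(cds)
  mats <- lapply(cds, function(s)
    match(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)), codons))
  nsites <- length(mats[[1]])
  lnl <- 0
  for (s in seq_len(nsites)) {
    lik <- 0
    for (root in 1:61) {
      term <- pi[root]
      for (k in seq_len(n)) term <- term * Ps[[k]][root, mats[[k]][s]]
      lik <- lik + term
    }
    lnl <- lnl + log(lik)
  }
  lnl
}

# --- convenience: match candidates against simulation truth ------------------
match_truth <- function(candidates, truth, min_overlap = 0.5) {
  hit <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ov <- pmin(candidates$end[i], truth$end) - pmax(candidates$start[i], truth$start)
    same <- truth$scaffold == candidates$scaffold[i]
    frac <- ov / (truth$end - truth$start)
    j <- which(same & frac >= min_overlap)
    hit[i] <- if (length(j)) j[which.max(frac[j])] else NA_integer_
  }
  hit
}

# small deterministic simulation shared by several tests
default_test_sim <- function(seed = 7, ...) {
  simulate_repertoire(sim_config(seed = seed, n_clusters = 3,
                                 genes_per_cluster = c(3, 5),
                                 gene_length = c(60, 120), ...))
}
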