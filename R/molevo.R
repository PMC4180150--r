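# Divergence and composition statistics: modified Nei-Gojobori dS/dN with
# transition/transversion weighting, GC and GC3 content, and the correlation
# contrasts used to diagnose concerted evolution.

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# weighted synonymous site count of one codon: per position, the three point
# mutations are weighted R (transition) or 1 (transversion); mutations to
# stop codons count as nonsynonymous. Returns s in [0, 3]; n = 3 - s.
.codon_syn_sites <- function(codon, R, gc) {
  bases <- c("A", "C", "G", "T")
  aa0 <- gc[[codon]]
  s <- 0
  for (p in 1:3) {
    orig <- substr(codon, p, p)
    wsum <- 0; wsyn <- 0
    for (b in bases[bases != orig]) {
      mut <- codon
      substr(mut, p, p) <- b
      w <- if (.is_transition(orig, b)) R else 1
      wsum <- wsum + w
      if (gc[[mut]] != "*" && gc[[mut]] == aa0) wsyn <- wsyn + w
    }
    s <- s + wsyn / wsum
  }
  s
}

# average syn/nonsyn differences between two codons over all shortest
# mutational paths; paths through stop codons are excluded (all paths kept if
# every path is blocked)
.codon_syn_diffs <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd, list(pos),
                  list(pos, pos[2:1]),
                  { p <- pos
                    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                         p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)]) })
  count_path <- function(ord) {
    cur <- c1
    sdif <- 0; ndif <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") return(NULL)
      if (gc[[nxt]] == gc[[cur]]) sdif <- sdif + 1 else ndif <- ndif + 1
      cur <- nxt
    }
    c(sdif, ndif)
  }
  res <- lapply(perms, count_path)
  ok <- !vapply(res, is.null, TRUE)
  if (!any(ok)) {       # every path crosses a stop: keep all paths
    res <- lapply(perms, function(ord) {
      cur <- c1; sdif <- 0; ndif <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] != "*" && gc[[nxt]] == gc[[cur]]) sdif <- sdif + 1
        else ndif <- ndif + 1
        cur <- nxt
      }
      c(sdif, ndif)
    })
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(sd = mean(m[, 1L]), nd = mean(m[, 2L]))
}

#' Modified Nei-Gojobori divergence (p-distance variant)
#'
#' Synonymous and nonsynonymous sites are counted with transition/transversion
#' weighting (transitions weighted `R`, transversions 1, normalized per
#' position; mutations to stop codons count as nonsynonymous so that
#' S + N = 3 x compared codons). Differences are classified by averaging over
#' all shortest mutational paths, excluding paths through stop codons. No
#' multiple-hit correction is applied (dS and dN are proportions).
#'
#' Codons containing gaps or ambiguous bases in either sequence are skipped
#' (codon-wise pairwise deletion), and a terminal stop codon shared by both
#' sequences is stripped before comparison.
#'
#' @param cds1,cds2 Equal-length CDS strings (length divisible by 3, no
#'   internal stops among compared codons).
#' @param R Transition/transversion ratio used in site weighting.
#' @return List of class `divergence_pair`: `dS`, `dN`, `S_sites`, `N_sites`,
#'   `syn_diffs`, `nonsyn_diffs`, `codons_compared`, `R`.
#' @export
nei_gojobori <- function(cds1, cds2, R = 2) {
  if (nchar(cds1) != nchar(cds2)) stop("CDS lengths differ")
  if (nchar(cds1) %% 3L != 0L) stop("CDS length not divisible by 3")
  gc <- as.list(genetic_code())
  co1 <- split_codons(cds1); co2 <- split_codons(cds2)
  # a shared terminal stop codon is conventional and not compared
  n <- length(co1)
  last1 <- gc[[co1[n]]]; last2 <- gc[[co2[n]]]
  if (identical(last1, "*") && identical(last2, "*")) {
    co1 <- co1[-n]; co2 <- co2[-n]
  }
  ok <- grepl("^[ACGT]{3}$", co1) & grepl("^[ACGT]{3}$", co2)
  co1 <- co1[ok]; co2 <- co2[ok]
  if (any(unlist(gc[co1]) == "*") || any(unlist(gc[co2]) == "*"))
    stop("internal stop codon in compared codons")
  if (!length(co1)) stop("no comparable codons")
  S1 <- sum(vapply(co1, .codon_syn_sites, 0, R = R, gc = gc))
  S2 <- sum(vapply(co2, .codon_syn_sites, 0, R = R, gc = gc))
  S <- (S1 + S2) / 2
  N <- 3 * length(co1) - S
  diffs <- vapply(seq_along(co1), function(i)
    .codon_syn_diffs(co1[i], co2[i], gc), c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  structure(list(dS = if (S > 0) Sd / S else NA_real_,
                 dN = if (N > 0) Nd / N else NA_real_,
                 S_sites = S, N_sites = N, syn_diffs = Sd, nonsyn_diffs = Nd,
                 codons_compared = length(co1), R = R),
            class = "divergence_pair")
}

#' @export
print.divergence_pair <- function(x, ...) {
  cat(sprintf("dS = %.4f (Sd %.2f / S %.2f), dN = %.4f (Nd %.2f / N %.2f), %d codons, R = %g\n",
              x$dS, x$syn_diffs, x$S_sites, x$dN, x$nonsyn_diffs, x$N_sites,
              x$codons_compared, x$R))
  invisible(x)
}

#' GC and third-codon-position GC content
#'
#' @param cds DNA string (length divisible by 3 for GC3; Ns are excluded from
#'   numerator and denominator).
#' @return Named numeric vector `c(GC, GC3)` in percent.
#' @export
nucleotide_composition <- function(cds) {
  if (!nchar(cds)) stop("empty input")
  ch <- strsplit(cds, "", fixed = TRUE)[[1L]]
  valid <- ch %in% c("A", "C", "G", "T")
  gc_all <- 100 * sum(ch[valid] %in% c("G", "C")) / sum(valid)
  if (length(ch) %% 3L != 0L) stop("CDS length not divisible by 3 for GC3")
  third <- ch[seq(3L, length(ch), by = 3L)]
  v3 <- third %in% c("A", "C", "G", "T")
  gc3 <- 100 * sum(third[v3] %in% c("G", "C")) / sum(v3)
  c(GC = gc_all, GC3 = gc3)
}

.pearson <- function(x, y) {
  if (length(x) < 3L) stop("need >= 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]))
}

#' Correlation between subfamily divergence and GC content
#'
#' Pearson correlation of mean pairwise dS against GC% and GC3% across
#' subfamily summaries, per compositional class and pooled. A negative
#' correlation (low dS at high GC) is the signature of GC-biased gene
#' conversion homogenizing frequently converted subfamilies.
#'
#' @param summaries Data frame with columns `subfamily`, `class`, `mean_dS`,
#'   `GC`, `GC3`.
#' @return Nested list: `$pooled`, and one entry per class, each containing
#'   correlation results `dS_vs_GC` and `dS_vs_GC3`.
#' @export
divergence_vs_gc <- function(summaries) {
  stopifnot(all(c("class", "mean_dS", "GC", "GC3") %in% names(summaries)))
  run <- function(df) list(dS_vs_GC = .pearson(df$GC, df$mean_dS),
                           dS_vs_GC3 = .pearson(df$GC3, df$mean_dS))
  out <- list(pooled = run(summaries))
  for (cl in unique(summaries$class)) {
    sub <- summaries[summaries$class == cl, , drop = FALSE]
    if (nrow(sub) >= 3L) out[[cl]] <- run(sub)
  }
  out
}

#' Between-species correlation of subfamily gene counts, by class
#'
#' For every species pair, the Pearson correlation of per-subfamily gene
#' counts is computed within each compositional class; homogenized (strongly
#' concerted) classes show higher between-species count correlations than
#' classes evolving independently.
#'
#' @param table A `repertoire_table` (see [load_repertoire_table()]) or a
#'   plain counts matrix (subfamilies x species).
#' @param class_map Named character vector mapping subfamily to class.
#' @return List with per-class vectors of pairwise r, the difference of their
#'   means (`mean_diff`, first class minus second), and a two-sided paired
#'   t-test p-value over species pairs.
#' @export
count_correlation <- function(table, class_map) {
  counts <- if (inherits(table, "repertoire_table")) table$total else table
  classes <- unique(class_map[rownames(counts)])
  classes <- classes[!is.na(classes)]
  if (length(classes) < 2L) stop("need at least two classes")
  nsp <- ncol(counts)
  if (nsp < 2L) stop("need >= 2 species")
  pair_r <- function(sub) {
    rs <- c()
    for (i in seq_len(nsp - 1L)) for (j in (i + 1L):nsp) {
      x <- sub[, i]; y <- sub[, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      rs <- c(rs, stats::cor(x, y))
    }
    rs
  }
  out <- list()
  for (cl in classes) {
    sf <- intersect(names(class_map)[class_map == cl], rownames(counts))
    sub <- counts[sf, , drop = FALSE]
    if (nrow(sub) < 2L) stop("class with < 2 subfamilies: ", cl)
    out[[cl]] <- pair_r(sub)
  }
  a <- out[[classes[1L]]]; b <- out[[classes[2L]]]
  paired_n <- min(length(a), length(b))
  tt <- stats::t.test(a[seq_len(paired_n)], b[seq_len(paired_n)], paired = TRUE)
  out$mean_diff <- mean(a) - mean(b)
  out$p_value <- tt$p.value
  out
}

#' Per-subfamily divergence and composition summary
#'
#' Mean pairwise dS over all intact-gene pairs of each subfamily, with mean
#' GC% and GC3% over the member CDSs.
#'
#' @param cds_by_subfamily Named list: per subfamily, a named character vector
#'   of intact CDS strings (equal length within a subfamily).
#' @param class_map Named character vector mapping subfamily to class.
#' @param R Transition/transversion ratio for [nei_gojobori()].
#' @return Data frame with `subfamily`, `class`, `n_genes`, `mean_dS`, `GC`,
#'   `GC3`.
#' @export
subfamily_summary <- function(cds_by_subfamily, class_map, R = 2) {
  rows <- lapply(names(cds_by_subfamily), function(sf) {
    seqs <- cds_by_subfamily[[sf]]
    n <- length(seqs)
    ds <- c()
    if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- tryCatch(nei_gojobori(seqs[[i]], seqs[[j]], R = R),
                    error = function(e) NULL)
      if (is.null(d)) { warning("skipping pair with no comparable codons in ", sf)
      } else ds <- c(ds, d$dS)
    }
    comp <- vapply(seqs, nucleotide_composition, c(GC = 0, GC3 = 0))
    data.frame(subfamily = sf, class = unname(class_map[[sf]]), n_genes = n,
               mean_dS = if (length(ds)) mean(ds, na.rm = TRUE) else NA_real_,
               GC = mean(comp["GC", ]), GC3 = mean(comp["GC3", ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
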