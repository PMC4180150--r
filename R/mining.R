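# Homology mining: seed-and-extend nucleotide search, hit merging into locus
# fragments, frameshift-aware translated alignment, and gene-candidate calling
# with reciprocal-best-hit confirmation against a reference panel.

#' Default search parameters
#'
#' Conventional nucleotide-search settings: 11-mer seeds, +1/-2 match/mismatch,
#' affine gaps -5/-2, E-value cutoff 10. `karlin_k` is the Karlin-Altschul K
#' for the ungapped +1/-2 scheme; lambda is solved from the scoring scheme.
#' `min_seed_hits` requires at least that many chained seeds before a region
#' is extended (a two-hit heuristic suppressing isolated chance seed matches).
#' @param ... Overrides for any default.
#' @return Named list of parameters.
#' @export
search_params <- function(...) {
  p <- list(seed_len = 11L, match = 1, mismatch = -2, gap_open = -5,
            gap_extend = -2, evalue_cutoff = 10, karlin_k = 0.46,
            min_seed_hits = 2L)
  utils::modifyList(p, list(...))
}

# Karlin-Altschul lambda for an ungapped match/mismatch scheme with uniform
# base frequencies: solves sum_ij p_i p_j exp(lambda * s_ij) = 1.
karlin_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

#' Seed-and-extend homology search
#'
#' Finds exact `seed_len`-mer seeds of the query on both strands of every
#' scaffold, chains nearby seeds, extends each chain by local alignment, and
#' reports non-overlapping locally maximal hits with score, identity and an
#' ungapped Karlin-Altschul E-value. Hits with E-value above the cutoff are
#' dropped.
#'
#' @param query Named character vector of length 1 (or a record from
#'   [read_fasta()]): the query DNA.
#' @param scaffolds Named character vector or list of scaffold DNA strings.
#' @param params [search_params()].
#' @return Data frame: `query_id`, `scaffold`, `start`, `end` (0-based
#'   half-open, forward coordinates), `strand`, `score`, `identity`, `evalue`.
#' @export
seed_extend_search <- function(query, scaffolds, params = search_params()) {
  if (is.list(query) && !is.null(query$sequence))
    query <- stats::setNames(query$sequence, query$id)
  if (length(scaffolds) == 0L) stop("empty scaffold set")
  if (is.list(scaffolds) && length(scaffolds) && is.list(scaffolds[[1L]]))
    scaffolds <- vapply(scaffolds, `[[`, "", "sequence")
  scaffolds <- unlist(scaffolds)
  qid <- names(query); qseq <- unname(query)
  k <- params$seed_len
  if (nchar(qseq) < k) stop("query shorter than seed_len")
  lambda <- karlin_lambda(params$match, params$mismatch)
  db_len <- sum(nchar(scaffolds))

  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1L), k:n)
  }
  qk <- kmers_of(qseq)

  submat <- matrix(params$mismatch, 4, 4,
                   dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  diag(submat) <- params$match
  # tolerate ambiguity codes in scaffolds
  submat_full <- matrix(params$mismatch, 16, 16)
  letters16 <- c("A","C","G","T","N","R","Y","S","W","K","M","B","V","D","H","-")
  dimnames(submat_full) <- list(letters16, letters16)
  submat_full[1:4, 1:4] <- submat

  hits <- list()
  for (sname in names(scaffolds)) {
    fwd <- scaffolds[[sname]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      sk <- kmers_of(s)
      if (!length(sk)) next
      m <- match(sk, qk)
      pos <- which(!is.na(m))
      if (!length(pos)) next
      qpos <- m[pos]
      diag_ <- pos - qpos
      ord <- order(diag_, pos)
      pos <- pos[ord]; qpos <- qpos[ord]; diag_ <- diag_[ord]
      # chain seeds: same diagonal band (+-30) and close along the scaffold
      grp <- cumsum(c(TRUE, abs(diff(diag_)) > 30L | diff(pos) > 400L))
      for (g in unique(grp)) {
        sel <- grp == g
        if (sum(sel) < params$min_seed_hits) next
        sp <- pos[sel]; qp <- qpos[sel]
        w0 <- max(1L, min(sp) - min(qp) - 50L)
        w1 <- min(nchar(s), max(sp) + (nchar(qseq) - max(qp)) + k + 50L)
        win <- substr(s, w0, w1)
        pa <- Biostrings::pairwiseAlignment(
          qseq, win, type = "local", substitutionMatrix = submat_full,
          gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))
        score <- Biostrings::score(pa)
        if (score <= 0) next
        al_len <- Biostrings::nchar(pa)
        ident <- Biostrings::nmatch(pa) / al_len
        st <- w0 - 1L + Biostrings::start(Biostrings::subject(pa)) - 1L  # 0-based in s
        en <- st + Biostrings::width(Biostrings::subject(pa))
        if (strand == "-") { tmp <- st; st <- L - en; en <- L - tmp }
        ev <- params$karlin_k * nchar(qseq) * db_len * exp(-lambda * score)
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = qid, scaffold = sname, start = st, end = en,
          strand = strand, score = score, identity = ident, evalue = ev,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(query_id = character(), scaffold = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), identity = numeric(),
                      evalue = numeric()))
  h <- do.call(rbind, hits)
  h <- h[h$evalue <= params$evalue_cutoff, , drop = FALSE]
  # keep locally maximal non-overlapping hits per scaffold/strand
  keep <- rep(TRUE, nrow(h))
  ord <- order(-h$score)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (j in seq_along(ord)) {
      b <- ord[j]
      if (b == a || !keep[b] || h$score[b] > h$score[a]) next
      if (h$scaffold[a] == h$scaffold[b] && h$strand[a] == h$strand[b]) {
        ov <- min(h$end[a], h$end[b]) - max(h$start[a], h$start[b])
        if (ov > 0.5 * (h$end[b] - h$start[b])) keep[b] <- FALSE
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$scaffold, h$start), , drop = FALSE]
}

#' Merge search hits into locus fragments
#'
#' Each hit is extended by `flank` nt on both sides (clamped to scaffold
#' bounds); extended intervals on the same scaffold whose gap is at most
#' `cluster_gap` are merged transitively. Fragments longer than `max_fragment`
#' are split recursively at their largest internal gap.
#'
#' @param hits Data frame from [seed_extend_search()] (possibly several
#'   queries' results row-bound together).
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param flank Extension in nt (both sides).
#' @param max_fragment Hard ceiling on fragment length (nt).
#' @param cluster_gap Maximum gap between extended intervals to merge.
#' @return Data frame: `scaffold`, `start`, `end`, `n_hits`, `hit_rows`
#'   (comma-separated row indices of `hits` supporting the fragment).
#' @export
merge_hits <- function(hits, scaffold_lengths, flank = 500L,
                       max_fragment = 300000L, cluster_gap = 10000L) {
  if (nrow(hits) == 0L)
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), n_hits = integer(),
                      hit_rows = character()))
  ext_start <- pmax(0L, hits$start - flank)
  ext_end <- pmin(scaffold_lengths[hits$scaffold], hits$end + flank)
  frags <- list()
  split_frag <- function(scaf, idx, s, e) {
    if (e - s <= max_fragment || length(idx) <= 1L) {
      frags[[length(frags) + 1L]] <<- data.frame(
        scaffold = scaf, start = s, end = min(e, s + max_fragment),
        n_hits = length(idx), hit_rows = paste(idx, collapse = ","),
        stringsAsFactors = FALSE)
      return(invisible())
    }
    o <- idx[order(ext_start[idx])]
    gaps <- ext_start[o][-1L] - cummax(ext_end[o])[-length(o)]
    cut <- which.max(gaps)
    left <- o[seq_len(cut)]; right <- o[-seq_len(cut)]
    split_frag(scaf, left, min(ext_start[left]), max(ext_end[left]))
    split_frag(scaf, right, min(ext_start[right]), max(ext_end[right]))
  }
  for (scaf in unique(hits$scaffold)) {
    idx <- which(hits$scaffold == scaf)
    idx <- idx[order(ext_start[idx])]
    grp <- cumsum(c(TRUE, ext_start[idx][-1L] -
                      cummax(ext_end[idx])[-length(idx)] > cluster_gap))
    for (g in unique(grp)) {
      gi <- idx[grp == g]
      split_frag(scaf, gi, min(ext_start[gi]), max(ext_end[gi]))
    }
  }
  out <- do.call(rbind, frags)
  out[order(out$scaffold, out$start), , drop = FALSE]
}

# amino-acid alphabet / BLOSUM62 machinery shared with phylo
aa_alphabet <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  data_env$BLOSUM62
}

.codon_aa_map <- function(alpha) {
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  map <- integer(64)
  for (a in 0:3) for (b in 0:3) for (c in 0:3) {
    codon <- paste0(bases[a + 1], bases[b + 1], bases[c + 1])
    map[16 * a + 4 * b + c + 1L] <- match(gc[[codon]], alpha) - 1L
  }
  map
}

.dna_codes <- function(dna) {
  x <- match(strsplit(dna, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
  x[is.na(x)] <- 5L
  x - 1L
}

#' Frameshift-aware translated alignment
#'
#' Aligns a reference protein against a DNA fragment in all reading frames of
#' both strands, allowing inter-frame transitions at a frameshift penalty
#' (local alignment, BLOSUM62, linear gaps). Frame transitions and in-frame
#' stop codons inside the aligned span are reported in forward fragment
#' coordinates.
#'
#' @param reference_protein Amino-acid string.
#' @param fragment_dna DNA string (length >= 3).
#' @param fs_penalty Frameshift penalty (protein scale, negative).
#' @param gap_penalty Linear gap penalty per residue (negative).
#' @return List: `score`, `strand`, `dna_start`, `dna_end` (0-based half-open,
#'   forward coordinates), `prot_start`, `prot_end`, `frameshifts`,
#'   `internal_stops` (0-based forward positions), `identity`, `n_aligned`.
#' @export
translated_align <- function(reference_protein, fragment_dna,
                             fs_penalty = -12, gap_penalty = -10) {
  if (nchar(fragment_dna) < 3L) stop("fragment shorter than 3 nt")
  B <- aa_alphabet()
  alpha <- rownames(B)
  codon_map <- .codon_aa_map(alpha)
  prot <- match(strsplit(toupper(reference_protein), "", fixed = TRUE)[[1L]], alpha)
  if (anyNA(prot)) stop("non-amino-acid character in reference protein")
  prot <- prot - 1L
  x_idx <- match("X", alpha) - 1L
  stop_idx <- match("*", alpha) - 1L
  run <- function(dna_str, global = FALSE) {
    cpp_translated_align(.dna_codes(dna_str), prot, B, codon_map,
                         x_idx, stop_idx, fs_penalty, gap_penalty, global)
  }
  L <- nchar(fragment_dna)
  to_forward <- function(r, strand) {
    r$strand <- strand
    if (strand == "-") {
      ds <- L - r$dna_end; de <- L - r$dna_start
      r$dna_start <- ds; r$dna_end <- de
      r$frameshifts <- sort(L - 1L - r$frameshifts)
      r$internal_stops <- sort(L - 3L - r$internal_stops)
    }
    r$identity <- if (r$n_aligned > 0) r$n_identical / r$n_aligned else 0
    r
  }
  fw <- run(fragment_dna)
  rc <- revcomp(fragment_dna)
  rv <- run(rc)
  strand <- if (fw$score >= rv$score) "+" else "-"
  raw <- if (strand == "+") fw else rv
  r <- to_forward(raw, strand)
  # terminal-lesion rescue: a lesion-free local alignment that does not cover
  # the whole reference is re-aligned with the protein forced end-to-end
  # (free DNA ends); lesions in the first/last codons are otherwise trimmed
  # away by local alignment.
  covered <- raw$prot_end - raw$prot_start
  if (length(r$frameshifts) + length(r$internal_stops) == 0L &&
      covered < length(prot) && covered > 0.6 * length(prot)) {
    # residue skips are made costlier than a frameshift here, so that a
    # terminal lesion is interpreted as a lesion rather than a short gap
    run <- function(dna_str, global = FALSE) {
      cpp_translated_align(.dna_codes(dna_str), prot, B, codon_map,
                           x_idx, stop_idx, fs_penalty,
                           min(gap_penalty, fs_penalty - 4), global)
    }
    g <- run(if (strand == "+") fragment_dna else rc, global = TRUE)
    if (length(g$frameshifts) + length(g$internal_stops) > 0L &&
        g$score > raw$score - 30) {
      r <- to_forward(g, strand)
    }
  }
  r
}

#' Call gene candidates on locus fragments
#'
#' Within each fragment, supporting hits are grouped into gene windows; each
#' window is aligned against every panel protein with [translated_align()],
#' assigned to its best-scoring reference, given a gene model (complete ORF
#' when one matches; otherwise the aligned span with its frameshift/stop
#' lesions) and confirmed by a reciprocal best hit of the extracted candidate
#' sequence against the full panel. Candidates whose reciprocal best subfamily
#' differs from the assigning reference's subfamily, or that fall below the
#' score floor, are dropped.
#'
#' @param fragments Data frame from [merge_hits()].
#' @param hits The hit table passed to [merge_hits()].
#' @param scaffolds Named character vector of scaffold sequences.
#' @param panel Reference panel: list with `dna`, `protein`, `subfamily`
#'   (all named by reference id), as produced by [simulate_repertoire()].
#' @param min_orf Minimum ORF length in codons for an intact model.
#' @param min_score Minimum translated-alignment score to call a candidate.
#' @param min_aa Minimum aligned residues to call a candidate.
#' @param fs_penalty,gap_penalty Passed to [translated_align()].
#' @return Data frame of gene candidates (one row each) with coordinates,
#'   model evidence (`frameshifts`, `internal_stops`, `has_start`, `has_stop`)
#'   and the assigned reference/subfamily.
#' @export
call_candidates <- function(fragments, hits, scaffolds, panel,
                            min_orf = 40L, min_score = 100, min_aa = 30L,
                            fs_penalty = -12, gap_penalty = -10) {
  if (length(panel$protein) == 0L) stop("empty reference panel")
  if (is.list(scaffolds) && length(scaffolds) && is.list(scaffolds[[1L]]))
    scaffolds <- vapply(scaffolds, `[[`, "", "sequence")
  scaffolds <- unlist(scaffolds)
  out <- list()
  for (f in seq_len(nrow(fragments))) {
    scaf <- fragments$scaffold[f]
    L <- nchar(scaffolds[[scaf]])
    hrows <- as.integer(strsplit(fragments$hit_rows[f], ",")[[1L]])
    hw <- hits[hrows, , drop = FALSE]
    # group hits into gene windows: extended hit intervals that overlap
    ws <- pmax(0L, hw$start - 500L); we <- pmin(L, hw$end + 500L)
    o <- order(ws)
    grp <- cumsum(c(TRUE, ws[o][-1L] > cummax(we[o])[-length(o)]))
    for (g in unique(grp)) {
      sel <- o[grp == g]
      w0 <- min(ws[sel]); w1 <- max(we[sel])
      win <- substr(scaffolds[[scaf]], w0 + 1L, w1)
      best <- NULL; best_ref <- NA_character_
      for (ref in names(panel$protein)) {
        ta <- translated_align(panel$protein[[ref]], win,
                               fs_penalty = fs_penalty, gap_penalty = gap_penalty)
        if (is.null(best) || ta$score > best$score) { best <- ta; best_ref <- ref }
      }
      if (best$score < min_score || best$n_aligned < min_aa) next

      has_start <- FALSE; has_stop <- FALSE
      cds0 <- best$dna_start; cds1 <- best$dna_end; strand <- best$strand
      n_lesion <- length(best$frameshifts) + length(best$internal_stops)
      if (n_lesion == 0L) {
        orfs <- find_orfs(win, min_codons = min_orf)
        if (nrow(orfs)) {
          ov <- pmin(orfs$end, best$dna_end) - pmax(orfs$start, best$dna_start)
          orfs <- orfs[ov > 0.5 * (best$dna_end - best$dna_start) &
                         orfs$strand == strand, , drop = FALSE]
          if (nrow(orfs)) {
            cds0 <- orfs$start[1L]; cds1 <- orfs$end[1L]
            has_start <- TRUE; has_stop <- TRUE
          }
        }
      }
      abs0 <- w0 + cds0; abs1 <- w0 + cds1
      cand_dna <- if (strand == "+")
        substr(scaffolds[[scaf]], abs0 + 1L, abs1) else
        revcomp(substr(scaffolds[[scaf]], abs0 + 1L, abs1))
      # reciprocal best hit against the full panel on the extracted candidate
      rbh_ref <- NA_character_; rbh_score <- -Inf
      for (ref in names(panel$protein)) {
        ta2 <- translated_align(panel$protein[[ref]], cand_dna,
                                fs_penalty = fs_penalty, gap_penalty = gap_penalty)
        if (ta2$score > rbh_score) { rbh_score <- ta2$score; rbh_ref <- ref }
      }
      if (panel$subfamily[[rbh_ref]] != panel$subfamily[[best_ref]]) next

      prot <- if (has_start)
        translate_cds(cand_dna, trim_stop = TRUE) else ""
      out[[length(out) + 1L]] <- data.frame(
        gene_id = sprintf("%s_cand%d", scaf, length(out) + 1L),
        scaffold = scaf, start = abs0, end = abs1, strand = strand,
        best_reference = best_ref, subfamily = panel$subfamily[[best_ref]],
        score = best$score, identity = best$identity,
        frameshifts = paste(w0 + best$frameshifts, collapse = ","),
        internal_stops = paste(w0 + best$internal_stops, collapse = ","),
        n_lesions = n_lesion, has_start = has_start, has_stop = has_stop,
        protein = prot, cds = cand_dna, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), scaffold = character(),
                      start = integer(), end = integer(), strand = character(),
                      best_reference = character(), subfamily = character(),
                      score = numeric(), identity = numeric(),
                      frameshifts = character(), internal_stops = character(),
                      n_lesions = integer(), has_start = logical(),
                      has_stop = logical(), protein = character(),
                      cds = character()))
  res <- do.call(rbind, out)
  res[order(res$scaffold, res$start), , drop = FALSE]
}

#' Run the full mining pipeline on a genome
#'
#' Convenience wrapper: searches every panel DNA reference against the
#' scaffolds, merges hits into fragments and calls candidates.
#' @param scaffolds Named character vector of scaffold sequences.
#' @param panel Reference panel (see [call_candidates()]).
#' @param params [search_params()].
#' @param ... Passed to [call_candidates()].
#' @return List with `hits`, `fragments` and `candidates`.
#' @export
mine_genome <- function(scaffolds, panel, params = search_params(), ...) {
  if (is.list(scaffolds) && length(scaffolds) && is.list(scaffolds[[1L]]))
    scaffolds <- vapply(scaffolds, `[[`, "", "sequence")
  scaffolds <- unlist(scaffolds)
  hits <- do.call(rbind, lapply(names(panel$dna), function(ref)
    seed_extend_search(stats::setNames(panel$dna[[ref]], ref), scaffolds, params)))
  slen <- stats::setNames(nchar(scaffolds), names(scaffolds))
  fragments <- merge_hits(hits, slen)
  candidates <- call_candidates(fragments, hits, scaffolds, panel, ...)
  list(hits = hits, fragments = fragments, candidates = candidates)
}
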