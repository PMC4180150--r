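# Classification of gene candidates: integrity (intact/partial/pseudogene),
# compositional class (high-sulfur vs high glycine-tyrosine), subfamily and
# genomic cluster membership.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Integrity status of a gene candidate
#'
#' A candidate with one or more frameshifts or internal stop codons is a
#' pseudogene. A lesion-free candidate whose model lacks a start or stop
#' codon, or whose CDS abuts a scaffold end, is partial (truncated, typically
#' by low assembly coverage). Everything else is intact.
#'
#' @param candidate One row of the [call_candidates()] table (data frame or
#'   list with fields `n_lesions`, `has_start`, `has_stop`, `scaffold`,
#'   `start`, `end`).
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @return One of `"intact"`, `"partial"`, `"pseudogene"`.
#' @export
classify_integrity <- function(candidate, scaffold_lengths) {
  if (candidate$n_lesions >= 1L) return("pseudogene")
  at_edge <- candidate$start <= 0L ||
    candidate$end >= scaffold_lengths[[candidate$scaffold]]
  if (!isTRUE(candidate$has_start) || !isTRUE(candidate$has_stop) || at_edge)
    return("partial")
  "intact"
}

#' Amino-acid composition profile
#'
#' Percent of each of the 20 standard residues; stop characters (`*`) are
#' excluded before counting. Any other character is an error.
#'
#' @param protein Amino-acid string.
#' @return Named numeric vector of class `composition_profile` (20 values,
#'   percent, summing to 100) with attributes `cys`, `gly`, `tyr`,
#'   `gly_tyr` for the derived percentages.
#' @export
composition_profile <- function(protein) {
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  aa <- aa[aa != "*"]
  if (!length(aa)) stop("empty protein after removing stops")
  bad <- setdiff(unique(aa), AA20)
  if (length(bad)) stop("non-amino-acid character(s): ", paste(bad, collapse = ","))
  counts <- table(factor(aa, levels = AA20))
  pct <- 100 * as.numeric(counts) / length(aa)
  names(pct) <- AA20
  structure(pct, class = "composition_profile",
            cys = pct[["C"]], gly = pct[["G"]], tyr = pct[["Y"]],
            gly_tyr = pct[["G"]] + pct[["Y"]])
}

#' Compositional class of a protein
#'
#' Glycine+tyrosine at or above `hgt_glytyr` percent (with cysteine below the
#' ultrahigh threshold) gives HGT; otherwise cysteine above 30 percent gives
#' ultrahigh-sulfur, and the remainder is high-sulfur. A cysteine content of
#' exactly 30 falls in the high-sulfur class.
#'
#' @param profile A [composition_profile()] (or a protein string, which is
#'   profiled first).
#' @param ultra_cys Ultrahigh-sulfur cysteine threshold (percent).
#' @param hgt_glytyr Combined glycine+tyrosine threshold for HGT (percent).
#' @return One of `"HGT"`, `"HS_ultrahigh"`, `"HS_high"`.
#' @export
assign_class <- function(profile, ultra_cys = 30, hgt_glytyr = 30) {
  if (is.character(profile)) profile <- composition_profile(profile)
  cys <- attr(profile, "cys"); gt <- attr(profile, "gly_tyr")
  if (gt >= hgt_glytyr && cys < ultra_cys) return("HGT")
  if (cys > ultra_cys) return("HS_ultrahigh")
  "HS_high"
}

#' Assign a candidate to a subfamily
#'
#' Global protein alignment identity against every panel reference; the best
#' reference's subfamily is assigned when identity reaches `floor`. Ties are
#' broken by higher identity, then lexically by subfamily id. An optional
#' motif library (named list of regular expressions per subfamily) can veto an
#' assignment whose subfamily motif is absent while another subfamily's motif
#' matches.
#'
#' @param protein Candidate protein string.
#' @param panel Reference panel (list with `protein` and `subfamily`).
#' @param motif_library Optional named list of peptide regexes per subfamily.
#' @param floor Minimum identity for assignment.
#' @return List with `subfamily` (or `"unassigned"`) and `confidence`
#'   (identity of the best reference).
#' @export
assign_subfamily <- function(protein, panel, motif_library = NULL, floor = 0.6) {
  if (length(panel$protein) == 0L) stop("empty reference panel")
  B <- aa_alphabet()
  ids <- names(panel$protein)
  ident <- vapply(ids, function(ref) {
    pa <- Biostrings::pairwiseAlignment(
      protein, panel$protein[[ref]], type = "global",
      substitutionMatrix = B, gapOpening = 10, gapExtension = 1)
    Biostrings::nmatch(pa) / max(nchar(protein), nchar(panel$protein[[ref]]))
  }, 0)
  subfams <- vapply(ids, function(ref) panel$subfamily[[ref]], "")
  ord <- order(-ident, subfams)
  best <- ord[1L]
  if (ident[best] < floor)
    return(list(subfamily = "unassigned", confidence = unname(ident[best])))
  assigned <- subfams[best]
  if (!is.null(motif_library) && !is.null(motif_library[[assigned]])) {
    if (!grepl(motif_library[[assigned]], protein)) {
      others <- names(motif_library)[vapply(motif_library, function(m)
        grepl(m, protein), TRUE)]
      others <- setdiff(others, assigned)
      if (length(others))
        return(list(subfamily = "unassigned", confidence = unname(ident[best])))
    }
  }
  list(subfamily = unname(assigned), confidence = unname(ident[best]))
}

#' Assign genes to genomic clusters
#'
#' Single-linkage grouping of genes on the same scaffold whose inter-gene gap
#' is at most `gap_threshold`; cluster ids are ordered by scaffold then
#' coordinate.
#'
#' @param annotations Data frame with `scaffold`, `start`, `end`.
#' @param gap_threshold Maximum gap (nt) between consecutive genes of a
#'   cluster.
#' @return The data frame with a `cluster_id` integer column added.
#' @export
cluster_assignment <- function(annotations, gap_threshold = 200000L) {
  ord <- order(annotations$scaffold, annotations$start)
  cl <- integer(nrow(annotations))
  cur <- 0L
  prev_scaf <- NULL; prev_end <- -Inf
  for (i in ord) {
    new_cluster <- is.null(prev_scaf) ||
      annotations$scaffold[i] != prev_scaf ||
      annotations$start[i] - prev_end > gap_threshold
    if (new_cluster) cur <- cur + 1L
    cl[i] <- cur
    prev_scaf <- annotations$scaffold[i]
    prev_end <- if (new_cluster) annotations$end[i] else
      max(prev_end, annotations$end[i])
  }
  annotations$cluster_id <- cl
  annotations
}

#' Annotate mined candidates
#'
#' Applies integrity, compositional class, subfamily and cluster assignment to
#' a candidate table. For lesioned or truncated candidates (no clean
#' translation) the class is taken from the assigning reference's protein.
#'
#' @param candidates Data frame from [call_candidates()].
#' @param scaffolds Named character vector of scaffold sequences.
#' @param panel Reference panel.
#' @param gap_threshold Passed to [cluster_assignment()].
#' @param floor Passed to [assign_subfamily()].
#' @return Annotation data frame (one row per candidate) with `status`,
#'   `class`, `subfamily`, `cluster_id` and composition percentages.
#' @export
annotate_candidates <- function(candidates, scaffolds, panel,
                                gap_threshold = 200000L, floor = 0.6) {
  if (is.list(scaffolds) && length(scaffolds) && is.list(scaffolds[[1L]]))
    scaffolds <- vapply(scaffolds, `[[`, "", "sequence")
  scaffolds <- unlist(scaffolds)
  slen <- stats::setNames(nchar(scaffolds), names(scaffolds))
  n <- nrow(candidates)
  status <- character(n); cls <- character(n); subfam <- character(n)
  conf <- numeric(n); cysp <- glyp <- tyrp <- numeric(n)
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    status[i] <- classify_integrity(cand, slen)
    prot <- cand$protein
    if (!nzchar(prot)) prot <- panel$protein[[cand$best_reference]]
    prof <- composition_profile(prot)
    cls[i] <- assign_class(prof)
    cysp[i] <- attr(prof, "cys"); glyp[i] <- attr(prof, "gly")
    tyrp[i] <- attr(prof, "tyr")
    sf <- if (nzchar(cand$protein))
      assign_subfamily(cand$protein, panel, floor = floor) else
      list(subfamily = unname(cand$subfamily), confidence = cand$identity)
    subfam[i] <- sf$subfamily; conf[i] <- sf$confidence
  }
  ann <- data.frame(gene_id = candidates$gene_id,
                    scaffold = candidates$scaffold,
                    start = candidates$start, end = candidates$end,
                    strand = candidates$strand, status = status, class = cls,
                    subfamily = subfam, confidence = conf,
                    cys_pct = cysp, gly_pct = glyp, tyr_pct = tyrp,
                    stringsAsFactors = FALSE)
  cluster_assignment(ann, gap_threshold)
}
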