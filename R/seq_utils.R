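# Sequence helpers shared across modules. DNA is handled as plain uppercase
# character strings; N is tolerated (low-coverage assemblies contain Ns).

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D", "-" = "-")

#' Reverse complement of a DNA string
#' @param dna Uppercase DNA string (IUPAC codes and '-' allowed).
#' @return The reverse complement string.
#' @export
revcomp <- function(dna) {
  ch <- rev(strsplit(dna, "", fixed = TRUE)[[1L]])
  out <- COMPLEMENT[ch]
  if (anyNA(out)) stop("non-IUPAC character in DNA: ",
                       paste(unique(ch[is.na(out)]), collapse = ","))
  paste(out, collapse = "")
}

# standard genetic code as a named vector codon -> one-letter AA ('*' = stop)
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Split a CDS into codons
#' @param cds DNA string, length divisible by 3.
#' @return Character vector of codons.
#' @export
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a CDS to protein
#'
#' Uses the standard genetic code; stops are rendered as `*`; codons containing
#' N or gaps translate to `X`.
#' @param cds DNA string with length divisible by 3.
#' @param trim_stop Drop a single trailing stop if present.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, trim_stop = FALSE) {
  codons <- split_codons(cds)
  gc <- genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  p <- paste(aa, collapse = "")
  if (trim_stop) p <- sub("\\*$", "", p)
  p
}

# positions of internal stop codons (codon index, 1-based), ignoring the final codon
internal_stop_codons <- function(cds) {
  codons <- split_codons(cds)
  if (length(codons) < 2L) return(integer())
  gc <- genetic_code()
  aa <- gc[codons[-length(codons)]]
  which(!is.na(aa) & aa == "*")
}

#' Find open reading frames
#'
#' Scans all six reading frames for ATG..stop ORFs.
#'
#' @param dna DNA string.
#' @param min_codons Minimum ORF length in codons (ATG and stop included).
#' @param both_strands Search the reverse complement too.
#' @return Data frame with columns `start`, `end` (0-based half-open on the
#'   forward sequence), `strand`, `codons`; sorted by decreasing length. The
#'   ORF spans ATG through the stop codon inclusive.
#' @export
find_orfs <- function(dna, min_codons = 40L, both_strands = TRUE) {
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    res <- list()
    for (frame in 0:2) {
      starts <- seq(1L + frame, n - 2L, by = 3L)
      if (length(starts) == 0L) next
      codons <- substring(s, starts, starts + 2L)
      is_atg <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open) && is_atg[i]) open <- i
        if (!is.na(open) && is_stop[i]) {
          len <- i - open + 1L
          if (len >= min_codons) {
            a <- starts[open] - 1L; b <- starts[i] + 2L   # 0-based half-open
            if (strand == "+") res[[length(res) + 1L]] <- c(a, b, len)
            else res[[length(res) + 1L]] <- c(n - b, n - a, len)
          }
          open <- NA_integer_
        }
      }
    }
    if (!length(res)) return(NULL)
    m <- do.call(rbind, res)
    data.frame(start = m[, 1L], end = m[, 2L], strand = strand, codons = m[, 3L])
  }
  out <- scan_strand(dna, "+")
  if (both_strands) out <- rbind(out, scan_strand(revcomp(dna), "-"))
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), codons = integer()))
  out[order(-out$codons, out$start), , drop = FALSE]
}

#' Random DNA sequence
#' @param n Length in nucleotides.
#' @param gc GC fraction.
#' @return DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substring by 0-based half-open interval on its own strand
extract_interval <- function(scaffolds, gi) {
  s <- scaffolds[[gi$scaffold_id]]
  if (is.list(s)) s <- s$sequence
  sub <- substr(s, gi$start + 1L, gi$end)
  if (gi$strand == "-") revcomp(sub) else sub
}
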