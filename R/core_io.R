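#' Genomic interval
#'
#' Construct a genomic interval in the package-wide coordinate convention:
#' 0-based, half-open (`start` inclusive, `end` exclusive). GFF3 output is the
#' only 1-based surface of the package.
#'
#' @param scaffold_id Scaffold (sequence) identifier.
#' @param start 0-based inclusive start (non-negative integer).
#' @param end Exclusive end; must satisfy `end > start`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval` (a named list).
#' @examples
#' gi <- genomic_interval("scaf1", 0L, 10L)
#' interval_length(gi)  # 10
#' @export
genomic_interval <- function(scaffold_id, start, end, strand = "+") {
  stopifnot(is.character(scaffold_id), length(scaffold_id) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L)
    stop("interval start must be a non-negative integer")
  if (end <= start)
    stop("interval end must exceed start (0-based half-open)")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  structure(list(scaffold_id = scaffold_id, start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$scaffold_id, x$start, x$end, x$strand))
  invisible(x)
}

#' Read a FASTA file
#'
#' Minimal strict FASTA reader. Sequences are whitespace-stripped, uppercased
#' and concatenated across lines; record order is preserved. Malformed input
#' (data before the first header, empty record) raises an error naming the
#' offending line.
#'
#' @param path Path to a FASTA file.
#' @return A named list of sequence records; each element is a list with
#'   fields `id`, `description` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop(sprintf("FASTA parse error at line 1: expected '>' header, got '%s'",
                 substr(lines[1L], 1L, 30L)))
  hdr_idx <- which(is_hdr)
  recs <- vector("list", length(hdr_idx))
  ids <- character(length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (i in seq_along(hdr_idx)) {
    h <- sub("^>", "", lines[hdr_idx[i]])
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    body <- lines[seq.int(hdr_idx[i] + 1L, bounds[i + 1L] - 1L,
                          length.out = max(0L, bounds[i + 1L] - hdr_idx[i] - 1L))]
    seqc <- toupper(gsub("[ \t\r]", "", paste(body, collapse = "")))
    if (nchar(seqc) == 0L)
      stop(sprintf("FASTA parse error at line %d: record '%s' has no sequence",
                   hdr_idx[i], id))
    ids[i] <- id
    recs[[i]] <- list(id = id, description = desc, sequence = seqc)
  }
  names(recs) <- ids
  recs
}

#' Write sequences to FASTA
#'
#' @param records Named character vector of sequences, or a list of records as
#'   returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.list(records) && length(records) && is.list(records[[1L]])) {
    seqs <- vapply(records, `[[`, "", "sequence")
    ids <- vapply(records, `[[`, "", "id")
    desc <- vapply(records, `[[`, "", "description")
  } else {
    seqs <- as.character(records)
    ids <- names(records)
    if (is.null(ids)) stop("records must be named")
    desc <- rep("", length(seqs))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hdr <- if (nzchar(desc[i])) paste0(">", ids[i], " ", desc[i]) else paste0(">", ids[i])
    writeLines(hdr, con)
    s <- seqs[i]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write intervals as GFF3
#'
#' Columns 4-5 are converted to the 1-based inclusive convention GFF3 requires
#' (`start + 1`, `end`).
#'
#' @param intervals List of [genomic_interval()] objects.
#' @param path Output path.
#' @param attributes Optional list (same length) of named character vectors,
#'   written as `key=value` pairs in column 9.
#' @param source,type Columns 2 and 3.
#' @export
write_gff3 <- function(intervals, path, attributes = NULL,
                       source = "kapkit", type = "gene") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(intervals)) {
    gi <- intervals[[i]]
    attr_str <- "."
    if (!is.null(attributes) && length(attributes) >= i && length(attributes[[i]])) {
      a <- attributes[[i]]
      attr_str <- paste(paste0(names(a), "=", a), collapse = ";")
    }
    writeLines(paste(gi$scaffold_id, source, type, gi$start + 1L, gi$end,
                     ".", gi$strand, ".", attr_str, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path Path to a GFF3 file.
#' @return A list with `intervals` (list of `genomic_interval`) and
#'   `attributes` (list of named character vectors).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  intervals <- vector("list", length(lines))
  attrs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop(sprintf("GFF3 parse error: line %d has %d columns", i, length(f)))
    intervals[[i]] <- genomic_interval(f[1L], as.integer(f[4L]) - 1L,
                                       as.integer(f[5L]), f[7L])
    if (f[9L] != ".") {
      kv <- strsplit(strsplit(f[9L], ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
      a <- vapply(kv, function(p) if (length(p) > 1L) p[2L] else "", "")
      names(a) <- vapply(kv, `[[`, "", 1L)
      attrs[[i]] <- a
    } else attrs[[i]] <- character()
  }
  list(intervals = intervals, attributes = attrs)
}

#' Read or write a tab-separated table with a header row
#'
#' Thin wrappers over [utils::read.delim()] / [utils::write.table()] fixing the
#' package's TSV conventions (no quoting, no row names).
#' @param path File path.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_tsv
#' @param df Data frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
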