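#' Read a BED6+1 conversion-read file
#'
#' The dialect is standard BED6 (0-based half-open, tab-separated) plus a
#' seventh column listing conversion offsets: comma-separated 0-based offsets
#' from the read start where a T-to-C (plus strand) or A-to-G (minus strand)
#' mismatch was observed, or `.` for none.
#'
#' @param path file path (plain or gzipped).
#' @return conversion-read data.frame (chrom, start, end, name, score,
#'   strand, conversions list-column).
#' @export
read_bed6c <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_reads())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  errs <- character(0)
  n <- length(parts)
  chrom <- name <- strand <- character(n)
  start <- end <- score <- integer(n)
  convs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) != 7L) { errs <- c(errs, sprintf("line %d: expected 7 columns, got %d", i, length(p))); next }
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e) || e <= s) { errs <- c(errs, sprintf("line %d: bad interval [%s, %s)", i, p[2], p[3])); next }
    if (!p[6] %in% c("+", "-")) { errs <- c(errs, sprintf("line %d: unknown strand '%s'", i, p[6])); next }
    off <- if (p[7] == ".") integer(0) else suppressWarnings(as.integer(strsplit(p[7], ",", fixed = TRUE)[[1]]))
    if (anyNA(off)) { errs <- c(errs, sprintf("line %d: non-integer conversion offsets '%s'", i, p[7])); next }
    if (any(off < 0L | off >= e - s)) {
      errs <- c(errs, sprintf("line %d: conversion offset outside read of length %d", i, e - s)); next
    }
    chrom[i] <- p[1]; start[i] <- s; end[i] <- e; name[i] <- p[4]
    score[i] <- suppressWarnings(as.integer(p[5])); strand[i] <- p[6]
    convs[[i]] <- sort(off)
  }
  if (length(errs) > 0L)
    stop("malformed BED6+1 file ", path, ":\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   score = score, strand = strand, stringsAsFactors = FALSE)
  df$conversions <- I(convs)
  df
}

#' Write a conversion-read table as BED6+1
#' @param reads conversion-read data.frame.
#' @param path output path.
#' @export
write_bed6c <- function(reads, path) {
  col7 <- vapply(reads$conversions, function(x)
    if (length(x) == 0L) "." else paste(x, collapse = ","), character(1))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s", reads$chrom, reads$start,
                   reads$end, reads$name, reads$score, reads$strand, col7)
  writeLines(lines, path)
  invisible(path)
}

#' Transcript-space conversion positions of each read
#'
#' Plus strand: `start + offset`; minus strand: `end - 1 - offset`.
#' @param reads conversion-read table.
#' @return list of integer position vectors, one per read.
#' @export
conversion_positions <- function(reads) {
  Map(function(s, e, st, off) {
    if (length(off) == 0L) integer(0)
    else if (st == "+") s + off else e - 1L - off
  }, reads$start, reads$end, reads$strand, reads$conversions)
}

.read_tsv_schema <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read a transcript annotation table
#'
#' Required columns: transcript_id, utr5_len, orf_start, orf_end, total_len
#' (0-based half-open; orf_start equals utr5_len).
#' @param path TSV path.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  df <- .read_tsv_schema(path, c("transcript_id", "utr5_len", "orf_start",
                                 "orf_end", "total_len"), "annotation")
  bad <- df$orf_end <= df$orf_start | df$orf_start != df$utr5_len |
    df$orf_end > df$total_len | df$utr5_len < 0
  if (any(bad))
    stop("annotation file ", path, ": invalid segment bounds for transcript(s) ",
         paste(df$transcript_id[bad], collapse = ", "), call. = FALSE)
  df
}

#' Write a transcript annotation table
#' @param annotation annotation data.frame.
#' @param path TSV path.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-transcript count table (columns transcript_id, count)
#' @param path TSV path.
#' @return data.frame; a header-only file yields an empty table.
#' @export
read_counts <- function(path) {
  df <- .read_tsv_schema(path, c("transcript_id", "count"), "count")
  if (nrow(df) > 0 && any(df$count < 0))
    stop("count file ", path, ": negative counts", call. = FALSE)
  df
}

#' Read a per-nucleotide score track (columns transcript_id, pos, score)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_track <- function(path) {
  .read_tsv_schema(path, c("transcript_id", "pos", "score"), "track")
}

#' Read a measurement table, checking a required schema
#' @param path TSV path.
#' @param required required column names.
#' @return data.frame.
#' @export
read_measurements <- function(path, required = character(0)) {
  .read_tsv_schema(path, required, "measurement")
}

#' Write a generic TSV table
#' @param df data.frame.
#' @param path TSV path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called binding sites
#'
#' Emits BED6 with the score column carrying the conversion count (a
#' documented deviation from the BED score semantics) plus a sidecar TSV
#' (`<path>.tsv`) with read counts and the mode location.
#'
#' @param sites binding-site data.frame from [call_sites()].
#' @param path BED output path.
#' @return invisibly, c(bed = path, sidecar = sidecar path).
#' @export
write_sites <- function(sites, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$chrom, sites$start,
                   sites$end, sites$name, sites$conversion_count, sites$strand)
  writeLines(lines, path)
  sidecar <- paste0(path, ".tsv")
  write.table(sites[, c("name", "chrom", "start", "end", "strand",
                        "read_count", "conversion_count",
                        "conversion_read_count", "mode_location")],
              sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = path, sidecar = sidecar))
}

#' Read binding sites written by [write_sites()]
#' @param path BED path (sidecar `<path>.tsv` must be present).
#' @return binding-site data.frame.
#' @export
read_sites <- function(path) {
  sc <- .read_tsv_schema(paste0(path, ".tsv"),
                         c("name", "chrom", "start", "end", "strand",
                           "read_count", "conversion_count",
                           "conversion_read_count", "mode_location"), "site")
  sc[, c("chrom", "start", "end", "name", "strand", "read_count",
         "conversion_count", "conversion_read_count", "mode_location")]
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping the package's internal
#' representation (named character vector).
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
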