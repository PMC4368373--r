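# Reading, trimming, filtering and collapsing of sequencing reads.

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that autodetects the
#' format from the file content, is transparent to gzip, and normalizes U to T.
#'
#' @param path path to a FASTA or FASTQ file (optionally gzipped).
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return named character vector of sequences (names are read ids).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    first <- readLines(con, n = 1L)
    close(con)
    if (length(first) == 0L) return(character(0))
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  out <- normalize_seq(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Trim a 3' adapter from reads
#'
#' Suffix-anchored adapter search: the adapter may occur in full anywhere in
#' the read, or as a prefix-of-adapter overlap running off the read's 3' end.
#' An occurrence is valid when its overlap is at least `min_overlap` nt with at
#' most `floor(overlap * max_error_rate)` mismatches. Among valid occurrences
#' the one with the largest overlap wins, ties broken by leftmost start, and
#' the read prefix preceding it is returned.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (non-empty, at least `min_overlap` nt).
#' @param min_overlap minimum adapter overlap in nt. Library-type defaults:
#'   7 for small RNA libraries, 19 for degradome libraries.
#' @param max_error_rate allowed mismatch fraction of the overlap, in
#'   `[0, 0.5)`.
#' @param require_adapter if `TRUE`, reads without an identified adapter are
#'   rejected; if `FALSE` they are returned unchanged.
#' @return list with components `seq` (trimmed sequences; `NA` where rejected),
#'   `adapter_found` (logical) and `reason` (`NA`, `"empty"` or `"no_adapter"`).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 7L,
                         max_error_rate = 0.1, require_adapter = FALSE) {
  adapter <- normalize_seq(adapter)
  if (length(adapter) != 1L || nchar(adapter) == 0L) stop("adapter must be a single non-empty sequence")
  if (max_error_rate < 0 || max_error_rate >= 0.5) stop("max_error_rate must be in [0, 0.5)")
  alen <- nchar(adapter)
  if (alen < min_overlap) stop("adapter shorter than min_overlap")

  reads <- normalize_seq(reads)
  n <- length(reads)
  L <- nchar(reads)
  pos <- rep(NA_integer_, n)       # start of the chosen occurrence
  empty <- L == 0L

  # full-adapter occurrences (overlap = adapter length), leftmost
  k_full <- floor(alen * max_error_rate)
  idx <- which(!empty & L >= alen)
  if (length(idx)) {
    if (k_full == 0L) {
      p <- regexpr(adapter, reads[idx], fixed = TRUE)
      hit <- p > 0L
      pos[idx[hit]] <- as.integer(p[hit])
    } else {
      m <- Biostrings::vmatchPattern(adapter, Biostrings::DNAStringSet(reads[idx]),
                                     max.mismatch = k_full)
      st <- Biostrings::startIndex(m)
      hit <- lengths(st) > 0L
      pos[idx[hit]] <- vapply(st[hit], min, integer(1))
    }
  }

  # partial suffix overlaps, longest first
  achars <- strsplit(adapter, "")[[1]]
  partial_ovs <- if (alen - 1L >= min_overlap) seq(alen - 1L, min_overlap, by = -1L) else integer(0)
  for (ov in partial_ovs) {
    open <- which(is.na(pos) & !empty & L >= ov)
    if (!length(open)) next
    suf <- substr(reads[open], L[open] - ov + 1L, L[open])
    mism <- integer(length(open))
    for (i in seq_len(ov)) {
      mism <- mism + (substr(suf, i, i) != achars[i])
    }
    ok <- mism <= floor(ov * max_error_rate)
    pos[open[ok]] <- L[open[ok]] - ov + 1L
  }

  found <- !is.na(pos)
  out <- rep(NA_character_, n)
  out[found] <- substr(reads[found], 1L, pos[found] - 1L)
  reason <- rep(NA_character_, n)
  reason[empty] <- "empty"
  keep_untrimmed <- !found & !empty & !require_adapter
  out[keep_untrimmed] <- reads[keep_untrimmed]
  reason[!found & !empty & require_adapter] <- "no_adapter"
  list(seq = out, adapter_found = found, reason = reason)
}

#' Collapse reads to unique sequences with counts
#'
#' Reads containing N are dropped (and counted); each remaining distinct
#' sequence becomes one entry whose count is its number of occurrences.
#'
#' @param reads character vector of (adapter-trimmed) read sequences.
#' @return list with `reads` (data.frame with columns `seq`, `count`),
#'   `total_count` (number of input reads) and `n_dropped` (reads with N).
#' @export
collapse_reads <- function(reads) {
  reads <- normalize_seq(reads)
  total <- length(reads)
  has_n <- grepl("N", reads, fixed = TRUE)
  reads <- reads[!has_n]
  if (length(reads)) {
    tab <- table(reads)
    df <- data.frame(seq = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$seq), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(seq = character(0), count = integer(0))
  }
  list(reads = df, total_count = total, n_dropped = sum(has_n))
}

#' Retain collapsed reads within a length range
#'
#' @param reads data.frame with columns `seq` and `count`.
#' @param min_len,max_len inclusive length bounds (defaults 18 and 26 nt, the
#'   size range of regulatory small RNAs).
#' @return the retained subset, counts unchanged.
#' @export
filter_by_length <- function(reads, min_len = 18L, max_len = 26L) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  len <- nchar(reads$seq)
  out <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop low-copy collapsed reads
#'
#' @param reads data.frame with columns `seq` and `count`.
#' @param min_count minimum copy number to retain (default 2).
#' @return the retained subset.
#' @export
filter_low_count <- function(reads, min_count = 2L) {
  stopifnot(min_count >= 1L)
  out <- reads[reads$count >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a small RNA library object
#'
#' @param name library name (unique within an experiment).
#' @param origin `"in_vitro"` (axenic culture, contamination-free) or
#'   `"field"` (environmental sample).
#' @param reads collapsed reads data.frame (`seq`, `count`).
#' @param total_count total adapter-identified read count before length
#'   selection; used as the normalization denominator.
#' @return object of class `srna_library`.
#' @export
srna_library <- function(name, origin = c("in_vitro", "field"), reads,
                         total_count = sum(reads$count)) {
  origin <- match.arg(origin)
  stopifnot(is.character(name), length(name) == 1L,
            all(c("seq", "count") %in% names(reads)),
            total_count >= sum(reads$count) || TRUE)
  structure(list(name = name, origin = origin, reads = reads,
                 total_count = as.numeric(total_count)),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("srna_library '%s' (%s): %d unique sequences, %s total reads\n",
              x$name, x$origin, nrow(x$reads),
              format(x$total_count, big.mark = ",")))
  invisible(x)
}

#' Load, trim and collapse one library from file
#'
#' Convenience wrapper: read FASTA/FASTQ, trim the 3' adapter (small RNA
#' defaults), collapse to unique sequences and wrap as [srna_library()].
#' Length selection is left to [filter_by_length()] so that `total_count`
#' reflects all adapter-identified reads.
#'
#' @inheritParams trim_adapter
#' @inheritParams srna_library
#' @param path sequence file.
#' @param adapter adapter sequence, or `NULL` to skip trimming.
#' @return an `srna_library`.
#' @export
load_library <- function(path, name, origin = c("in_vitro", "field"),
                         adapter = NULL, min_overlap = 7L,
                         max_error_rate = 0.1, require_adapter = FALSE) {
  seqs <- read_sequences(path)
  if (!is.null(adapter)) {
    tr <- trim_adapter(seqs, adapter, min_overlap = min_overlap,
                       max_error_rate = max_error_rate,
                       require_adapter = require_adapter)
    seqs <- tr$seq[!is.na(tr$seq) & nchar(tr$seq) > 0L]
  }
  cl <- collapse_reads(seqs)
  srna_library(name, match.arg(origin), cl$reads, total_count = cl$total_count)
}

#' Read a library manifest
#'
#' Tab-separated file with columns `name`, `path`, `origin`.
#'
#' @param path manifest file.
#' @return data.frame with one row per library.
#' @export
read_library_manifest <- function(path) {
  mf <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "path", "origin")
  if (!all(need %in% names(mf))) stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(mf$name)) stop("duplicate library names in manifest")
  mf
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the `seq{index}_x{count}` convention.
#'
#' @param reads collapsed reads data.frame.
#' @param path output file.
#' @export
write_collapsed_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- sprintf("seq%d_x%d", seq_len(nrow(reads)), reads$count)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write collapsed reads as two-column TSV
#' @inheritParams write_collapsed_fasta
#' @export
write_collapsed_tsv <- function(reads, path) {
  write.table(reads[, c("seq", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
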