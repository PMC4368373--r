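# Assignment of reads/clusters to known miRNA families by ungapped overlap
# alignment with a mismatch budget, and cross-species homology scans.

#' Best ungapped overlap alignment of two short sequences
#'
#' Slides one sequence against the other over all ungapped offsets with
#' overlap of at least `min_overlap` nt and returns the alignment minimizing
#' the number of mismatches in the overlapping region (the Mn statistic).
#' Ties are broken by larger overlap, then smaller absolute offset, so the
#' result is deterministic and favors containment of the shorter sequence.
#'
#' @param query,ref nucleotide sequences (U and T equivalent).
#' @param min_overlap minimum overlap length (default 17).
#' @return object of class `overlap_alignment`: `query`, `ref`, `offset`
#'   (0-based position of ref start relative to query start), `overlap_len`,
#'   `mismatches`, and `mismatch_positions` (1-based query coordinates).
#' @export
best_overlap_alignment <- function(query, ref, min_overlap = 17L) {
  q <- strsplit(normalize_seq(query), "")[[1]]
  r <- strsplit(normalize_seq(ref), "")[[1]]
  nq <- length(q); nr <- length(r)
  if (min(nq, nr) < min_overlap) stop("no valid overlap")
  best <- NULL
  for (off in seq(-(nr - 1L), nq - 1L)) {
    s <- max(1L, 1L + off)            # query coords of the overlap
    e <- min(nq, nr + off)
    ov <- e - s + 1L
    if (ov < min_overlap) next
    neq <- q[s:e] != r[(s - off):(e - off)]
    mm <- sum(neq)
    if (is.null(best) || mm < best$mismatches ||
        (mm == best$mismatches && ov > best$overlap_len) ||
        (mm == best$mismatches && ov == best$overlap_len &&
         abs(off) < abs(best$offset))) {
      best <- list(query = paste(q, collapse = ""),
                   ref = paste(r, collapse = ""),
                   offset = off, overlap_len = ov, mismatches = mm,
                   mismatch_positions = (s:e)[neq])
    }
  }
  if (is.null(best)) stop("no valid overlap")
  structure(best, class = "overlap_alignment")
}

#' @export
print.overlap_alignment <- function(x, ...) {
  cat(sprintf("overlap_alignment: offset %d, overlap %d nt, Mn = %d\n",
              x$offset, x$overlap_len, x$mismatches))
  invisible(x)
}

#' Read a mature miRNA reference catalogue
#'
#' Accepts FASTA with `family|member|species` headers or a tab-separated file
#' with columns `family`, `member`, `species`, `seq`.
#'
#' @param path catalogue file.
#' @return data.frame with columns `family`, `member`, `species`, `seq`.
#' @export
read_reference_catalogue <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    seqs <- read_sequences(path, format = "fasta")
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    out <- data.frame(
      family = vapply(parts, `[`, character(1), 1L),
      member = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", character(1)),
      species = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", character(1)),
      seq = unname(seqs), stringsAsFactors = FALSE)
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("family", "member", "species", "seq")
    if (!all(need %in% names(out))) stop("catalogue TSV needs columns: ",
                                         paste(need, collapse = ", "))
    out$seq <- normalize_seq(out$seq)
  }
  if (!nrow(out) || any(out$family == "")) stop("invalid reference catalogue")
  out
}

#' Assign queries to known miRNA families
#'
#' Each query (a cluster representative or read) is aligned to every
#' reference mature miRNA; references whose best overlap alignment carries at
#' most `max_mismatches` mismatches become hits. A query hitting several
#' members or families is reported under all of them; the lowest-Mn hit is
#' flagged primary. Unassigned queries flow to the novel-candidate path.
#'
#' @param queries named character vector of query sequences.
#' @param refs reference catalogue data.frame
#'   (see [read_reference_catalogue()]).
#' @param max_mismatches mismatch budget (default 2).
#' @param min_overlap minimum overlap length (default 17).
#' @return data.frame with columns `query`, `query_seq`, `family`, `member`,
#'   `species`, `offset`, `overlap`, `mn`, `primary`.
#' @export
assign_families <- function(queries, refs, max_mismatches = 2L,
                            min_overlap = 17L) {
  if (is.null(refs) || !nrow(refs)) stop("empty reference catalogue")
  if (is.null(names(queries))) names(queries) <- queries
  queries <- setNames(normalize_seq(queries), names(queries))
  rows <- list()
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    if (nchar(q) < min_overlap) next
    for (ri in seq_len(nrow(refs))) {
      if (nchar(refs$seq[ri]) < min_overlap) next
      al <- best_overlap_alignment(q, refs$seq[ri], min_overlap)
      if (al$mismatches <= max_mismatches) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = names(queries)[qi], query_seq = q,
          family = refs$family[ri], member = refs$member[ri],
          species = refs$species[ri], offset = al$offset,
          overlap = al$overlap_len, mn = al$mismatches,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query = character(0), query_seq = character(0),
                      family = character(0), member = character(0),
                      species = character(0), offset = integer(0),
                      overlap = integer(0), mn = integer(0),
                      primary = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$primary <- FALSE
  for (q in unique(out$query)) {
    sel <- which(out$query == q)
    out$primary[sel[order(out$mn[sel], -out$overlap[sel])[1]]] <- TRUE
  }
  out
}

#' Per-family mean count over libraries
#'
#' For each assigned family, the per-library counts of all distinct assigned
#' queries are summed and averaged over libraries (raw counts by default,
#' per-million on request).
#'
#' @param assignments output of [assign_families()].
#' @param counts numeric matrix of per-library counts with rownames matching
#'   `assignments$query` and one column per library.
#' @param per_million if `TRUE`, counts are scaled to reads per million using
#'   `lib_sizes` before averaging.
#' @param lib_sizes per-library total read counts (required for
#'   `per_million = TRUE`).
#' @return named numeric vector, family -> mean count.
#' @export
family_mean_count <- function(assignments, counts, per_million = FALSE,
                              lib_sizes = NULL) {
  if (per_million) {
    if (is.null(lib_sizes)) stop("lib_sizes required for per-million scaling")
    counts <- sweep(counts, 2L, lib_sizes / 1e6, "/")
  }
  fams <- sort(unique(assignments$family))
  vapply(fams, function(f) {
    qs <- unique(assignments$query[assignments$family == f])
    mean(colSums(counts[qs, , drop = FALSE]))
  }, numeric(1))
}

#' Cross-species homology scan
#'
#' Reports every (candidate, foreign sequence) pair whose best overlap
#' alignment has at most `max_mismatches` mismatches, with the offset,
#' overlap and mismatch positions -- the statistic used to recognize
#' candidate miRNAs shared with the small RNA complement of another species.
#'
#' @param candidates named character vector of candidate miRNA sequences.
#' @param foreign named character vector of foreign small RNA sequences.
#' @param max_mismatches mismatch budget (default 2).
#' @param min_overlap minimum overlap length (default 17).
#' @return data.frame with one row per homologous pair.
#' @export
cross_species_scan <- function(candidates, foreign, max_mismatches = 2L,
                               min_overlap = 17L) {
  if (is.null(names(candidates))) names(candidates) <- candidates
  if (is.null(names(foreign))) names(foreign) <- foreign
  candidates <- setNames(normalize_seq(candidates), names(candidates))
  foreign <- setNames(normalize_seq(foreign), names(foreign))
  rows <- list()
  for (ci in seq_along(candidates)) {
    if (nchar(candidates[[ci]]) < min_overlap) next
    for (fi in seq_along(foreign)) {
      if (nchar(foreign[[fi]]) < min_overlap) next
      al <- best_overlap_alignment(candidates[[ci]], foreign[[fi]], min_overlap)
      if (al$mismatches <= max_mismatches) {
        rows[[length(rows) + 1L]] <- data.frame(
          candidate = names(candidates)[ci], foreign = names(foreign)[fi],
          candidate_seq = candidates[[ci]], foreign_seq = foreign[[fi]],
          offset = al$offset, overlap = al$overlap_len, mn = al$mismatches,
          mismatch_positions = paste(al$mismatch_positions, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(candidate = character(0), foreign = character(0),
                      candidate_seq = character(0), foreign_seq = character(0),
                      offset = integer(0), overlap = integer(0),
                      mn = integer(0), mismatch_positions = character(0)))
  }
  do.call(rbind, rows)
}
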