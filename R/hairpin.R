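# Precursor location, secondary-structure prediction, miR/miR* duplex
# validation and star-sequence inference.

#' Locate candidate precursor windows on transcripts
#'
#' Every exact forward-strand occurrence of the mature miRNA in a transcript
#' is expanded by `flank` nt on both sides (clipped to the transcript) to
#' delimit a window for secondary-structure prediction.
#'
#' @param mirna mature miRNA sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param flank flank size in nt (default 200; plant pre-miRNA fold-backs
#'   span roughly 55-834 nt, so a 200-nt flank covers most precursors and can
#'   be widened to 500 for long fold-backs).
#' @return data.frame with columns `transcript_id`, `win_start`, `win_end`,
#'   `mir_start`, `mir_end` (1-based, transcript coordinates).
#' @export
find_precursor_windows <- function(mirna, transcripts, flank = 200L) {
  stopifnot(flank >= 0L)
  mirna <- normalize_seq(mirna)
  rows <- list()
  for (tid in names(transcripts)) {
    tx <- normalize_seq(transcripts[[tid]])
    m <- gregexpr(mirna, tx, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (s in as.integer(m)) {
      e <- s + nchar(mirna) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid,
        win_start = max(1L, s - flank), win_end = min(nchar(tx), e + flank),
        mir_start = s, mir_end = e, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(0), win_start = integer(0),
                      win_end = integer(0), mir_start = integer(0),
                      mir_end = integer(0)))
  }
  do.call(rbind, rows)
}

#' Predict RNA secondary structure
#'
#' The built-in engine maximizes the number of canonical (A:U, G:C) plus G:U
#' wobble base pairs by dynamic programming with a minimum hairpin loop of
#' 3 nt and a deterministic traceback, so results are exactly reproducible.
#' The optional `"vienna"` engine shells out to `RNAfold` for a thermodynamic
#' minimum-free-energy structure; its score is in kcal/mol and is never
#' comparable with the built-in pair-count score.
#'
#' @param seq nucleotide sequence, at most 2000 nt (sequences shorter than
#'   5 nt trivially fold with no pairs).
#' @param engine `"maxpair"` (default) or `"vienna"`.
#' @return object of class `fold_result`: `seq`, `structure` (dot-bracket),
#'   `pair_table` (1-based partner positions, 0 = unpaired), `score`,
#'   `engine`.
#' @export
fold <- function(seq, engine = c("maxpair", "vienna")) {
  engine <- match.arg(engine)
  seq <- normalize_seq(seq)
  if (nchar(seq) < 1L || nchar(seq) > 2000L) stop("sequence length must be in [1, 2000]")
  if (grepl("[^ACGT]", seq)) stop("invalid characters in sequence")
  if (engine == "maxpair") {
    pt <- nussinov_pairs(seq)
    struct <- rep(".", length(pt))
    struct[pt > seq_along(pt)] <- "("
    struct[pt != 0L & pt < seq_along(pt)] <- ")"
    res <- list(seq = seq, structure = paste(struct, collapse = ""),
                pair_table = pt, score = sum(pt > 0) / 2, engine = "maxpair")
  } else {
    if (Sys.which("RNAfold") == "") stop("RNAfold not found on PATH")
    out <- system2("RNAfold", c("--noPS"), input = chartr("T", "U", seq),
                   stdout = TRUE)
    line <- out[2L]
    struct <- sub("\\s.*$", "", line)
    mfe <- as.numeric(gsub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
    pt <- integer(nchar(seq))
    stack <- integer(0)
    chars <- strsplit(struct, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") stack <- c(stack, i)
      else if (chars[i] == ")") {
        j <- stack[length(stack)]; stack <- stack[-length(stack)]
        pt[i] <- j; pt[j] <- i
      }
    }
    res <- list(seq = seq, structure = struct, pair_table = pt,
                score = mfe, engine = "vienna")
  }
  structure(res, class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(chartr("T", "U", x$seq), "\n", x$structure, "\n", sep = "")
  cat(sprintf("engine %s, score %s\n", x$engine,
              if (x$engine == "maxpair") sprintf("%d base pairs", x$score)
              else sprintf("%.1f kcal/mol", x$score)))
  invisible(x)
}

#' Validate a miR/miR* hairpin duplex
#'
#' Accepts a folded precursor window when (a) at least `paired_fraction` of
#' miRNA positions are paired, (b) all partners of miRNA positions lie on a
#' single opposing arm (no pairing into the terminal loop or within the
#' miRNA itself), (c) the number of unpaired miRNA positions (duplex
#' mismatches) is at most `max_unpaired`, and (d) the partners form a
#' contiguous helix up to `max_bulge` bulged nucleotides (their span may
#' not exceed the miRNA length plus `max_bulge`). These mirror the
#' structural requirements for the precise excision of a miR/miR* duplex
#' from a stem-loop precursor; scattered long-range pairing, which
#' base-pair maximization readily finds in random sequence, fails (d).
#'
#' @param fold_res a [fold()] result for the window.
#' @param mir_start,mir_end 1-based miRNA coordinates within the window.
#' @param paired_fraction minimum fraction of paired miRNA positions
#'   (default 0.6).
#' @param max_unpaired maximum unpaired miRNA positions (default 4).
#' @param max_bulge maximum excess of the opposing-arm span over the miRNA
#'   length (default 4).
#' @return object of class `precursor_candidate` with fields `accepted`,
#'   `reasons`, `arm` (`"five_prime"`/`"three_prime"`), `duplex_mismatches`,
#'   `mir`, `fold`.
#' @export
validate_hairpin <- function(fold_res, mir_start, mir_end,
                             paired_fraction = 0.6, max_unpaired = 4L,
                             max_bulge = 4L) {
  stopifnot(inherits(fold_res, "fold_result"))
  n <- nchar(fold_res$seq)
  if (mir_start < 1L || mir_end > n || mir_start > mir_end) {
    stop("miRNA coordinates outside window")
  }
  pt <- fold_res$pair_table
  idx <- mir_start:mir_end
  partners <- pt[idx]
  paired <- partners > 0L
  reasons <- character(0)
  if (mean(paired) < paired_fraction) reasons <- c(reasons, "low_paired_fraction")
  arm <- NA_character_
  p <- partners[paired]
  if (length(p)) {
    if (all(p > mir_end)) arm <- "five_prime"
    else if (all(p < mir_start)) arm <- "three_prime"
    else reasons <- c(reasons, "partners_on_both_sides")
    if (diff(range(p)) + 1L > (mir_end - mir_start + 1L) + max_bulge) {
      reasons <- c(reasons, "discontiguous_helix")
    }
  } else {
    reasons <- c(reasons, "no_paired_positions")
  }
  mm <- sum(!paired)
  if (mm > max_unpaired) reasons <- c(reasons, "too_many_duplex_mismatches")
  structure(list(accepted = length(reasons) == 0L, reasons = reasons,
                 arm = arm, duplex_mismatches = mm,
                 mir = c(mir_start, mir_end), fold = fold_res),
            class = "precursor_candidate")
}

#' @export
print.precursor_candidate <- function(x, ...) {
  cat(sprintf("precursor_candidate: %s (arm %s, %d duplex mismatches)%s\n",
              if (x$accepted) "accepted" else "rejected", x$arm,
              x$duplex_mismatches,
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ","), "]") else ""))
  invisible(x)
}

#' Infer the miRNA* span from an accepted hairpin
#'
#' Applies the 2-nt 3' overhang convention of Dicer-like processing: the star
#' span is `[partner(mir_end) + o, partner(mir_start) + o]` with `o = +2` for
#' a 5'-arm miRNA and `o = -2` for a 3'-arm miRNA, clipped to the window.
#' When an miRNA end is unpaired, the innermost paired positions are used as
#' anchors.
#'
#' @param candidate an accepted [validate_hairpin()] result.
#' @param reads optional character vector of observed small RNA sequences;
#'   the star is flagged supported if its sequence, or an end variant shifted
#'   by one nt on either end, occurs among them.
#' @return list with `star` (1-based window span), `seq` (star sequence) and
#'   `star_supported`.
#' @export
infer_star <- function(candidate, reads = NULL) {
  stopifnot(inherits(candidate, "precursor_candidate"))
  if (!candidate$accepted) stop("candidate was not accepted")
  pt <- candidate$fold$pair_table
  n <- nchar(candidate$fold$seq)
  idx <- candidate$mir[1]:candidate$mir[2]
  paired_idx <- idx[pt[idx] > 0L]
  if (length(paired_idx) < 2L) stop("fewer than two paired miRNA positions")
  a_start <- min(paired_idx)        # innermost anchors fall back to paired ends
  a_end <- max(paired_idx)
  o <- if (candidate$arm == "five_prime") 2L else -2L
  span <- sort(c(pt[a_end] + o, pt[a_start] + o))
  span[1] <- max(1L, span[1]); span[2] <- min(n, span[2])
  star_seq <- substr(candidate$fold$seq, span[1], span[2])
  supported <- FALSE
  if (!is.null(reads) && length(reads)) {
    reads <- normalize_seq(reads)
    variants <- character(0)
    for (ds in -1:1) for (de in -1:1) {
      s <- span[1] + ds; e <- span[2] + de
      if (s >= 1L && e <= n && s < e) variants <- c(variants, substr(candidate$fold$seq, s, e))
    }
    supported <- any(unique(variants) %in% reads)
  }
  list(star = span, seq = star_seq, star_supported = supported)
}

#' Detect co-expressed 5p/3p arm pairs
#'
#' Pairs of candidate miRNAs that map to opposite arms of one accepted
#' hairpin, with their pooled abundances. A pair is flagged `both_abundant`
#' when the minor/major abundance ratio is at least `min_ratio` -- the
#' signature of a duplex whose both strands are retained as functional
#' miRNAs.
#'
#' @param precursors data.frame of accepted precursor candidates with columns
#'   `mirna_id`, `transcript_id`, `win_start`, `win_end`, `arm`.
#' @param abundances named numeric vector, miRNA id -> pooled abundance.
#' @param min_ratio abundance-ratio threshold (default 0.2).
#' @return data.frame with one row per arm pair.
#' @export
detect_arm_pairs <- function(precursors, abundances, min_ratio = 0.2) {
  rows <- list()
  if (nrow(precursors) >= 2L) {
    for (i in seq_len(nrow(precursors) - 1L)) {
      for (j in seq(i + 1L, nrow(precursors))) {
        a <- precursors[i, ]; b <- precursors[j, ]
        same_tx <- a$transcript_id == b$transcript_id
        overlap <- a$win_start <= b$win_end && b$win_start <= a$win_end
        if (same_tx && overlap && a$arm != b$arm && a$mirna_id != b$mirna_id) {
          ab <- abundances[[a$mirna_id]]; bb <- abundances[[b$mirna_id]]
          ratio <- min(ab, bb) / max(ab, bb)
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_5p = if (a$arm == "five_prime") a$mirna_id else b$mirna_id,
            mirna_3p = if (a$arm == "five_prime") b$mirna_id else a$mirna_id,
            transcript_id = a$transcript_id,
            abundance_5p = if (a$arm == "five_prime") ab else bb,
            abundance_3p = if (a$arm == "five_prime") bb else ab,
            ratio = ratio, both_abundant = ratio >= min_ratio,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_5p = character(0), mirna_3p = character(0),
                      transcript_id = character(0), abundance_5p = numeric(0),
                      abundance_3p = numeric(0), ratio = numeric(0),
                      both_abundant = logical(0)))
  }
  do.call(rbind, rows)
}
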