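# miRNA target-site scanning and the mismatch/G:U duplex scoring rule.

# pairing states are encoded per miRNA position 1..n (5'->3') as
# "|" Watson-Crick, "o" G:U wobble, "x" mismatch

state_counts <- function(states, max_pos = Inf) {
  ch <- strsplit(states, "")
  vapply(ch, function(s) {
    s <- s[seq_len(min(length(s), max_pos))]
    sum(s == "x") + 0.5 * sum(s == "o")
  }, numeric(1))
}

#' Score a miRNA:target duplex
#'
#' One point per mismatch and half a point per G:U wobble. The total score
#' runs over all miRNA positions; the seed score restricts the same sum to
#' miRNA positions 1-12 (5' end), the region whose complementarity governs
#' cleavage.
#'
#' @param states character vector of pairing-state strings
#'   (`"|"` = Watson-Crick, `"o"` = G:U, `"x"` = mismatch), ordered by miRNA
#'   position.
#' @return data.frame with columns `total_score` and `seed_score`.
#' @export
score_duplex <- function(states) {
  data.frame(total_score = state_counts(states),
             seed_score = state_counts(states, max_pos = 12L))
}

scan_one <- function(mirna, transcript, score_ceiling) {
  n <- nchar(mirna)
  L <- nchar(transcript)
  S <- L - n + 1L
  if (S < 1L) return(NULL)
  m <- strsplit(mirna, "")[[1]]
  # complement of the transcript, unreversed: miRNA position k pairs
  # transcript position site_end - k + 1, whose complement sits at index
  # site_start + n - k in this vector
  comp <- strsplit(chartr("ACGT", "TGCA", transcript), "")[[1]]
  tot <- numeric(S)
  seed <- numeric(S)
  st <- matrix("x", nrow = n, ncol = S)
  for (k in seq_len(n)) {
    cc <- comp[(0:(S - 1L)) + n - k + 1L]
    wc <- cc == m[k]
    gu <- (m[k] == "G" & cc == "A") | (m[k] == "T" & cc == "C")
    st[k, wc] <- "|"
    st[k, gu & !wc] <- "o"
    add <- ifelse(wc, 0, ifelse(gu, 0.5, 1))
    tot <- tot + add
    if (k <= 12L) seed <- seed + add
  }
  keep <- which(tot < score_ceiling)
  if (!length(keep)) return(NULL)
  data.frame(site_start = keep, site_end = keep + n - 1L,
             states = apply(st[, keep, drop = FALSE], 2L, paste, collapse = ""),
             total_score = tot[keep], seed_score = seed[keep],
             stringsAsFactors = FALSE)
}

#' Scan transcripts for miRNA target sites
#'
#' Ungapped antiparallel scan: at every offset the site has the miRNA's
#' length, miRNA position k faces transcript position `site_end - k + 1`,
#' and each position is classed Watson-Crick, G:U wobble or mismatch.
#' Alignments with a total score below `score_ceiling` are emitted for
#' downstream filtering.
#'
#' @param mirnas named character vector of mature miRNA sequences
#'   (18-26 nt).
#' @param transcripts named character vector of transcript sequences.
#' @param score_ceiling hard emission ceiling on the total score (default 7).
#' @return data.frame of duplex alignments: `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end`, `states`, `total_score`, `seed_score`.
#' @export
scan_targets <- function(mirnas, transcripts, score_ceiling = 7) {
  if (is.null(names(mirnas))) names(mirnas) <- mirnas
  if (is.null(names(transcripts))) stop("transcripts must be named")
  mirnas <- setNames(normalize_seq(mirnas), names(mirnas))
  transcripts <- setNames(normalize_seq(transcripts), names(transcripts))
  stopifnot(all(nchar(mirnas) >= 18L), all(nchar(mirnas) <= 26L))
  rows <- list()
  for (mi in seq_along(mirnas)) {
    for (ti in seq_along(transcripts)) {
      hit <- scan_one(mirnas[[mi]], transcripts[[ti]], score_ceiling)
      if (is.null(hit)) next
      hit <- cbind(data.frame(mirna_id = names(mirnas)[mi],
                              transcript_id = names(transcripts)[ti],
                              stringsAsFactors = FALSE), hit)
      rows[[length(rows) + 1L]] <- hit
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      states = character(0), total_score = numeric(0),
                      seed_score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predicted cleavage window of a duplex
#'
#' RISC slices the target opposite miRNA position 10; the transcript
#' position facing it is `site_end - 9` (canonical), and the window facing
#' miRNA positions 9-11 is `site_end - c(8, 9, 10)`, clipped to the
#' transcript.
#'
#' @param site_start,site_end 1-based site coordinates on the transcript.
#' @param transcript_length transcript length for clipping (default
#'   unclipped).
#' @return list with `canonical` (position facing miRNA position 10) and
#'   `window` (sorted positions facing miRNA positions 9-11).
#' @export
predicted_cleavage_window <- function(site_start, site_end,
                                      transcript_length = Inf) {
  canonical <- site_end - 9L
  window <- sort(site_end - c(8L, 9L, 10L))
  window <- window[window >= 1L & window <= transcript_length]
  list(canonical = canonical, window = window)
}

#' Apply the duplex retention thresholds
#'
#' Duplexes are discarded when the total score reaches `total_max` or the
#' positions 1-12 score exceeds `seed_max`. With `combine = "either"`
#' (default) either condition discards; `combine = "both"` requires both.
#' Retained and discarded candidates are returned with the predicted
#' cleavage window and, for discards, the reason.
#'
#' @param duplexes data.frame from [scan_targets()] or
#'   [import_external_sites()].
#' @param total_max total-score discard threshold (default 4; discard when
#'   `total_score >= total_max`).
#' @param seed_max positions 1-12 discard threshold (default 2.5; discard
#'   when `seed_score > seed_max`).
#' @param combine `"either"` or `"both"`.
#' @param transcript_lengths optional named vector for window clipping.
#' @return the input with added columns `retained`, `rejection_reason`,
#'   `canonical_cleavage`, `window_start`, `window_end`.
#' @export
filter_duplexes <- function(duplexes, total_max = 4, seed_max = 2.5,
                            combine = c("either", "both"),
                            transcript_lengths = NULL) {
  combine <- match.arg(combine)
  if (!nrow(duplexes)) {
    return(cbind(duplexes, retained = logical(0),
                 rejection_reason = character(0),
                 canonical_cleavage = integer(0),
                 window_start = integer(0), window_end = integer(0)))
  }
  bad_total <- duplexes$total_score >= total_max
  bad_seed <- duplexes$seed_score > seed_max
  discard <- if (combine == "either") bad_total | bad_seed else bad_total & bad_seed
  reason <- rep(NA_character_, nrow(duplexes))
  reason[discard & bad_total & bad_seed] <- "total;seed"
  reason[discard & bad_total & !bad_seed] <- "total"
  reason[discard & !bad_total & bad_seed] <- "seed"
  duplexes$retained <- !discard
  duplexes$rejection_reason <- reason
  duplexes$canonical_cleavage <- duplexes$site_end - 9L
  wlo <- duplexes$site_end - 10L
  whi <- duplexes$site_end - 8L
  if (!is.null(transcript_lengths)) {
    tl <- transcript_lengths[duplexes$transcript_id]
    whi <- pmin(whi, tl)
  }
  duplexes$window_start <- pmax(wlo, 1L)
  duplexes$window_end <- whi
  duplexes
}

#' Import externally predicted target sites
#'
#' Reads a tab-separated site list (columns `mirna_id`, `transcript_id`,
#' `site_start`, `site_end`, `states`) such as re-formatted output of
#' third-party target predictors, re-scores each row with [score_duplex()]
#' and returns duplex alignments identical in shape to [scan_targets()]
#' output. Malformed rows (state string length different from the site
#' length, or non-numeric coordinates) are rejected with a warning naming
#' the line.
#'
#' @param path TSV file.
#' @return data.frame of duplex alignments.
#' @export
import_external_sites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "transcript_id", "site_start", "site_end", "states")
  if (!all(need %in% names(df))) stop("site list needs columns: ",
                                      paste(need, collapse = ", "))
  if (!nrow(df)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      states = character(0), total_score = numeric(0),
                      seed_score = numeric(0)))
  }
  ok <- rep(TRUE, nrow(df))
  slen <- suppressWarnings(as.integer(df$site_end) - as.integer(df$site_start) + 1L)
  bad <- is.na(slen) | nchar(df$states) != slen |
    grepl("[^|ox]", df$states)
  for (i in which(bad)) {
    warning(sprintf("row %d (line %d): malformed site, rejected", i, i + 1L),
            call. = FALSE)
  }
  ok[bad] <- FALSE
  df <- df[ok, need, drop = FALSE]
  sc <- score_duplex(df$states)
  df$total_score <- sc$total_score
  df$seed_score <- sc$seed_score
  df$site_start <- as.integer(df$site_start)
  df$site_end <- as.integer(df$site_end)
  rownames(df) <- NULL
  df
}
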