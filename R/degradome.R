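# Degradome (PARE) tag mapping, T-plot construction with TP1M
# normalization, and cleavage-site calling.

#' Map degradome tags to transcripts
#'
#' Exact forward-strand substring matching of adapter-trimmed tags; the
#' 5' position of every occurrence is recorded and the tag's multiplicity
#' `m` counts the distinct transcripts it hits. The mapped library size
#' (total count of mapped tags) is the normalization denominator; unmapped
#' tags are excluded from it.
#'
#' @param tags data.frame with columns `seq`, `count` (collapsed tags,
#'   length >= 14 nt after trimming).
#' @param transcripts named character vector of transcript sequences.
#' @return list with `hits` (data.frame `seq`, `transcript_id`, `position`),
#'   `tags` (input plus `m`), `library_size` (total mapped count).
#' @export
map_tags <- function(tags, transcripts) {
  stopifnot(all(c("seq", "count") %in% names(tags)))
  if (is.null(names(transcripts))) stop("transcripts must be named")
  transcripts <- setNames(normalize_seq(transcripts), names(transcripts))
  tags$seq <- normalize_seq(tags$seq)
  rows <- list()
  m <- integer(nrow(tags))
  for (i in seq_len(nrow(tags))) {
    hit_tx <- character(0)
    g <- gregexpr(tags$seq[i], transcripts, fixed = TRUE)
    for (j in seq_along(transcripts)) {
      p <- g[[j]]
      if (p[1] == -1L) next
      hit_tx <- c(hit_tx, names(transcripts)[j])
      rows[[length(rows) + 1L]] <- data.frame(
        seq = tags$seq[i], transcript_id = names(transcripts)[j],
        position = as.integer(p), stringsAsFactors = FALSE)
    }
    m[i] <- length(unique(hit_tx))
  }
  tags$m <- m
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq = character(0), transcript_id = character(0),
               position = integer(0))
  list(hits = hits, tags = tags,
       library_size = sum(tags$count[tags$m > 0]))
}

#' TP1M normalization of a tag count
#'
#' `TP1M = (raw / library_size) * 1e6 / m`: tags per million, additionally
#' divided by the number of distinct transcripts the tag maps to so that
#' multi-mapping tags are not double-counted.
#'
#' @param raw raw tag count.
#' @param library_size total mapped tag count (> 0).
#' @param m tag multiplicity (>= 1).
#' @return normalized TP1M value.
#' @export
normalize_tp1m <- function(raw, library_size, m = 1L) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(m < 1L)) stop("multiplicity m must be >= 1")
  (raw / library_size) * 1e6 / m
}

#' Build a T-plot for one transcript
#'
#' The signal at each position is the summed TP1M of tags whose 5' end maps
#' there; the cleavage-signal threshold is the arithmetic mean of the signal
#' over tag-bearing positions.
#'
#' @param transcript_id transcript to plot.
#' @param mapping a [map_tags()] result.
#' @return object of class `tplot`: `transcript_id`, `signal` (named
#'   vector, position -> TP1M), `raw` (position -> raw count), `threshold`,
#'   `library_size`. Transcripts without tags yield an empty plot with
#'   `NA` threshold.
#' @export
build_tplot <- function(transcript_id, mapping) {
  h <- mapping$hits[mapping$hits$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(h)) {
    return(structure(list(transcript_id = transcript_id,
                          signal = setNames(numeric(0), character(0)),
                          raw = setNames(numeric(0), character(0)),
                          threshold = NA_real_,
                          library_size = mapping$library_size),
                     class = "tplot"))
  }
  ti <- match(h$seq, mapping$tags$seq)
  tp1m <- normalize_tp1m(mapping$tags$count[ti], mapping$library_size,
                         mapping$tags$m[ti])
  sig <- tapply(tp1m, h$position, sum)
  raw <- tapply(mapping$tags$count[ti], h$position, sum)
  structure(list(transcript_id = transcript_id,
                 signal = setNames(as.numeric(sig), names(sig)),
                 raw = setNames(as.numeric(raw), names(raw)),
                 threshold = mean(as.numeric(sig)),
                 library_size = mapping$library_size),
            class = "tplot")
}

#' @export
print.tplot <- function(x, ...) {
  cat(sprintf("tplot %s: %d tag positions, threshold %.3f TP1M\n",
              x$transcript_id, length(x$signal), x$threshold))
  invisible(x)
}

#' Export a T-plot as TSV
#' @param tplot a [build_tplot()] result.
#' @param path output file.
#' @export
write_tplot_tsv <- function(tplot, path) {
  write.table(data.frame(position = as.integer(names(tplot$signal)),
                         raw = tplot$raw, tp1m = tplot$signal),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call a miRNA-guided cleavage site from a T-plot
#'
#' The candidate position is the strongest signal inside the predicted
#' 9-11 window of the duplex. Category 1: signal above the threshold and
#' the unique transcript-wide maximum; category 2: above the threshold but
#' not the unique maximum; category 3: window signal present but at or
#' below the threshold (low confidence). No call when the window carries no
#' signal. No call is ever made outside the predicted window.
#'
#' @param tplot a [build_tplot()] result.
#' @param target one row of a [filter_duplexes()] result (retained, same
#'   transcript).
#' @return one-row data.frame (`mirna_id`, `transcript_id`, `position`,
#'   `signal`, `category`, `window_offset`) or `NULL`.
#' @export
call_cleavage <- function(tplot, target) {
  stopifnot(inherits(tplot, "tplot"))
  if (!length(tplot$signal)) return(NULL)
  win <- target$window_start:target$window_end
  pos_all <- as.integer(names(tplot$signal))
  sig <- setNames(rep(0, length(win)), win)
  inwin <- pos_all %in% win
  sig[as.character(pos_all[inwin])] <- tplot$signal[inwin]
  if (all(sig == 0)) return(NULL)
  canon <- target$canonical_cleavage
  o <- order(-sig, abs(win - canon), win)
  pos <- win[o[1]]
  val <- sig[o[1]]
  if (val > tplot$threshold) {
    is_unique_max <- sum(tplot$signal >= val) == 1L && max(tplot$signal) == val
    category <- if (is_unique_max) 1L else 2L
  } else {
    category <- 3L
  }
  data.frame(mirna_id = target$mirna_id, transcript_id = target$transcript_id,
             position = pos, signal = as.numeric(val), category = category,
             window_offset = pos - canon, stringsAsFactors = FALSE)
}

#' Summarize cleavage calls into a final target table
#'
#' One row per cleavage site: miRNAs sharing the same site on the same
#' transcript are collapsed into one row listing all miRNA ids. The cleavage
#' region (5' UTR / CDS / 3' UTR) comes from the coding annotations.
#'
#' @param calls data.frame of [call_cleavage()] rows.
#' @param annotations named list of [find_coding_region()] results.
#' @return data.frame with columns `mirnas`, `transcript_id`,
#'   `cleavage_site`, `cleavage_region`, `category`, `signal`.
#' @export
summarize_targets <- function(calls, annotations = NULL) {
  if (is.null(calls) || !nrow(calls)) {
    return(data.frame(mirnas = character(0), transcript_id = character(0),
                      cleavage_site = integer(0), cleavage_region = character(0),
                      category = integer(0), signal = numeric(0)))
  }
  key <- paste(calls$transcript_id, calls$position, sep = "@")
  out <- lapply(unique(key), function(k) {
    sel <- calls[key == k, , drop = FALSE]
    region <- NA_character_
    if (!is.null(annotations) && sel$transcript_id[1] %in% names(annotations)) {
      ann <- annotations[[sel$transcript_id[1]]]
      if (isTRUE(ann$coding)) region <- classify_region(ann, sel$position[1])
    }
    data.frame(mirnas = paste(sort(unique(sel$mirna_id)), collapse = ","),
               transcript_id = sel$transcript_id[1],
               cleavage_site = sel$position[1],
               cleavage_region = region,
               category = min(sel$category),
               signal = sel$signal[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$transcript_id, out$cleavage_site), , drop = FALSE]
}
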