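# Codon-usage based coding-region identification and 5'UTR/CDS/3'UTR
# position classification.

GENETIC_STOPS <- c("TAA", "TAG", "TGA")

ALL_CODONS <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))

codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Train a codon-usage log-odds model
#'
#' Codon frequencies are estimated from in-frame training coding sequences
#' with add-one smoothing and scored as log-odds against a uniform 1/64
#' background. A single model is fitted (one isochore).
#'
#' @param training character vector of CDS sequences (each length >= 33 and
#'   divisible by 3), or a path to a FASTA file of such sequences.
#' @return object of class `codon_model`: named numeric vector of 64
#'   log-odds values.
#' @export
train_codon_model <- function(training) {
  if (length(training) == 1L && file.exists(training)) {
    training <- read_sequences(training, format = "fasta")
  }
  training <- normalize_seq(training)
  if (!length(training)) stop("empty training set")
  ok <- nchar(training) >= 33L & nchar(training) %% 3L == 0L
  if (!any(ok)) stop("no usable training sequence (need length >= 33, divisible by 3)")
  cod <- unlist(lapply(training[ok], codons_of))
  cod <- cod[!grepl("[^ACGT]", cod)]
  counts <- table(factor(cod, levels = ALL_CODONS))
  freq <- (as.numeric(counts) + 1) / (sum(counts) + 64)
  lo <- log(freq / (1 / 64))
  structure(setNames(lo, ALL_CODONS), class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat(sprintf("codon_model: 64 log-odds values, range [%.2f, %.2f]\n",
              min(x), max(x)))
  invisible(x)
}

#' Write a codon model as TSV
#' @param model a `codon_model`.
#' @param path output file.
#' @export
write_codon_model <- function(model, path) {
  write.table(data.frame(codon = names(model), log_odds = as.numeric(model)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Identify the best-scoring coding region of a transcript
#'
#' Scans all ATG-to-stop open reading frames in the three forward frames and
#' scores each as the sum of codon log-odds (stop codon excluded from the
#' score). The maximum-score ORF wins, ties broken by longer then leftmost.
#' Transcripts without an ORF of at least `min_codons` codons are marked
#' non-coding and should be excluded from target prediction.
#'
#' @param transcript transcript sequence (length >= 60).
#' @param model a [train_codon_model()] result.
#' @param min_codons minimum ORF length in codons, stop excluded
#'   (default 20).
#' @return object of class `coding_annotation`: `cds` (1-based inclusive
#'   span, stop codon included), `frame` (0-2), `score`, `coding` flag, and
#'   `length` of the transcript.
#' @export
find_coding_region <- function(transcript, model, min_codons = 20L) {
  stopifnot(inherits(model, "codon_model"))
  tx <- normalize_seq(transcript)
  L <- nchar(tx)
  if (L < 60L) stop("transcript shorter than 60 nt")
  best <- NULL
  for (fr in 0:2) {
    cods <- codons_of(substr(tx, fr + 1L, L))
    if (!length(cods)) next
    is_start <- cods == "ATG"
    is_stop <- cods %in% GENETIC_STOPS
    stops <- which(is_stop)
    for (s in which(is_start)) {
      nxt <- stops[stops > s]
      if (!length(nxt)) next                      # require a complete ORF
      e <- nxt[1]
      ncod <- e - s                               # codons before the stop
      if (ncod < min_codons) next
      sc <- sum(model[cods[s:(e - 1L)]])
      cand <- list(start = fr + 3L * (s - 1L) + 1L,
                   end = fr + 3L * e,             # includes the stop codon
                   frame = fr, score = sc, ncod = ncod)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && ncod > best$ncod) ||
          (sc == best$score && ncod == best$ncod && cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(cds = NULL, frame = NA_integer_, score = NA_real_,
                          coding = FALSE, length = L),
                     class = "coding_annotation"))
  }
  structure(list(cds = c(best$start, best$end), frame = best$frame,
                 score = best$score, coding = TRUE, length = L),
            class = "coding_annotation")
}

#' @export
print.coding_annotation <- function(x, ...) {
  if (x$coding) {
    cat(sprintf("coding_annotation: CDS [%d, %d], frame %d, score %.2f\n",
                x$cds[1], x$cds[2], x$frame, x$score))
  } else {
    cat("coding_annotation: non-coding\n")
  }
  invisible(x)
}

#' Classify a transcript position as 5'UTR, CDS or 3'UTR
#'
#' @param annotation a [find_coding_region()] result (must be coding).
#' @param position 1-based transcript position.
#' @return one of `"5' UTR"`, `"CDS"`, `"3' UTR"`.
#' @export
classify_region <- function(annotation, position) {
  stopifnot(inherits(annotation, "coding_annotation"))
  if (position < 1L || position > annotation$length) stop("position out of range")
  if (!annotation$coding) return(NA_character_)
  if (position < annotation$cds[1]) "5' UTR"
  else if (position <= annotation$cds[2]) "CDS"
  else "3' UTR"
}

#' Write coding annotations as GFF3
#'
#' One `five_prime_UTR`, `CDS` and `three_prime_UTR` feature per coding
#' transcript (UTR features only when non-empty).
#'
#' @param annotations named list of `coding_annotation` objects.
#' @param path output file.
#' @export
write_coding_gff3 <- function(annotations, path) {
  lines <- "##gff-version 3"
  for (tid in names(annotations)) {
    a <- annotations[[tid]]
    if (!a$coding) next
    feats <- list()
    if (a$cds[1] > 1L) feats[["five_prime_UTR"]] <- c(1L, a$cds[1] - 1L)
    feats[["CDS"]] <- a$cds
    if (a$cds[2] < a$length) feats[["three_prime_UTR"]] <- c(a$cds[2] + 1L, a$length)
    for (ft in names(feats)) {
      lines <- c(lines, sprintf("%s\tmirfree\t%s\t%d\t%d\t.\t+\t.\tID=%s_%s",
                                tid, ft, feats[[ft]][1], feats[[ft]][2], tid, ft))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
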