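# End-to-end orchestration of the discovery stages and evaluation of
# simulated runs against their ground truth.

#' Pipeline parameters
#'
#' Every stage constant surfaces here with its default: read length window
#' 18-26 nt, copy-number filter 2, adapter overlap 7 (small RNA) with the
#' degradome handled at overlap 19 and minimum trimmed length 14, dominance
#' band 20-21 nt at fraction 0.5, family budget 2 mismatches over an overlap
#' of at least 17, duplex discard thresholds 4 (total) and 2.5 (positions
#' 1-12), and
#' the 9-11 cleavage window.
#'
#' @param ... named overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(min_len = 18L, max_len = 26L, min_count = 2L,
            adapter_min_overlap = 7L, adapter_max_error = 0.1,
            adapter_require = FALSE,
            preferred_band = c(20L, 21L), min_fraction = 0.5,
            max_mismatches = 2L, min_overlap = 17L,
            contaminant_max_mismatches = 0L,
            n_top = Inf, min_abundance = 10,
            precursor_flank = 200L, paired_fraction = 0.6, max_unpaired = 4L,
            score_ceiling = 7, total_max = 4, seed_max = 2.5,
            combine = "either", min_orf_codons = 20L,
            degradome_min_tag_len = 14L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

trim_stage <- function(raw_libs, adapter, params) {
  lapply(raw_libs, function(lb) {
    reads <- lb$reads
    if (!is.null(adapter)) {
      tr <- trim_adapter(reads$seq, adapter,
                         min_overlap = params$adapter_min_overlap,
                         max_error_rate = params$adapter_max_error,
                         require_adapter = params$adapter_require)
      keep <- !is.na(tr$seq) & nchar(tr$seq) > 0L
      agg <- tapply(reads$count[keep], tr$seq[keep], sum)
      reads <- data.frame(seq = names(agg), count = as.integer(agg),
                          stringsAsFactors = FALSE)
    }
    drop_n <- grepl("N", reads$seq, fixed = TRUE)
    total <- sum(reads$count)
    reads <- reads[!drop_n, , drop = FALSE]
    srna_library(lb$name, lb$origin, reads, total_count = total)
  })
}

#' Run the discovery pipeline end-to-end
#'
#' Stages: adapter trimming and collapse -> length/copy filtering ->
#' clustering -> conserved-family assignment -> contaminant screening and
#' candidate selection -> precursor folding and validation -> coding-region
#' annotation -> target scanning and duplex filtering -> degradome mapping,
#' T-plots and cleavage calls. Reruns with identical inputs and parameters
#' give identical results (every stage is deterministic).
#'
#' @param x a [simulate_experiment()] result, or a list with elements
#'   `libraries` (each a list with `name`, `origin`, `reads` data.frame of
#'   `seq`/`count`), `transcripts` (named character), optionally
#'   `degradome_tags` (data.frame `seq`, `count`), `contaminants` (named
#'   list), `training_cds` (character vector of coding sequences) and
#'   `adapter`.
#' @param reference mature-miRNA catalogue (default: the bundled one).
#' @param params a [pipeline_params()] list.
#' @return object of class `mir_pipeline` with all stage outputs and a
#'   manifest of parameters and stage tallies.
#' @export
run_pipeline <- function(x, reference = NULL, params = pipeline_params()) {
  if (inherits(x, "mir_simulation")) {
    training <- substr(x$transcripts[x$coding$transcript_id],
                       x$coding$cds_start, x$coding$cds_end)
    inputs <- list(libraries = x$libraries, transcripts = x$transcripts,
                   degradome_tags = x$degradome$tags,
                   contaminants = x$contaminants,
                   training_cds = unname(training),
                   adapter = x$config$adapter)
  } else inputs <- x
  if (is.null(reference)) reference <- bundled_reference()

  libs <- trim_stage(inputs$libraries, inputs$adapter, params)
  libs_f <- lapply(libs, function(lb) {
    r <- filter_low_count(filter_by_length(lb$reads, params$min_len,
                                           params$max_len),
                          params$min_count)
    srna_library(lb$name, lb$origin, r, total_count = lb$total_count)
  })

  clusters <- build_clusters(libs_f)
  decisions <- dominance_test(clusters, params$preferred_band,
                              params$min_fraction)

  # conserved families, assigned over the expressed clusters' mature
  # (most abundant) sequences
  expressed <- clusters$clusters$abundance >= params$min_abundance
  reps <- setNames(clusters$clusters$mature_seq,
                   clusters$clusters$id)[expressed]
  assignments <- assign_families(reps, reference,
                                 max_mismatches = params$max_mismatches,
                                 min_overlap = params$min_overlap)
  family_mean <- if (nrow(assignments)) {
    family_mean_count(assignments,
                      clusters$counts[rownames(clusters$counts) %in%
                                        assignments$query, , drop = FALSE])
  } else numeric(0)

  # contaminant screening restricted to dominance-passing expressed clusters
  pass_ids <- decisions$cluster_id[decisions$passed]
  xs <- clusters
  xs$clusters <- clusters$clusters[clusters$clusters$id %in% pass_ids &
                                     expressed, , drop = FALSE]
  contaminant_hits <- screen_contaminants(
    xs, if (is.null(inputs$contaminants)) list() else inputs$contaminants,
    params$contaminant_max_mismatches)
  annotations <- rbind(contaminant_hits,
                       if (nrow(assignments)) data.frame(
                         cluster_id = unique(assignments$query),
                         set = "known_miRNA", stringsAsFactors = FALSE))

  candidates <- select_candidates(clusters, decisions, annotations,
                                  n_top = params$n_top,
                                  min_abundance = params$min_abundance)

  # precursor search for candidates plus assigned conserved mature sequences
  mir_set <- c(setNames(candidates$mature_seq, candidates$id),
               reps[names(reps) %in% assignments$query])
  mir_set <- mir_set[!duplicated(names(mir_set))]
  all_reads <- unique(unlist(lapply(libs_f, function(lb) lb$reads$seq)))
  prec_rows <- list()
  for (mid in names(mir_set)) {
    w <- find_precursor_windows(mir_set[[mid]], inputs$transcripts,
                                flank = params$precursor_flank)
    for (r in seq_len(nrow(w))) {
      win_seq <- substr(inputs$transcripts[[w$transcript_id[r]]],
                        w$win_start[r], w$win_end[r])
      f <- fold(win_seq)
      v <- validate_hairpin(f, w$mir_start[r] - w$win_start[r] + 1L,
                            w$mir_end[r] - w$win_start[r] + 1L,
                            paired_fraction = params$paired_fraction,
                            max_unpaired = params$max_unpaired)
      star <- if (v$accepted) infer_star(v, reads = all_reads) else NULL
      prec_rows[[length(prec_rows) + 1L]] <- data.frame(
        mirna_id = mid, transcript_id = w$transcript_id[r],
        win_start = w$win_start[r], win_end = w$win_end[r],
        mir_start = w$mir_start[r], mir_end = w$mir_end[r],
        accepted = v$accepted, arm = v$arm,
        duplex_mismatches = v$duplex_mismatches,
        engine = f$engine, score = f$score,
        star_start = if (!is.null(star)) star$star[1] + w$win_start[r] - 1L else NA_integer_,
        star_end = if (!is.null(star)) star$star[2] + w$win_start[r] - 1L else NA_integer_,
        star_supported = if (!is.null(star)) star$star_supported else NA,
        stringsAsFactors = FALSE)
    }
  }
  precursors <- if (length(prec_rows)) do.call(rbind, prec_rows) else NULL
  arm_pairs <- if (!is.null(precursors) && any(precursors$accepted)) {
    ab <- setNames(rep(0, length(mir_set)), names(mir_set))
    known <- intersect(names(mir_set), clusters$clusters$id)
    ab[known] <- clusters$clusters$abundance[match(known, clusters$clusters$id)]
    detect_arm_pairs(precursors[precursors$accepted, , drop = FALSE], ab)
  } else NULL

  # coding regions
  model <- if (!is.null(inputs$training_cds)) {
    train_codon_model(inputs$training_cds)
  } else NULL
  coding <- if (!is.null(model)) {
    anns <- lapply(inputs$transcripts, function(t) {
      if (nchar(t) >= 60L) find_coding_region(t, model, params$min_orf_codons)
      else structure(list(cds = NULL, frame = NA_integer_, score = NA_real_,
                          coding = FALSE, length = nchar(t)),
                     class = "coding_annotation")
    })
    anns
  } else NULL

  # target scan over coding transcripts
  tx_for_targets <- if (!is.null(coding)) {
    inputs$transcripts[vapply(coding, function(a) isTRUE(a$coding), logical(1))]
  } else inputs$transcripts
  duplexes <- scan_targets(mir_set, tx_for_targets,
                           score_ceiling = params$score_ceiling)
  targets <- filter_duplexes(duplexes, total_max = params$total_max,
                             seed_max = params$seed_max,
                             combine = params$combine,
                             transcript_lengths = nchar(inputs$transcripts))

  # degradome validation
  calls <- NULL; mapping <- NULL; target_table <- NULL
  if (!is.null(inputs$degradome_tags) && nrow(inputs$degradome_tags)) {
    tags <- inputs$degradome_tags
    tags <- tags[nchar(tags$seq) >= params$degradome_min_tag_len, , drop = FALSE]
    mapping <- map_tags(tags, inputs$transcripts)
    ret <- targets[targets$retained, , drop = FALSE]
    call_rows <- list()
    for (tid in unique(ret$transcript_id)) {
      tp <- build_tplot(tid, mapping)
      sel <- ret[ret$transcript_id == tid, , drop = FALSE]
      for (r in seq_len(nrow(sel))) {
        cc <- call_cleavage(tp, sel[r, ])
        if (!is.null(cc)) call_rows[[length(call_rows) + 1L]] <- cc
      }
    }
    calls <- if (length(call_rows)) do.call(rbind, call_rows) else NULL
    target_table <- summarize_targets(calls, coding)
  }

  manifest <- list(
    params = params,
    libraries = data.frame(
      name = vapply(libs, function(l) l$name, character(1)),
      origin = vapply(libs, function(l) l$origin, character(1)),
      total_count = vapply(libs, function(l) l$total_count, numeric(1)),
      retained_unique = vapply(libs_f, function(l) nrow(l$reads), numeric(1))),
    n_clusters = nrow(clusters$clusters),
    n_candidates = nrow(candidates),
    n_assigned = length(unique(assignments$query)),
    n_retained_targets = sum(targets$retained),
    n_calls = if (is.null(calls)) 0L else nrow(calls))

  structure(list(libraries = libs_f, clusters = clusters,
                 decisions = decisions, assignments = assignments,
                 family_mean = family_mean,
                 contaminant_hits = contaminant_hits,
                 candidates = candidates, precursors = precursors,
                 arm_pairs = arm_pairs, codon_model = model,
                 coding = coding, duplexes = duplexes, targets = targets,
                 tag_mapping = mapping, calls = calls,
                 target_table = target_table, manifest = manifest),
            class = "mir_pipeline")
}

#' @export
print.mir_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("mir_pipeline: %d clusters, %d candidates, %d clusters ",
                     "assigned to families, %d retained targets, %d cleavage ",
                     "calls\n"),
              m$n_clusters, m$n_candidates, m$n_assigned,
              m$n_retained_targets, m$n_calls))
  invisible(x)
}

#' Compare a pipeline run with its simulation ground truth
#'
#' A planted miRNA counts as recovered when the cluster holding its
#' canonical sequence is either an emitted candidate or assigned to a
#' family. A planted target counts as recovered when a category-1/2
#' cleavage call sits within one nucleotide of its canonical position on
#' its transcript. An emitted candidate is spurious when its cluster holds
#' no planted mature, length-variant or star sequence.
#'
#' @param sim a [simulate_experiment()] result.
#' @param pipe the [run_pipeline()] result on `sim`.
#' @return list with `mirna_recovery`, `target_recovery`,
#'   `spurious_fraction` and per-item detail tables.
#' @export
evaluate_recovery <- function(sim, pipe) {
  stopifnot(inherits(sim, "mir_simulation"), inherits(pipe, "mir_pipeline"))
  mir <- sim$truth$mirnas
  members <- pipe$clusters$members
  cluster_of <- function(s) {
    i <- match(s, members$seq)
    if (is.na(i)) NA_character_ else members$cluster[i]
  }
  mir$cluster <- vapply(mir$seq, cluster_of, character(1))
  mir$as_candidate <- mir$cluster %in% pipe$candidates$id
  mir$as_family <- mir$cluster %in% pipe$assignments$query
  mir$recovered <- mir$as_candidate | mir$as_family
  mirna_recovery <- mean(mir$recovered)

  tg <- sim$truth$targets
  target_recovery <- NA_real_
  if (!is.null(tg) && nrow(tg)) {
    hit <- logical(nrow(tg))
    if (!is.null(pipe$calls) && nrow(pipe$calls)) {
      good <- pipe$calls[pipe$calls$category <= 2L, , drop = FALSE]
      for (k in seq_len(nrow(tg))) {
        hit[k] <- any(good$transcript_id == tg$transcript_id[k] &
                        abs(good$position - tg$canonical_cleavage[k]) <= 1L)
      }
    }
    tg$recovered <- hit
    target_recovery <- mean(hit)
  }

  planted_seqs <- unique(c(
    mir$seq, mir$star_seq,
    unlist(lapply(seq_len(nrow(mir)), function(k) {
      mir_length_variants(sim$transcripts[[mir$transcript_id[k]]],
                          mir$mir_start[k], mir$mir_end[k])
    }))))
  cand <- pipe$candidates
  spurious <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    mseq <- members$seq[members$cluster == cand$id[k]]
    spurious[k] <- !any(mseq %in% planted_seqs)
  }
  spurious_fraction <- if (nrow(cand)) mean(spurious) else 0

  list(mirna_recovery = mirna_recovery, target_recovery = target_recovery,
       spurious_fraction = spurious_fraction,
       mirnas = mir,
       targets = tg,
       spurious_candidates = cand$id[spurious])
}
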