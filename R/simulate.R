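# Seeded synthetic experiments: transcriptome, planted MIR hairpins and
# target sites, multi-library small RNA reads, degradome tags -- with full
# ground truth for every pipeline stage.

# mildly biased codon weights (A/T-leaning third positions, stops excluded)
# used both to emit synthetic ORFs and as the default training distribution
default_codon_weights <- function() {
  p3 <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  w <- setNames(rep(1, 64), ALL_CODONS)
  w <- w * p3[substr(names(w), 3L, 3L)] * 4
  w[GENETIC_STOPS] <- 0
  w
}

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

point_edits <- function(seq, n_edits) {
  if (n_edits == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_edits)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Seeded study conditions for a synthetic miRNA-discovery experiment: a
#' transcriptome with one ORF per transcript, planted conserved-like and
#' novel miRNA hairpins, perfect-complement target sites, five small RNA
#' libraries (three axenic, two field) and a degradome library with cleavage
#' spikes at the canonical positions.
#'
#' @param seed integer seed (mandatory; every run is reproducible).
#' @param n_transcripts number of transcripts (default 50).
#' @param transcript_length UTR-inclusive length is driven by these uniform
#'   bounds on the 3' UTR (default `c(400, 900)`); see
#'   [generate_transcriptome()].
#' @param gc GC fraction of UTRs and loops (default 0.5).
#' @param n_conserved,n_novel planted miRNA counts (defaults 10 and 10).
#' @param libraries data.frame with columns `name`, `origin`, `depth`
#'   (default: three in-vitro and two field libraries at depth 100000).
#' @param expression_meanlog,expression_sdlog log-normal parameters of
#'   per-miRNA relative abundance on the natural-log scale (defaults 4 and
#'   1.5, spanning the 1 to ~3e5 count range typical of miRNA surveys).
#' @param canonical_fraction fraction of a miRNA's reads at canonical length
#'   (default 0.85).
#' @param star_ratio star/mature abundance ratio (default 0.1).
#' @param background_fraction degradation-read share per library
#'   (default 0.4).
#' @param contaminant_fraction contaminant-read share in field libraries
#'   (default 0.02).
#' @param n_targets planted perfect-complement target sites (default 15).
#' @param adapter 3' sequencing adapter appended to simulated reads.
#' @param degradome list: `spike_fraction` (default 0.3), `tags_per_target`
#'   (default 200), `background_rate` (background tags per transcript
#'   position, default 0.02), `tag_length` (default 20).
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(seed,
                              n_transcripts = 50L,
                              transcript_length = c(400L, 900L),
                              gc = 0.5,
                              n_conserved = 10L,
                              n_novel = 10L,
                              libraries = data.frame(
                                name = c("vitro_f1", "vitro_f2", "vitro_m1",
                                         "field_f1", "field_m1"),
                                origin = c("in_vitro", "in_vitro", "in_vitro",
                                           "field", "field"),
                                depth = 100000L,
                                stringsAsFactors = FALSE),
                              expression_meanlog = 4,
                              expression_sdlog = 1.5,
                              canonical_fraction = 0.85,
                              star_ratio = 0.1,
                              background_fraction = 0.4,
                              contaminant_fraction = 0.02,
                              n_targets = 15L,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              degradome = list(spike_fraction = 0.3,
                                               tags_per_target = 200L,
                                               background_rate = 0.02,
                                               tag_length = 20L)) {
  if (missing(seed)) stop("seed is mandatory")
  fr <- c(gc, canonical_fraction, star_ratio, background_fraction,
          contaminant_fraction, degradome$spike_fraction)
  stopifnot(all(fr >= 0 & fr <= 1), all(libraries$depth >= 1000L),
            all(libraries$origin %in% c("in_vitro", "field")))
  structure(list(seed = as.integer(seed), n_transcripts = n_transcripts,
                 transcript_length = transcript_length, gc = gc,
                 n_conserved = n_conserved, n_novel = n_novel,
                 libraries = libraries,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 canonical_fraction = canonical_fraction,
                 star_ratio = star_ratio,
                 background_fraction = background_fraction,
                 contaminant_fraction = contaminant_fraction,
                 n_targets = n_targets, adapter = normalize_seq(adapter),
                 degradome = degradome),
            class = "sim_config")
}

#' Generate a synthetic transcriptome with one planted ORF per transcript
#'
#' Each transcript is 5'UTR + (ATG + codons drawn from the default codon
#' bias + stop) + 3'UTR; the 3' UTR is deliberately long so that hairpins
#' and target sites can be planted into it later. Coordinates are recorded
#' as ground truth. The planted ORF is the unique maximal reading of its
#' frame: internal codons exclude ATG and an in-frame stop insulates the
#' ORF from upstream 5'UTR start codons, so coding-region recovery is
#' well-defined.
#'
#' @param config a [simulation_config()].
#' @return list with `transcripts` (named character) and `coding`
#'   (data.frame `transcript_id`, `cds_start`, `cds_end`).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  w <- default_codon_weights()
  sense <- setdiff(names(w)[w > 0], "ATG")
  pw <- w[sense] / sum(w[sense])
  tx <- character(config$n_transcripts)
  cds <- matrix(0L, nrow = config$n_transcripts, ncol = 2L)
  for (i in seq_len(config$n_transcripts)) {
    utr5 <- paste0(random_seq(sample(50:150, 1L), config$gc), "TAA")
    ncod <- sample(80:220, 1L)
    orf <- paste0("ATG", paste(sample(sense, ncod, replace = TRUE, prob = pw),
                               collapse = ""),
                  sample(GENETIC_STOPS, 1L))
    utr3 <- random_seq(sample(config$transcript_length[1]:config$transcript_length[2], 1L),
                       config$gc)
    tx[i] <- paste0(utr5, orf, utr3)
    cds[i, ] <- c(nchar(utr5) + 1L, nchar(utr5) + nchar(orf))
  }
  names(tx) <- sprintf("tx%03d", seq_len(config$n_transcripts))
  list(transcripts = tx,
       coding = data.frame(transcript_id = names(tx),
                           cds_start = cds[, 1], cds_end = cds[, 2],
                           stringsAsFactors = FALSE))
}

# build one hairpin around a mature sequence; retried until the fold
# validates under the default thresholds
build_hairpin <- function(mir, gc, arm) {
  n <- nchar(mir)
  for (attempt in 1:25) {
    loop <- random_seq(sample(8:15, 1L), gc)
    star <- point_edits(revcomp(mir), sample(0:2, 1L))
    hp <- if (arm == "five_prime") paste0(mir, loop, star) else paste0(star, loop, mir)
    mir_start <- if (arm == "five_prime") 1L else nchar(star) + nchar(loop) + 1L
    f <- fold(hp)
    v <- validate_hairpin(f, mir_start, mir_start + n - 1L)
    if (v$accepted && v$arm == arm) {
      star_start <- if (arm == "five_prime") n + nchar(loop) + 1L else 1L
      return(list(seq = hp, mir = c(mir_start, mir_start + n - 1L),
                  star = c(star_start, star_start + nchar(star) - 1L),
                  star_seq = star, arm = arm))
    }
  }
  stop("failed to construct a validating hairpin")
}

#' Plant MIR hairpins and target sites into a transcriptome
#'
#' Conserved-like planted miRNAs are copies (at most 2 point edits) of
#' entries of the bundled mature-miRNA catalogue; novel ones are random
#' 21-mers starting with U with probability 0.8. Each mature sequence is
#' embedded in a stem-loop (mir + 8-15 nt loop + noisy reverse complement,
#' at most 2 edits, construction checked against [validate_hairpin()])
#' inserted into a transcript 3' UTR. Perfect-complement target sites are
#' planted into the UTRs of other transcripts with their canonical cleavage
#' position recorded.
#'
#' @param transcriptome a [generate_transcriptome()] result.
#' @param config a [simulation_config()].
#' @param reference optional reference catalogue data.frame; defaults to the
#'   bundled catalogue.
#' @return list with modified `transcripts`, `coding`, and `truth`
#'   (`mirnas` and `targets` data.frames).
#' @export
plant_mir_hairpins <- function(transcriptome, config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  if (is.null(reference)) reference <- bundled_reference()
  tx <- transcriptome$transcripts
  coding <- transcriptome$coding
  n_mir <- config$n_conserved + config$n_novel
  if (n_mir == 0L && config$n_targets == 0L) {
    return(list(transcripts = tx, coding = coding,
                truth = list(mirnas = NULL, targets = NULL)))
  }
  if (config$n_conserved > 0L && nrow(reference) < 1L) stop("empty reference")

  ids <- character(0); seqs <- character(0); fams <- character(0)
  if (config$n_conserved > 0L) {
    pick <- sample(nrow(reference), config$n_conserved,
                   replace = config$n_conserved > nrow(reference))
    for (k in seq_along(pick)) {
      ids <- c(ids, sprintf("cons%02d", k))
      seqs <- c(seqs, point_edits(normalize_seq(reference$seq[pick[k]]),
                                  sample(0:2, 1L)))
      fams <- c(fams, reference$family[pick[k]])
    }
  }
  if (config$n_novel > 0L) {
    for (k in seq_len(config$n_novel)) {
      first <- if (runif(1) < 0.8) "T" else sample(DNA_BASES, 1L)
      s <- paste0(first, random_seq(20L, config$gc))
      ids <- c(ids, sprintf("novel%02d", k))
      seqs <- c(seqs, s)
      fams <- c(fams, "novel")
    }
  }

  # hairpins into distinct transcript 3' UTRs
  host <- sample(length(tx), n_mir)
  mir_rows <- list()
  for (k in seq_len(n_mir)) {
    arm <- if (k %% 2L == 1L) "five_prime" else "three_prime"
    hp <- build_hairpin(seqs[k], config$gc, arm)
    i <- host[k]
    utr3_start <- coding$cds_end[i] + 1L
    L <- nchar(tx[i])
    at <- sample(seq(utr3_start + 5L, L - nchar(hp$seq) - 5L), 1L)
    tx[i] <- paste0(substr(tx[i], 1L, at - 1L), hp$seq, substr(tx[i], at, L))
    mir_rows[[k]] <- data.frame(
      mirna_id = ids[k], seq = seqs[k], family = fams[k],
      class = if (fams[k] == "novel") "novel" else "conserved",
      transcript_id = names(tx)[i],
      hairpin_start = at, hairpin_end = at + nchar(hp$seq) - 1L,
      mir_start = at + hp$mir[1] - 1L, mir_end = at + hp$mir[2] - 1L,
      star_start = at + hp$star[1] - 1L, star_end = at + hp$star[2] - 1L,
      star_seq = hp$star_seq, arm = hp$arm, stringsAsFactors = FALSE)
  }
  mirnas <- do.call(rbind, mir_rows)

  # perfect-complement target sites into UTRs of non-host transcripts
  targets <- NULL
  if (config$n_targets > 0L && n_mir > 0L) {
    free <- setdiff(seq_along(tx), host)
    t_host <- sample(free, config$n_targets,
                     replace = config$n_targets > length(free))
    t_mir <- sample(n_mir, config$n_targets, replace = config$n_targets > n_mir)
    t_rows <- list()
    for (k in seq_len(config$n_targets)) {
      i <- t_host[k]
      site <- revcomp(seqs[t_mir[k]])
      utr3_start <- coding$cds_end[i] + 1L
      L <- nchar(tx[i])
      at <- sample(seq(utr3_start + 5L, L - nchar(site) - 5L), 1L)
      tx[i] <- paste0(substr(tx[i], 1L, at - 1L), site, substr(tx[i], at, L))
      site_end <- at + nchar(site) - 1L
      t_rows[[k]] <- data.frame(
        mirna_id = ids[t_mir[k]], mirna_seq = seqs[t_mir[k]],
        transcript_id = names(tx)[i],
        site_start = at, site_end = site_end,
        canonical_cleavage = site_end - 9L, stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, t_rows)
  }

  list(transcripts = tx, coding = coding,
       truth = list(mirnas = mirnas, targets = targets))
}

mir_length_variants <- function(transcript, mir_start, mir_end) {
  L <- nchar(transcript)
  v <- c(substr(transcript, mir_start + 1L, mir_end),        # 5' -1
         substr(transcript, mir_start, mir_end - 1L),        # 3' -1
         if (mir_start > 1L) substr(transcript, mir_start - 1L, mir_end),
         if (mir_end < L) substr(transcript, mir_start, mir_end + 1L))
  unique(v)
}

#' Simulate multi-library small RNA reads
#'
#' Per library: miRNA reads with log-normal relative abundances (canonical
#' sequence at `canonical_fraction`, the remainder spread over 1-nt 5'/3'
#' length variants taken from the hairpin), star reads at `star_ratio`,
#' degradation background (uniform 18-26 nt fragments of random transcripts)
#' at `background_fraction`, and -- in field libraries only -- contaminant
#' fragments. The adapter is appended to every read.
#'
#' @param planted a [plant_mir_hairpins()] result.
#' @param config a [simulation_config()].
#' @return list with `libraries` (per library, a collapsed data.frame
#'   `seq`, `count` of adapter-carrying reads and the `origin`),
#'   `contaminants` (named list of contaminant sequence sets) and
#'   `true_counts` (per-library canonical-read counts per planted miRNA).
#' @export
simulate_srna_libraries <- function(planted, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  tx <- planted$transcripts
  mir <- planted$truth$mirnas
  n_mir <- if (is.null(mir)) 0L else nrow(mir)
  weights <- if (n_mir) rlnorm(n_mir, config$expression_meanlog,
                               config$expression_sdlog) else numeric(0)

  contam <- replicate(3L, random_seq(150L, config$gc))
  names(contam) <- sprintf("contaminant_set_%d", seq_along(contam))

  variant_pool <- if (n_mir) lapply(seq_len(n_mir), function(k) {
    full_tx <- tx[[mir$transcript_id[k]]]
    setdiff(mir_length_variants(full_tx, mir$mir_start[k], mir$mir_end[k]),
            mir$seq[k])
  }) else list()

  true_counts <- matrix(0L, nrow = n_mir, ncol = nrow(config$libraries),
                        dimnames = if (n_mir) list(mir$mirna_id, config$libraries$name))
  libs <- vector("list", nrow(config$libraries))
  names(libs) <- config$libraries$name
  for (j in seq_len(nrow(config$libraries))) {
    depth <- config$libraries$depth[j]
    is_field <- config$libraries$origin[j] == "field"
    n_contam <- if (is_field) round(depth * config$contaminant_fraction) else 0L
    n_bg <- round(depth * config$background_fraction)
    n_mir_reads <- depth - n_bg - n_contam

    seqs <- character(0); counts <- integer(0)
    if (n_mir > 0L && n_mir_reads > 0L) {
      alloc <- as.integer(rmultinom(1L, n_mir_reads, weights))
      for (k in seq_len(n_mir)) {
        if (alloc[k] == 0L) next
        canon <- rbinom(1L, alloc[k], config$canonical_fraction)
        true_counts[k, j] <- canon
        rest <- alloc[k] - canon
        vp <- variant_pool[[k]]
        if (length(vp) && rest > 0L) {
          va <- as.integer(rmultinom(1L, rest, rep(1, length(vp))))
          seqs <- c(seqs, vp[va > 0L]); counts <- c(counts, va[va > 0L])
        } else canon <- canon + rest
        if (canon > 0L) { seqs <- c(seqs, mir$seq[k]); counts <- c(counts, canon) }
        n_star <- rbinom(1L, alloc[k], config$star_ratio)
        if (n_star > 0L) { seqs <- c(seqs, mir$star_seq[k]); counts <- c(counts, n_star) }
      }
    }
    if (n_bg > 0L) {
      ti <- sample(length(tx), n_bg, replace = TRUE, prob = nchar(tx))
      len <- sample(18:26, n_bg, replace = TRUE)
      maxs <- nchar(tx)[ti] - len + 1L
      st <- 1L + floor(runif(n_bg) * maxs)
      frag <- substr(tx[ti], st, st + len - 1L)
      cf <- table(frag)
      seqs <- c(seqs, names(cf)); counts <- c(counts, as.integer(cf))
    }
    if (n_contam > 0L) {
      ci <- sample(length(contam), n_contam, replace = TRUE)
      len <- sample(18:26, n_contam, replace = TRUE)
      st <- 1L + floor(runif(n_contam) * (nchar(contam)[ci] - len + 1L))
      frag <- substr(contam[ci], st, st + len - 1L)
      cf <- table(frag)
      seqs <- c(seqs, names(cf)); counts <- c(counts, as.integer(cf))
    }
    df <- data.frame(seq = paste0(seqs, config$adapter), count = counts,
                     stringsAsFactors = FALSE)
    agg <- tapply(df$count, df$seq, sum)
    libs[[j]] <- list(name = config$libraries$name[j],
                      origin = config$libraries$origin[j],
                      reads = data.frame(seq = names(agg),
                                         count = as.integer(agg),
                                         stringsAsFactors = FALSE))
  }
  list(libraries = libs, contaminants = as.list(contam),
       true_counts = true_counts)
}

#' Simulate a degradome library
#'
#' For every planted target, `spike_fraction` of that transcript's tags
#' start exactly at the canonical cleavage position (the tag being the
#' downstream `tag_length`-mer); the rest start at uniform positions.
#' All transcripts additionally receive uniform background tags at
#' `background_rate` per position.
#'
#' @param planted a [plant_mir_hairpins()] result.
#' @param config a [simulation_config()].
#' @return list with `tags` (collapsed data.frame `seq`, `count`) and
#'   `spike_counts` (data.frame of planted raw spike counts).
#' @export
simulate_degradome <- function(planted, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  tx <- planted$transcripts
  tg <- planted$truth$targets
  tl <- config$degradome$tag_length
  seqs <- character(0); counts <- integer(0)
  spike_rows <- list()
  if (!is.null(tg) && nrow(tg)) {
    for (k in seq_len(nrow(tg))) {
      t_seq <- tx[[tg$transcript_id[k]]]
      n_tags <- config$degradome$tags_per_target
      n_spike <- round(n_tags * config$degradome$spike_fraction)
      canon <- tg$canonical_cleavage[k]
      if (canon + tl - 1L <= nchar(t_seq) && n_spike > 0L) {
        seqs <- c(seqs, substr(t_seq, canon, canon + tl - 1L))
        counts <- c(counts, n_spike)
        spike_rows[[k]] <- data.frame(transcript_id = tg$transcript_id[k],
                                      position = canon, raw = n_spike,
                                      stringsAsFactors = FALSE)
      }
      n_bg <- n_tags - n_spike
      if (n_bg > 0L) {
        st <- sample(nchar(t_seq) - tl + 1L, n_bg, replace = TRUE)
        cf <- table(substr(rep(t_seq, n_bg), st, st + tl - 1L))
        seqs <- c(seqs, names(cf)); counts <- c(counts, as.integer(cf))
      }
    }
  }
  for (i in seq_along(tx)) {
    n_bg <- rbinom(1L, nchar(tx[i]), config$degradome$background_rate)
    if (n_bg == 0L) next
    st <- sample(nchar(tx[i]) - tl + 1L, n_bg, replace = TRUE)
    cf <- table(substr(rep(tx[[i]], n_bg), st, st + tl - 1L))
    seqs <- c(seqs, names(cf)); counts <- c(counts, as.integer(cf))
  }
  agg <- tapply(counts, seqs, sum)
  list(tags = data.frame(seq = names(agg), count = as.integer(agg),
                         stringsAsFactors = FALSE),
       spike_counts = do.call(rbind, spike_rows))
}

#' Run the full synthetic experiment
#'
#' Chains [generate_transcriptome()], [plant_mir_hairpins()],
#' [simulate_srna_libraries()] and [simulate_degradome()] under one seed.
#'
#' @param config a [simulation_config()].
#' @param reference optional reference catalogue for the conserved-like
#'   planted miRNAs.
#' @return object of class `mir_simulation`.
#' @export
simulate_experiment <- function(config, reference = NULL) {
  base <- generate_transcriptome(config)
  planted <- plant_mir_hairpins(base, config, reference = reference)
  srna <- simulate_srna_libraries(planted, config)
  deg <- simulate_degradome(planted, config)
  structure(list(config = config, transcripts = planted$transcripts,
                 coding = planted$coding, truth = planted$truth,
                 libraries = srna$libraries, contaminants = srna$contaminants,
                 true_counts = srna$true_counts,
                 degradome = deg), class = "mir_simulation")
}

#' @export
print.mir_simulation <- function(x, ...) {
  nm <- if (is.null(x$truth$mirnas)) 0L else nrow(x$truth$mirnas)
  nt <- if (is.null(x$truth$targets)) 0L else nrow(x$truth$targets)
  cat(sprintf(paste0("mir_simulation (seed %d): %d transcripts, %d planted ",
                     "miRNAs, %d planted targets, %d libraries\n"),
              x$config$seed, length(x$transcripts), nm, nt,
              length(x$libraries)))
  invisible(x)
}

#' Write simulated reads as FASTQ
#'
#' Expands collapsed reads to individual records with constant high
#' qualities.
#'
#' @param reads collapsed data.frame (`seq`, `count`).
#' @param path output file.
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- rep(reads$seq, reads$count)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), con)
  invisible(path)
}
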