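# Grouping of perfectly co-aligned small RNA reads into clusters, size
# profiling, and selection of novel miRNA candidate clusters.

#' Build clusters of perfectly co-aligned reads
#'
#' Two reads share a cluster iff they are connected under "one sequence is an
#' exact ungapped substring of the other" (transitive closure), which captures
#' the picture of a dominant mature species plus shorter or shifted length
#' variants. Clusters carrying fewer than two read copies in total are
#' discarded.
#'
#' @param libraries list of [srna_library()] objects with length-filtered
#'   collapsed reads.
#' @return object of class `srna_clusters`: per-cluster feature table, a
#'   cluster-by-library count matrix, the member table, and pooled size
#'   profiles.
#' @export
build_clusters <- function(libraries) {
  stopifnot(length(libraries) >= 1L)
  lib_names <- vapply(libraries, function(l) l$name, character(1))
  if (anyDuplicated(lib_names)) stop("library names must be unique")
  origins <- vapply(libraries, function(l) l$origin, character(1))

  seqs <- sort(unique(unlist(lapply(libraries, function(l) l$reads$seq))))
  n <- length(seqs)
  counts <- matrix(0, nrow = n, ncol = length(libraries),
                   dimnames = list(NULL, lib_names))
  for (j in seq_along(libraries)) {
    r <- libraries[[j]]$reads
    counts[match(r$seq, seqs), j] <- r$count
  }
  pooled <- rowSums(counts)
  len <- nchar(seqs)

  # containment edges by substring hashing: enumerate, for every observed
  # shorter length, all windows of each longer sequence and look them up
  parent <- seq_len(n)
  uf_find <- function(i) {          # path halving on the local parent vector
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    lens_present <- sort(unique(len))
    for (lsub in lens_present) {
      longer <- which(len > lsub)
      if (!length(longer)) next
      max_off <- max(len[longer]) - lsub + 1L
      for (off in seq_len(max_off)) {
        src <- longer[len[longer] - lsub + 1L >= off]
        if (!length(src)) next
        sub <- substr(seqs[src], off, off + lsub - 1L)
        hit <- match(sub, seqs)
        ok <- which(!is.na(hit))
        for (k in ok) {
          a <- uf_find(src[k]); b <- uf_find(hit[k])
          if (a != b) parent[b] <- a
        }
      }
    }
  }
  comp <- vapply(seq_len(n), uf_find, integer(1))

  keep_cl <- tapply(pooled, comp, sum) >= 2
  comp_ids <- as.integer(names(keep_cl)[keep_cl])
  ord <- order(-vapply(comp_ids, function(cid) sum(pooled[comp == cid]), numeric(1)),
               vapply(comp_ids, function(cid) {
                 m <- which(comp == cid)
                 m <- m[order(-len[m], seqs[m])]
                 seqs[m[1]]
               }, character(1)))
  comp_ids <- comp_ids[ord]

  cl_id <- sprintf("cl%05d", seq_along(comp_ids))
  members <- NULL
  reps <- character(length(comp_ids))
  ab <- matrix(0, nrow = length(comp_ids), ncol = length(libraries),
               dimnames = list(cl_id, lib_names))
  first_nt <- matrix(0, nrow = length(comp_ids), ncol = 4L,
                     dimnames = list(cl_id, DNA_BASES))
  profiles <- vector("list", length(comp_ids))
  member_counts <- NULL
  for (k in seq_along(comp_ids)) {
    m <- which(comp == comp_ids[k])
    m <- m[order(-pooled[m], seqs[m])]
    reps[k] <- seqs[m[order(-len[m], seqs[m])][1]]
    ab[k, ] <- colSums(counts[m, , drop = FALSE])
    f <- tapply(pooled[m], substr(seqs[m], 1L, 1L), sum)
    first_nt[k, names(f)] <- f / sum(pooled[m])
    p <- tapply(pooled[m], len[m], sum)
    profiles[[k]] <- setNames(as.numeric(p), names(p))
    members <- rbind(members, data.frame(
      cluster = cl_id[k], seq = seqs[m], length = len[m],
      count = pooled[m], stringsAsFactors = FALSE))
    member_counts <- rbind(member_counts, counts[m, , drop = FALSE])
  }
  if (!is.null(member_counts)) rownames(member_counts) <- members$seq

  # the mature-sequence estimate is the most abundant member (the dominant
  # species); the representative stays the longest member
  mature <- vapply(cl_id, function(id) members$seq[members$cluster == id][1],
                   character(1))
  clusters <- data.frame(
    id = cl_id,
    representative = reps,
    rep_length = nchar(reps),
    mature_seq = unname(mature),
    mature_length = nchar(unname(mature)),
    abundance = rowSums(ab),
    gc_content = gc_fraction(reps),
    n_members = as.integer(table(factor(members$cluster, levels = cl_id))),
    library_presence = apply(ab > 0, 1L, function(z) paste(lib_names[z], collapse = ",")),
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL

  structure(list(clusters = clusters, counts = ab, members = members,
                 member_counts = member_counts,
                 first_nt = first_nt, size_profiles = setNames(profiles, cl_id),
                 libraries = data.frame(name = lib_names, origin = origins,
                                        stringsAsFactors = FALSE)),
            class = "srna_clusters")
}

#' @export
print.srna_clusters <- function(x, ...) {
  cat(sprintf("srna_clusters: %d clusters over %d libraries (%s)\n",
              nrow(x$clusters), nrow(x$libraries),
              paste(x$libraries$name, collapse = ", ")))
  invisible(x)
}

#' Read-length profile of a cluster
#'
#' Counts of member reads summed by read length, pooled over libraries or for
#' a single library.
#'
#' @param x an `srna_clusters` object.
#' @param id cluster id.
#' @param library optional library name for a per-library view.
#' @return named numeric vector, length -> summed count.
#' @export
size_profile <- function(x, id, library = NULL) {
  stopifnot(inherits(x, "srna_clusters"))
  if (!id %in% x$clusters$id) stop("empty cluster: unknown id ", id)
  if (is.null(library)) return(x$size_profiles[[id]])
  if (!library %in% x$libraries$name) stop("unknown library ", library)
  sel <- x$members$cluster == id
  p <- tapply(x$member_counts[sel, library], x$members$length[sel], sum)
  p <- p[p > 0]
  setNames(as.numeric(p), names(p))
}

#' Dominance test for candidate clusters
#'
#' A cluster passes when a single read length carries at least `min_fraction`
#' of its pooled abundance and that dominant length lies in the preferred
#' band. Known miRNA clusters show exactly this shape: a clearly dominant
#' signal, preferably at 20-21 nt.
#'
#' @param x an `srna_clusters` object.
#' @param preferred_band lengths accepted as dominant (default `c(20, 21)`;
#'   widen to `19:24` for a permissive scan).
#' @param min_fraction minimum fraction of pooled abundance at the dominant
#'   length (default 0.5).
#' @return data.frame with one row per cluster: `cluster_id`,
#'   `dominant_length`, `dominance_fraction`, `passed`, `reasons`.
#' @export
dominance_test <- function(x, preferred_band = c(20L, 21L), min_fraction = 0.5) {
  stopifnot(inherits(x, "srna_clusters"))
  out <- lapply(x$clusters$id, function(id) {
    p <- x$size_profiles[[id]]
    if (!length(p)) stop("empty cluster")
    lens <- as.integer(names(p))
    o <- order(-p, lens)            # tie -> shorter length
    dom <- lens[o[1]]
    frac <- as.numeric(p[o[1]] / sum(p))
    reasons <- character(0)
    if (frac < min_fraction) reasons <- c(reasons, "no_dominant_length")
    if (!dom %in% preferred_band) reasons <- c(reasons, "outside_preferred_band")
    data.frame(cluster_id = id, dominant_length = dom,
               dominance_fraction = frac, passed = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Screen cluster representatives against contaminant sequence sets
#'
#' A cluster is annotated with every contaminant set (e.g. rRNA/tRNA models,
#' bacterial, fungal or algal sequence collections) in which its
#' representative occurs as an ungapped substring with at most
#' `max_mismatches` mismatches. Annotated clusters are excluded from
#' candidacy but kept in reports.
#'
#' @param x an `srna_clusters` object.
#' @param contaminant_sets named list; each element a character vector of
#'   sequences or a path to a FASTA file.
#' @param max_mismatches mismatch tolerance (default 0).
#' @return data.frame with columns `cluster_id`, `set`.
#' @export
screen_contaminants <- function(x, contaminant_sets, max_mismatches = 0L) {
  stopifnot(inherits(x, "srna_clusters"))
  if (!length(contaminant_sets)) {
    return(data.frame(cluster_id = character(0), set = character(0)))
  }
  if (is.null(names(contaminant_sets)) || any(names(contaminant_sets) == "")) {
    stop("contaminant_sets must be named")
  }
  sets <- lapply(contaminant_sets, function(s) {
    if (length(s) == 1L && file.exists(s)) s <- read_sequences(s)
    Biostrings::DNAStringSet(normalize_seq(s))
  })
  hits <- list()
  for (nm in names(sets)) {
    subj <- sets[[nm]]
    for (k in seq_len(nrow(x$clusters))) {
      cnt <- Biostrings::vcountPattern(x$clusters$representative[k], subj,
                                       max.mismatch = max_mismatches)
      if (any(cnt > 0)) {
        hits[[length(hits) + 1L]] <- data.frame(
          cluster_id = x$clusters$id[k], set = nm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(cluster_id = character(0), set = character(0)))
  }
  do.call(rbind, hits)
}

#' Select and rank novel miRNA candidate clusters
#'
#' Candidates are unannotated clusters that pass the dominance test, are
#' present in at least one axenic (in vitro) library, and carry at least
#' `min_abundance` pooled read copies. They are ranked by pooled abundance
#' (ties by representative sequence) and truncated to `n_top`. GC content and
#' the count-weighted 5' nucleotide profile are reported for each candidate;
#' optional hard filters on both are available.
#'
#' @param x an `srna_clusters` object.
#' @param decisions output of [dominance_test()].
#' @param annotations output of [screen_contaminants()] (may be empty).
#' @param n_top maximum number of candidates to return (default all).
#' @param min_abundance minimum pooled read count (default 10).
#' @param gc_range optional numeric length-2 GC-content filter.
#' @param require_5prime_U if `TRUE`, require the majority 5' nucleotide to
#'   be U (T).
#' @return data.frame of ranked candidates with features.
#' @export
select_candidates <- function(x, decisions, annotations = NULL, n_top = Inf,
                              min_abundance = 10, gc_range = NULL,
                              require_5prime_U = FALSE) {
  stopifnot(inherits(x, "srna_clusters"))
  cl <- x$clusters
  passed <- decisions$passed[match(cl$id, decisions$cluster_id)]
  annotated <- if (is.null(annotations) || !nrow(annotations)) {
    rep(FALSE, nrow(cl))
  } else cl$id %in% annotations$cluster_id
  invitro <- x$libraries$name[x$libraries$origin == "in_vitro"]
  in_vitro_present <- rowSums(x$counts[, invitro, drop = FALSE] > 0) > 0
  keep <- passed & !annotated & in_vitro_present & cl$abundance >= min_abundance
  if (!is.null(gc_range)) {
    keep <- keep & cl$gc_content >= gc_range[1] & cl$gc_content <= gc_range[2]
  }
  if (require_5prime_U) {
    maj <- DNA_BASES[max.col(x$first_nt, ties.method = "first")]
    keep <- keep & maj == "T"
  }
  cand <- cl[keep, , drop = FALSE]
  if (!nrow(cand)) return(cbind(cand, dominant_length = integer(0),
                                dominance_fraction = numeric(0)))
  d <- decisions[match(cand$id, decisions$cluster_id), ]
  cand$dominant_length <- d$dominant_length
  cand$dominance_fraction <- d$dominance_fraction
  fr <- x$first_nt[match(cand$id, rownames(x$first_nt)), , drop = FALSE]
  colnames(fr) <- paste0("first_", c("A", "C", "G", "U"))
  cand <- cbind(cand, as.data.frame(fr))
  cand <- cand[order(-cand$abundance, cand$representative), , drop = FALSE]
  cand <- head(cand, n = if (is.finite(n_top)) n_top else nrow(cand))
  rownames(cand) <- NULL
  cand
}
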