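# Independent brute-force oracles and small fixture builders used across
# the suite. All are deliberately naive and unoptimized.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

make_library <- function(seqs, counts, name = "lib1", origin = "in_vitro") {
  srna_library(name, origin,
               data.frame(seq = seqs, count = as.integer(counts),
                          stringsAsFactors = FALSE))
}

# exhaustive-offset overlap alignment: minimize mismatches, tie by larger
# overlap then smaller |offset|
oracle_overlap <- function(q, r, min_ov = 17L) {
  q <- strsplit(toupper(gsub("u", "t", q, ignore.case = TRUE)), "")[[1]]
  r <- strsplit(toupper(gsub("u", "t", r, ignore.case = TRUE)), "")[[1]]
  nq <- length(q); nr <- length(r); best <- NULL
  for (off in seq(-(nr - 1L), nq - 1L)) {
    s <- max(1L, 1L + off); e <- min(nq, nr + off)
    ov <- e - s + 1L
    if (ov < min_ov) next
    mm <- sum(q[s:e] != r[(s - off):(e - off)])
    if (is.null(best) || mm < best$mm ||
        (mm == best$mm && ov > best$ov) ||
        (mm == best$mm && ov == best$ov && abs(off) < abs(best$off))) {
      best <- list(mm = mm, ov = ov, off = off)
    }
  }
  best
}

# pairwise substring-containment closure over a read set; returns the
# partition as a list of sequence sets (clusters of total count >= 2)
oracle_clusters <- function(seqs, counts) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && grepl(seqs[j], seqs[i], fixed = TRUE)) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- split(seq_len(n), comp)
  out <- Filter(function(idx) sum(counts[idx]) >= 2, out)
  lapply(out, function(idx) sort(seqs[idx]))
}

can_pair_bf <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG",
                                                  "GT", "TG")

# pure enumeration of every nested structure (min loop 3); maximum pairs
oracle_fold_maxpairs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (can_pair_bf(ch[i], ch[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + if (k + 1L <= j) rec(k + 1L, j) else 0L
        if (v > best) best <- v
      }
    }
    best
  }
  rec(1L, length(ch))
}

# naive all-offsets duplex scorer with the explicit per-position rule
oracle_scan <- function(mirna, transcript) {
  m <- strsplit(mirna, "")[[1]]
  tx <- strsplit(transcript, "")[[1]]
  n <- length(m); L <- length(tx)
  out <- list()
  for (s in seq_len(L - n + 1L)) {
    states <- character(n)
    for (k in seq_len(n)) {
      t <- tx[s + n - k]                 # transcript base facing position k
      pairkey <- paste0(m[k], t)
      states[k] <- if (pairkey %in% c("AT", "TA", "GC", "CG")) "|"
      else if (pairkey %in% c("GT", "TG")) "o"
      else "x"
    }
    total <- sum(states == "x") + 0.5 * sum(states == "o")
    seed <- sum(states[1:12] == "x") + 0.5 * sum(states[1:12] == "o")
    out[[s]] <- list(site_start = s, site_end = s + n - 1L,
                     states = paste(states, collapse = ""),
                     total = total, seed = seed)
  }
  out
}

# hand-built fold_result with a prescribed pair table, for controlled
# hairpin-validation cases
fake_fold <- function(seq, pair_table) {
  struct <- rep(".", length(pair_table))
  struct[pair_table > seq_along(pair_table)] <- "("
  struct[pair_table != 0 & pair_table < seq_along(pair_table)] <- ")"
  structure(list(seq = seq, structure = paste(struct, collapse = ""),
                 pair_table = as.integer(pair_table),
                 score = sum(pair_table > 0) / 2, engine = "maxpair"),
            class = "fold_result")
}

# a perfect hairpin: S + loop + reverse complement of S
perfect_hairpin <- function(stem_len = 20L, loop = "AACC") {
  s <- rand_seq(stem_len)
  list(seq = paste0(s, loop,
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(s)))),
       stem = s, loop_len = nchar(loop))
}
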