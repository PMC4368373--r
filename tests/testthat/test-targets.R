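test_that("scanning scores perfect, mutated and self sites correctly", {
  set.seed(51)
  mir <- rand_seq(21)
  tx <- c(t1 = paste0(rand_seq(60), revcomp(mir), rand_seq(60)))
  hits <- scan_targets(c(m1 = mir), tx)
  perfect <- hits[hits$total_score == 0, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$site_start, 61)
  expect_equal(perfect$states, strrep("|", 21))
  expect_equal(perfect$seed_score, 0)

  # one substitution facing miRNA position 15
  site <- strsplit(revcomp(mir), "")[[1]]
  k <- 15
  pos_in_site <- 21 - k + 1
  old <- site[pos_in_site]
  site[pos_in_site] <- setdiff(c("A", "C", "G", "T"), c(old,
    chartr("ACGT", "TGCA", substr(mir, k, k)),   # keep it a true mismatch
    if (substr(mir, k, k) == "G") "T", if (substr(mir, k, k) == "T") "G"))[1]
  tx2 <- c(t2 = paste0(rand_seq(30), paste(site, collapse = ""), rand_seq(30)))
  h2 <- scan_targets(c(m1 = mir), tx2)
  edited <- h2[h2$site_start == 31, ]
  expect_equal(edited$total_score, 1)
  expect_equal(substr(edited$states, 15, 15), "x")
  expect_equal(substr(edited$states, 1, 14), strrep("|", 14))

  # the miRNA's own sequence is not a target site
  tx3 <- c(t3 = paste0(rand_seq(30), mir, rand_seq(30)))
  h3 <- scan_targets(c(m1 = mir), tx3, score_ceiling = 7)
  oracle <- oracle_scan(mir, tx3[[1]])
  expect_equal(nrow(h3), sum(vapply(oracle, function(o) o$total < 7, logical(1))))
})

test_that("scanning equals the all-offsets brute-force scorer", {
  set.seed(52)
  for (i in 1:4) {
    mir <- rand_seq(sample(18:24, 1))
    tx <- paste0(rand_seq(sample(100:250, 1)),
                 if (i %% 2 == 0) revcomp(mir) else "",
                 rand_seq(50))
    got <- scan_targets(c(m = mir), c(t = tx), score_ceiling = 100)
    want <- oracle_scan(mir, tx)
    expect_equal(nrow(got), length(want))
    for (j in seq_along(want)) {
      expect_equal(got$states[j], want[[j]]$states)
      expect_equal(got$total_score[j], want[[j]]$total)
      expect_equal(got$seed_score[j], want[[j]]$seed)
    }
  }
})

test_that("duplex scores follow the one-point / half-point rule", {
  expect_equal(score_duplex(strrep("|", 21)),
               data.frame(total_score = 0, seed_score = 0))

  # 2 mismatches at 14, 18 and 3 wobbles at 13, 16, 20
  st <- strsplit(strrep("|", 21), "")[[1]]
  st[c(14, 18)] <- "x"; st[c(13, 16, 20)] <- "o"
  sc <- score_duplex(paste(st, collapse = ""))
  expect_equal(sc$total_score, 3.5)
  expect_equal(sc$seed_score, 0)

  st2 <- strsplit(strrep("|", 21), "")[[1]]
  st2[c(2, 5, 9)] <- "x"
  sc2 <- score_duplex(paste(st2, collapse = ""))
  expect_equal(sc2$total_score, 3)
  expect_equal(sc2$seed_score, 3)

  # total is permutation-invariant; seed depends only on positions 1-12
  set.seed(53)
  for (i in 1:20) {
    states <- sample(c("|", "o", "x"), 21, TRUE)
    s_orig <- score_duplex(paste(states, collapse = ""))
    s_perm <- score_duplex(paste(sample(states), collapse = ""))
    expect_equal(s_perm$total_score, s_orig$total_score)
    tail_changed <- states
    tail_changed[13:21] <- "x"
    expect_equal(score_duplex(paste(tail_changed, collapse = ""))$seed_score,
                 s_orig$seed_score)
  }
})

test_that("retention thresholds discard on total or seed score", {
  mk <- function(total, seed) {
    # construct a state string with the requested scores
    st <- rep("|", 21)
    n_seed_mm <- floor(seed); st[seq_len(n_seed_mm)] <- "x"
    if (seed %% 1 == 0.5) st[12] <- "o"
    rest <- total - seed
    n_mm <- floor(rest); if (n_mm > 0) st[13:(12 + n_mm)] <- "x"
    if (rest %% 1 == 0.5) st[21] <- "o"
    data.frame(mirna_id = "m", transcript_id = "t", site_start = 100,
               site_end = 120, states = paste(st, collapse = ""),
               total_score = total, seed_score = seed,
               stringsAsFactors = FALSE)
  }
  expect_true(filter_duplexes(mk(3.5, 0))$retained)
  f4 <- filter_duplexes(mk(4, 0))
  expect_false(f4$retained)
  expect_equal(f4$rejection_reason, "total")
  both <- mk(3, 3)
  expect_false(filter_duplexes(both)$retained)
  expect_equal(filter_duplexes(both)$rejection_reason, "seed")
  expect_true(filter_duplexes(both, combine = "both")$retained)
  # seed 2.5 is the boundary: kept (discard requires strictly greater)
  expect_true(filter_duplexes(mk(3.5, 2.5))$retained)
})

test_that("cleavage window faces miRNA positions 9-11", {
  w <- predicted_cleavage_window(100, 120)
  expect_equal(w$canonical, 111)
  expect_equal(w$window, c(110, 111, 112))

  w24 <- predicted_cleavage_window(1, 24)
  expect_equal(w24$canonical, 15)

  clip <- predicted_cleavage_window(100, 120, transcript_length = 111)
  expect_equal(clip$window, c(110, 111))

  fd <- filter_duplexes(data.frame(mirna_id = "m", transcript_id = "t",
                                   site_start = 100, site_end = 120,
                                   states = strrep("|", 21),
                                   total_score = 0, seed_score = 0))
  expect_equal(fd$canonical_cleavage, 111)
  expect_equal(c(fd$window_start, fd$window_end), c(110, 112))
})

test_that("external site lists re-score identically to native scans", {
  set.seed(54)
  dir <- withr::local_tempdir()
  mir <- rand_seq(21)
  tx <- c(t1 = paste0(rand_seq(40), revcomp(mir), rand_seq(40)))
  native <- scan_targets(c(m1 = mir), tx)
  native <- native[native$total_score == 0, ]
  path <- file.path(dir, "sites.tsv")
  write.table(native[, c("mirna_id", "transcript_id", "site_start",
                         "site_end", "states")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  imported <- import_external_sites(path)
  expect_equal(imported$total_score, native$total_score)
  expect_equal(imported$seed_score, native$seed_score)

  # malformed row: state string shorter than the site
  bad <- native
  bad$states <- substr(bad$states, 1, 10)
  write.table(bad[, c("mirna_id", "transcript_id", "site_start",
                      "site_end", "states")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(out <- import_external_sites(path), "malformed")
  expect_equal(nrow(out), 0)

  empty <- native[0, c("mirna_id", "transcript_id", "site_start",
                       "site_end", "states")]
  write.table(empty, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(import_external_sites(path)), 0)
})
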