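test_that("precursor windows expand exact occurrences by the flank", {
  set.seed(30)
  tx <- c(t1 = paste0(rand_seq(249), "TGACAGAAGAGAGTGAGCACA", rand_seq(730)))
  mir <- "TGACAGAAGAGAGTGAGCACA"
  w <- find_precursor_windows(mir, tx, flank = 200)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$win_start, w$win_end), c(50, 470))
  expect_equal(c(w$mir_start, w$mir_end), c(250, 270))

  expect_equal(nrow(find_precursor_windows(rand_seq(21), tx)), 0)

  tx2 <- c(t2 = paste0(rand_seq(100), mir, rand_seq(300), mir, rand_seq(100)))
  expect_equal(nrow(find_precursor_windows(mir, tx2)), 2)
})

test_that("maximum-pair folding handles perfect repeats and unpairable input", {
  set.seed(33)
  s <- rand_seq(15)
  f <- fold(paste0(s, "AAAA", revcomp(s)))
  expect_equal(f$score, 15)
  expect_true(all(f$pair_table[1:15] > 0))

  f0 <- fold(strrep("A", 30))
  expect_equal(f0$score, 0)
  expect_equal(f0$structure, strrep(".", 30))

  expect_error(fold("ACGTN"), "invalid characters")
})

test_that("folding equals exhaustive structure enumeration up to 18 nt", {
  set.seed(21)
  for (n in c(10, 12, 14, 16, 18)) {
    for (i in 1:6) {
      s <- rand_seq(n)
      expect_equal(fold(s)$score, oracle_fold_maxpairs(s),
                   info = paste("seq", s))
    }
  }
})

test_that("pair tables are involutive, crossing-free and loop-respecting", {
  set.seed(77)
  for (i in 1:10) {
    f <- fold(rand_seq(60))
    pt <- f$pair_table
    paired <- which(pt > 0)
    expect_equal(pt[pt[paired]], paired)               # involution
    expect_true(all(abs(pt[paired] - paired) >= 4))    # min loop 3
    arcs <- cbind(pmin(paired, pt[paired]), pmax(paired, pt[paired]))
    arcs <- unique(arcs)
    if (nrow(arcs) > 1) {
      for (a in seq_len(nrow(arcs) - 1)) {
        for (b in seq(a + 1, nrow(arcs))) {
          i1 <- arcs[a, 1]; j1 <- arcs[a, 2]; i2 <- arcs[b, 1]; j2 <- arcs[b, 2]
          crossing <- (i1 < i2 && i2 < j1 && j1 < j2) ||
            (i2 < i1 && i1 < j2 && j2 < j1)
          expect_false(crossing)
        }
      }
    }
    # only canonical and wobble pairs
    ch <- strsplit(f$seq, "")[[1]]
    for (p in paired) {
      expect_true(paste0(ch[p], ch[pt[p]]) %in%
                    c("AT", "TA", "GC", "CG", "GT", "TG"))
    }
  }
})

test_that("hairpin validation separates clean duplexes from loop-spanning ones", {
  set.seed(31)
  hp <- perfect_hairpin(20, "AACC")
  f <- fold(hp$seq)
  v <- validate_hairpin(f, 1, 20)
  expect_true(v$accepted)
  expect_equal(v$arm, "five_prime")
  expect_equal(v$duplex_mismatches, 0)

  v3 <- validate_hairpin(f, 25, 44)
  expect_true(v3$accepted)
  expect_equal(v3$arm, "three_prime")

  # a miRNA spanning the loop pairs to both sides
  vloop <- validate_hairpin(f, 12, 32)
  expect_false(vloop$accepted)
  expect_true("partners_on_both_sides" %in% vloop$reasons)

  # 40% unpaired miRNA positions: fails both the pairing fraction (8 of 20
  # below 0.6 once fewer than 12 pair) and the 5-mismatch cap
  pt <- integer(44)
  for (i in 1:11) { pt[i] <- 45 - i; pt[45 - i] <- i }   # only 11 of 20 paired
  fk <- fake_fold(hp$seq, pt)
  v40 <- validate_hairpin(fk, 1, 20)
  expect_false(v40$accepted)
  expect_true("low_paired_fraction" %in% v40$reasons)
  expect_true("too_many_duplex_mismatches" %in% v40$reasons)
})

test_that("star inference applies the 2-nt overhang convention", {
  set.seed(32)
  # perfect stem pairing i <-> 45 - i, miRNA on the 5' arm at [1, 20]
  hp <- perfect_hairpin(20, "AACC")
  f <- fold(hp$seq)
  v <- validate_hairpin(f, 1, 20)
  st <- infer_star(v)
  expect_equal(st$star, c(27, 44))

  # mirrored: miRNA on the 3' arm
  v3 <- validate_hairpin(f, 25, 44)
  st3 <- infer_star(v3)
  expect_equal(st3$star, c(1, 18))

  # the star's reverse complement matches the miRNA over the paired region
  expect_equal(revcomp(st3$seq), substr(hp$seq, 25 + 2, 44))

  # support flag reflects the observed read set
  reads <- c(rand_seq(21), st$seq)
  expect_true(infer_star(v, reads = reads)$star_supported)
  expect_false(infer_star(v, reads = rand_seq(21))$star_supported)
})

test_that("planted precursors validate and shuffled windows are rejected", {
  set.seed(8)
  cfg <- simulation_config(seed = 12, n_transcripts = 12, n_conserved = 3,
                           n_novel = 5, n_targets = 0,
                           libraries = data.frame(name = "v1",
                                                  origin = "in_vitro",
                                                  depth = 1000L))
  planted <- plant_mir_hairpins(generate_transcriptome(cfg), cfg)
  mir <- planted$truth$mirnas
  accept <- logical(nrow(mir))
  reject_shuffled <- 0L; n_shuffled <- 0L
  for (k in seq_len(nrow(mir))) {
    tx <- planted$transcripts[[mir$transcript_id[k]]]
    hp <- substr(tx, mir$hairpin_start[k], mir$hairpin_end[k])
    rel <- c(mir$mir_start[k], mir$mir_end[k]) - mir$hairpin_start[k] + 1
    v <- validate_hairpin(fold(hp), rel[1], rel[2])
    accept[k] <- v$accepted
    for (r in 1:5) {
      n_shuffled <- n_shuffled + 1L
      sh <- paste(sample(strsplit(hp, "")[[1]]), collapse = "")
      vs <- validate_hairpin(fold(sh), rel[1], rel[2])
      reject_shuffled <- reject_shuffled + !vs$accepted
    }
  }
  expect_true(all(accept))
  expect_gte(reject_shuffled / n_shuffled, 0.95)
})

test_that("arm pairs are detected with their abundance ratios", {
  prec <- data.frame(mirna_id = c("m5", "m3"),
                     transcript_id = "tx1",
                     win_start = c(100, 100), win_end = c(400, 400),
                     arm = c("five_prime", "three_prime"),
                     stringsAsFactors = FALSE)
  ab <- c(m5 = 1000, m3 = 800)
  pairs <- detect_arm_pairs(prec, ab)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$ratio, 0.8)
  expect_true(pairs$both_abundant)

  weak <- detect_arm_pairs(prec, c(m5 = 1000, m3 = 50))
  expect_equal(weak$ratio, 0.05)
  expect_false(weak$both_abundant)

  solo <- detect_arm_pairs(prec[1, ], ab)
  expect_equal(nrow(solo), 0)
})
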