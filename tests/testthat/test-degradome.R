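test_that("tag mapping records positions and multiplicity", {
  set.seed(61)
  core <- rand_seq(20)
  tx <- c(t1 = paste0(rand_seq(50), core, rand_seq(50)),
          t2 = paste0(rand_seq(30), core, rand_seq(70)))
  uniq <- substr(tx[["t1"]], 1, 20)
  tags <- data.frame(seq = c(uniq, core, rand_seq(20)),
                     count = c(5L, 3L, 7L))
  mp <- map_tags(tags, tx)
  expect_equal(mp$tags$m, c(1L, 2L, 0L))
  expect_equal(mp$hits$position[mp$hits$seq == uniq], 1L)
  expect_setequal(mp$hits$transcript_id[mp$hits$seq == core], c("t1", "t2"))
  # unmapped tags do not count toward the library size
  expect_equal(mp$library_size, 8)
})

test_that("TP1M normalization follows the printed formula", {
  expect_equal(normalize_tp1m(10, 2e6, 1), 5)
  expect_equal(normalize_tp1m(10, 2e6, 2), 2.5)
  expect_equal(normalize_tp1m(0, 2e6, 1), 0)
  expect_error(normalize_tp1m(10, 0, 1), "library_size")
  expect_error(normalize_tp1m(10, 100, 0), "multiplicity")
})

# one transcript whose T-plot carries signal 50/1/1 at positions 100/7/300
fixture_tplot <- function() {
  set.seed(62)
  tx <- c(t1 = rand_seq(400))
  tag_at <- function(p) substr(tx[["t1"]], p, p + 19)
  tags <- data.frame(seq = c(tag_at(100), tag_at(7), tag_at(300)),
                     count = c(50L, 1L, 1L))
  mp <- map_tags(tags, tx)
  mp$library_size <- 1e6          # scale so TP1M equals the raw count
  list(tx = tx, mp = mp, tp = build_tplot("t1", mp))
}

test_that("T-plots sum per-position signal and threshold on the mean", {
  fx <- fixture_tplot()
  tp <- fx$tp
  expect_equal(tp$signal[["100"]], 50)
  expect_equal(tp$threshold, 52 / 3, tolerance = 1e-9)

  # single tag position: threshold equals the signal
  one <- map_tags(data.frame(seq = substr(fx$tx[["t1"]], 50, 69), count = 4L),
                  fx$tx)
  tp1 <- build_tplot("t1", one)
  expect_equal(tp1$threshold, unname(tp1$signal[1]))

  # transcript without tags: empty plot, no calls possible
  tp0 <- build_tplot("t_absent", fx$mp)
  expect_length(tp0$signal, 0)
  expect_true(is.na(tp0$threshold))
  expect_null(call_cleavage(tp0, data.frame(mirna_id = "m", transcript_id = "t_absent",
                                            window_start = 10, window_end = 12,
                                            canonical_cleavage = 11)))
})

test_that("cleavage calls follow the three-category semantics", {
  fx <- fixture_tplot()
  target <- data.frame(mirna_id = "m1", transcript_id = "t1",
                       window_start = 99, window_end = 101,
                       canonical_cleavage = 100, stringsAsFactors = FALSE)
  cc <- call_cleavage(fx$tp, target)
  expect_equal(cc$category, 1L)
  expect_equal(cc$position, 100)
  expect_equal(cc$window_offset, 0)

  # a window over the weak position: signal 1 below threshold 17.33
  weak <- data.frame(mirna_id = "m1", transcript_id = "t1",
                     window_start = 6, window_end = 8,
                     canonical_cleavage = 7, stringsAsFactors = FALSE)
  c3 <- call_cleavage(fx$tp, weak)
  expect_equal(c3$category, 3L)

  # no signal anywhere in the window: no call
  none <- data.frame(mirna_id = "m1", transcript_id = "t1",
                     window_start = 200, window_end = 202,
                     canonical_cleavage = 201, stringsAsFactors = FALSE)
  expect_null(call_cleavage(fx$tp, none))

  # above threshold but not the unique maximum: category 2
  tx <- fx$tx
  tag_at <- function(p) substr(tx[["t1"]], p, p + 19)
  mp2 <- map_tags(data.frame(seq = c(tag_at(100), tag_at(300), tag_at(7)),
                             count = c(50L, 50L, 1L)), tx)
  mp2$library_size <- 1e6
  tp2 <- build_tplot("t1", mp2)
  c2 <- call_cleavage(tp2, target)
  expect_equal(c2$category, 2L)
})

test_that("counts are conserved and calls are invariant to count scaling", {
  set.seed(63)
  tx <- c(t1 = rand_seq(500), t2 = rand_seq(400))
  tags <- data.frame(seq = c(substr(tx[["t1"]], 101, 120),
                             substr(tx[["t1"]], 230, 249),
                             substr(tx[["t2"]], 51, 70)),
                     count = c(40L, 6L, 9L))
  mp <- map_tags(tags, tx)
  tp <- build_tplot("t1", mp)
  expect_equal(sum(tp$raw), sum(tags$count[1:2]))   # conservation per transcript

  target <- data.frame(mirna_id = "m", transcript_id = "t1",
                       window_start = 100, window_end = 102,
                       canonical_cleavage = 101, stringsAsFactors = FALSE)
  base_call <- call_cleavage(tp, target)

  tags10 <- tags; tags10$count <- tags10$count * 10L
  mp10 <- map_tags(tags10, tx)
  expect_equal(mp10$library_size, mp$library_size * 10)
  tp10 <- build_tplot("t1", mp10)
  expect_equal(tp10$signal, tp$signal)              # TP1M unchanged
  expect_equal(tp10$threshold, tp$threshold)
  expect_equal(call_cleavage(tp10, target), base_call)
})

test_that("planted degradome spikes at 5% are recovered as category 1", {
  set.seed(64)
  n_tx <- 200L
  ok <- 0L
  for (i in seq_len(n_tx)) {
    tx <- c(t = rand_seq(500))
    canon <- sample(100:400, 1)
    n_tags <- 200L
    n_spike <- round(0.05 * n_tags)
    st <- c(rep(canon, n_spike),
            sample(500 - 19, n_tags - n_spike, replace = TRUE))
    cf <- table(substr(rep(tx[["t"]], length(st)), st, st + 19))
    mp <- map_tags(data.frame(seq = names(cf), count = as.integer(cf)), tx)
    tp <- build_tplot("t", mp)
    target <- data.frame(mirna_id = "m", transcript_id = "t",
                         window_start = canon - 1, window_end = canon + 1,
                         canonical_cleavage = canon, stringsAsFactors = FALSE)
    cc <- call_cleavage(tp, target)
    if (!is.null(cc) && cc$category == 1L && cc$position == canon) ok <- ok + 1L
  }
  expect_gte(ok / n_tx, 0.95)
})

test_that("target summaries collapse shared sites and annotate regions", {
  ann <- list(t1 = structure(list(cds = c(101, 400), frame = 0, score = 1,
                                  coding = TRUE, length = 600),
                             class = "coding_annotation"))
  calls <- data.frame(
    mirna_id = c("miR472", "miR482a", "miR2118", "miR9999"),
    transcript_id = "t1",
    position = c(250, 250, 250, 500),
    signal = c(30, 30, 30, 12),
    category = c(1L, 1L, 1L, 2L),
    window_offset = 0L, stringsAsFactors = FALSE)
  tab <- summarize_targets(calls, ann)
  expect_equal(nrow(tab), 2)
  shared <- tab[tab$cleavage_site == 250, ]
  expect_equal(shared$mirnas, "miR2118,miR472,miR482a")
  expect_equal(shared$cleavage_region, "CDS")
  expect_equal(tab$cleavage_region[tab$cleavage_site == 500], "3' UTR")
})
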