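test_that("containment clustering groups variants and enforces two copies", {
  a21 <- rand_seq(21)
  lib <- make_library(a21, 2L)
  x <- build_clusters(list(lib))
  expect_equal(nrow(x$clusters), 1)
  expect_equal(x$clusters$abundance, 2)

  b21 <- rand_seq(21)
  lib2 <- make_library(c(a21, substr(a21, 1, 20), b21), c(5L, 3L, 4L))
  x2 <- build_clusters(list(lib2))
  expect_equal(sort(x2$clusters$abundance), c(4, 8))
  big <- x2$clusters$id[x2$clusters$abundance == 8]
  expect_setequal(x2$members$seq[x2$members$cluster == big],
                  c(a21, substr(a21, 1, 20)))
  expect_equal(x2$clusters$representative[x2$clusters$abundance == 8], a21)
  expect_equal(x2$clusters$mature_seq[x2$clusters$abundance == 8], a21)

  # a lone single-copy read forms no cluster
  x3 <- build_clusters(list(make_library(rand_seq(21), 1L)))
  expect_equal(nrow(x3$clusters), 0)
})

test_that("clustering equals the pairwise-closure oracle and is order-invariant", {
  set.seed(42)
  for (rep_i in 1:5) {
    base <- vapply(rep(24, 15), rand_seq, "")
    seqs <- unique(c(base,
                     substr(base[1:8], 1 + (rep_i %% 3), 21 + (rep_i %% 3)),
                     substr(base[1:5], 2, 21),
                     vapply(rep(21, 10), rand_seq, "")))
    counts <- sample(1:5, length(seqs), TRUE)
    x <- build_clusters(list(make_library(seqs, counts)))
    got <- lapply(split(x$members$seq, x$members$cluster), sort)
    want <- oracle_clusters(seqs, counts)
    expect_setequal(unname(lapply(got, paste, collapse = " ")),
                    unname(lapply(want, paste, collapse = " ")))
    # partition: no read in two clusters
    expect_equal(anyDuplicated(x$members$seq), 0)

    sh <- sample(length(seqs))
    x_sh <- build_clusters(list(make_library(seqs[sh], counts[sh])))
    got_sh <- lapply(split(x_sh$members$seq, x_sh$members$cluster), sort)
    expect_setequal(unname(lapply(got_sh, paste, collapse = " ")),
                    unname(lapply(got, paste, collapse = " ")))
  }
})

test_that("size profiles sum member counts by length and total the abundance", {
  a <- rand_seq(21)
  lib <- make_library(c(a, substr(a, 1, 20)), c(100L, 6L))
  x <- build_clusters(list(lib))
  p <- size_profile(x, x$clusters$id[1])
  expect_equal(p[["21"]], 100)
  expect_equal(p[["20"]], 6)
  expect_equal(sum(p), x$clusters$abundance[1])

  single <- build_clusters(list(make_library(rand_seq(22), 4L)))
  expect_equal(length(size_profile(single, single$clusters$id[1])), 1)

  set.seed(5)
  seqs <- vapply(sample(18:26, 12, TRUE), rand_seq, "")
  counts <- sample(2:9, 12, TRUE)
  xr <- build_clusters(list(make_library(seqs, counts)))
  for (id in xr$clusters$id) {
    expect_equal(sum(size_profile(xr, id)),
                 xr$clusters$abundance[xr$clusters$id == id])
  }
  expect_error(size_profile(xr, "no_such"), "empty cluster")
})

test_that("per-library size profiles split the pooled view", {
  a <- rand_seq(21)
  l1 <- make_library(c(a, substr(a, 1, 20)), c(10L, 2L), "l1")
  l2 <- make_library(a, 5L, "l2", "field")
  x <- build_clusters(list(l1, l2))
  expect_equal(size_profile(x, x$clusters$id[1], library = "l2"),
               c("21" = 5))
  expect_equal(size_profile(x, x$clusters$id[1], library = "l1"),
               c("20" = 2, "21" = 10))
})

test_that("dominance follows the profile arithmetic", {
  a <- rand_seq(22)
  mk <- function(counts_by_len) {
    # one cluster whose members are nested substrings at given lengths
    seqs <- vapply(as.integer(names(counts_by_len)),
                   function(L) substr(a, 1, L), "")
    build_clusters(list(make_library(seqs, unlist(counts_by_len))))
  }
  d1 <- dominance_test(mk(c("21" = 100L, "20" = 6L, "22" = 4L)))
  expect_equal(d1$dominant_length, 21)
  expect_equal(d1$dominance_fraction, 100 / 110, tolerance = 1e-12)
  expect_true(d1$passed)

  # a flat profile (the negative-control shape) fails
  d2 <- dominance_test(mk(c("19" = 10L, "20" = 11L, "21" = 12L, "22" = 10L)))
  expect_equal(d2$dominance_fraction, 12 / 43, tolerance = 1e-12)
  expect_false(d2$passed)
  expect_match(d2$reasons, "no_dominant_length")

  d3 <- dominance_test(mk(c("21" = 50L)))
  expect_equal(d3$dominance_fraction, 1)
  expect_true(d3$passed)

  # dominant length outside the preferred band fails even at fraction 1
  d4 <- dominance_test(mk(c("24" = 50L)))
  expect_false(d4$passed)
  expect_match(d4$reasons, "outside_preferred_band")
  d5 <- dominance_test(mk(c("24" = 50L)), preferred_band = 19:24)
  expect_true(d5$passed)

  # tie goes to the shorter length
  d6 <- dominance_test(mk(c("20" = 10L, "21" = 10L)), min_fraction = 0.4)
  expect_equal(d6$dominant_length, 20)
})

test_that("contaminant screening annotates by ungapped containment", {
  rep_seq <- rand_seq(21)
  lib <- make_library(rep_seq, 3L)
  x <- build_clusters(list(lib))
  contam <- paste0(rand_seq(30), rep_seq, rand_seq(30))
  hits <- screen_contaminants(x, list(rrna = contam))
  expect_equal(hits$cluster_id, x$clusters$id[1])
  expect_equal(hits$set, "rrna")

  expect_equal(nrow(screen_contaminants(x, list())), 0)

  mut <- rep_seq
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(mut, 10, 10))[1]
  contam1 <- paste0(rand_seq(10), mut, rand_seq(10))
  expect_equal(nrow(screen_contaminants(x, list(s = contam1),
                                        max_mismatches = 0L)), 0)
  expect_equal(nrow(screen_contaminants(x, list(s = contam1),
                                        max_mismatches = 1L)), 1)
})

test_that("candidate selection requires in vitro presence and ranks by abundance", {
  a <- rand_seq(21); b <- rand_seq(21); c21 <- rand_seq(21)
  vit <- make_library(c(a, b), c(100L, 50L), "vit", "in_vitro")
  fld <- make_library(c(a, b, c21), c(10L, 5L, 80L), "fld", "field")
  x <- build_clusters(list(vit, fld))
  d <- dominance_test(x)
  cand <- select_candidates(x, d, min_abundance = 1)
  # the field-only cluster is excluded despite its abundance
  expect_false(c21 %in% cand$representative)
  expect_equal(cand$representative, c(a, b))   # ranked by pooled abundance

  top1 <- select_candidates(x, d, n_top = 1, min_abundance = 1)
  expect_equal(top1$representative, a)
  all_of_them <- select_candidates(x, d, n_top = 100, min_abundance = 1)
  expect_equal(nrow(all_of_them), 2)

  # contaminant-annotated clusters drop out but stay in the cluster table
  ann <- data.frame(cluster_id = cand$id[1], set = "rrna")
  cand2 <- select_candidates(x, d, annotations = ann, min_abundance = 1)
  expect_equal(cand2$representative, b)
  expect_true(cand$id[1] %in% x$clusters$id)
})
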