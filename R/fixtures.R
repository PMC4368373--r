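# Access to the bundled transcriptions of published mature-miRNA tables and
# their self-verification.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "mirfree")
  if (p == "") stop("bundled fixture not found: ", name)
  p
}

#' Bundled conserved mature-miRNA catalogue
#'
#' A small transcription of published common land-plant mature miRNAs
#' (family, member, species tag, sequence) used as the default reference for
#' tests and simulations; supply a full catalogue with
#' [read_reference_catalogue()] for real analyses.
#'
#' @return data.frame with columns `family`, `member`, `species`, `seq` and
#'   the printed `length`, `mir_length`, `mn`, `mean_count` columns.
#' @export
bundled_reference <- function() {
  df <- read.delim(fixture_path("table1_conserved.tsv"),
                   stringsAsFactors = FALSE, na.strings = NULL)
  df$member[is.na(df$member)] <- ""
  df$seq <- normalize_seq(df$seq)
  df
}

#' Bundled novel-miRNA table
#'
#' Transcription of the published table of 42 novel liverwort miRNAs
#' (name, sequence, length, mean count).
#'
#' @return data.frame.
#' @export
bundled_novel_table <- function() {
  df <- read.delim(fixture_path("table2_novel.tsv"), stringsAsFactors = FALSE)
  df$seq <- normalize_seq(df$seq)
  df
}

#' Bundled cross-species homolog pairs
#'
#' The three published liverwort/green-alga sequence pairs with their Mn
#' mismatch counts.
#'
#' @return data.frame with columns `name`, `member`, `pen_seq`, `cre_seq`,
#'   `mn`.
#' @export
bundled_cross_species <- function() {
  df <- read.delim(fixture_path("table3_cross_species.tsv"),
                   stringsAsFactors = FALSE, na.strings = NULL)
  df$member[is.na(df$member)] <- ""
  df$pen_seq <- normalize_seq(df$pen_seq)
  df$cre_seq <- normalize_seq(df$cre_seq)
  df
}

#' Extract the numeric miRNA family from a miRNA name
#'
#' `pen-miR8156a`, `pen-miR8172.1` and `pen-miR8162-5p` all map to their
#' numeric family (`miR8156`, `miR8172`, `miR8162`).
#'
#' @param name character vector of miRNA names.
#' @return character vector of family labels.
#' @export
mirna_family <- function(name) {
  sub("^.*?(miR[0-9]+).*$", "\\1", name)
}

#' Verify the bundled fixtures against their published values
#'
#' Recomputes, from the bundled tables alone, the overlap-alignment mismatch
#' counts of the cross-species pairs, the family and row counts of the
#' conserved and novel tables, and two printed sequence lengths; each item
#' is reported pass/fail.
#'
#' @return data.frame with columns `item`, `expected`, `observed`, `pass`.
#' @export
verify_fixtures <- function() {
  t1 <- bundled_reference()
  t2 <- bundled_novel_table()
  t3 <- bundled_cross_species()
  items <- list()
  add <- function(item, expected, observed) {
    items[[length(items) + 1L]] <<- data.frame(
      item = item, expected = expected, observed = observed,
      pass = isTRUE(all.equal(expected, observed)), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(t3))) {
    al <- best_overlap_alignment(t3$pen_seq[i], t3$cre_seq[i])
    add(paste0("cross_species_mn_", t3$name[i], t3$member[i]),
        t3$mn[i], al$mismatches)
  }
  add("conserved_families", 11, length(unique(t1$family)))
  add("novel_rows", 42, nrow(t2))
  novel <- t2$name[mirna_family(t2$name) != "miR408"]
  add("novel_families", 34, length(unique(mirna_family(novel))))
  add("len_miR8163", 23, nchar(t2$seq[t2$name == "pen-miR8163"]))
  add("len_miR8187", 24, nchar(t2$seq[t2$name == "pen-miR8187"]))
  do.call(rbind, items)
}
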