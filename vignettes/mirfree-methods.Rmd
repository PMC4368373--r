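---
title: "Reference-free miRNA discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free miRNA discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfree)
```

## The problem

Most plant miRNA annotation starts from a genome: reads are mapped, loci are
folded, and hairpins are scored. For species without a sequenced genome —
bryophytes, liverworts, most non-model lineages — none of that machinery
applies. `mirfree` implements a discovery route that needs only sequencing
data: small RNA libraries, an assembled transcriptome, and a degradome (PARE)
library.

The route has five stages:

1. **Preprocessing.** Reads are adapter-trimmed (suffix-anchored search with
   a mismatch budget of `floor(overlap * max_error_rate)`), collapsed to
   unique sequences with counts, restricted to 18–26 nt, and filtered for a
   minimum copy number (default 2).
2. **Clustering.** Reads are grouped into *clusters*: connected components
   under the relation "one sequence is an exact ungapped substring of the
   other". A genuine miRNA produces a characteristic cluster — one dominant
   mature species plus rarer 5'/3' length variants — so a cluster is a
   candidate when a single read length carries at least half its pooled
   abundance and that length lies in the 20–21 nt band. Clusters matching a
   contaminant set (rRNA/tRNA, bacterial, fungal, algal collections) are
   annotated and excluded; candidates must also be present in at least one
   axenic (in vitro) library, because field material can carry endophytic
   fungi and algae whose small RNAs would otherwise masquerade as host miRNAs.
3. **Conserved families.** Cluster mature sequences are aligned to a
   catalogue of known mature miRNAs by ungapped overlap alignment over all
   offsets: the best alignment minimizes the mismatch count Mn in the
   overlapping region (ties: larger overlap, then smaller |offset|). A hit
   within 2 mismatches over an overlap of at least 17 nt assigns the family.
   The same statistic drives cross-species scans against foreign small RNA
   sets.
4. **Structure.** Candidates are located in transcripts and the surrounding
   window is folded. The built-in engine maximizes canonical + G:U base
   pairs (Nussinov recursion, minimum loop 3, deterministic traceback); a
   hairpin is accepted when ≥ 60% of miRNA positions pair, all partners lie
   on a single opposing arm forming a contiguous helix (partner span within
   the miRNA length + 4 bulged nucleotides), and at most 4 miRNA positions
   are unpaired. The
   star species is inferred with the 2-nt 3' overhang convention of
   Dicer-like processing.
5. **Targets and degradome.** An ungapped antiparallel scanner scores
   miRNA:transcript duplexes with the plant rule — 1 point per mismatch,
   0.5 per G:U wobble — and discards duplexes with total score ≥ 4 or a
   positions 1–12 score > 2.5. RISC slices opposite miRNA position 10, so
   each retained duplex predicts a cleavage window at transcript positions
   facing miRNA positions 9–11. Degradome tags are mapped exactly; per
   position, signal is tags-per-million divided by the tag's transcript
   multiplicity (TP1M), and the per-transcript threshold is the mean signal
   over tag-bearing positions. A window maximum above the threshold is a
   category-1 call when it is the unique transcript-wide maximum, category 2
   otherwise; sub-threshold window signal is reported as category 3.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_len`, `max_len` | 18, 26 nt | small RNA size selection |
| `min_count` | 2 | copy-number floor per library |
| `adapter_min_overlap` | 7 (sRNA), 19 (degradome) | suffix-anchored adapter search |
| `max_error_rate` | 0.1 | adapter mismatch tolerance |
| `preferred_band` | 20–21 nt | dominant length accepted for candidacy |
| `min_fraction` | 0.5 | dominance threshold |
| `max_mismatches` | 2 | family-assignment budget (Mn) |
| `min_overlap` | 17 nt | overlap floor for alignment |
| `min_abundance` | 10 | pooled copies required for candidacy |
| `paired_fraction`, `max_unpaired` | 0.6, 4 | hairpin duplex acceptance |
| `max_bulge` | 4 nt | partner-span excess allowed over the miRNA length |
| `total_max`, `seed_max` | 4, 2.5 | duplex discard thresholds |
| `precursor_flank` | 200 nt | window around a mature match |

Degradome tags shorter than 14 nt are discarded after trimming.

Three of these deserve comment.

**`min_abundance` (10 pooled copies).** Ranking clusters by abundance and
truncating to a manual-validation budget (`n_top`) is how desk validation is
organized, but precision of the emitted candidate list comes from an
expression floor: degradation fragments that duplicate by chance sit at 2–6
pooled copies, while genuinely expressed miRNAs sit orders of magnitude
higher. The floor is reported per candidate, and `n_top` remains available.

**The discard rule for duplexes.** The two discard conditions (total ≥ 4;
positions 1–12 > 2.5) can be combined as a union or a conjunction. A
conjunction would retain a duplex with 10 mismatches confined to positions
13–21, which no plant target-scoring convention accepts, so the union
(either condition discards) is the default and `combine = "both"` exposes
the conjunction for comparison. Whether G:U wobbles should contribute to
the positions 1–12 sum is a genuine modelling choice; they contribute 0.5
here, in both sums.

**Mature sequence vs representative.** A cluster's *representative* is its
longest member; its *mature sequence* is its most abundant member. The
representative can be a chance degradation fragment that happens to contain
the miRNA, so family assignment, precursor search and target scanning all
use the mature sequence — the species the dominance test actually detects —
while the representative is kept for reporting and GC content.

## The folding engine

The built-in engine is a base-pair maximization, not a thermodynamic model:
it admits A:U, G:C and G:U pairs, enforces a minimum hairpin loop of 3 nt,
and breaks ties deterministically (prefer the closing pair, then an
unpaired 5' base, then the smallest pairing partner). Two consequences:

* results are exactly reproducible and testable against brute-force
  enumeration of all nested structures (the suite verifies equality up to
  18 nt and structural invariants — involution, no crossings, loop size —
  at 60 nt);
* on long windows it over-pairs: random flanks find spurious partners that
  a free-energy model would reject. The duplex-continuity criterion in
  `validate_hairpin()` (partner span bounded by the miRNA length plus
  `max_bulge`) exists precisely to reject the scattered pairing that
  maximization produces on non-hairpin sequence; with it, shuffled-window
  negatives are rejected at ≥ 95% while construction-checked hairpins all
  validate. Scores are engine-tagged pair counts, never comparable to
  kcal/mol, and an optional `"vienna"` engine (shelling out to `RNAfold`
  when present) provides thermodynamic MFE structures behind the same
  interface.

The ORF stage is likewise a deliberate simplification of indel-tolerant
HMM-based coding-region finders: one codon-usage log-odds table (log
frequency over a uniform 1/64 background, add-one smoothing; a single
isochore), scored over every ATG-to-stop ORF in the three forward frames,
maximum score winning with longer-then-leftmost tie-breaks, and a 20-codon
floor (config-exposed; no published value exists for this cutoff).
Assembled transcripts are assumed sense-oriented, so reverse-strand ORFs
are not scanned. This is adequate for frame-intact assembled transcripts;
it does not repair frameshifts.

## What the simulator emulates

`simulation_config()` fixes the study conditions; `simulate_experiment()`
generates a transcriptome, plants hairpins and target sites, and draws
reads and tags. Defaults:

* **Libraries:** five (three in vitro, two field), depth 100,000 reads
  each, mirroring a multi-library small RNA survey with both axenic and
  environmental material.
* **Planted miRNAs:** 10 conserved-like (copies of bundled catalogue
  entries with ≤ 2 point edits) and 10 novel (random 21-mers, 5' U with
  probability 0.8 — the nucleotide bias of plant miRNAs loaded into
  AGO1). Per-miRNA abundance is log-normal (meanlog 4, sdlog 1.5 on the
  natural scale), spanning the 1–10^5 count range that real miRNA tables
  cover.
* **Read structure:** 85% of a miRNA's reads at canonical length, the rest
  1-nt 5'/3' variants cut from the hairpin; star reads at 10% of mature;
  40% of each library is degradation background — genuine transcript
  fragments of 18–26 nt, not random strings, so clustering and contaminant
  screening face realistic near-duplicates; field libraries carry 2%
  contaminant fragments.
* **Degradome:** per planted target, 200 tags of which 30% start exactly at
  the canonical cleavage position; all transcripts receive uniform
  background tags at 0.02 per position.
* **Transcripts:** 5'UTR + one ORF + a long 3' UTR. ORF codons are drawn
  from a pronounced A/T third-position bias (0.4/0.1/0.1/0.4), exclude
  internal ATGs, and an in-frame stop sits immediately upstream of the
  start — so the planted ORF is the unique maximal reading of its frame and
  "exact CDS recovery" is well-defined ground truth, while chance ORFs in
  random UTR sequence score clearly negative under the trained codon model.
* **Hairpins:** mature + 8–15 nt loop + reverse complement with ≤ 2 edits,
  re-drawn until the built-in fold validates the duplex, alternating arms.
  Target sites are perfect complements, so every planted target passes the
  duplex filter by construction and the degradome stage is tested in
  isolation from target-prediction noise.

What it does **not** emulate: sequencing errors, quality-score structure,
variable adapter truncation, isomiR tailing, multi-locus miRNA families
sharing mature sequences, or expression correlation between libraries.
Passing the end-to-end tests therefore demonstrates that the pipeline's
logic recovers a clean planted signal under realistic abundance and
background regimes — not that it is robust to platform artifacts.

In the end-to-end evaluation, star-sequence clusters count as
planted-derived (a star is a genuine hairpin product, and real surveys
routinely annotate abundant stars as miRNAs in their own right), so the
spurious-candidate fraction measures background clusters only.

## Problem sizes and determinism

All randomness is seeded: the simulator derives per-stage seeds from
`config$seed`, so identical configurations give byte-identical outputs.
The test suite runs the full default study (5 libraries × 100,000 reads,
20 planted miRNAs, 15 targets) for seeds 1–5; oracle-equivalence checks use
enumerable sizes (≤ 200 reads for clustering, ≤ 26 nt pairs for alignment,
≤ 18 nt for folding, ≤ 300 nt transcripts for target scanning); degradome
sensitivity uses 200 simulated transcripts at the 5% spike floor. These
sizes were chosen so the whole suite completes quickly on a single CPU
while still exercising every stage at full default depth.

## Known limitations

* Exact-substring clustering does not merge offset-shifted partial
  overlaps; two reads sharing 20 of 21 nt at a 1-nt shift without
  containment fall into separate clusters. This is the conservative choice
  for count attribution; offset-overlap merging would require a different
  cluster count bookkeeping.
* The trimmed-mean ambiguity in the degradome threshold ("mean of the tags
  aligned to the transcript") is resolved as the mean over tag-bearing
  positions — the strictest computable reading; a single-position T-plot can
  therefore never exceed its own threshold and yields category 3 at best.
* Family assignment reports a query under every family it hits within the
  budget; the primary hit is the lowest-Mn one. Families sharing a target
  site (the miR472/482/2118 pattern) are collapsed only in the final target
  table, not in the assignment table.
* The pipeline is single-threaded and keeps all stage outputs in memory;
  at desk scale (10^5–10^6 reads per library) this is a feature, not a
  constraint.
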