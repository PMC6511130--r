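---
title: "Primer trimming for multiplex amplicon sequencing: methods and design"
author: "amptrim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primer trimming for multiplex amplicon sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amptrim)
```

## The problem

Multiplex amplicon sequencing (MAS) amplifies hundreds to thousands of
target regions with gene-specific primer pairs in one reaction. Every read
therefore begins with a synthetic primer, and — because oligonucleotide
synthesis has an error rate of roughly one base in several hundred — those
primer bases carry errors that have nothing to do with the sample. Left in
place they inflate variant allele frequencies at primer-overlapping sites
and produce false calls. The primers must be removed before alignment, at
the scale of thousands of distinct primer sequences per panel, which rules
out the per-adapter scanning strategies of generic adapter trimmers.

A second complication is geometry. In liquid-biopsy (cfDNA) panels the
amplicon is often ~140 bp while the read is 150 bp, so the read runs
through the insert into the *reverse complement of the partner primer* at
its 3' end (the **read-through condition**). When the amplicon is longer
than the read, only the 5' primer is present (the **normal condition**).
amptrim handles both, steered by the panel's declared insert length.

## The matching procedure

The panel is a tab-delimited table of forward primer, reverse primer and
insert length. Here *insert length excludes the primers*: it is the number
of bases between the two primer 3' ends. The table format does not state
this convention anywhere, so the package fixes it and applies it
consistently in the trimmer, the simulator and the evaluator.

At start-up every 1-base-shift k-mer (default k = 8) of every primer, and
of every primer's reverse complement, is recorded in a hash table together
with its source primer and offset. k-mers containing `N` are skipped —
wildcard expansion would multiply the table for no benefit, and `N`
handling is deferred to the verification step, where a primer-side `N`
matches any read base (a read-side `N` matches nothing but a primer `N`).

Primer location at a read's 5' end then proceeds in two stages:

* **k-mers model** (seed and verify). For read offsets
  `s = 0, 1, ..., buffer_len` (default 12) the k-mer starting at `s` is
  looked up in the hash. Every hit implies a placement of its source
  primer at `read_start = s - offset`; placements that start before the
  read or run past its end are discarded, and each surviving placement is
  verified by the Hamming distance between the *whole* primer and the read
  segment it covers. The best match is the placement with the fewest
  mismatches; it is accepted iff that count is within the mismatch
  allowance (default 3). Cost ties go to the smaller panel index, so
  results are reproducible under re-ordering of equal candidates. A
  perfect (0-mismatch) hit stops the search early, which cannot change the
  result because 0 is globally minimal.

* **dynamic model** (fallback). An indel inside the primer shifts every
  downstream base, so no single placement survives whole-primer Hamming
  verification, and exact seeds near the indel are destroyed. When the
  k-mers model fails, all k-mers of the read prefix (longest primer plus
  the 12 bp buffer) are tallied per candidate primer; the candidate with
  the most hits is aligned to the prefix with a semi-global
  Needleman–Wunsch alignment — match 0, mismatch −1, gap −1, a single
  linear gap penalty — in which the primer must align end-to-end, the
  alignment is anchored at text position 0, and the text suffix is free.
  Under this scoring the score is minus the edit distance to the
  best-matching prefix, and the match is accepted iff that edit distance
  is within the same allowance. Score ties resolve to the shortest prefix.

Both 5' roles (forward and reverse primers) are searched for both mates:
read orientation varies by library kit, and restricting mate 1 to forward
primers would silently fail on half the kits.

After a 5' match, bases `[0, read_end)` are removed — leading junk in
front of a shifted placement goes with the primer, since those bases are
not insert. If the remaining read is longer than the matched amplicon's
insert length, the read-through condition applies: the reverse complement
of the partner primer is expected at position `insert_len` and is tested
at every offset within ±5 bases (the `readthrough_slack`, absorbing small
upstream indels) by Hamming distance over the overlapping portion. A
truncated 3' primer is accepted down to k overlapping bases; shorter
overlaps are statistically unverifiable and are left in place. Ties prefer
the offset closest to the expected position, then the smaller offset.
Qualities are cut exactly as sequences, so the two never diverge in
length.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `k` | 8 | bases | seed length; smaller is more sensitive, larger more specific; must not exceed the shortest primer |
| `max_mismatch` | 3 | mismatches / edits | per-primer error allowance for both models |
| `buffer_len` | 12 | bases | extra 5' offsets tried when seeding, and extra prefix searched |
| `min_qual` | 0 (off) | mean Phred | drops a read (and its mate) when the full-read mean quality is below the threshold; computed pre-trim |
| `readthrough_slack` | 5 | bases | half-width of the 3'-boundary search window |
| `keep_untrimmed` | TRUE | — | whether primer-free reads are written to the main output |

`min_qual` is defined as a *mean* quality because the filter's purpose
here is to discard globally bad reads before they can soak up mismatch
allowance; minimum- or window-based statistics answer different questions
and belong to dedicated QC trimmers.

## Quality-encoding detection

FASTQ qualities are Phred+33 or Phred+64. Any ASCII code below 59 is
illegal under Phred+64 and forces Phred+33. A sample is called Phred+64
only when every code is at least 64 *and* some code exceeds 74 (`'J'`,
the ceiling of modern Illumina Phred+33 data); a sample confined to
`'@'..'J'` is ordinary high-quality Phred+33 and is treated as such. The
pre-scan that feeds this heuristic is bounded (first 1000–10000 records):
the 5' search window is sized by the longest primer plus the buffer, so an
exact global maximum read length is never required.

## The simulator

The bundled generator produces the study conditions used by the test
suite and the acceptance script, with every random choice under one seed:

* a panel of 50 amplicons with 18–25 bp uniform-random primers. A
  candidate primer is redrawn whenever its offset-0 Hamming distance to
  any already-accepted primer, or to an accepted primer's reverse
  complement, is ≤ 10 (twice the largest allowance exercised), so no read
  within allowance of its true primer can also be within allowance of a
  wrong one — ground truth is unambiguous by construction;
* 80–100 bp uniform-random inserts on 150 bp reads. This mirrors
  cfDNA-style short amplicons (insert plus two ~20 bp primers ≈ 120–150
  bp), and it deliberately keeps the 3' partner primer fully inside the
  read: boundary geometries with 1..k−1 overlapping 3' primer bases are
  untrimmable by design, and mixing them in would conflate a geometric
  artefact with matching errors;
* 100 read pairs per amplicon ("100× depth"), plus 10% primer-free
  uniform-random reads as true negatives;
* exactly `errors_in_primer` substitutions placed uniformly in the 5'
  primer copy of every read (with probability `indel_prob`, one of them
  becomes a 1 bp insertion or deletion). The insert and the 3'
  partner-primer occurrence are error-free, so sensitivity and accuracy
  isolate the 5' seeding/verification path under test;
* uniform Q30 qualities — the quality filter is exercised separately with
  crafted records, not through the generator.

What the simulator does **not** emulate: platform-specific error profiles
(quality-correlated miscalls, homopolymer indels), errors in the insert,
real panel sequence composition, or adapter dimers. A perfect score on
simulated data therefore demonstrates the correctness of the matching and
trimming logic under controlled error loads, not performance on any
particular instrument's artefacts.

## Evaluation metrics

Scored against the simulator's truth table, over reads (not pairs):

* **TPR** — fraction of primer-bearing reads with at least one base
  removed;
* **TNR** — fraction of primer-free reads left byte-identical;
* **ACC** — fraction of primer-bearing reads whose output equals the true
  insert exactly (truncated at the read end for normal-condition reads).

ACC ≤ TPR always. A metric whose class is empty is reported `NA`, never
0, so an all-negative run cannot masquerade as "zero sensitivity".

## An intrinsic sensitivity ceiling under fixed error counts

Placing exactly *e* substitutions uniformly in a primer of length *L* can
destroy every intact k-mer window: both models need at least one exact
k-mer hit to consider a candidate at all, so such reads are unfindable by
a hash-seeded method regardless of the allowance. Exhaustive enumeration
over the `choose(L, e)` placements gives the probability of losing every
clean window with k = 8:

```{r ceiling, eval = FALSE}
k <- 8
p_no_clean_window <- function(L, e) {
  placements <- combn(L, e)
  dead <- 0
  for (j in seq_len(ncol(placements))) {
    err <- placements[, j]
    clean <- any(vapply(0:(L - k), function(s)
      !any(err > s & err <= s + k), logical(1)))
    if (!clean) dead <- dead + 1
  }
  dead / ncol(placements)
}
sapply(18:25, p_no_clean_window, e = 2)  # 0.137 (L=18) ... 0 (L>=24)
```

Averaged over 18–25 bp primers this is ≈ 4% at e = 2 and rises steeply
(≈ 19% at e = 3, ≈ 58% at e = 5). In practice the panel separation guard
shifts accepted primers toward the long end of the range, which softens
the realized rate, but the ceiling is structural: under
matched-error-count benchmarks the sensitivity at high error loads is
bounded well below 100% for any seed-and-verify matcher with these seed
and primer lengths. The degradation-curve test documents this measured
behaviour rather than hiding it; runs whose error process produces *at
most* a couple of errors per primer (as real synthesis error rates do)
sit far from the ceiling.

## Numerical and degenerate-input choices

* Needleman–Wunsch tie-breaks go to the smallest text end. When a
  substitution sits exactly on the primer's terminal base, a gap and a
  mismatch tie, and the boundary lands one base short; this affects only
  dynamic-model reads and is accepted for the sake of determinism.
* An insertion at the primer's very first position leaves the intact
  primer one base downstream, where the k-mers model finds it with cost 0
  and removes the junk base together with the primer — the correct
  output, reached without the fallback.
* Empty inputs produce empty outputs plus a warning, not an error;
  truncated FASTQ records and sequence/quality length mismatches are
  format errors naming the record ordinal.
* Trimming is deterministic end to end: byte-identical inputs give
  byte-identical outputs, and category counts in the stats file reconcile
  exactly with the records written.
* Problem sizes in the shipped tests: oracle comparisons use 500 random
  alignment pairs (≤ 10 bp) and 1000 Hamming pairs; the benchmark tests
  run one 50-amplicon 100×-depth dataset per condition (≈ 11,000 reads
  each) — sizes chosen so the full suite exercises every path at the
  study conditions while remaining routine to run.

## Known limitations

* Only `N` degeneracy is supported; full IUPAC codes in panels are
  rejected at parse time.
* The dynamic model verifies only the top-ranked candidate; a wrong
  candidate with more chance k-mer hits than the true primer (vanishingly
  rare with well-separated panels, less rare with heavily overlapping
  ones) is rejected by the alignment and the read stays untrimmed rather
  than being re-tried against the runner-up.
* Gap scoring is linear; affine gaps, banded DP and bit-parallel
  alignment are out of scope, as are BAM soft-clip trimming and generic
  3' adapter removal.
* The streaming reader holds one chunk (2000 records) in memory; record
  order is preserved and pair synchronization is enforced by chunk-level
  count checks, but interleaved FASTQ is not supported.
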