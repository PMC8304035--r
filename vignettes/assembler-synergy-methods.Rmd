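---
title: "Methods: baseline-anchored assembly scoring and assembler synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline-anchored assembly scoring and assembler synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmsynergy)
```

## Scope and model

`asmsynergy` quantifies how much a de novo transcriptome reconstruction
gains from combining the outputs of several assemblers. It does not run
assemblers, aligners or ortholog searches; it takes candidate assemblies
(FASTA), reads (FASTQ) and a marker set, and owns everything downstream:
consensus construction, quality metrics, baseline-anchored normalization,
and exhaustive combination ranking with significance tests. Parsers for
real BUSCO short summaries and aligner log lines let real-tool outputs
stand in for the built-in proxy metrics wherever they are available; the
two providers fill the identical metric-record contract, so the scoring
and synergy machinery is indifferent to the source.

## Consensus construction

A combination's assembly is `merge -> length filter -> redundancy
reduction`:

* **merge** concatenates member contigs, prefixing ids with the source
  label;
* **length filter** drops contigs under `min_contig_length` (default
  **200 bp**, the common convention for discarding uninformative transcript
  fragments);
* **redundancy reduction** is greedy incremental clustering in
  length-descending order (ties by id so runs are reproducible): a contig
  is discarded when its identity over its own length against an
  already-retained, not-shorter representative reaches `identity_threshold`
  (default **0.95**). Candidate representatives are shortlisted by a shared
  exact word of `word_size` (default **11 bp**) on either strand
  (reverse-complement matching defaults on, as transcripts from unstranded
  libraries arrive in either orientation).

Identity is estimated as the matched-base count of the best *ungapped*
diagonal (diagonals proposed by the shared words), or exact substring
containment, divided by the query length — query-side semantics as in
greedy clustering tools. Skipping gapped dynamic programming is a speed
choice; the tests compare the estimate against an exact all-diagonal oracle
and verify it can only under-estimate, never over-estimate, so clustering
errs toward retaining contigs. A contig sharing no word with any longer
contig is always retained. Because processing order is a deterministic
sort, the retained sequence multiset is invariant to the order in which
assemblies are supplied, and the pipeline is idempotent on its own output.

Read-based contig scoring and chimera detection are deliberately out of
scope: consensus here is merge + filter + dedupe only.

## Assessment metrics

Three raw metrics per candidate per dataset:

* **Read representation** (alignment-rate stand-in): percentage of reads
  with at least `hit_frac` (default **0.80**) of their canonical k-mers
  (default **k = 31**, odd so no k-mer is its own reverse complement)
  present in the assembly's canonical k-mer set. Exact k-mer membership is
  deterministic, strand-agnostic and superset-monotone: adding contigs can
  only add k-mers. Reads shorter than k are skipped and tallied.
* **Marker recovery** (completeness stand-in): for each marker, the best
  single-contig coverage is the longest exact common substring with any
  contig (either strand; computed with a suffix automaton, exact and
  linear in contig length) divided by marker length. Coverage ≥
  `complete_frac` (default **0.95**) is *complete*, ≥ `fragment_frac`
  (default **0.30**) is *fragmented*, else *missing*; markers complete in
  two or more contigs are also *duplicated*. The three exclusive
  categories always sum to the marker-set size. The thresholds are
  package defaults, configurable; true profile-HMM ortholog scoring uses
  model-specific score cutoffs that cannot be reproduced without the HMMs,
  which is why exact substring coverage was chosen — it has an independent
  brute-force oracle.
* **Contiguity**: N50 and N90 — traversing contigs longest-first, the
  length of the first contig at which cumulative bases reach 50% / 90% of
  the total. Ties are consumed in input order and the returned value is
  always an actual contig length (no interpolation), the standard
  convention.

## Baseline-anchored normalization and the AAS

Within one dataset's comparison set (all candidates scored together,
including every combination tier, so all share one zero point), each
metric is normalized against the baseline candidate's raw score:
equal-to-baseline maps to 0, scores above the baseline map linearly onto
(0, +0.5] with the set maximum at +0.5, and scores below map linearly onto
[−0.5, 0) with the set minimum at −0.5. This piecewise-linear map is the
unique one satisfying the three anchors (baseline 0, best +0.5, worst
−0.5); the alternative raw forms `AS_X / AS_MAX × 0.5` and
`(AS_X − AS_MIN) × 0.5` do not respect those anchors and are kept only
behind `mode = "literal"` for comparison. Normalization is affine-invariant
per metric, so unit changes in a raw metric never move a score.

The **AAS** is the 1:1:1 average of the alignment score, the completeness
score and the contiguity component, where n50 and n90 are normalized
separately and pre-averaged so contiguity carries the same weight as each
other axis while each component stays inside [−0.5, +0.5]. Completeness
enters as the complete-marker *count*; since normalization is
affine-invariant, feeding percentages instead would change nothing but
axis labels. Normalize-then-average is used rather than average-then-
normalize because the raw metrics have incommensurate units (percent,
counts, base pairs); averaging raw values would be meaningless.

Per-candidate AAS values are averaged across datasets under a strict
complete-design rule — a candidate missing from any dataset is an error,
never imputed.

## Combination enumeration and tier tests

All subsets of 1..3 assemblers are enumerated (9 assemblers give
9 + 36 + 84 = 129), each evaluated as its consensus assembly — a singleton
combination also passes the length filter and redundancy reduction so
tiers are comparable. Rows are ranked by mean AAS descending, ties broken
by label for deterministic reports.

Per assembler group, single-vs-bi and bi-vs-tri differences are tested
with a two-tailed paired t-test. The pairing unit is the per-dataset
group-mean AAS (datasets are the replicates); pairing on combinations
instead is possible but conflates within-dataset correlation, so datasets
were chosen. All raw p-values are adjusted with the Benjamini–Hochberg
step-up (the standard FDR control when no specific method is mandated),
and stars are assigned at 0.05 / 0.001 / 0.00001 on the adjusted values.
Degenerate groups (zero-variance, nonzero-mean differences) report the
machine-minimum p with a `degenerate` flag instead of aborting a full run;
all-zero differences report t = 0, p = 1.

## Adaptive k-mer planning

For de Bruijn graph assemblers that accept several k values, the plan is
`{21, Q1, Q2, Q3, k_max}`: a fixed minimum of 21, the top as the largest
odd integer ≤ read length − 1 (every read then contains at least two
k-mers) bounded by any assembler-specific cap (MEGAHIT 255), and the three
interior quartile points rounded to the nearest odd integer with ties
upward (odd k avoids palindromic k-mers; the tie direction is fixed for
determinism). Duplicates after rounding collapse, so plans hold at most
five values and exactly five once the span reaches 8. The read statistic
driving the top is the maximum *read* length; for paired-end data the
fragment ("insert") length is a defensible alternative, but k larger than
a read is unusable by the assembler, and the common 100 bp read case then
tops out at 99 exactly as MEGAHIT's stock ladder does — hence this
reading. Assemblers that take a single k (BinPacker 25, Shannon Cpp 25,
TransLig 31, Trinity 25) keep their published defaults.

## Synthetic data: what it does and does not emulate

The generator produces uniform-random truth transcripts (default 250–1200
bp), degrades them per assembler profile — a *sensitivity* fraction
reconstructed (deterministic seeded subsample, so counts are exact rather
than binomial), a *fragmentation* fraction split in two at a random point
≥ 100 bp from the ends, a *redundancy* fraction duplicated verbatim — and
samples error-free fixed-quality reads at position-uniform starts on
random strands, plus markers as substrings of distinct truth transcripts.
Everything is a pure function of its arguments and seed; no global RNG
state is touched.

This emulates the failure modes that drive the scoring machinery
(incompleteness, fragmentation, duplication) while deliberately omitting
sequencing error, coverage bias, isoform structure and polymorphism.
Error-free data is what makes the exact-match proxies analytically
predictable (a truth assembly scores alignment 100.0 and full
completeness by construction), so green tests certify the scoring,
ranking and testing machinery — not robustness of the proxies to noisy
real reads, for which the real-tool parsers exist.

Default fixture sizes used throughout the tests (tens of transcripts,
hundreds of reads, 8–20 markers, 3–4 assemblers, 1–2 datasets) keep a
full combination evaluation in the tens of seconds on a single CPU while
leaving every code path non-trivially exercised; they are fixture-scale
choices, not statements about real study sizes.

## Numerical and degenerate-input conventions

* Sequences are stored uppercase; `N` is the only ambiguity code kept
  (others map to `N` with a warning) — one symbol never matching anything
  keeps k-mer and substring logic simple.
* `nx_length` of an empty assembly, an empty merge list, an
  all-filtered consensus (the error names the threshold), a baseline
  absent from a comparison set, and ragged cross-dataset designs are all
  errors, not silent results.
* Normalization outside `[AS_MIN, AS_MAX]` is a context-violation error;
  the branch denominators cannot degenerate because the equal-to-baseline
  case is handled first.
* TSV output rounds floats to 4 decimals (2 for raw metric records);
  writes are temp-then-rename so a crashed run never leaves a truncated
  file under its final name.

## Known limitations

Identity estimation is ungapped, so highly similar contigs differing by an
indel may both be retained (conservative direction). Marker coverage uses
exact substrings, so a single mismatch inside an otherwise complete marker
caps its coverage at the longest exact piece — real-data completeness
should come from the BUSCO parser instead. Tier t-tests need at least two
datasets; with one dataset the report carries an empty test table. The
combination cap defaults to 3 but is configurable; runtime grows with
C(n, 3) evaluations of the consensus pipeline.
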