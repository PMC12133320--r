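---
title: "mpraqc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mpraqc: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpraqc)
```

This vignette is the package's own account of what it computes and why:
the assumptions behind each stage, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and
the numerical corner cases. The README shows a worked run; here we
explain the machinery.

## The experiment being modelled

A massively parallel reporter assay couples each designed candidate
regulatory sequence (an *oligo*, typically 100–200 nt) to many random
DNA *barcodes* placed in the transcribed part of a reporter construct.
Three sequencing stages read the experiment out:

* **association mapping** — fragments carrying oligo and barcode
  together, sequenced paired-end, establish the barcode→oligo
  correspondence;
* **plasmid (DNA) counting** — barcode abundance in the plasmid pool
  actually delivered to cells;
* **RNA (cDNA) counting** — barcode abundance in reporter transcripts,
  per replicate.

The estimand for oligo $i$ with usable barcode set $B(i)$ is

$$\mathrm{activity}_i \;=\;
  \frac{\sum_{b \in B(i)} \mathrm{RNA\ CPM}(b)}
       {\sum_{b \in B(i)} \mathrm{DNA\ CPM}(b)},$$

the transcript output per plasmid copy, normalized so that the
library-average oligo sits near 1.

## Stage 1: association mapping

**Merging.** Read pairs are merged by overlap consensus: the reverse
read is reverse-complemented and every overlap length
$o \ge$ `min_overlap` (default 10 nt) is scored by its mismatch
fraction; the smallest fraction wins, ties going to the longest
overlap, and the merge is rejected if the best fraction exceeds
`max_mismatch_frac` (default 0.1). Disagreements within the overlap
resolve to the base with the higher Phred score, ties to the forward
read. This is the standard internal-merger behavior of paired-end
tools; pipelines that prefer an external merger can feed its
extended-fragment FASTQ through `load_premerged()` instead — the two
routes are interchangeable downstream.

**Extraction.** The barcode is located from the configured fragment end
(`read_structure()`): with a constant flank, by exact flank match; with
no flank, positionally as the terminal `barcode_len` bases. One subtlety
matters at scale: a 6-nt flank occurs by chance inside a random 12-nt
barcode in roughly 0.2% of barcodes, so the search only considers flank
occurrences that leave at least `barcode_len` bases for the barcode and
takes the one nearest the configured end. Without that admissibility
rule those barcodes would be systematically unrecoverable. Barcodes
containing `N` are discarded at extraction (they would otherwise
inflate the barcode inventory with phantom neighbours); failures are
counted by category (`no_flank`, `short`, `N_in_barcode`).

**Matching and assignment.** Inserts are matched to the designed
library by exact hash lookup; optionally (`max_mismatches` > 0) a
unique equal-length Hamming neighbour is accepted, with ties rejected.
Matching is deliberately not indel-tolerant: MPRA designs are
fixed-length and substitution errors dominate Illumina data. Each
barcode is then assigned its modal oligo when two filters pass:

* `min_support` (default 3) — at least this many reads agree on the
  modal oligo; protects against barcodes fabricated by sequencing
  errors, which rarely recur identically;
* `purity_threshold` (default 0.75) — the modal oligo owns at least
  this fraction of the barcode's reads; protects against barcode
  collisions and PCR chimeras. A tie at the mode is always dropped:
  the ambiguity is unresolvable by thresholds.

These conservative defaults suit typical designs where each true
barcode collects tens of association reads; all three are exposed in
the configuration and CLI.

The stage's complexity metric is the number of unique barcodes per
oligo: too few (a handful) makes the activity estimate noisy; too many
(many hundreds) means each barcode will be thinly covered in the
counting stages. The default "qualified oligo" criterion — at least 5
barcodes (`min_barcodes_qualified`) — is a placeholder to calibrate
per design.

## Stages 2–3: DNA and RNA counting

Both counting stages are the same computation on different inputs, so
they share one code path parameterized by role. Only the
barcode-bearing mate of a paired counting run is read. Because
counting reads may present the barcode in the opposite orientation
from the association fragments, `read_structure()` carries an explicit
`barcode_revcomp` flag; making orientation explicit configuration
prevents the silent all-barcodes-unmapped failure mode.

Reads whose barcode is absent from the association map are counted and
reported (`frac_reads_unmapped`) but excluded from coverage and
activity: without an assignment they are uninterpretable.

**Coverage.** The stage reports the fraction of mapped barcodes
detected, the fraction of oligos with ≥1 detected barcode, the mean
detection count, and the detection-count histogram (emitted raw; the
report figure uses a log axis, since barcode abundances are
approximately lognormal and a linear axis hides the low tail).

**Saturation.** To ask "would deeper sequencing help?", the counted
read multiset is subsampled *without replacement* (multivariate
hypergeometric) at fractions 0.1…1.0 (default), `n_resamples = 20`
draws per fraction, and coverage recomputed. Sampling without
replacement models re-sequencing the same molecular pool shallower,
which is the question actually being asked; with-replacement sampling
would overstate losses at high fractions. Fraction 1.0 is reported
from the full table verbatim, so the curve's endpoint is exact. The
resampler is seeded (default 17) and restores the caller's RNG state.

## Stage 4: activity

Counts are normalized to CPM over mapped barcodes only, so the
activity ratio is invariant to sequencing depth on both sides — any
global scaling of raw counts cancels exactly (this is a tested
invariant).

Two modelling decisions deserve explanation:

* **Ratio of sums, not mean of ratios.** Summing CPM before dividing
  weights each barcode by its plasmid abundance. A mean of per-barcode
  ratios gives equal weight to poorly covered barcodes, whose ratios
  are noisiest; the two estimators genuinely differ and the choice is
  stated here because users of either convention exist.
* **Zero-RNA barcodes count.** A barcode present in DNA but absent
  from RNA is evidence of low activity, not missing data; it
  contributes 0 to the numerator by default. The literature contains
  both conventions, so `include_missing_rna = FALSE` switches to
  dropping such barcodes. Barcodes with no DNA evidence are always
  unusable — their ratio is undefined.

Filters: `min_dna_count` (CPM; default 0, i.e. presence in the DNA
sample suffices) and `min_barcodes` (default 1). Dropped oligos are
written to a table with their reason rather than silently vanishing.

The stage's QC metric is the Pearson correlation between log2 DNA and
log2 RNA CPM across shared barcodes (pseudocount 1 CPM avoids log 0;
a zero-variance sample reports r = 0 with a flag instead of NaN). When
activities vary across the library, RNA abundance decouples from
plasmid abundance; an *excessively high* correlation (default alarm:
r > 0.8, risk direction "above") indicates plasmid DNA survived into
the RNA prep and is contaminating the numerator.

## Stage 5 and export

Replicate concordance is Pearson and Spearman correlation of
log2 activity over oligos shared by each pair, with non-finite values
(zero-RNA oligos) excluded pairwise and pairs sharing fewer than 3
oligos reported as missing. No imputation is attempted.

The export writes wide DNA/RNA count matrices (rows = oligos with ≥1
mapped barcode, columns = replicate × barcode-slot) plus a column
annotation. Slots are assigned lexicographically by barcode within each
oligo, identically across assays and replicates, so a column refers to
the same physical barcode everywhere. Raw counts are exported —
downstream tools normalize themselves — and undetected barcodes are
written as 0 by default (`na_missing = TRUE` writes NA instead; the
default treats them as observed zeros, consistent with the activity
stage). The column naming `<replicate>_bc<slot>` is this package's
convention and is documented in the annotation file.

## QC framework

Every metric is evaluated against a closed-interval reference range
with a declared risk direction; boundary values pass. Ranges ship as an
editable YAML file (`system.file("extdata", "qc_ranges.yaml")`) whose
defaults are deliberately labelled placeholders — they are sanity
bounds, **not** percentiles of any curated MPRA dataset collection, and
every report says so. Labs should recalibrate them on their own
historical runs. Risks are advisories: they attach a recommendation and
never fail a run, because the correct intervention is experimental, not
computational.

Reports are deterministic (no timestamps in the TSV twin), so repeated
runs on identical inputs are byte-identical — a property the test
suite enforces and that makes reports diffable across reruns.

## The synthetic generator

`simulate_truth()` + `emit_*` produce the three sequencing stages with
known ground truth. The generative model:

* oligos: unique uniform-random sequences (`n_oligos = 200`,
  `oligo_len = 100` nt by default);
* barcodes per oligo: Poisson(`mean_barcodes_per_oligo = 15`), floored
  at 1, globally unique (a hard error if the barcode space is not at
  least 10× the demand);
* barcode abundance: lognormal with `abundance_log2_sd = 0.5` log2
  units, normalized — the skew cloning bottlenecks produce;
* true activity: lognormal with `activity_log2_sd = 1` log2 unit, a
  typical enhancer-screen dynamic range;
* association fragments: `oligo + GCTAGC linker + barcode`, cut into
  75-nt paired reads (`reads_step1 = 2e5` pairs);
* counting reads: `linker + barcode`, DNA drawn ∝ abundance, RNA drawn
  ∝ abundance × activity (renormalized), `5e5` reads per replicate,
  each replicate an independent multinomial draw;
* errors: substitutions only, uniform at `error_rate = 0.001`/base,
  with constant Phred strings consistent with that rate.

These defaults are the study conditions under which the package's
recovery guarantees are stated (the acceptance checks run at exactly
these sizes; the smoke tests scale `n_oligos` and read counts down for
speed). Determinism: every emission derives a sub-seed from the master
seed (offset 1 for the association run, 100 + replicate for DNA,
200 + replicate for RNA), so artifacts are byte-reproducible.

What the generator does **not** emulate — and what passing tests on it
therefore cannot certify about real data: indels and
quality-dependent error profiles (matching is substitution-only by
design), PCR jackpotting and duplicate structure, UMI behavior, batch
effects between replicates beyond multinomial resampling, cross-sample
index hopping, and barcode sequencing-error correction (near-duplicate
barcodes remain distinct; at Illumina error rates and `min_support = 3`
the error-barcode inventory is almost entirely filtered, but a cluster
of reads sharing one error can in principle survive).

## Numerical choices and degenerate inputs

* Purity ties always drop the barcode regardless of thresholds.
* Hamming matching considers only equal-length library sequences, and
  duplicated library sequences make their exact hits ambiguous (NA).
* `log2(0)` activities are written as `-Inf` in tables and excluded
  pairwise from replicate correlations.
* Correlations over < 3 shared items are errors (DNA–RNA) or missing
  cells (replicates), never silently computed.
* Empty fragment streams yield a valid empty map with zeroed counters;
  an empty map is a hard error for every downstream stage, naming the
  mapping step as the missing prerequisite.
* Gzip is detected from file content, not extension; FASTQ is streamed
  in bounded chunks, and a truncated trailing record is a hard error
  naming the record index.
* TSV artifacts are written in sorted, deterministic order so reruns
  are byte-comparable.

## Problem sizes

The test suite exercises the full default study conditions (200
oligos, ~3000 barcodes, 2×10⁵ association pairs, 5×10⁵ counting reads
per sample, three seeds for the recovery check) in well under two
minutes on a single core; the end-to-end smoke tests use scaled-down
configurations (20–50 oligos, 10³–10⁴ reads) where only plumbing, not
statistical power, is at stake.

## Known limitations

Single-threaded by design (the per-read inner loops are compiled, and
the default problem sizes do not warrant parallelism). No UMI support.
No indel-tolerant matching — libraries synthesized with appreciable
deletion rates will lose those molecules at the exact-match step and
show it in `frac_reads_matched`. Reference ranges are placeholders
until locally calibrated. The DNA–RNA correlation alarm assumes
activities genuinely vary; a library of near-identical activities will
legitimately show high correlation without contamination.
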