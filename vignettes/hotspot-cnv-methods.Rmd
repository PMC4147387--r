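---
title: "Rare CNV discovery on hotspot arrays: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare CNV discovery on hotspot arrays: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotCNV)
```

## The problem

Carriers of an *FMR1* premutation (55–200 CGG repeats) show strikingly
variable neurological and neurodevelopmental involvement. One hypothesis is
a "second genetic hit": a rare copy-number variant (CNV) on top of the
premutation that exacerbates the phenotype. Testing it in a small clinical
cohort needs a pipeline that (i) calls CNVs from hotspot-targeted array-CGH
intensities, (ii) separates rare events from common polymorphisms using a
large control database, and (iii) computes carrier-rate statistics across
clinical subgroups. hotspotCNV implements that pipeline end to end, with a
synthetic-data generator that stands in for the unavailable raw arrays, and
a replay mode that re-derives every summary number from the published CNV
table of a 56-carrier premutation cohort.

## The calling model

**Array design.** The simulated array mirrors a segmental-duplication
hotspot design: ~251 Kb hotspot regions flanked by segmental-duplication
blocks, probed at ~2.6 Kb spacing, on a genomic backbone probed at ~36 Kb.
Hotspots are where recurrent rearrangements concentrate, because the
flanking duplications sponsor unequal crossover.

**z-scores.** Per-probe log2 ratios are standardized per chromosome:
$z = (x - \bar{x}_c)/\sigma_c$ with the population (divide-by-$n$) SD. The
population convention is fixed and documented; at array scale the difference
from the sample SD is immaterial, and a dedicated test pins the two-point
case ($\{-1, 1\} \mapsto \{-1, 1\}$). A zero-SD chromosome (constant track)
degenerates to all-zero z-scores rather than dividing by zero.

**Segmentation.** A three-state hidden Markov model (loss / neutral / gain)
with Gaussian emissions at means $(-\mu, 0, +\mu)$, shared SD 1, decodes the
z-score track by Viterbi, independently per chromosome. The separation
$\mu = 2$ encodes a 2-SD Gaussian model of altered copy number. The
remaining knobs are this package's choices, each exposed in
`hmm_params()`:

* `tau = 1e-4` per-probe switch probability — at 2.6 Kb hotspot spacing this
  prices a breakpoint at roughly one per 26 Mb of neutral track, strongly
  discouraging single-probe calls while leaving 10-probe events cheap to
  enter;
* initial distribution `neutral = 1 - 1e-3`;
* Viterbi rather than posterior decoding — the smallest model consistent
  with maximum-probability segment output; ties in the backtrace resolve
  toward neutral, so decoding is deterministic and conservative.

Decoding is in log space throughout; a 10^5-probe track keeps finite
log-probabilities (tested). On every chromosome of ≤ 8 probes the decoder is
verified against exhaustive enumeration of all $3^n$ paths.

**Boundaries.** The published method never defines call boundaries, so the
package uses the standard midpoint convention: a run of probes $i..j$ spans
from the midpoint between probe $i$ and its left neighbour to the midpoint
between probe $j$ and its right neighbour; a run touching the chromosome
edge uses the edge probe's position itself (right edge: position + 1, so the
half-open interval stays valid). Noiseless events land within one
inter-probe gap of truth.

## The filter cascade

Raw calls are refined by four rules, a call being discarded when

* |mean segment z| < 1.5,
* probe support < 10,
* segmental-duplication overlap of its bases > 50% (union-merged before
  measuring), or
* length < 50 Kb.

Removal is by strict inequality — a literal reading of the published
thresholds — so boundary calls (exactly 10 probes, exactly 50 Kb, exactly
50% overlap, |z| exactly 1.5) are retained, and the tests assert those sharp
semantics. The rules are evaluated independently for every call and the full
flag vector is returned: nothing is silently dropped, and the retained set
is exactly the conjunction of the four flags. Filters operate on unmerged
HMM segments (whether the original study merged adjacent segments first is
unstated; this choice is fixed and documented).

## Rarity and burden

A retained call is compared against a control database (default 8,328
controls) by **reciprocal overlap**: `min(|a∩b|/|a|, |a∩b|/|b|)`. Control
events matching at > 50% reciprocal overlap — state-matched by default
(dup vs dup, del vs del; a flag disables this, since the original text does
not say) — contribute their carrier counts, and the call is **rare** when
the matched frequency is strictly below 0.1%. With 8,328 controls the
rare/common boundary sits between 8 and 9 carriers
(8/8328 ≈ 0.00096 < 0.001 ≤ 9/8328), asserted exactly in the tests.

The **burden test** tabulates events above vs at/below a size threshold
(default 325 Kb) in cases vs controls and applies Fisher's exact test —
chosen over chi-square because event counts can be small; the source names
neither test. The burden unit is the event, not the sample (a per-sample
rate can be derived from the verdicts table). A label-permutation p-value is
available as a cross-check: under permutation of case/control labels with
margins fixed, the case count of large events is hypergeometric, and
extremeness is measured by table probability — the same ordering Fisher's
two-sided p sums — so the permutation p converges to the Fisher p.

## Cohort association

Carriers (participants with ≥ 1 rare CNV, counted once) are joined to the
phenotype sheet. The report computes carrier rates per group with
one-decimal half-up percent formatting (the convention of clinical tables),
the standard contrasts (neurological involvement: groups 3+4 vs 1+2; within
neurological: ASD vs not; ASD overall), a closed-form 2×2 chi-square, and
Fisher's exact p for each contrast. The chi-square defaults to no continuity
correction, and both the Yates-corrected and Fisher variants are emitted
alongside, because the source's printed p-values for these contrasts cannot
be regenerated from its printed counts by any of the three — the
discrepancy is reported, not hidden. The exact McNemar test (two-sided
binomial on discordant counts) is implemented generically; the replay does
not apply it because the source's pairing for what is structurally an
unpaired comparison is undefined. Welch's t (via `stats::t.test`) serves the
CGG and psychometric score comparisons; in replay mode, scores and
non-carrier CGG sizes are unpublished, so those comparisons run only on
synthetic cohorts.

## The synthetic-data generator

The generator emulates exactly the statistical structure the calling model
assumes:

* per-probe log2 ratios i.i.d. Gaussian around the copy-number effect —
  heterozygous deletion −1.0 (= log2(1/2)), single-copy duplication +0.58
  (= log2(3/2)) — with noise SD 0.15; no wave, GC, or batch artifacts, which
  matches the per-chromosome Gaussian assumption of the z-score model but
  understates real-array structure;
* a control database with common polymorphic loci at configurable
  frequencies (default two loci at 5%) plus rare background events;
* a 19/20/9/8 four-group cohort (mostly male, a few female carriers) with
  premutation CGG alleles uniform in 55–200, plus synthetic ADOS/FSIQ/SCQ
  scores for exercising the score comparisons. The per-group probability of
  carrying one injected rare CNV defaults to 0.2 — the source does not state
  an injection rate; 0.2 is the scale of the cohort's observed 19.6% carrier
  fraction and was fixed once.

Two scales exist: the default **desk** genome (2 chromosomes, 20 Mb, 16
hotspots, ~2,000 probes) keeps full pipeline runs at seconds, and a **full**
scale approximates the 107-hotspot array. All generators are pure functions
of (config, seed).

Because the noise model is idealized, passing tests demonstrate correctness
of the *algorithms* under the model's own assumptions — they do not certify
sensitivity on real arrays with wave artifacts, dye bias, or male-X
baseline shifts (X is simulated with a diploid-like baseline; the original
study called male-X events without describing its normalization).

## Replay conventions

Printed table coordinates are ingested verbatim as half-open (start, end):
`end − start` then reproduces every printed size cell, which settles the
otherwise unstated 0/1-based question empirically. Size labels floor
(182,706 bp → "182 Kb"; ≥ 1 Mb: floor to two decimals, 1,672,881 → "1.67
Mb") — flooring matches all 12 printed cells where rounding would not. Two
internal inconsistencies of the source are carried as explicit notes in the
replay report rather than patched: the 2q21.3 deletion printed as 347 Kb in
the text but 374 Kb (from its own coordinates) in the table, and a narrative
size range starting at 175 Kb although the table's smallest event is 160 Kb.
The table is authoritative in both cases, as it is for group membership
(case 1's narrative group label conflicts with the table's).

## Numerical choices and degenerate inputs

* Coordinates are doubles (exact integer arithmetic below 2^53), avoiding
  32-bit overflow in products of genome positions.
* Empty tracks decode to no calls; an all-zero z track is all-neutral
  because the initial distribution favours neutral.
* A degenerate burden table (an empty size class) returns p = 1 with a
  `degenerate` flag instead of erroring.
* A 2×2 chi-square with a zero margin errors and points to Fisher's exact
  test, which the report computes anyway.
* Seeds: every generator takes an explicit seed; the pipeline derives
  per-sample seeds by fixed offsets from the master seed, so runs are
  byte-reproducible (manifest checksums are compared in the tests).

## Problem sizes in the shipped experiments

The recovery experiment runs 200 desk-scale replicates (one injected event
of 20–80 hotspot probes, hence ≥ 52 Kb, per replicate) and scores recovery
as a retained **rare** call at ≥ 50% reciprocal overlap with truth; injected
events are placed in hotspots free of polymorphic control loci, which is
what makes them rare by construction. The burden power experiment uses 100
replicates of 500 events per arm with a 10-fold enrichment (20% vs 2%
large). Both finish in well under a minute at desk scale.

## Known limitations

* No posterior (forward–backward) confidence on calls; Viterbi only.
* No multi-sample joint calling, GC correction, or sample-level QC metrics.
* No liftover or cytoband resolution — band labels are carried as strings.
* The published cohort's inferential p-values are not reproducible from the
  printed counts (raw case/control call sets are private); the replay
  reproduces the arithmetic that *is* derivable, and the statistical
  machinery is validated by property tests and independent oracles instead.
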