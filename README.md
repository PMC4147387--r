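# hotspotCNV

Rare copy-number variant (CNV) discovery on segmental-duplication hotspot
arrays, and carrier-rate association in small clinical cohorts — built for
the "second genetic hit" question in *FMR1* premutation carriers (55–200 CGG
repeats), whose neurological and neurodevelopmental involvement is highly
variable.

The package implements the full analysis chain:

1. **Simulation** — a hotspot-targeted array (~2.6 Kb probe spacing in
   ~251 Kb hotspot regions, ~36 Kb backbone), per-probe log2 ratios with
   Gaussian noise around copy-number effects (del −1.0, dup +0.58), a
   control CNV database (default 8,328 controls), and a 19/20/9/8 four-group
   cohort with injected truth events.
2. **Calling** — per-chromosome z-scores
   `z = (x − mean_c) / sd_c`, then Viterbi decoding of a 3-state HMM
   (loss / neutral / gain; emission means −2, 0, +2 in z units).
3. **Refinement** — a call is kept iff |mean z| ≥ 1.5, probes ≥ 10,
   segmental-duplication overlap ≤ 50%, and length ≥ 50 Kb.
4. **Rarity** — reciprocal overlap `min(|a∩b|/|a|, |a∩b|/|b|)` against the
   control database; rare means matched-carrier frequency < 0.1%
   (with 8,328 controls the boundary falls between 8 and 9 carriers).
5. **Burden** — Fisher's exact test on events above vs below a 325 Kb size
   threshold in cases vs controls, with a permutation cross-check.
6. **Association** — carrier rates per clinical group, 2×2 chi-square
   (closed form, with Yates and Fisher variants), exact McNemar, Welch t.

A **replay mode** re-derives the summary arithmetic of a published
56-carrier premutation cohort from its printed CNV table, which ships as a
plain-text fixture.

## Worked example

```r
library(hotspotCNV)

r <- replay_table1()
print(r)
#> CNV cohort report: 12 events (8 dup / 4 del) in 11 of 56 participants (19.6%)
#> event sizes: 160 Kb to 1.67 Mb, mean 508 Kb
#> per-group carriers: group 1: 3, group 2: 3, group 3: 1, group 4: 4
#> neuro_vs_not: 5/17 (29.4%) vs 6/39 (15.4%) (chi-sq p = 0.224)
#> neuro_asd_vs_neuro_only: 1/9 (11.1%) vs 4/8 (50.0%) (chi-sq p = 0.079)
#> asd_vs_not: 4/28 (14.3%) vs 7/28 (25.0%) (chi-sq p = 0.313)
#> overlap at Xp22.31 (case3, case4): X:6442757-6907093 (reciprocal 0.278)
#> overlap at 10q26.3 (case5, case6): 10:134543728-134941539 (reciprocal 0.886)
```

Reading the output: 12 rare events (8 duplications, 4 deletions) across 11
of 56 participants — a 19.6% carrier rate, mean event size 508 Kb. Carriers
concentrate in the neurologically involved groups (29.4% vs 15.4%), though
the 2×2 chi-square is not significant at this cohort size. The two
duplication pairs at 10q26.3 and Xp22.31 overlap at the printed coordinates,
the 10q26.3 pair at 88.6% reciprocal overlap — well past the 50% matching
criterion.

A fully simulated run:

```r
run <- run_pipeline(sim_config(seed = 42), out_dir = "runs/demo")
print(run$report)
#> CNV cohort report: 11 events (8 dup / 3 del) in 11 of 56 participants (19.6%)
#> event sizes: 78 Kb to 200 Kb, mean 136 Kb
#> per-group carriers: group 1: 0, group 2: 8, group 3: 2, group 4: 1
#> ...
run$burden$p_value   # Fisher p for >325 Kb enrichment, cases vs controls
```

Every tunable lives in one of four config objects: `sim_config()`
(genome/noise/cohort), `hmm_params()` (segmentation), `filter_thresholds()`
(refinement), `rarity_config()` (rarity and burden). A thin command-line
wrapper with `simulate` / `analyze` / `replay` / `report` subcommands is
installed at `system.file("cli", "hotspotcnv.R", package = "hotspotCNV")`.

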