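---
title: "Modeling collision-stimulated mRNA quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling collision-stimulated mRNA quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocollide)
```

## The model

`ribocollide` simulates a single class of mRNA in a cell as a rule-defined
continuous-time Markov chain and samples it exactly with the Gillespie
direct method.  Three processes are coupled on one molecule:

1. **Translation.** Ribosomes initiate on capped mRNAs whose start region
   is free (rate `k_init`), step codon by codon (10 s⁻¹ at ordinary
   codons), and terminate at the last codon (1 s⁻¹).  Each ribosome
   occupies a footprint of 10 codons, so a ribosome can neither initiate
   into nor step into a codon within a footprint of the next ribosome
   downstream.  A ribosome whose forward step is blocked by a neighbour at
   exactly one footprint's distance instead *collides* with it, at the
   same rate its step would have had; the collision is recorded as an
   explicit bond between the trailing ribosome's entry site and the
   leading ribosome's exit site.  The bond dissolves when the leading
   partner moves, terminates, or is removed.

2. **Canonical mRNA decay.** The poly(A) tail (60 residues) is removed
   3'→5' one residue at a time (0.03 s⁻¹ per residue), complete
   deadenylation licenses decapping (0.01 s⁻¹), and decapping licenses
   5'→3' exonucleolysis (1 s⁻¹ per backbone position).  An mRNA's
   *lifetime* is the interval from transcription to its first 5'→3'
   exonucleolysis event.  With these rates the mean lifetime of an
   untranslated mRNA is the sum of the sequential step means,
   60/0.03 + 1/0.01 + 1/1 = 2101 s ≈ 35 min, which the test suite
   verifies by simulation.

3. **Quality control at stalls.**  A stall is a stretch of `n_stall`
   consecutive slow codons; each slow codon's rate is
   `n_stall * net_stall_rate`, so the summed mean dwell time across the
   stall is `1/net_stall_rate` however the stall is subdivided.  Two
   quality-control channels act on translating ribosomes, each with four
   rate constants indexed by the ribosome's collision state (not hit,
   hit from the back, hit from the front, hit from both sides):

   * **Abortive termination** removes the ribosome without producing a
     full-length protein.
   * **Endonucleolytic cleavage** cuts the mRNA backbone `L_c = 10`
     codons 5' of the ribosome's A site and removes the cap at the same
     instant, so a cleaved mRNA can neither initiate nor be cleaved a
     second time, and its 5'→3' exonucleolysis begins almost immediately.
     Ribosomes stranded with the cut in their A site are recycled at a
     uniform 1 s⁻¹ (`k_abort_truncated`) regardless of collision state.

Model presets select which of the four rates are nonzero
(see `?model_preset`): `tj` (no abort), `sat` (abort independent of
collisions), `cat` (the trailing partner of a collision aborts), `csat`
(the leading partner aborts), and `none`/`sec`/`csec` analogously for
cleavage.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `k_init` | 0.1 (swept) | 1/s | initiation rate; the control variable |
| `k_elong_default` | 10 | 1/s | elongation per ordinary codon |
| `k_term` | 1 | 1/s | termination |
| `k_transcription` | 0.001 | 1/s | maintains a pool of 1–2 translatable mRNAs |
| `k_deadenylation` | 0.03 | 1/s per residue | 3'→5' tail shortening |
| `k_decapping` | 0.01 | 1/s | after complete deadenylation |
| `k_exo_53` | 1 | 1/s | 5'→3' exonucleolysis |
| `k_exo_35` | 0 | 1/s | 3'→5' exonucleolysis (off) |
| `L_m`, `L_p` | 650 codons, 60 nt | | reporter-sized mRNA |
| `footprint` | 10 codons | | steric exclusion span |
| `L_c` | 10 codons | | cleavage offset 5' of the A site |
| `stall_start`, `n_stall` | 401, 6 | | stall after 400 codons |
| `net_stall_rate` | 0.1 | 1/s | net rate across the whole stall |
| `k_a` | 0.5 | 1/s | nonzero abort rate of the chosen preset |
| `k_cleave` | 0.001 | 1/s | nonzero cleavage rate of the chosen preset |

The in vivo abort and cleavage rates are unknown; they are free
parameters of the model and the defaults here are chosen once so that
quality control changes the observables appreciably under the default
stall:

* For the collision-gated abort models (`csat`, `cat`) the relevant
  competition is between abort and transit of a slow codon
  (6 × 0.1 = 0.6 s⁻¹).  `k_a = 0.5` sits in that window.  Much smaller
  values (≲ 0.1) leave stall transit nearly lossless even under a
  permanent traffic jam, and the characteristic non-monotonic
  output-versus-initiation curve of the `csat` model disappears.
* For `sat`, abort competes with elongation at *every* codon, so the loss
  factor is the product `∏ k_i/(k_i + k_a)` over the whole lattice — for
  a 650-codon mRNA a small rate is already expensive, and
  `k_a = 0.5` would suppress output by ~13 orders of magnitude.  The
  suite uses `k_a = 0.02` for `sat`, which removes roughly three quarters
  of protein output.  This whole-lattice product (times the termination
  factor `k_term/(k_term + k_a)`) is also the closed form the tests use
  for the low-initiation limit of `sat`; a stall-only partition count
  would ignore the dominant uniform drop-off.

## Simulation protocol and observables

Two run modes mirror the two kinds of question:

* **Decay off** (`sweep_initiation(..., cleave = "none")`):
  `k_transcription = 0`, `k_deadenylation = 0`, and a single mRNA present
  from time 0 is tracked for the whole run.  The observable is the
  protein synthesis rate (PSR), full-length proteins per second.
* **Decay on** (cleavage sweeps): transcription keeps a small pool of
  mRNAs; both PSR (per system, not per mRNA — the convention matters and
  is deliberately not re-normalized) and the mean lifetime over
  uncensored mRNAs are reported.  mRNAs still alive at the end of a run
  are censored and excluded from lifetime means; at desk-scale durations
  the censored count is reported rather than ignored.

The test suite runs sweeps at 10⁵ s with 4 replicates per grid point
(the reference parameterization uses 10⁶ s); all tolerances are stated
in standard-error units across replicates, so the duration scaling is
principled rather than cosmetic.  Replicate seeds derive
deterministically from a base seed (`base_seed + replicate − 1`;
sweep cells offset the base by `n_reps` per cell), and identical
`(params, duration, seed)` reproduce a trajectory bit for bit.

## Numerical choices

* **Exactness.** The engine is a direct-method sampler: after every
  event the affected mRNA's propensities are re-enumerated in a fixed
  order, the waiting time is exponential in the total, and the firing
  event is chosen by one uniform draw walking the same fixed order.  The
  walk that sums and the walk that selects share one code path, so
  selection is exactly consistent with the total; a round-off fallback
  picks the last enabled event in the (measure-zero) case where the
  cumulative walk undershoots.  Exactness is verified against analytic
  exponential sojourn laws (KS tests at α = 0.01) and closed-form means.
* **State compression.** Deadenylation and 5'→3' exonucleolysis are
  strictly sequential, so the tail is a counter and the degraded 5'
  prefix a front pointer; cleavage can occur at most once per mRNA
  (it requires the cap and removes it), so a single cut position
  suffices.  A pure-R rule layer (`enabled_events()` / `apply_event()`)
  keeps the fully explicit representation; randomized-state tests check
  it against a per-equation brute-force oracle, and the compiled engine
  against the R layer.
* **Event cap.** A configurable cap (default 5 × 10⁸ events) guards
  runaway parameterizations; hitting it truncates the run with a warning
  and a flag, never silently.
* **Chemically inert mRNAs** (fully degraded, or cut fragments with no
  ribosomes and no reachable reactions) are dropped from the active set;
  their records remain.

## Design choices where the rules are genuinely open

* **Start region after an early abort.**  Written literally, the abort
  rules never clear the start region, so a ribosome aborting while its A
  site is still within the first 9 codons would leave the mRNA blocked
  for initiation forever; with any nonzero collision-independent abort
  rate this artifact accumulates and drives output to zero on long runs.
  The package clears the start region whenever a ribosome occupying the
  first 9 codons is removed, making "start blocked" equivalent to "a
  ribosome occupies the start footprint".
* **Cleavage and the collision bond.**  The cleavage rules dissolve the
  collision bond they are conditioned on (the back bond for a
  back-hit or doubly hit ribosome — the cut lands exactly on the
  trailing partner's A site when `L_c` equals the footprint — and the
  front bond for a front-hit ribosome).  This is dynamically almost
  neutral, because cleavage also removes the cap and the stranded
  trailer aborts at 1 s⁻¹ regardless of its bonds.
* **Exonuclease blocking** is enforced at A-site codons only: the
  5'→3' exonuclease can chew up to, but never through, a bonded codon,
  and may trail immediately behind a translocating ribosome.
  Full-footprint blocking would only delay degradation by ~1 s per
  ribosome encountered.
* **A ribosome may step onto an endonucleolytically cut position**
  (the step checks the backbone under the *source* codon); it then has
  no further elongation and leaves via the truncated-A-site abort.
* **Deadenylated but still capped mRNAs initiate at full efficiency**
  right until decapping.
* The compiled engine requires `k_exo_35 = 0` (the default); the 3'→5'
  exonucleolysis rules exist in the R rule layer and are covered by the
  oracle tests, but the engine's sequential-prefix compression does not
  represent 3' backbone chewing.

## Sequence and profiling companions

* `scan_windows()` slides a 10-codon window at single-codon stride and
  reports windows with ≥ 6 lysine/arginine codons (`kr`), ≥ 6 prolines
  (`p`), or — as a control class — ≥ 6 glutamate/aspartate codons
  (`ed`).  Stride 1 is the only stride that cannot miss a qualifying
  window.  Codons with ambiguous nucleotides disqualify the windows
  containing them.  `collapse_windows()` merges overlapping or adjacent
  windows into maximal regions; a gene's stall location is the start of
  its most 5' region.
* `psite_coverage()` assigns each footprint read to the 13th nucleotide
  from its 5' end.  `metagene_profile()` normalizes the coverage in a
  150-nt window around each region by the window's own mean and averages
  position-wise, with the region's first nucleotide at offset +1.
* `compute_te()` is the ratio of footprint rpkm to mRNA rpkm, keeping
  genes with ≥ 5 rpkm in both samples.  `te_upstream()` restricts
  coverage to the region 5' of a gene's first stall codon (≥ 100 region
  reads required in each assay); stall-free genes use a fixed control
  boundary, by default codon 215, the median stall location among
  stall-containing genes in the yeast annotation this analysis is
  designed for.  `compare_te_groups()` reports the difference of group
  *mean* log₂ TE together with a two-sided Wilcoxon rank-sum p-value
  (the median difference is also returned, since a rank test pairs more
  naturally with it — the mean is the default because the group summary
  plotted in the original analyses is a mean).
* `count_barcodes()` / `mrna_levels()` implement the pooled-reporter
  assay arithmetic: exact 8-nt barcode matching at a fixed read offset
  (no error correction — identification, not correction, is the stated
  operation, and at high depth collisions are the larger risk),
  per-barcode log₂(cDNA/gDNA) after discarding barcodes under 100 counts
  in either assay, per-reporter mean ± SE over retained barcodes, and
  median normalization within each reporter group.

## What the synthetic generators do and do not emulate

`synth_cds_set()`, `synth_te_tables()`, `synth_coverage_tracks()` and
`synth_barcode_reads()` produce inputs whose *ground truth is known by
construction*: implanted windows satisfy their rule exactly and uniquely,
TE tables carry a prescribed group offset on log-normal abundances,
coverage tracks carry a Gaussian density bump at a prescribed offset, and
read sets realize prescribed cDNA/gDNA ratios under multinomial sampling.
They deliberately do not emulate codon-usage bias, positional coverage
skew along real transcripts, sequencing error, PCR amplification bias, or
overdispersion beyond Poisson/multinomial noise.  Passing the round-trip
tests therefore shows that the analysis arithmetic is correct and its
thresholds act as specified — not that the pipeline is robust to every
artifact of real libraries.

## Limitations

* One mRNA species per simulation; no competition for a finite ribosome
  or nuclease pool (initiation is pseudo-first-order in each eligible
  mRNA).
* Elongation is uniform outside the stall; no codon-specific dwell times
  or tRNA dynamics.
* Ribosomal subunits, ubiquitination states, and the downstream fate of
  aborted nascent chains are not represented; abort is one lumped rate.
* The 3' fragment left behind a cut is never degraded (3'→5'
  exonucleolysis is off) and is only garbage-collected once
  ribosome-free.
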