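---
title: "Mapping meiotic DSB hotspot landscapes from SSDS fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping meiotic DSB hotspot landscapes from SSDS fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Meiotic recombination starts with programmed DNA double-strand breaks
(DSBs) made by SPO11. Single-stranded DNA sequencing (SSDS) after DMC1
chromatin immunoprecipitation yields aligned ssDNA fragments that mark break
sites; most fragments pile up in discrete hotspots positioned by PRDM9,
which also deposits H3K4me3 at the sites it binds. `dsbscape` implements the
fragment-level analysis of such experiments as composable steps:

1. **Fragment processing.** Records where *either* end read has a quality
   score below 30 are discarded (a single bad end discards the pair), then
   at most 20 records are retained per exact (chrom, start, end, strand)
   locus, then replicates are pooled. The duplicate-capping locus
   definition is the standard one for paired-end-derived fragments; the cap
   bounds PCR-duplicate inflation without removing genuine signal at strong
   hotspots.
2. **Hotspot calling.** Fragment midpoints are counted in 1 kb windows
   advanced by 100 bp. Each window is tested against a Poisson background
   whose rate is the larger of the local flank mean (±10 kb) and the
   genome-wide mean; p-values are Benjamini–Hochberg adjusted genome-wide
   (FDR 0.05), significant windows closer than 200 bp are merged, and each
   merged hotspot receives `strength` (fragment-midpoint count in its
   interval) and `center` (floor of the mean midpoint). The caller is this
   package's own design — its acceptance surface is recovery of planted
   truth in simulation, not replication of any specific published caller.
3. **Consensus scanning.** An exhaustive, no-mismatch forward-strand scan
   for gapped IUPAC consensus patterns, specialized to the 17 bp Gal4
   consensus CGG-N11-CCG. The pattern equals its own reverse complement, so
   forward scanning is strand-complete and each genomic interval is counted
   once (sites, not strand events). Degenerate pattern positions match only
   unambiguous A/C/G/T genome bases: an assembly N never supports a call.
4. **Overlap classification.** Overlap calls are restricted to central
   windows around hotspot centers: 400 nt for hotspot–hotspot sharing, 1 kb
   for hotspot–H3K4me3, 2 kb for hotspot–motif (motif sites enter as raw
   17 bp intervals; the window convention fixes the hotspot side only). An
   overlap is ≥1 bp of window intersection and each query hotspot counts
   once however many partners it touches. Strengths of shared hotspots are
   compared by Spearman's rho on log10 strength of best-overlap pairs.
5. **Chromosomal landscape.** In-hotspot signal (fragments whose midpoints
   fall in reference hotspot intervals) is binned at 1 Mb and normalized to
   percent of the genome-wide in-hotspot total, so unmasked bins sum
   to 100. The first 3 Mb of each chromosome is masked by default,
   mirroring the unavailable centromeric-end sequence of mouse assemblies.
   Subtelomeric depletion is summarized as
   R = mean(query/reference bin ratio in end bins) / (same in interior
   bins), with end bins within 5 Mb of the high-coordinate chromosome end;
   significance comes from ≥1000 circular rotations of the per-bin ratios
   within chromosomes, a test chosen because it respects the within-
   chromosome autocorrelation of binned coverage. The PAR statistic is
   simply the percent of all fragments whose midpoint lies in the PAR
   cluster interval, reported to two decimals.

## The synthetic-data generator

Desk-scale validation uses generated data with planted ground truth
(`sim_config()`, `generate_genome()`, `simulate_fragments()`,
`simulate_h3k4me3_tags()`). The generator emulates the *statistical*
structure the analysis relies on:

- **Genome**: i.i.d. uniform A/C/G/T bases. This makes the analytic motif
  null exact (expected matches = (L−16)·(1/4)^6 for the Gal4 pattern), at
  the cost of realism: real mammalian sequence has repeats and GC skew, and
  its Gal4-consensus density is roughly an order of magnitude lower (about
  one site per 30 kb in the mouse genome vs one per ~4 kb in uniform
  sequence).
  Consequently the *fraction* of hotspots carrying a consensus by chance is
  much higher in simulation than in real data, and no conclusion about
  that fraction transfers; the shape contrasts (central peak vs flat
  profile) do.
- **Hotspots**: quasi-uniform placement with a guaranteed minimum
  separation (5 kb default), Pareto-distributed strengths (shape 2,
  scale 10 by default — heavy right tail), fragment centers Gaussian around
  the hotspot center (sd 500 bp, truncated at ±3 sd, so footprints span
  ~1–2 kb, matching the central-window conventions). The Gaussian offset is
  a stand-in: the empirical SSDS fragment-offset law around centers is not
  asserted anywhere in the analysis.
- **Gal4-targeted hotspots**: a configurable fraction of hotspots carries
  an exact planted consensus whose midpoint is the hotspot center (no
  jitter by default); these hotspots are active only in conditions with
  Gal4 targeting enabled, emulating fusion-protein-directed breaks absent
  from the reference strain. Accidental matches are always scrubbed from
  planted-site neighbourhoods; optionally also from hotspot central
  windows, which gives clean specific-vs-shared classification tests.
- **PAR cluster**: 20 overlapping hotspots evenly spaced over a 40 kb
  interval at the high-coordinate end of the last chromosome (individual
  hotspots in the real cluster cannot be resolved). Its total strength
  defaults to the value that makes the cluster contribute 0.33% of expected
  fragments in reference-like conditions; conditions emulating the fusion
  protein multiply it by 1/33, a >30-fold deficiency.
  Note that uniform background fragments also land in the PAR interval, so
  at strong suppression the measured fraction has a background floor; the
  simulated fold change is therefore a lower bound on the planted one.
- **Subtelomeric suppression**: a single multiplicative factor (0.2
  default) on non-PAR hotspots whose center lies within `end_width`
  (5 Mb default) of the *high-coordinate* chromosome end. Mouse chromosomes
  are acrocentric and the depletion phenomenon is specific to
  non-centromeric ends, so suppression is applied only there; a smooth
  ramp is out of scope.
- **Duplicates and qualities**: duplicate multiplicity is 1 + Geometric
  (configurable mean); per-end qualities are a mixture with a low tail
  below 30 so the quality filter removes a testable fraction. Whether the
  real per-end score is mapping or base quality is immaterial here — it is
  treated as an opaque integer.
- **H3K4me3 tags** cluster at *every* planted hotspot with no suppression
  of any kind, so the landscape module can reproduce the dissociation
  between DSB depletion and unchanged H3K4me3 at chromosome ends.

Everything is deterministic given the config seed (truth and sequence) and
per-call seeds (sampling).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `min_quality` | 30 | per-end read-quality floor; either end below discards |
| `max_duplicates` | 20 | per-locus duplicate cap |
| caller `window`/`step`/`flank` | 1000/100/10000 bp | window matches hotspot footprint; flank sets the local background |
| caller `fdr`, `merge_gap`, `min_fragments` | 0.05, 200 bp, 5 | genome-wide BH control; merge fragmented windows; drop sub-threshold calls |
| `hotspot_window` | 400 nt | hotspot–hotspot sharing window |
| `h3k4me3_window` | 1000 nt | hotspot–peak window |
| `motif_window` | 2000 nt | hotspot–motif window (motif side raw) |
| `tss_window` | 2000 nt | TSS treated as points ± 1 kb; no published convention exists, so this is configurable |
| landscape `bin`, `end_mask`, `end_width` | 1 Mb, 3 Mb, 5 Mb | profile resolution; unavailable centromeric sequence; subtelomeric zone (no published width — chosen from the visible extent of end depletion and configurable) |

## Numerical choices and degenerate inputs

- Percentages in rendered tables use half-up rounding to one decimal
  (`round_half_up()`), matching the usual table convention; machine TSV
  output is never rounded.
- Hotspot centers are floors of midpoint means — deterministic under ties.
- Duplicate capping keeps first-seen records, so re-running on its own
  output is a no-op (idempotence), and the quality filter runs first,
  matching the stated order of the published filters.
- Windows are truncated at chromosome boundaries; no wraparound. An empty
  fragment set calls no hotspots; a zero-coverage chromosome contributes
  p = 1 windows, never division errors.
- `strength_correlation()` refuses fewer than 3 pairs;
  `in_hotspot_window_profile()` refuses a profile with no unmasked
  in-region signal; `par_cluster_fraction()` refuses empty input.
- Ambiguity convention in scanning: pattern N matches A/C/G/T only, fixed
  pattern positions never match genome N, overlapping matches all reported,
  matching is case-insensitive (soft-masking carries no meaning here).
- Genome-wide consensus totals depend on whether palindromic intervals are
  counted once or per strand and on which assembly contigs are included;
  this package counts unique forward-strand intervals on the supplied
  chromosomes, and its tests verify that convention is strand-complete.

## Problem sizes

The bundled tests and the acceptance script run on miniature genomes —
0.5–10 Mb chromosomes, hundreds of hotspots, 10^4–10^6 fragments — sizes at
which every stage's statistical behaviour (recovery, false-call rate,
normalization, depletion, PAR fraction) is measurable in seconds. The
workflow under `analysis/` uses a 30 Mb three-chromosome genome. All
functions scale linearly in fragments and genome length and accept
full-genome inputs unchanged.

## What passing tests do and do not show

Planted-truth recovery, the analytic motif null, oracle-equivalent
scanning and overlap counting, exact profile normalization, and the
DSB-vs-H3K4me3 depletion dissociation are all verified on synthetic data.
They show the machinery is correct under the generator's assumptions. They
do not show that real SSDS signal is Gaussian around centers, that real
strengths are Pareto, or that real consensus-bearing hotspot fractions
match the simulated ones — uniform sequence inflates chance motif overlap
substantially, and replicate strength correlations at shallow simulated
depth are Poisson-noise-limited. Claims about real genomes require real
fragment data and the real assembly through the same interfaces.

## Known limitations

- The caller is single-track: no strand-asymmetry modelling of SSDS signal
  and no explicit handling of overlapping hotspots closer than the merge
  scale (the PAR cluster is deliberately treated as one unresolvable
  interval).
- H3K4me3 peak calling is consumed as intervals, never computed (external
  peak callers own that step); PWM/MAST-style scoring is out of scope — the
  scanner handles exact IUPAC consensus matching only.
- The depletion statistic assumes the reference profile is positive in the
  bins being compared; bins with zero reference value are dropped from both
  zones.
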