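---
title: "Quantifying allele-specific expression from pyrosequencing allele percentages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific expression from pyrosequencing allele percentages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroASE)
```

## The measurement model

Pyrosequencing of an exonic reporter SNP (rSNP) in a heterozygote reports
the two alleles as percentages of incorporated nucleotides. The package
works on the **allelic transcript ratio** `r = pct_allele1 / pct_allele2`,
with the numerator allele fixed per assay in configuration — never inferred
from data — so that ratios are comparable across samples.

Two systematic corrections define the pipeline:

1. **Incorporation bias.** The same primers amplify genomic DNA (gDNA) of
   the same heterozygotes, where an equimolar allele ratio is expected. The
   arithmetic mean of raw gDNA ratios for an assay, `b`, estimates the
   assay's nucleotide-incorporation bias; all cDNA and gDNA ratios are
   divided by `b` (`estimate_gdna_bias()`, `normalize_ratio()`). By
   construction the mean normalized gDNA ratio is exactly 1. The bias is
   pooled per gene across breeds by default; a per-breed option exists for
   assays suspected of breed-specific sequence context, but pooling uses
   all controls and matches the one-bias-per-assay measurement model.
2. **Replicate averaging.** Technical replicates (2 by default) are each
   normalized, then arithmetically averaged; `replicate_sd` records their
   spread. The alternative — averaging percentages first, then forming one
   ratio — is available via `average = "percent_first"`. The orders differ
   only at second order in the replicate spread; we default to
   ratio-first because it makes the per-sample value an unweighted mean of
   the quantity that is thresholded and tested, and we expose the
   alternative for sensitivity analysis.

## Classification, neutralization, and the threshold

A sample is called ASE when its replicate-mean normalized ratio exceeds the
60:40 allele-proportion threshold: `r > 1.5` toward allele 1 or `r < 2/3`
toward allele 2, with **strict** inequalities (a ratio exactly at a
threshold stays balanced). We use `2/3` exactly, not its 3-decimal
rendering 0.667: with reciprocal thresholds, relabeling the alleles
(`r -> 1/r`) exactly swaps the two ASE categories and leaves balanced calls
fixed, a symmetry the classifier is property-tested on. With 0.667 as a
literal bound there is a sliver `(1/0.667, 1.5]` whose reciprocals are
classified differently, which cannot be intended by a 40:60/60:40 rule.

**Neutralization** maps `r` to `max(r, 1/r)` so the magnitude of imbalance
can be averaged when different animals over-express different alleles
(bi-directional ASE). Group summaries and the cDNA-vs-gDNA test take a
per-gene `neutralize` flag: on for genes showing bi-directional ASE, off
otherwise. Folding a near-symmetric distribution at 1 skews it; at small
group sizes (n ≈ 14) this makes the two-sided Welch test on folded values
slightly anticonservative (we measure ≈ 0.057 empirical type-I at nominal
0.05), whereas the unfolded log-ratio comparison is calibrated at 0.050.
The Monte-Carlo calibration suites therefore run the unfolded test, which
is also what the per-gene rule prescribes for their one-directional
point-fold scenarios; folded-mode summaries remain the right display for
bi-directional genes, read with that caveat.

## Group-level inference

- **cDNA vs gDNA** (`test_cdna_vs_gdna()`): two-sample, two-tailed Welch
  t-test on log10 ratios, one cDNA group per breed × tissue against the
  breed's heterozygous gDNA. A two-sample design (rather than a one-sample
  test of the cDNA mean against 0) is used because the gDNA group carries
  its own residual noise and its mean is informative; the summary table
  reports a gDNA column for exactly that reason. Breeds are analysed only
  when at least 10 rSNP heterozygotes are available (`min_het`), the
  smallest group size at which the Welch approximation and the threshold
  prevalence estimates are meaningfully stable in this design; smaller
  groups are excluded with their heterozygote count logged.
- **Directionality** (`classify_directionality()`): a gene × breed × tissue
  group is one-directional when only one allele is ever over-expressed
  (suggesting a cis element in LD with the gene) and bi-directional when
  both occur (suggesting an unlinked regulatory variant).
- **Candidate-variant association** (`phase_correct()`,
  `test_variant_association()`): within rSNP heterozygotes, each
  candidate-SNP heterozygote's log10 ratio is re-oriented so the numerator
  haplotype carries the candidate reference allele (a sign flip when the
  alternate allele is in cis with the rSNP numerator allele; flipping the
  sign equals taking the reciprocal before the log, so the two published
  formulations coincide). Corrected heterozygote values are compared to
  homozygote values by Welch t-test. If the candidate (or anything in LD
  with it) drives expression, heterozygote values shift coherently away
  from 0; if not, correction only permutes signs of noise. Phase is an
  input column — the package never infers haplotypes.
- **Significance codes**: `*`, `**`, `***` at strict p < 0.05, 0.01, 0.001.
  Raw p-values are reported per cell without multiplicity adjustment, the
  convention for this table layout; a Benjamini–Hochberg column can be
  switched on (`bh_correct`).
- Zero-variance degenerate groups raise an error rather than emitting NaN,
  except two *identical* groups, which return t = 0, p = 1.

## Methylation comparison

Per configured CpG island (1-based inclusive coordinates; islands are
configuration, not sequence-derived), percent 5-methylcytosine at each CpG
site is compared between ASE samples and balanced controls — samples
classified balanced whose ratio lies within `1 ± 0.15`, ranked by closeness
to 1 and truncated to a target size (default 10). The test is the classic
pooled-variance Student t-test, two-sided; Welch is available by flag, and
with exactly equal group variances and sizes the two coincide. Sites with
fewer than 2 samples in a group are flagged not-tested; records failing the
bisulfite conversion control are excluded with a logged count. ASE group
membership comes from the ASE calls for the same tissue — this module never
re-thresholds. By default ASE and control groups are not breed-matched (a
config filter exists): the comparison is within-tissue, and breed-matching
at these group sizes costs more power than the stratification returns.

## The synthetic cohort generator

`simulate_cohort()` draws, in a fixed order (animals, heterozygosity,
haplotypes, folds, gDNA, cDNA by tissue, methylation) so a config + seed
pins the dataset byte-for-byte:

- **Design**: four breed groups of 51/35/38/21 animals, rSNP heterozygote
  fraction 0.4 (a SNP near 0.3 minor-allele frequency under
  Hardy–Weinberg), three tissues, duplicate measurements.
- **Fractions**: with assay bias `b` on allelic odds and per-animal cis
  fold `f`, the expected measured allele-1 fraction is `b/(1+b)` in gDNA
  and `b·f/(1+b·f)` in cDNA; bias acts in both materials, which is the
  premise of dividing it out. Each replicate draws from a Beta distribution
  with that mean and precision `noise_concentration` — bounded and
  right-shaped for percentage read-outs (a Gaussian-on-percentage
  alternative is deliberately absent; logit-normal could be added).
  Exported percentages are rounded to 0.1 like instrument output and sum
  to exactly 100; ground truth keeps full precision.
- **Defaults as calibration**: `noise_concentration = 300` and a lognormal
  fold (SD 0.13 on log10) were chosen once so that (a) per-sample gDNA
  folded-log means land near 0.02–0.04, the magnitude such assays show,
  and (b) roughly 15–25% of fat-tissue samples exceed the 60:40 threshold,
  echoing the prevalence range such studies report. This is a calibration
  of plausibility, not a reproduction claim: the generator has no
  animal-level technical random effect, no breed structure in the folds,
  and independent tissues, so passing tests demonstrate the pipeline's
  arithmetic and calibration, not biological generality.
- **Candidate SNP in LD**: each haplotype carries a latent causal state
  (high/low expression, fold `causal_fold`); the candidate allele copies
  that state with probability `(1+r)/2`, `r = sqrt(ld_r2)`, at matched 0.5
  frequencies, so `ld_r2 = 1` makes the candidate the driver and
  `ld_r2 = 0` an unlinked variant. The candidate reference allele is the
  high-expressing one, so phase-corrected heterozygote means are positive
  under a true effect. When a candidate is configured the fold is genetic
  and constant across tissues; otherwise folds are drawn per
  animal × tissue, reflecting tissue-specific regulation.
- **Methylation**: per island × site × group (ASE by true fold vs balanced)
  normal draws truncated to [0, 100], default SD 1 percentage point, with a
  +3-point shift at designated sites of ASE samples.

`simulate_null_and_power_grid()` derives one seed per dataset from a base
seed (`base + 10000·cell + replicate`), giving a reproducible manifest for
the calibration suites.

## Numerical and degenerate-input choices

- Percent scale is 0–100 throughout; logs are base 10.
- Percentages of exactly 0 or 100 are rejected as failed assays, not
  clamped: a true heterozygote cannot yield 0% of an allele at
  pyrosequencing depth, so such values indicate genotyping error.
  Replicate pairs must sum to 100 ± 0.5 (instrument rounding).
- Ratios at a classification threshold are balanced (strict inequalities).
- Invalid rows are partitioned into an exclusion log with machine-readable
  reason codes, never silently dropped; the run log records counts at every
  filter and carries no timestamps, so identical inputs give byte-identical
  outputs.
- Genomic coordinates are 1-based inclusive everywhere except BED export,
  which converts to 0-based half-open.

## Problem sizes used by the test and calibration suites

Type-I error runs 2000 null replicates at 14 heterozygotes per group;
variant-association null calibration 2000 replicates at 20 animals; power
checks 60–200 replicates per cell; fold recovery uses n = 30 at
f ∈ {1.5, 2, 3}; bias recovery 500 gDNA samples at b = 1.25; methylation
detection 500 replicates (10 vs 10 samples, 6 sites) and 1000 null
replicates. At these sizes the Monte-Carlo standard error of a 0.05
rejection rate is about 0.005, well inside the ±0.015 calibration band the
suites assert.

## Known limitations

- The generator's noise precision is a free parameter; no instrument
  replicate-variance estimate exists to anchor it, so absolute power
  numbers from simulations transfer to real assays only qualitatively.
- The neutralized-mode group test is slightly anticonservative at small n
  (see above); prefer the unfolded test for one-directional genes.
- LD is modelled at matched 0.5/0.5 allele frequencies; unequal-frequency
  LD (where r² is bounded below 1) is not simulated.
- Real-data haplotype phase must be supplied; there is no phasing step.
- The pipeline analyses one gene per assay independently; no cross-gene
  borrowing of information.
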