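---
title: "Estimating circulating tumor fraction from cfDNA fragmentation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating circulating tumor fraction from cfDNA fragmentation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delfitf)
```

## The problem

Circulating tumor DNA (ctDNA) quantification usually requires knowing a
tumor's mutations in advance — a targeted assay such as droplet digital PCR
(ddPCR) tracks one known variant and reports its mutant allele frequency
(MAF). Many patients have no trackable hotspot variant, and designing
per-patient assays does not scale. `delfitf` implements a mutation- and
tumor-independent alternative: tumor-derived cfDNA perturbs the genome-wide
*fragmentation profile* of plasma DNA — fragment sizes shift shorter,
short/long coverage ratios deviate regionally from the healthy chromatin
landscape, and chromosome arms gain or lose coverage with tumor copy-number
events. A regression model trained on samples where ddPCR ground truth *is*
available learns to read tumor burden off these genome-wide features, and
can then score any low-coverage WGS cfDNA sample, including samples from
patients without a trackable mutation. The resulting score, DELFI-TF, is a
predicted MAF in percent.

## Coordinate system

All computation happens on a fixed reference tiling of the 22 autosomes:
26,236 non-overlapping 100-kb bins (0-based, half-open BED coordinates),
aggregated into 504 regions of 50 consecutive bins (5 Mb of retained
sequence) and assigned to the 39 scored chromosome arms — every arm except
the heterochromatic short arms of the acrocentric chromosomes (13p, 14p,
15p, 21p, 22p). Bins intersecting excluded regions (telomeres, centromeres,
low-mappability/blacklist intervals) are removed before grouping; leftover
bins that cannot complete a 50-bin group on their arm stay ungrouped.

Because published blacklists are referenced rather than printed, and
computing per-bin GC content would require the reference FASTA (out of
scope), `hg19_tiling()` *constructs* the packaged tiling: real hg19
chromosome sizes and centromere coordinates, telomere/centromere/acrocentric
exclusions, plus additional 100-kb exclusion intervals placed by a
deterministic per-arm allocation so the canonical 26,236 / 504 / 39 counts
hold exactly. Per-bin GC fractions are a smooth deterministic synthetic
surrogate (`synthetic_gc()`), clamped to [0.30, 0.62], with megabase-scale
autocorrelation similar to real GC content; they carry no sequence
information, which is irrelevant here because GC correction is a per-sample
regression against whatever covariate is supplied. A 1,000-bin two-
chromosome tiling (`mini_tiling()`) ships for fast structural tests; note
that with only two chromosomes it cannot support the PA-score, which needs
five chromosomes.

## From fragments to features

Fragments arrive as BED3+ intervals; length = end − start. Each fragment is
assigned to the unique bin containing its midpoint `floor((start+end)/2)` —
the convention for boundary-straddling fragments, chosen because it is
unambiguous. Fragments are *short* at 100–150 bp, *long* at 151–220 bp;
other lengths count in neither class but still enter the 50–400 bp length
histogram used for mixture fitting (the window is this package's
convention).

Sixteen features feed the model:

1. **Mixture weights (11).** The genome-wide fragment-length distribution is
   summarized by a 12-component univariate normal mixture — 12 means +
   12 standard deviations + 11 free weights = 35 free parameters. The
   components are fitted *once* by expectation-maximization on the pooled
   healthy-panel lengths (means initialized evenly over 50–400 bp, sds at
   15 bp, convergence at a relative log-likelihood change below 1e-6 or 500
   iterations, sd floor 0.5 bp, components sorted by mean). Per sample, only
   the weights are re-estimated (a convex EM over weights with frozen
   components), which keeps the weight features comparable across samples.
   The first 11 weights (lowest-mean components) are the features; dropping
   the largest-mean component as the redundant one is this package's
   convention since weights sum to one.
2. **PA-score (1).** Per-arm z-scores standardize each arm's fraction of
   total GC-corrected (short+long) counts against the healthy panel's
   per-arm mean and sd. For each chromosome take its max-|z| arm, rank
   chromosomes, keep the top five, convert each |z| to a *two-sided*
   p-value under a Student's t distribution with 3 degrees of freedom
   (floored at 1e-300 to avoid log(0)), and sum the negative natural logs.
   The two-sided convention makes PA = 0 exactly when all z = 0, matching
   the score's "no aneuploidy" semantics; sidedness and log base are not
   otherwise constrained.
3. **Top-2 |z| (2).** The two largest absolute arm z-scores, ties broken by
   arm label order.
4. **Profile principal components (2).** Per 5-Mb group, GC-corrected short
   counts divided by GC-corrected long counts form a 504-long fragmentation
   profile. A PCA (column-centered, unscaled) of the training samples'
   profiles retains the top two components; loading signs are fixed so each
   loading's largest-magnitude entry is positive, making projections
   reproducible across SVD implementations.

GC correction is additive residual correction around the per-sample median:
a locally weighted regression of counts on GC (span 0.75, two robustness
iterations, `stats::lowess`) is subtracted and the median added back, with
a floor at zero, applied separately to short and long counts. On exactly
linear GC bias the local-linear smoother interpolates the trend and the
correction is exact; a constant GC vector degenerates to recentering on the
median, and all-zero counts pass through unchanged. A 5-Mb group with zero
corrected long counts yields a missing ratio (imputed with the panel median
downstream); a sample with more than 5% missing groups is rejected.

## The regression model

A random forest regresses ddPCR MAF (percent) on the 16 features. The
forest uses 1000 trees, 5 of 16 features tried per split, minimum node size
2, impurity importances, and a fixed seed (`ranger`, single-threaded);
these hyperparameters are package defaults, overridable via
`default_hyper()`. Training rows are put in a canonical order (by sample
id) before fitting so results are invariant to input sample order. ddPCR-
undetectable samples enter training with label 0 by default (they carry
real information: the tumor signal is below the assay's limit), switchable
off. Predictions are clipped to [0, 100].

DELFI-TF is defined by **leave-one-patient-out cross-validation**: for each
patient, the profile PCA and the forest are refitted on all *other*
patients' samples and the held-out patient's samples are scored
out-of-fold. Refitting the PCA inside each fold prevents the held-out
patient's profiles from leaking into their own fold's feature space. The
healthy-panel statistics and mixture components are *not* refit per fold —
they derive from non-cancer samples outside the labeled cohort. Note what
leave-one-patient-out does and does not isolate: a patient's own
out-of-fold scores cannot depend on that patient's labels (this is tested
by perturbation), but every patient's samples are training data for all
other folds, so perturbing one patient does change other patients' scores.

A *locked model* (`train()` then `score()`) applies one fitted model to new
samples with no refitting of any component — the mode used to score
patients for whom no tracking mutation exists.

## Longitudinal slopes

For treatment monitoring, a patient's DELFI-TF series is reduced to the
ordinary least-squares slope (percentage points per day) of score on days
since T1, the earliest draw strictly after treatment start. Draws from T1
through progression are included for the progression-free-survival (PFS)
analysis, through progression + 60 days for the overall-survival (OS)
analysis. A patient is eligible with at least three draws strictly before
progression (T1 included; whether to count T1 is unspecified upstream, and
counting all pre-progression draws is this package's choice) and at least
one draw inside the window — 120 days up to progression for PFS, extended
60 days past it for OS. Eligible patients are dichotomized at the median
slope; a slope exactly at the median goes to the "below" group, a
deterministic and conservative tie rule (below-median is the favorable
group). Dates are ISO-8601 and day differences are whole calendar days.

## The synthetic cohort

Real cohorts of this kind are controlled-access, so the package carries a
generative model (`simulate_cohort()`) that makes every claim testable
against known truth. It simulates at the *bin level* — the method consumes
bin counts and a length histogram, so per-read simulation would add cost
without adding test power; fragment-level BED emission is available for I/O
tests (it realizes exactly the binned short/long counts, so re-binning a
BED reproduces them).

* **Healthy archetype.** Smooth per-bin spatial weights and a smooth
  per-group short/long tilt, drawn from a *fixed internal seed* independent
  of the cohort seed: the healthy fragmentation landscape models
  population-level chromatin structure, so healthy panels must be
  transferable across simulated cohorts — a locked model trained on one
  cohort can score samples from another. The healthy length mixture is
  0.80·N(167, 10) + 0.15·N(320, 30) + 0.05·N(480, 40) bp (mono-, di-,
  tri-nucleosomal), truncated to the 50–400 bp window.
* **Tumor archetype (per patient).** `n_altered_arms` arms (default 8)
  receive multiplicative count effects 2^±u with u ~ U(0.2, 1); a
  patient-specific smooth profile tilt perturbs the short/long pattern; the
  tumor length mixture 0.40·N(145, 12) + 0.45·N(167, 10) + 0.15·N(320, 30)
  shifts mass to sub-mononucleosomal sizes, so mean fragment length
  decreases in tumor fraction.
* **A sample at tumor fraction θ** draws per-bin short and long counts from
  Poisson means mixing the two archetypes (1−θ)/θ — with a per-sample GC
  bias coefficient (N(1, 0.25) slope against GC) and per-arm log-normal
  wobble (sd 0.01) — and a length histogram from the θ-mixed length model
  (multinomial over the integer bp grid).
* **Trajectories and labels.** Baseline θ is uniform on [0.01, 0.40]
  (default); on treatment it decays at 0.085/day to a nadir of 2% of
  baseline, holds, then regrows at 0.04/day after a per-patient progression
  time uniform on 70–160 days, with draws every 45 days. These rates are
  set so the cohort reproduces the qualitative dynamics of first-line
  treatment monitoring: an order-of-magnitude-plus drop by the first
  on-treatment draw and regrowth toward progression. Labels are ddPCR-like:
  mutant droplets ~ Binomial(5000, θ·s) with per-patient clonality
  s ~ Beta(50, 2.5); 5,000 partitions model *assayable genome equivalents*
  at realistic cfDNA input rather than nominal droplet counts, and fewer
  than 10 mutant droplets (a 0.2% MAF limit of detection) gives label 0,
  flagged undetectable. Detectable labels then span roughly 0.2–40% MAF
  and a realistic share of on-treatment draws is undetectable — without
  0-label training samples a forest has no support near zero and healthy
  samples would score spuriously high.
* All randomness flows from the single config seed (`withr::with_seed`);
  identical configs give byte-identical cohorts.

What the simulator does *not* emulate: sequencing error, mappability
structure, within-patient clonal evolution of the copy-number profile,
library-preparation batch effects, or the clinical covariate structure of
any real cohort. Passing recovery tests on this generator demonstrates the
pipeline's correctness and internal consistency — that the features respond
to tumor fraction as designed and the model recovers a known signal — not
clinical performance on real plasma.

## Problem sizes and numerical choices

The default study conditions are 60 patients × 4 draws at 300,000 expected
fragments per sample plus a 30-sample healthy panel; on the full 26,236-bin
tiling the whole simulate → featurize → cross-validate pipeline runs in
about two minutes on one CPU. Unit tests use a 6-chromosome toy tiling
(1,230 bins, 24 groups) with 15 patients × 3 draws at 60,000 fragments,
which preserves every code path (including the PA-score's five-chromosome
selection) at a fraction of the cost.

Numerical edge cases are handled explicitly: EM components that lose all
responsibility keep their previous parameters instead of collapsing to
garbage; coincident components at the sd floor (a point-mass input drives
several components onto one value) are merged onto the heaviest and means
epsilon-spaced to keep a strict ordering; p-values are floored at 1e-300;
zero-variance profiles return NA correlation with a warning; ties in the
top-|z| selection break by arm label order; slope ties at the median go
below.

## Limitations

The packaged tiling's exclusion placement and GC surrogate are synthetic
stand-ins that reproduce the published structural counts, not the published
coordinates. The recovery correlation on simulated data (r ≈ 0.99 under
defaults) exceeds what mutation-ground-truth comparisons on real plasma
report (r ≈ 0.90) because the generator omits the biological and technical
noise sources listed above; the acceptance checks treat the published
figure as a lower bound, not a target to match. The maxMAF utility assumes
recurrence counts are supplied in the variant table; it performs no
catalogue lookups. Survival modelling on slopes is out of scope.
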