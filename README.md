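# delfitf

Mutation- and tumor-independent estimation of circulating tumor fraction
from low-coverage whole-genome sequencing of cell-free DNA (cfDNA).

Tracking tumor burden in plasma usually means tracking a known mutation —
e.g. droplet digital PCR (ddPCR) of a *RAS/BRAF* hotspot — which requires
knowing the tumor's genotype and excludes patients without a trackable
variant. `delfitf` instead reads tumor burden off the genome-wide
**fragmentation profile** of cfDNA:

- GC-corrected **short/long fragment ratios** (short = 100–150 bp, long =
  151–220 bp) in 504 five-megabase regions built from 26,236 100-kb autosome
  bins, summarized by their top two principal components;
- **arm-level aneuploidy z-scores** for 39 chromosome arms, their two largest
  magnitudes, and the **plasma aneuploidy score**
  PA = −Σ ln p over the five chromosomes with the most extreme arms, with
  z → p via a two-sided Student's *t*(3 df) tail;
- the genome-wide **fragment-length distribution** summarized by a
  12-component normal mixture (35 free parameters) whose components are fit
  once on a healthy panel, with 11 per-sample re-fitted weights as features.

A random-forest regressor maps these 16 features to a predicted mutant
allele frequency — the **DELFI-TF score** (percent). Scores are generated by
leave-one-patient-out cross-validation (every patient scored by a model that
never saw them) or by a locked model applied to new samples. Longitudinal
series are reduced to per-patient **slopes** (percentage points per day from
the first post-treatment draw, within progression eligibility windows), and
a `max_maf()` utility implements the hotspot-filtered maximum MAF used for
targeted-panel validation cohorts. Because real cohorts of this kind are
controlled-access, the package includes a synthetic-cohort simulator with
known ground-truth tumor fractions that exercises the entire pipeline.

## Worked example

Simulate a labeled longitudinal cohort on the packaged hg19 tiling, build
the healthy reference panel, featurize, and cross-validate:

```r
library(delfitf)

tiling <- hg19_tiling()            # 26,236 bins, 504 groups, 39 arms
cfg    <- simulation_config(n_patients = 20, draws_per_patient = 4, seed = 1)
sim    <- simulate_cohort(cfg, tiling)
panel  <- build_healthy_panel(sim$panel, tiling, seed = 1)
feats  <- featurize_cohort(sim$samples, tiling, panel)
cv     <- lopo_cv(feats, seed = 1)
head(cv[, c("sample_id", "patient_id", "fold", "delfi_tf", "maf_label", "detectable")])
#>   sample_id patient_id fold  delfi_tf maf_label detectable
#> 1 P001_T0   P001       P001     7.17      10.6  TRUE
#> 2 P001_T1   P001       P001     0.465      0    FALSE
#> 3 P001_T2   P001       P001     0.175      0.3  TRUE
#> 4 P001_T3   P001       P001     0.944      1.86 TRUE
#> 5 P002_T0   P002       P002    31.4       33.0  TRUE
#> 6 P002_T1   P002       P002     0.716      0.78 TRUE
```

Each row is one blood draw: `delfi_tf` is the out-of-fold predicted MAF in
percent and `maf_label` the simulated ddPCR ground truth (0 when the assay
is below its limit of detection, `detectable = FALSE`). Patient P001 shows
the canonical treatment arc — baseline burden (10.6%), suppression below
the ddPCR detection limit at the first on-treatment draw, regrowth by the
fourth. Agreement with truth among detectable draws:

```r
det <- cv$detectable
cor(cv$delfi_tf[det], cv$maf_label[det])
#> Pearson r (detectable, n = 62): 0.994
```

Per-patient slopes against the simulated clinical metadata:

```r
clinical <- sim$patients[, c("patient_id", "treatment_start", "progression_date")]
scores   <- cbind(sim$cohort[, c("patient_id", "date")], delfi_tf = cv$delfi_tf)
delfi_slopes(scores, clinical, analysis = "PFS")
#>   patient_id analysis    slope n_points eligible above_median
#> 1 P001       PFS      NA              1 FALSE    NA
#> 2 P002       PFS      NA              1 FALSE    NA
#> 3 P003       PFS       0.00373        2 TRUE     TRUE
#> 4 P004       PFS      NA              1 FALSE    NA
```

Positive slopes (rising DELFI-TF after treatment start) flag patients
heading to progression; eligible patients are dichotomized at the cohort
median slope.

A command-line wrapper covering the same flows (`simulate`, `featurize`,
`cv`, `slope`, `maxmaf`, `tiling`) is installed at `inst/cli/delfitf`.
Fragment input is BED3+ (`chrom start end`, 0-based half-open); see
`?read_fragments`. To go from an aligned, deduplicated BAM to that BED:
`samtools sort -n in.bam | bedtools bamtobed -bedpe -i - | awk -v OFS='\t'
'{print $1,$2,$6}'`.

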