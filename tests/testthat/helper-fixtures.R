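# Shared fixtures, built in code and memoized for the test run.

.fix <- new.env(parent = emptyenv())

# 6 toy chromosomes of 21 Mb with a 0.5-Mb excluded centromere each:
# 1,230 bins, 24 groups, 12 arms -- enough chromosomes for the PA-score.
pipe_tiling <- function() {
  if (is.null(.fix$pipe_tiling)) {
    sizes <- data.frame(chrom = paste0("chr", 1:6), size = 21e6)
    cen <- data.frame(chrom = paste0("chr", 1:6), start = 10.0e6, end = 10.5e6)
    .fix$pipe_tiling <- build_tiling(sizes, exclusions = cen, centromeres = cen)
  }
  .fix$pipe_tiling
}

# small simulated cohort + panel + features, shared across model tests
pipe_cohort <- function() {
  if (is.null(.fix$pipe_cohort)) {
    tiling <- pipe_tiling()
    cfg <- simulation_config(n_patients = 15, draws_per_patient = 3,
                             coverage = 6e4, n_panel = 12, seed = 42)
    sim <- simulate_cohort(cfg, tiling)
    panel <- build_healthy_panel(sim$panel, tiling, seed = 42)
    feats <- featurize_cohort(sim$samples, tiling, panel)
    .fix$pipe_cohort <- list(tiling = tiling, cfg = cfg, sim = sim,
                             panel = panel, feats = feats)
  }
  .fix$pipe_cohort
}

# a healthy panel object alone (for feature-level tests)
pipe_panel <- function() pipe_cohort()$panel

# named z-score vector spanning >= 5 chromosomes
zvec <- function(values, arms) setNames(values, arms)
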