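test_that("simulation is byte-identical under a fixed seed and validates config", {
  t <- pipe_tiling()
  cfg <- simulation_config(n_patients = 3, draws_per_patient = 2, coverage = 2e4,
                           n_panel = 3, seed = 5)
  s1 <- simulate_cohort(cfg, t)
  s2 <- simulate_cohort(cfg, t)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  expect_error(simulation_config(seed = NULL), class = "delfi_config_error")
  expect_error(simulation_config(tf_range = c(0.2, 0.6), seed = 1),
               class = "delfi_config_error")
  expect_error(simulation_config(coverage = 100, seed = 1),
               class = "delfi_config_error")
})

test_that("tumor-fraction-zero samples carry zero truth and labels", {
  t <- pipe_tiling()
  cfg <- simulation_config(n_patients = 4, draws_per_patient = 2, coverage = 2e4,
                           tf_range = c(0, 0), n_panel = 3, seed = 6)
  sim <- simulate_cohort(cfg, t)
  expect_true(all(sim$cohort$truth_tf == 0))
  expect_true(all(sim$cohort$maf_label == 0))
  expect_false(any(sim$cohort$detectable))
})

test_that("mean fragment length decreases with tumor fraction", {
  t <- pipe_tiling()
  cfg <- simulation_config(n_patients = 2, draws_per_patient = 1, coverage = 2e5,
                           n_panel = 2, seed = 8)
  grid <- 50:400
  mean_len <- vapply(c(0, 0.1, 0.3), function(th) {
    s <- simulate_spikein(cfg, t, th, patient_seed = 3)[[1]]
    sum(grid * s$counts$length_hist) / sum(s$counts$length_hist)
  }, numeric(1))
  expect_true(all(diff(mean_len) < 0))
})

test_that("healthy samples reproduce the archetype's expected arm fractions", {
  pc <- pipe_cohort()
  t <- pc$tiling
  fr <- t(vapply(pc$sim$panel, function(p) {
    tot <- p$short + p$long
    as.numeric(rowsum(tot, factor(t$arm, levels = attr(t, "arms"))) / sum(tot))
  }, numeric(length(attr(t, "arms")))))
  obs <- colMeans(fr)
  se <- apply(fr, 2, sd) / sqrt(nrow(fr))
  expect_true(all(abs(obs - pc$sim$archetype$healthy_arm_expect) < 3 * se + 1e-4))
})

test_that("arm z-scores of simulated tumors are enriched on the altered arms", {
  pc <- pipe_cohort()
  t <- pc$tiling
  # 4 altered arms against 8 unaltered on the toy tiling (the default of 8
  # would leave too few unaltered arms for a rank comparison)
  cfg <- simulation_config(n_patients = 2, draws_per_patient = 1, coverage = 6e4,
                           n_altered_arms = 4L, n_panel = 2, seed = 77)
  sp <- simulate_spikein(cfg, t, 0.25, patient_seed = 11)[[1]]
  f <- featurize_sample(sp$counts, t, pc$panel)
  arch <- withr::with_seed(cfg$seed + 11, {
    delfitf:::draw_patient_tumor(delfitf:::healthy_archetype(t, cfg), t, 4L)
  })
  on <- abs(f$z[names(f$z) %in% arch$alt])
  off <- abs(f$z[!names(f$z) %in% arch$alt])
  expect_lt(stats::wilcox.test(on, off, alternative = "greater")$p.value, 0.01)
})

test_that("profiles of high-burden samples diverge from the healthy reference", {
  pc <- pipe_cohort()
  cor0 <- vapply(simulate_spikein(pc$cfg, pc$tiling, rep(0, 4), patient_seed = 21),
                 function(s) featurize_sample(s$counts, pc$tiling, pc$panel)$correlation,
                 numeric(1))
  cor3 <- vapply(simulate_spikein(pc$cfg, pc$tiling, rep(0.3, 4), patient_seed = 21),
                 function(s) featurize_sample(s$counts, pc$tiling, pc$panel)$correlation,
                 numeric(1))
  expect_gt(mean(cor0), mean(cor3))
})

test_that("written cohorts round-trip through the fragment and counts paths", {
  t <- pipe_tiling()
  cfg <- simulation_config(n_patients = 2, draws_per_patient = 1, coverage = 2e4,
                           n_panel = 2, seed = 9)
  sim <- simulate_cohort(cfg, t)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir, tiling = t, bed = TRUE)
  s <- sim$samples[[1]]
  # counts TSV round trip
  rc <- read_counts(file.path(dir, paste0(s$sample_id, "_counts.tsv")),
                    file.path(dir, paste0(s$sample_id, "_lengths.tsv")))
  expect_equal(rc$short, s$counts$short)
  expect_equal(rc$length_hist, s$counts$length_hist)
  # BED round trip reproduces the short/long bin counts exactly
  fr <- read_fragments(file.path(dir, paste0(s$sample_id, ".bed")))
  bc <- bin_fragments(fr, t)
  expect_equal(bc$short, s$counts$short)
  expect_equal(bc$long, s$counts$long)
  # truth columns never reach the label export
  lab <- read.delim(file.path(dir, "cohort_labels.tsv"))
  expect_false(any(grepl("^truth_", names(lab))))
  expect_true("truth_tf" %in% names(read.delim(file.path(dir, "cohort_metadata.tsv"))))
})
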