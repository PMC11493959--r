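# Synthetic longitudinal cfDNA cohorts with known ground-truth tumor
# fractions. Counts are simulated at the bin level (the method consumes bin
# counts and a length histogram, not reads); fragment-level BED emission is
# an opt-in for I/O testing.

# archetype fragment-length mixtures (bp). The healthy distribution carries a
# mononucleosomal peak at 167 bp plus di-/tri-nucleosomal mass; tumor-derived
# cfDNA is shifted toward shorter, sub-mononucleosomal fragments.
HEALTHY_LENGTH_MIX <- list(means = c(167, 320, 480), sds = c(10, 30, 40),
                           weights = c(0.80, 0.15, 0.05))
TUMOR_LENGTH_MIX <- list(means = c(145, 167, 320), sds = c(12, 10, 30),
                         weights = c(0.40, 0.45, 0.15))

length_grid_density <- function(mix) {
  x <- LENGTH_WINDOW[1L]:LENGTH_WINDOW[2L]
  d <- colSums(mix$weights * t(outer(x, seq_along(mix$means),
                                     function(i, k) dnorm(i, mix$means[k], mix$sds[k]))))
  d / sum(d)
}

range_mass <- function(dens, range) {
  x <- LENGTH_WINDOW[1L]:LENGTH_WINDOW[2L]
  sum(dens[x >= range[1L] & x <= range[2L]])
}

smooth_noise <- function(n, window = 12L) {
  k <- window
  x <- rnorm(n + 2L * k)
  y <- stats::filter(x, rep(1 / (2 * k + 1), 2L * k + 1L), sides = 2)
  v <- as.numeric(y[(k + 1L):(k + n)])
  v / sd(v)
}

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the package: 60
#' patients with 4 longitudinal draws at an expected 300,000 fragments per
#' sample, baseline tumor fractions uniform on \[0.01, 0.40\], and 8
#' copy-altered arms per tumor. The on-treatment trajectory drops
#' exponentially at 0.085/day to a nadir of 2% of baseline (first-line
#' response typically reduces circulating tumor fraction by more than an
#' order of magnitude by the first on-treatment draw), holds the nadir until
#' a per-patient progression time, then regrows at 0.04/day. A 30-sample
#' healthy panel is generated alongside. The ddPCR label process partitions 5,000 assayable genome
#' equivalents (limited cfDNA input, not the nominal droplet count) with a
#' 10-droplet detection threshold, i.e. a 0.2% MAF limit of detection, so
#' that on-treatment draws from responding patients fall below the limit and
#' enter training with label 0, as undetectable samples do in real
#' longitudinal ddPCR monitoring.
#'
#' @param n_patients,draws_per_patient cohort shape.
#' @param coverage expected fragments per sample (>= 10,000).
#' @param tf_range baseline tumor-fraction range, within \[0, 0.5\].
#' @param n_altered_arms copy-altered arms per tumor.
#' @param response_decay,regrowth_rate per-day exponential rates of the
#'   tumor-fraction trajectory before/after progression.
#' @param nadir_fraction floor of the on-treatment decay, as a fraction of
#'   the baseline tumor fraction.
#' @param droplet_count,lod_droplets ddPCR label process: droplets partitioned
#'   and the minimum mutant-droplet count for a detectable MAF.
#' @param n_panel healthy-panel samples (tumor fraction 0).
#' @param draw_interval_days days between consecutive draws.
#' @param arm_noise_sd per-sample, per-arm multiplicative log-noise sd.
#' @param gc_bias_mean,gc_bias_sd per-sample GC-bias coefficient distribution.
#' @param seed mandatory integer seed.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_patients = 60L, draws_per_patient = 4L,
                              coverage = 300000, tf_range = c(0.01, 0.40),
                              n_altered_arms = 8L, response_decay = 0.085,
                              regrowth_rate = 0.04, nadir_fraction = 0.02,
                              droplet_count = 5000L,
                              lod_droplets = 10L, n_panel = 30L,
                              draw_interval_days = 45L, arm_noise_sd = 0.01,
                              gc_bias_mean = 1.0, gc_bias_sd = 0.25, seed) {
  if (missing(seed) || is.null(seed))
    delfi_error("a seed is mandatory for simulation", "delfi_config_error")
  if (!(tf_range[1L] >= 0 && tf_range[1L] <= tf_range[2L] && tf_range[2L] <= 0.5))
    delfi_error("tf_range must satisfy 0 <= lo <= hi <= 0.5", "delfi_config_error")
  if (coverage < 10000)
    delfi_error("coverage must be at least 10,000 fragments", "delfi_config_error")
  structure(list(n_patients = as.integer(n_patients),
                 draws_per_patient = as.integer(draws_per_patient),
                 coverage = coverage, tf_range = tf_range,
                 n_altered_arms = as.integer(n_altered_arms),
                 response_decay = response_decay, regrowth_rate = regrowth_rate,
                 nadir_fraction = nadir_fraction,
                 droplet_count = as.integer(droplet_count),
                 lod_droplets = as.integer(lod_droplets),
                 n_panel = as.integer(n_panel),
                 draw_interval_days = as.integer(draw_interval_days),
                 arm_noise_sd = arm_noise_sd, gc_bias_mean = gc_bias_mean,
                 gc_bias_sd = gc_bias_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# Healthy archetype: smooth per-bin spatial weights and per-group short/long
# tilt. Drawn from a FIXED internal seed, independent of the cohort seed: the
# healthy fragmentation landscape is a population property of the genome
# (chromatin structure), so panels and cohorts simulated under different
# seeds share the same baseline and healthy panels are transferable.
healthy_archetype <- function(tiling, config) {
  nb <- nrow(tiling)
  G <- n_groups(tiling)
  grp <- tiling$group5mb
  arms <- attr(tiling, "arms")
  withr::with_seed(760520L, {
    u <- exp(0.1 * smooth_noise(nb, 25L))
    a_g <- 0.15 * smooth_noise(G, 6L)
    a_bin <- rep(0, nb)
    a_bin[!is.na(grp)] <- a_g[grp[!is.na(grp)]]
    dens_h <- length_grid_density(HEALTHY_LENGTH_MIX)
    dens_t <- length_grid_density(TUMOR_LENGTH_MIX)
    arch <- list(
      u = u, a_g = a_g,
      hs = u * (1 + a_bin / 2), hl = u * (1 - a_bin / 2),
      dens_h = dens_h, dens_t = dens_t,
      p_short_h = range_mass(dens_h, SHORT_RANGE),
      p_long_h = range_mass(dens_h, LONG_RANGE),
      p_short_t = range_mass(dens_t, SHORT_RANGE),
      p_long_t = range_mass(dens_t, LONG_RANGE))
    arch$hs <- arch$hs / sum(arch$hs)
    arch$hl <- arch$hl / sum(arch$hl)
    # expected healthy arm fraction (diagnostics; includes mean GC bias)
    ebias <- pmax(1 + (config$gc_bias_mean - 1) * (tiling$gc - mean(tiling$gc)), 0.05)
    etot <- (arch$p_short_h * arch$hs + arch$p_long_h * arch$hl) * ebias
    arch$healthy_arm_expect <-
      rowsum(etot, factor(tiling$arm, levels = arms))[, 1L] / sum(etot)
    arch
  })
}

# one patient's tumor archetype: altered arms with 2^(+/-u) count effects and
# a patient-specific short/long tilt (consumes the current RNG stream)
draw_patient_tumor <- function(arch, tiling, n_alt) {
  arms <- attr(tiling, "arms")
  nb <- nrow(tiling)
  grp <- tiling$group5mb
  alt <- sort(sample(arms, n_alt))
  eff <- 2^(sample(c(-1, 1), n_alt, replace = TRUE) * runif(n_alt, 0.2, 1.0))
  cfac <- rep(1, nb)
  for (j in seq_len(n_alt)) cfac[tiling$arm == alt[j]] <- eff[j]
  tilt_g <- arch$a_g + 0.25 * smooth_noise(n_groups(tiling), 6L)
  tilt_bin <- rep(0, nb)
  tilt_bin[!is.na(grp)] <- tilt_g[grp[!is.na(grp)]]
  ts <- arch$u * cfac * (1 + tilt_bin / 2)
  tl <- arch$u * cfac * (1 - tilt_bin / 2)
  list(ts = ts / sum(ts), tl = tl / sum(tl), alt = alt, eff = eff)
}

#' Spike-in series for one synthetic patient
#'
#' Draws a single patient tumor archetype and simulates one sample at each
#' requested tumor fraction, sharing the archetype across the series. Used
#' to check that locked-model scores respond monotonically to tumor fraction.
#'
#' @param config a `sim_config`.
#' @param tiling a `delfi_tiling`.
#' @param thetas numeric vector of tumor fractions.
#' @param patient_seed offset added to the config seed for this patient.
#' @return list of samples (`counts`, `sample_id`, `patient_id`, `truth_tf`).
#' @export
simulate_spikein <- function(config, tiling, thetas, patient_seed = 1L) {
  arch <- healthy_archetype(tiling, config)
  n_alt <- min(config$n_altered_arms, length(attr(tiling, "arms")))
  withr::with_seed(config$seed + patient_seed, {
    parch <- draw_patient_tumor(arch, tiling, n_alt)
    lapply(seq_along(thetas), function(i) {
      counts <- simulate_sample_counts(sprintf("spike_%02d", i), thetas[i],
                                       arch, parch, config, tiling)
      list(counts = counts, sample_id = counts$sample_id,
           patient_id = "spike", truth_tf = thetas[i])
    })
  })
}

# draw one sample's binned counts + length histogram at tumor fraction theta
simulate_sample_counts <- function(sample_id, theta, arch, patient_arch, cfg, tiling) {
  gc_bias <- 1 + rnorm(1L, cfg$gc_bias_mean - 1, cfg$gc_bias_sd) *
    (tiling$gc - mean(tiling$gc))
  gc_bias <- pmax(gc_bias, 0.05)
  arm_idx <- match(tiling$arm, attr(tiling, "arms"))
  wobble <- exp(rnorm(length(attr(tiling, "arms")), 0, cfg$arm_noise_sd))[arm_idx]
  noise <- gc_bias * wobble
  lam_s <- cfg$coverage * ((1 - theta) * arch$p_short_h * arch$hs +
                             theta * arch$p_short_t * patient_arch$ts) * noise
  lam_l <- cfg$coverage * ((1 - theta) * arch$p_long_h * arch$hl +
                             theta * arch$p_long_t * patient_arch$tl) * noise
  short <- rpois(length(lam_s), lam_s)
  long <- rpois(length(lam_l), lam_l)
  dens <- (1 - theta) * arch$dens_h + theta * arch$dens_t
  hist <- rmultinom(1L, round(cfg$coverage), dens)[, 1L]
  new_binned_counts(sample_id, short, long, hist)
}

#' Simulate a longitudinal cfDNA cohort with known truth
#'
#' Generative model: a healthy archetype defines smooth per-bin spatial
#' weights and a smooth per-group short/long tilt plus the healthy
#' fragment-length mixture; each patient's tumor carries `n_altered_arms`
#' arms with multiplicative count effects `2^(+/-u)`, `u ~ U(0.2, 1)`, a
#' patient-specific profile tilt, and the short-shifted tumor length
#' mixture. A sample at tumor fraction theta draws per-bin short/long counts
#' from Poisson means mixing the archetypes `(1 - theta)` / `theta` (with
#' per-sample GC bias and per-arm log-normal wobble) and a length histogram
#' from the theta-mixed length model. Tumor fraction decays exponentially
#' from baseline to a nadir, holds it until a per-patient progression time,
#' then regrows. Labels
#' are ddPCR-like: mutant droplets `~ Binomial(droplet_count, theta * s)`
#' with per-patient clonality `s ~ Beta(50, 2.5)`; below `lod_droplets`
#' mutant droplets the MAF label is 0 and flagged undetectable. A healthy
#' panel of `n_panel` tumor-fraction-0 samples is generated alongside.
#' Fully deterministic given the config seed.
#'
#' @param config a `sim_config`.
#' @param tiling a `delfi_tiling`.
#' @return list with `samples` (per-draw list: `counts`, ids, `date`,
#'   `maf_label`, `detectable`, `truth_tf`), `panel` (list of
#'   `binned_counts`), `cohort` (metadata tibble including truth columns),
#'   `patients` (per-patient truth: trajectory parameters, altered arms,
#'   clinical dates), `archetype` (expected healthy structure, for
#'   diagnostics), and `config`.
#' @export
simulate_cohort <- function(config, tiling) {
  stopifnot(inherits(config, "sim_config"), inherits(tiling, "delfi_tiling"))
  arms <- attr(tiling, "arms")
  n_alt <- min(config$n_altered_arms, length(arms))
  arch <- healthy_archetype(tiling, config)
  withr::with_seed(config$seed, {
    nb <- nrow(tiling)
    G <- n_groups(tiling)
    grp <- tiling$group5mb
    gof <- function(v_g) {                    # per-group value -> per-bin
      out <- rep(0, nb)
      out[!is.na(grp)] <- v_g[grp[!is.na(grp)]]
      out
    }
    a_g <- arch$a_g
    cohort_start <- as.Date("2020-01-06")
    patients <- vector("list", config$n_patients)
    samples <- list()
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", i)
      theta0 <- runif(1L, config$tf_range[1L], config$tf_range[2L])
      clon <- rbeta(1L, 50, 2.5)
      parch <- draw_patient_tumor(arch, tiling, n_alt)
      alt <- parch$alt
      t_prog <- runif(1L, 70, 160)
      treatment_start <- cohort_start + 3L * (i - 1L)
      progression_date <- treatment_start + round(t_prog)
      patients[[i]] <- tibble::tibble(
        patient_id = pid, theta0 = theta0, clonality = clon,
        truth_arms = paste(alt, collapse = ","),
        treatment_start = as.character(treatment_start),
        progression_date = as.character(progression_date))
      days <- (seq_len(config$draws_per_patient) - 1L) * config$draw_interval_days
      for (d in seq_along(days)) {
        t <- days[d]
        theta <- min(0.5, theta0 *
                       max(exp(-config$response_decay * min(t, t_prog)),
                           config$nadir_fraction) *
                       exp(config$regrowth_rate * max(0, t - t_prog)))
        sid <- sprintf("%s_T%d", pid, d - 1L)
        counts <- simulate_sample_counts(sid, theta, arch, parch, config, tiling)
        k <- rbinom(1L, config$droplet_count, min(1, theta * clon))
        detectable <- k >= config$lod_droplets
        samples[[length(samples) + 1L]] <- list(
          counts = counts, sample_id = sid, patient_id = pid,
          date = as.character(treatment_start + t),
          maf_label = if (detectable) 100 * k / config$droplet_count else 0,
          detectable = detectable, truth_tf = theta)
      }
    }
    panel <- lapply(seq_len(config$n_panel), function(i) {
      parch0 <- list(ts = arch$hs, tl = arch$hl)  # unused at theta = 0
      simulate_sample_counts(sprintf("panel_%02d", i), 0, arch, parch0, config, tiling)
    })
    cohort <- do.call(rbind, lapply(samples, function(s) tibble::tibble(
      sample_id = s$sample_id, patient_id = s$patient_id, date = s$date,
      maf_label = s$maf_label, detectable = s$detectable,
      truth_tf = s$truth_tf)))
    pts <- do.call(rbind, patients)
    cohort <- merge(cohort, pts[, c("patient_id", "treatment_start", "progression_date")],
                    by = "patient_id", sort = FALSE)
    list(samples = samples, panel = panel,
         cohort = tibble::as_tibble(cohort[order(cohort$sample_id), ]),
         patients = pts, archetype = arch, config = config)
  })
}

#' Write a simulated cohort to disk
#'
#' Writes a cohort metadata TSV (truth columns prefixed `truth_`), a feature
#' export-safe metadata TSV without truth columns, per-sample counts and
#' length-histogram TSVs, and optionally per-sample BED fragment files. BED
#' emission realizes each bin's short and long counts as fragments whose
#' midpoints fall in the bin, with lengths drawn from the class-conditional
#' mixed length model, so re-binning a BED reproduces the sample's short and
#' long counts exactly.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param tiling the tiling used (required when `bed = TRUE`).
#' @param bed also emit per-sample BED fragment files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, tiling = NULL, bed = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- sim$cohort
  data.table::fwrite(meta, file.path(dir, "cohort_metadata.tsv"), sep = "\t")
  public <- meta[, setdiff(names(meta), grep("^truth_", names(meta), value = TRUE))]
  data.table::fwrite(public, file.path(dir, "cohort_labels.tsv"), sep = "\t")
  data.table::fwrite(sim$patients, file.path(dir, "patients.tsv"), sep = "\t")
  for (s in sim$samples) {
    write_counts(s$counts, file.path(dir, paste0(s$sample_id, "_counts.tsv")),
                 file.path(dir, paste0(s$sample_id, "_lengths.tsv")))
    if (bed) {
      stopifnot(!is.null(tiling))
      write_sample_bed(s$counts, tiling, file.path(dir, paste0(s$sample_id, ".bed")))
    }
  }
  for (p in sim$panel)
    write_counts(p, file.path(dir, paste0(p$sample_id, "_counts.tsv")),
                 file.path(dir, paste0(p$sample_id, "_lengths.tsv")))
  invisible(dir)
}

# realize bin-level short/long counts as BED fragments (midpoint in bin)
write_sample_bed <- function(counts, tiling, path) {
  grid <- LENGTH_WINDOW[1L]:LENGTH_WINDOW[2L]
  hist <- counts$length_hist
  draw_lengths <- function(n, range) {
    sel <- grid >= range[1L] & grid <= range[2L]
    p <- hist[sel]
    if (sum(p) == 0) p <- rep(1, sum(sel))
    sample(grid[sel], n, replace = TRUE, prob = p)
  }
  rows <- lapply(which(counts$short + counts$long > 0), function(b) {
    ns <- counts$short[b]
    nl <- counts$long[b]
    len <- c(draw_lengths(ns, SHORT_RANGE), draw_lengths(nl, LONG_RANGE))
    # keep midpoints >= 200 bp into the genome so starts never clamp at 0
    mid <- floor(runif(ns + nl, max(tiling$start[b], 200), tiling$end[b]))
    start <- mid - len %/% 2L
    data.frame(chrom = tiling$chrom[b], start = as.integer(start),
               end = as.integer(start + len))
  })
  bedr <- do.call(rbind, rows)
  data.table::fwrite(bedr, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
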