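# Fragmentome features: GC correction, 5-Mb short/long profiles, arm-level
# aneuploidy z-scores, and the plasma aneuploidy (PA) score.

#' GC-correct per-bin fragment counts
#'
#' Removes GC-dependent coverage bias by additive residual correction around
#' the per-sample median: a locally weighted regression of counts on GC
#' fraction (span 0.75, 2 robustness iterations) is fitted, and
#' `corrected = raw - fitted + median(raw)`, floored at zero. Applied
#' separately to short and to long counts.
#'
#' @param counts numeric vector of raw per-bin counts.
#' @param gc per-bin GC fractions aligned with `counts`.
#' @return numeric vector of corrected counts (non-negative, same length).
#' @export
gc_correct <- function(counts, gc) {
  stopifnot(length(counts) == length(gc))
  if (all(counts == 0)) return(counts)
  if (diff(range(gc)) < .Machine$double.eps) {
    # constant GC: nothing to fit; recentre on the median only
    return(pmax(counts - mean(counts) + median(counts), 0))
  }
  fit <- lowess(gc, counts, f = 0.75, iter = 2)
  fitted <- approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
  pmax(counts - fitted + median(counts), 0)
}

#' GC-corrected short/long fragmentation profile over 5-Mb groups
#'
#' Sums GC-corrected short and long counts over each group's 50 bins and
#' returns the per-group short-to-long ratio. A group whose corrected long
#' count is zero gets a missing ratio; the sample is rejected if more than 5%
#' of groups are missing.
#'
#' @param short_corr,long_corr GC-corrected per-bin count vectors.
#' @param tiling a `delfi_tiling`.
#' @return numeric vector of length `n_groups(tiling)` (NA where missing),
#'   with attribute `n_missing`.
#' @export
short_long_profile <- function(short_corr, long_corr, tiling) {
  grp <- tiling$group5mb
  keep <- !is.na(grp)
  G <- n_groups(tiling)
  s <- rowsum(short_corr[keep], grp[keep])
  ids <- as.integer(rownames(s))
  l <- rowsum(long_corr[keep], grp[keep])[, 1L]
  ratio <- rep(NA_real_, G)
  ratio[ids] <- ifelse(l > 0, s[, 1L] / l, NA_real_)
  n_missing <- sum(is.na(ratio))
  if (n_missing > 0.05 * G)
    delfi_error(sprintf("sample rejected: %d of %d 5-Mb groups have zero long counts",
                        n_missing, G), "delfi_sample_error")
  attr(ratio, "n_missing") <- n_missing
  ratio
}

#' Correlation of a fragmentation profile with the healthy reference
#'
#' Pearson correlation of the per-group short/long ratios with the healthy
#' panel's median profile; missing ratios are imputed with the panel median.
#'
#' @param profile per-group ratio vector.
#' @param panel a `healthy_panel`.
#' @return correlation in \[-1, 1\], or `NA` with a warning for a
#'   zero-variance profile.
#' @export
profile_correlation <- function(profile, panel) {
  stopifnot(length(profile) == length(panel$median_profile))
  miss <- is.na(profile)
  profile[miss] <- panel$median_profile[miss]
  if (sd(profile) < .Machine$double.eps) {
    warning("zero-variance profile: correlation undefined")
    return(NA_real_)
  }
  cor(profile, panel$median_profile)
}

# per-arm fraction of total corrected (short+long) counts
arm_fractions <- function(short_corr, long_corr, tiling) {
  tot <- short_corr + long_corr
  arms <- attr(tiling, "arms")
  f <- rowsum(tot, factor(tiling$arm, levels = arms))[, 1L]
  f / sum(f)
}

#' Arm-level aneuploidy z-scores
#'
#' For each scored chromosome arm, the sample's fraction of total corrected
#' (short+long) fragment counts on that arm is standardized against the
#' healthy panel's per-arm mean and standard deviation. Also reports the two
#' largest absolute z-scores (model features), ties broken by arm label order.
#'
#' @param counts a `binned_counts` of GC-corrected counts, or a list with
#'   `short`/`long` corrected vectors.
#' @param tiling a `delfi_tiling`.
#' @param panel a `healthy_panel` with `arm_mean` and `arm_sd`.
#' @return list with `z` (named vector, one per arm), `top1_abs`, `top2_abs`.
#' @export
arm_zscores <- function(counts, tiling, panel) {
  if (any(panel$arm_sd <= 0))
    delfi_error("invalid healthy panel: non-positive arm sd", "delfi_config_error")
  f <- arm_fractions(counts$short, counts$long, tiling)
  stopifnot(identical(names(f), names(panel$arm_mean)))
  z <- (f - panel$arm_mean) / panel$arm_sd
  ord <- order(-abs(z), names(z))
  list(z = z, top1_abs = abs(z[[ord[1L]]]),
       top2_abs = if (length(z) >= 2L) abs(z[[ord[2L]]]) else 0)
}

#' Plasma aneuploidy score
#'
#' Takes each chromosome's maximum-|z| arm, ranks chromosomes by that |z|,
#' keeps the top five, converts each |z| to a two-sided p-value under a
#' Student's t distribution with 3 degrees of freedom (floored at 1e-300),
#' and returns the negative sum of the natural-log p-values. Zero when all
#' z-scores are zero; monotone non-decreasing in any selected |z|.
#'
#' @param z named vector of arm z-scores (names like "1p", "17q").
#' @return non-negative scalar.
#' @export
pa_score <- function(z) {
  z <- z[is.finite(z)]
  chrom <- sub("[pq]$", "", names(z))
  if (length(unique(chrom)) < 5L)
    delfi_error("PA-score needs z-scores on at least 5 chromosomes",
                "delfi_config_error")
  per_chrom <- tapply(abs(z), chrom, max)
  top5 <- sort(per_chrom, decreasing = TRUE)[1:5]
  p <- pmax(2 * pt(top5, df = 3, lower.tail = FALSE), 1e-300)
  -sum(log(p))
}

#' Build the healthy reference panel
#'
#' Computes the reference statistics used to score samples, from a set of
#' non-cancer samples on the same tiling: per-arm mean and standard deviation
#' of GC-corrected count fractions, the per-group median short/long ratio
#' profile, and the shared 12-component fragment-length mixture fitted to the
#' pooled panel lengths (per-sample scoring later refits only the weights).
#'
#' @param panel_counts list of `binned_counts` for non-cancer samples
#'   (at least 2; the spec's panels use 20+).
#' @param tiling a `delfi_tiling`.
#' @param k number of mixture components (default 12).
#' @param seed RNG seed forwarded to the mixture fit.
#' @return a `healthy_panel`: list with `arm_mean`, `arm_sd`,
#'   `median_profile`, `base_components`, `n_samples`.
#' @export
build_healthy_panel <- function(panel_counts, tiling, k = 12L, seed = 1L) {
  stopifnot(length(panel_counts) >= 2L)
  arms <- attr(tiling, "arms")
  fr <- matrix(NA_real_, length(panel_counts), length(arms),
               dimnames = list(NULL, arms))
  prof <- matrix(NA_real_, length(panel_counts), n_groups(tiling))
  pooled <- numeric(diff(LENGTH_WINDOW) + 1L)
  for (i in seq_along(panel_counts)) {
    cc <- panel_counts[[i]]
    sc <- gc_correct(cc$short, tiling$gc)
    lc <- gc_correct(cc$long, tiling$gc)
    fr[i, ] <- arm_fractions(sc, lc, tiling)
    prof[i, ] <- short_long_profile(sc, lc, tiling)
    pooled <- pooled + cc$length_hist
  }
  arm_sd <- apply(fr, 2L, sd)
  if (any(arm_sd <= 0))
    delfi_error("healthy panel has a zero-variance arm", "delfi_config_error")
  structure(list(
    arm_mean = colMeans(fr),
    arm_sd = arm_sd,
    median_profile = apply(prof, 2L, median, na.rm = TRUE),
    base_components = fit_base_components(hist_counts = pooled, k = k, seed = seed),
    n_samples = length(panel_counts)),
    class = "healthy_panel")
}

#' Featurize one sample against a tiling and healthy panel
#'
#' Runs the full per-sample feature pipeline: GC correction of short and long
#' counts, 5-Mb short/long profile, profile-vs-healthy correlation, arm
#' z-scores with the two largest magnitudes, PA-score, and the 12 re-fitted
#' mixture weights (the first 11 are model features).
#'
#' @param counts a `binned_counts`.
#' @param tiling a `delfi_tiling`.
#' @param panel a `healthy_panel`.
#' @return list with `features` (named numeric: w1..w11, pa, z_top1, z_top2),
#'   `profile` (per-group ratios), `correlation`, `z` (all arm z-scores),
#'   `weights` (all 12 weights).
#' @export
featurize_sample <- function(counts, tiling, panel) {
  sc <- gc_correct(counts$short, tiling$gc)
  lc <- gc_correct(counts$long, tiling$gc)
  profile <- short_long_profile(sc, lc, tiling)
  arm <- arm_zscores(list(short = sc, long = lc), tiling, panel)
  w <- sample_length_weights(hist_counts = counts$length_hist,
                             base = panel$base_components)
  features <- c(setNames(w[1:11], paste0("w", 1:11)),
                pa = pa_score(arm$z), z_top1 = arm$top1_abs, z_top2 = arm$top2_abs)
  list(features = features, profile = profile,
       correlation = profile_correlation(profile, panel),
       z = arm$z, weights = w)
}

#' Featurize a cohort of samples
#'
#' Applies [featurize_sample()] to a list of samples (as produced by
#' [simulate_cohort()] or assembled from [bin_fragments()] output plus
#' labels) and assembles the model's input tables.
#'
#' @param samples list; each element needs `counts` (a `binned_counts`) and
#'   optionally `sample_id`, `patient_id`, `date`, `maf_label`, `detectable`.
#' @param tiling a `delfi_tiling`.
#' @param panel a `healthy_panel`.
#' @return a `delfi_features` object: list with `meta` (tibble of ids, labels,
#'   the 14 non-PC features and the healthy-profile correlation) and
#'   `profiles` (samples x groups ratio matrix).
#' @export
featurize_cohort <- function(samples, tiling, panel) {
  rows <- vector("list", length(samples))
  profiles <- matrix(NA_real_, length(samples), n_groups(tiling))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    f <- featurize_sample(s$counts, tiling, panel)
    profiles[i, ] <- f$profile
    rows[[i]] <- tibble::tibble(
      sample_id = s$sample_id %||% s$counts$sample_id,
      patient_id = s$patient_id %||% NA_character_,
      date = as.character(s$date %||% NA_character_),
      maf_label = as.numeric(s$maf_label %||% NA_real_),
      detectable = isTRUE(s$detectable),
      cor_healthy = f$correlation,
      !!!as.list(f$features))
  }
  meta <- do.call(rbind, rows)
  # impute any missing group ratio with the panel median before modelling
  for (j in seq_len(ncol(profiles))) {
    miss <- is.na(profiles[, j])
    if (any(miss)) profiles[miss, j] <- panel$median_profile[j]
  }
  structure(list(meta = meta, profiles = profiles), class = "delfi_features")
}
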