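test_that("GC correction removes a constructed linear GC trend", {
  withr::local_seed(11)
  gc <- runif(5000, 0.3, 0.6)
  counts <- 100 + 200 * (gc - mean(gc))
  corr <- gc_correct(counts, gc)
  expect_true(all(abs(corr - 100) < 1))  # within 1% of the flat level
  # counts independent of GC are left essentially unchanged
  flat <- rpois(5000, 100)
  corr2 <- gc_correct(flat, gc)
  expect_lt(max(abs(corr2 - flat)), 0.1 * median(flat))
  # identities
  expect_equal(gc_correct(rep(7, 100), runif(100, .3, .6)), rep(7, 100))
  expect_equal(gc_correct(numeric(100), gc[1:100]), numeric(100))
  expect_equal(gc_correct(counts[1:50], rep(0.5, 50)),
               pmax(counts[1:50] - mean(counts[1:50]) + median(counts[1:50]), 0))
})

test_that("a residual GC fit on corrected counts is flat", {
  withr::local_seed(12)
  gc <- runif(8000, 0.3, 0.6)
  counts <- rpois(8000, 150 * (1 + 1.2 * (gc - mean(gc))))
  corr <- gc_correct(counts, gc)
  refit <- lowess(gc, corr, f = 0.75, iter = 2)
  expect_lt(max(abs(refit$y - median(corr))), 0.05 * median(corr))
})

test_that("5-Mb profiles are group ratios, scale-invariant and flag zero groups", {
  t <- pipe_tiling()
  G <- n_groups(t)
  short <- rep(120, nrow(t))
  long <- rep(100, nrow(t))
  prof <- short_long_profile(short, long, t)
  expect_equal(as.numeric(prof), rep(1.2, G))
  expect_equal(short_long_profile(2 * short, 2 * long, t), prof)
  # one zero-long group is flagged missing; too many reject the sample
  long2 <- long
  long2[which(t$group5mb == 1)] <- 0
  prof2 <- short_long_profile(short, long2, t)
  expect_true(is.na(prof2[1]))
  expect_equal(attr(prof2, "n_missing"), 1L)
  long3 <- long
  long3[!is.na(t$group5mb) & t$group5mb <= ceiling(0.06 * G)] <- 0
  expect_error(short_long_profile(short, long3, t), class = "delfi_sample_error")
})

test_that("profile correlation matches the direct formula and its boundary cases", {
  panel <- pipe_panel()
  mp <- panel$median_profile
  expect_equal(profile_correlation(mp, panel), 1)
  refl <- -(mp - mean(mp)) + mean(mp)
  expect_equal(profile_correlation(refl, panel), -1)
  withr::local_seed(3)
  r <- runif(length(mp), 0.3, 0.7)
  expect_equal(profile_correlation(r, panel), cor(r, mp))
  expect_warning(out <- profile_correlation(rep(1, length(mp)), panel), "zero-variance")
  expect_true(is.na(out))
})

test_that("arm z-scores standardize arm count fractions against the panel", {
  t <- pipe_tiling()
  panel <- pipe_panel()
  arms <- attr(t, "arms")
  # a sample sitting exactly at the panel mean has all z = 0
  base <- panel$arm_mean[t$arm] * 1e6 / as.numeric(table(t$arm)[t$arm])
  at_mean <- list(short = base / 2, long = base / 2)
  z0 <- arm_zscores(at_mean, t, panel)
  expect_equal(unname(z0$z), rep(0, length(arms)), tolerance = 1e-10)
  expect_equal(z0$top1_abs, 0)
  # doubling one arm makes it the unique maximum |z|; brute-force fractions agree
  doubled <- at_mean
  doubled$short[t$arm == "3q"] <- doubled$short[t$arm == "3q"] * 2
  z1 <- arm_zscores(doubled, t, panel)
  expect_equal(names(which.max(abs(z1$z))), "3q")
  tot <- doubled$short + doubled$long
  frac <- tapply(tot, factor(t$arm, levels = arms), sum) / sum(tot)
  zb <- (frac - panel$arm_mean) / panel$arm_sd
  expect_equal(unname(z1$z), unname(as.numeric(zb)))
  # top1/top2 ordering
  fake <- panel
  z <- setNames(c(3, -5, 0, rep(0, length(arms) - 3)), arms)
  ord <- sort(abs(z), decreasing = TRUE)
  expect_equal(unname(ord[1:2]), c(5, 3))
})

test_that("PA-score follows the t(3) tail formula over the top five chromosomes", {
  arms <- c(paste0(1:10, "p"), paste0(1:10, "q"))
  expect_equal(pa_score(zvec(rep(0, 20), arms)), 0)
  # five selected |z| at the one-tailed 1% t(3) critical value
  z <- zvec(rep(0, 20), arms)
  z[c("1p", "2q", "3p", "4q", "5p")] <- c(4.541, -4.541, 4.541, 4.541, -4.541)
  expect_equal(pa_score(z), -5 * log(0.02), tolerance = 1e-3)
  # per-chromosome max: both arms extreme on one chromosome count once
  z2 <- zvec(rep(0, 20), arms)
  z2[c("1p", "1q")] <- 8
  z2[c("2p", "3p", "4p", "5p")] <- 4
  manual <- -(log(pmax(2 * pt(8, 3, lower.tail = FALSE), 1e-300)) +
                4 * log(pmax(2 * pt(4, 3, lower.tail = FALSE), 1e-300)))
  expect_equal(pa_score(z2), manual)
  # permutation invariance and brute-force equality on random z
  withr::local_seed(5)
  for (i in 1:5) {
    zr <- zvec(rnorm(20, sd = 3), arms)
    perm <- sample(20)
    expect_equal(pa_score(zr[perm]), pa_score(zr))
    per_chrom <- tapply(abs(zr), sub("[pq]$", "", names(zr)), max)
    top5 <- sort(per_chrom, decreasing = TRUE)[1:5]
    expect_equal(pa_score(zr), -sum(log(pmax(2 * pt(top5, 3, lower.tail = FALSE), 1e-300))))
  }
  # monotonicity: inflating a selected z never decreases the score
  z3 <- zvec(abs(rnorm(20, sd = 2)), arms)
  sel <- names(which.max(z3))
  z4 <- z3
  z4[sel] <- z4[sel] + 1
  expect_gte(pa_score(z4), pa_score(z3))
  expect_error(pa_score(zvec(c(1, 2), c("1p", "2p"))), class = "delfi_config_error")
})
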