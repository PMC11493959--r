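test_that("profile PCA centers, normalizes, and captures a planted direction", {
  withr::local_seed(21)
  G <- 60
  direction <- rnorm(G)
  direction <- direction / sqrt(sum(direction^2))
  scores <- rnorm(40, sd = 5)
  X <- outer(scores, direction) + matrix(rnorm(40 * G, sd = 0.01), 40)
  pca <- fit_pca(X)
  expect_equal(sqrt(rowSums(pca$loadings^2)), c(pc1 = 1, pc2 = 1))
  # pc1 aligns with the planted direction
  expect_gt(abs(sum(pca$loadings[1, ] * direction)), 0.999)
  # projecting the training mean gives (0, 0)
  expect_equal(as.numeric(project_pca <- (matrix(colMeans(X), 1) - matrix(pca$center, 1)) %*%
                            t(pca$loadings)), c(0, 0), tolerance = 1e-12)
  # pc1 variance dominates
  proj <- sweep(X, 2, pca$center) %*% t(pca$loadings)
  expect_gt(var(proj[, 1]) / (var(proj[, 1]) + var(proj[, 2])), 0.99)
  expect_error(fit_pca(X[1:2, ]), class = "delfi_config_error")
  expect_error(fit_pca(matrix(rep(1:5, 3), 5, 3)), class = "delfi_config_error")
})

test_that("training is deterministic and fits separable synthetic data", {
  pc <- pipe_cohort()
  m1 <- train(pc$feats, pc$panel, seed = 7)
  m2 <- train(pc$feats, pc$panel, seed = 7)
  s1 <- score(m1, pc$feats)
  s2 <- score(m2, pc$feats)
  expect_identical(s1$delfi_tf, s2$delfi_tf)
  expect_true(all(s1$delfi_tf >= 0 & s1$delfi_tf <= 100))
  # in-sample predictions track labels on separable data
  expect_gt(cor(s1$delfi_tf, pc$feats$meta$maf_label), 0.9)
  # constant labels give constant predictions
  fc <- pc$feats
  fc$meta$maf_label <- rep(5, nrow(fc$meta))
  mc <- train(fc, pc$panel, seed = 7)
  expect_equal(score(mc, fc)$delfi_tf, rep(5, nrow(fc$meta)), tolerance = 1e-9)
})

test_that("leave-one-patient-out folds are leak-free and order-invariant", {
  pc <- pipe_cohort()
  cv <- lopo_cv(pc$feats, seed = 7)
  expect_equal(nrow(cv), nrow(pc$feats$meta))
  expect_true(all(cv$fold == cv$patient_id))
  # a patient's own out-of-fold scores cannot depend on that patient's labels
  # (the held-out patient is excluded from their fold's training data), while
  # other patients' folds, which train on the perturbed patient, do change
  pert <- pc$feats
  p1 <- pert$meta$patient_id == "P001"
  pert$meta$maf_label[p1] <- pert$meta$maf_label[p1] + 25
  cv2 <- lopo_cv(pert, seed = 7)
  expect_identical(cv2$delfi_tf[p1], cv$delfi_tf[p1])
  expect_false(identical(cv2$delfi_tf[!p1], cv$delfi_tf[!p1]))
  # permuting sample order within the table leaves per-sample scores unchanged
  perm <- sample(nrow(pc$feats$meta))
  shuf <- list(meta = pc$feats$meta[perm, ], profiles = pc$feats$profiles[perm, ])
  class(shuf) <- "delfi_features"
  cv3 <- lopo_cv(shuf, seed = 7)
  expect_equal(cv3$delfi_tf[match(cv$sample_id, cv3$sample_id)], cv$delfi_tf)
})

test_that("out-of-fold recovery of true burden holds across simulator seeds", {
  t <- pipe_tiling()
  r <- vapply(c(1, 2, 3), function(s) {
    cfg <- simulation_config(n_patients = 12, draws_per_patient = 3,
                             coverage = 6e4, n_panel = 10, seed = s)
    sim <- simulate_cohort(cfg, t)
    panel <- build_healthy_panel(sim$panel, t, seed = s)
    feats <- featurize_cohort(sim$samples, t, panel)
    cv <- lopo_cv(feats, seed = s)
    cor(cv$delfi_tf[cv$detectable], cv$maf_label[cv$detectable])
  }, numeric(1))
  expect_gte(median(r), 0.85)
  expect_gte(r[1], 0.90)
})

test_that("locked-model scoring is consistent with training and guards the tiling", {
  pc <- pipe_cohort()
  m <- train(pc$feats, pc$panel, seed = 7)
  s <- score(m, pc$feats)
  expect_identical(s$delfi_tf, score(m, pc$feats)$delfi_tf)
  wrong <- list(meta = pc$feats$meta, profiles = pc$feats$profiles[, 1:10])
  class(wrong) <- "delfi_features"
  expect_error(score(m, wrong), class = "delfi_validation_error")
})

test_that("grouped importances sum to one and follow the informative group", {
  pc <- pipe_cohort()
  m <- train(pc$feats, pc$panel, seed = 7)
  gi <- grouped_importance(m)
  expect_equal(sum(gi), 1, tolerance = 1e-9)
  expect_named(gi, c("chromosomal", "mixture", "sl"))
  # labels driven only by the PA-score concentrate importance on that group
  fpa <- pc$feats
  fpa$meta$maf_label <- fpa$meta$pa
  mpa <- train(fpa, pc$panel, seed = 7)
  expect_gt(grouped_importance(mpa)[["chromosomal"]], 0.5)
  # pure-noise labels spread importance across groups
  withr::local_seed(3)
  fn <- pc$feats
  fn$meta$maf_label <- runif(nrow(fn$meta), 0, 10)
  mn <- train(fn, pc$panel, seed = 7)
  expect_lt(max(grouped_importance(mn)), 0.9)
})
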