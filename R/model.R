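# DELFI-TF model: PCA over fragmentation profiles, random-forest regression
# of ddPCR MAF on the 16-feature vector, leave-one-patient-out
# cross-validation, and locked-model scoring.

FEATURE_GROUPS <- list(
  chromosomal = c("pa", "z_top1", "z_top2"),
  mixture = paste0("w", 1:11),
  sl = c("pc1", "pc2"))

#' Default forest hyperparameters
#'
#' 1000 trees, a third of the 16 features tried per split, minimum leaf size
#' 2. All overridable wherever a `hyper` argument is accepted.
#'
#' @param num_trees,mtry,min_node_size forest controls.
#' @return named list of hyperparameters.
#' @export
default_hyper <- function(num_trees = 1000L, mtry = 5L, min_node_size = 2L) {
  list(num_trees = as.integer(num_trees), mtry = as.integer(mtry),
       min_node_size = as.integer(min_node_size))
}

#' Principal components of fragmentation profiles
#'
#' Column-centers the training samples x groups ratio matrix (no scaling) and
#' retains the top two right singular vectors. Loading signs are fixed so the
#' largest-magnitude entry of each loading is positive, making projections
#' reproducible across SVD implementations.
#'
#' @param profiles numeric matrix, training samples in rows, 5-Mb groups in
#'   columns; needs at least 3 rows and rank 2.
#' @return list with `center` (column means) and `loadings` (2 x groups,
#'   orthonormal rows).
#' @export
fit_pca <- function(profiles) {
  if (nrow(profiles) < 3L)
    delfi_error("PCA needs at least 3 training samples", "delfi_config_error")
  center <- colMeans(profiles)
  sv <- svd(sweep(profiles, 2L, center), nu = 0, nv = 2L)
  if (length(sv$d) < 2L || sv$d[2L] < 1e-12 * sv$d[1L])
    delfi_error("profile matrix has rank < 2", "delfi_config_error")
  loadings <- t(sv$v)
  for (r in 1:2) {
    j <- which.max(abs(loadings[r, ]))
    if (loadings[r, j] < 0) loadings[r, ] <- -loadings[r, ]
  }
  rownames(loadings) <- c("pc1", "pc2")
  list(center = center, loadings = loadings)
}

project_pca <- function(pca, profiles) {
  sweep(profiles, 2L, pca$center) %*% t(pca$loadings)
}

# assemble the 16-column feature matrix (data.frame) for the forest
feature_matrix <- function(features, pca) {
  meta <- features$meta
  pcs <- project_pca(pca, features$profiles)
  X <- as.data.frame(meta[, c(paste0("w", 1:11), "pa", "z_top1", "z_top2")])
  X$pc1 <- pcs[, 1L]
  X$pc2 <- pcs[, 2L]
  bad <- !apply(X, 1L, function(r) all(is.finite(r)))
  if (any(bad))
    delfi_error(paste("non-finite features for sample(s):",
                      paste(meta$sample_id[bad], collapse = ", ")),
                "delfi_validation_error")
  X
}

#' Train the DELFI-TF model on labeled samples
#'
#' Fits the profile PCA on all provided samples, assembles the 16-feature
#' matrix (11 mixture weights, PA-score, two largest |z|, two profile PCs),
#' and fits a random-forest regressor against the ddPCR MAF labels (percent).
#' Reproducible bit-for-bit given identical inputs and seed.
#'
#' @param features a `delfi_features` from [featurize_cohort()], with
#'   `maf_label` populated.
#' @param panel the `healthy_panel` the features were computed against
#'   (stored in the model so locked-model scoring uses the same reference).
#' @param hyper hyperparameters from [default_hyper()].
#' @param seed integer seed for the forest.
#' @param include_undetectable keep samples with undetectable ddPCR (label 0)
#'   in training (default TRUE).
#' @return a `delfi_model`.
#' @export
train <- function(features, panel = NULL, hyper = default_hyper(), seed = 1L,
                  include_undetectable = TRUE) {
  meta <- features$meta
  keep <- rep(TRUE, nrow(meta))
  if (!include_undetectable) keep <- meta$detectable
  if (sum(keep) < 2L) delfi_error("need at least 2 training samples", "delfi_config_error")
  if (length(unique(meta$patient_id[keep])) < 2L)
    delfi_error("need at least 2 patients", "delfi_config_error")
  if (any(!is.finite(meta$maf_label[keep])))
    delfi_error(paste("non-finite label for sample(s):",
                      paste(meta$sample_id[keep][!is.finite(meta$maf_label[keep])],
                            collapse = ", ")), "delfi_validation_error")
  # canonical training order: forest fits are invariant to input sample order
  sub <- list(meta = meta[keep, ], profiles = features$profiles[keep, , drop = FALSE])
  ord <- order(sub$meta$sample_id)
  sub <- list(meta = sub$meta[ord, ], profiles = sub$profiles[ord, , drop = FALSE])
  pca <- fit_pca(sub$profiles)
  X <- feature_matrix(sub, pca)
  X$.y <- sub$meta$maf_label
  forest <- ranger::ranger(
    dependent.variable.name = ".y", data = X,
    num.trees = hyper$num_trees, mtry = hyper$mtry,
    min.node.size = hyper$min_node_size, importance = "impurity",
    seed = seed, num.threads = 1L)
  structure(list(forest = forest, pca = pca, panel = panel, hyper = hyper,
                 seed = as.integer(seed),
                 n_groups = ncol(features$profiles),
                 label_range = c(0, max(sub$meta$maf_label))),
            class = "delfi_model")
}

#' @export
print.delfi_model <- function(x, ...) {
  cat(sprintf("<delfi_model> %d trees, %d profile groups, labels in [0, %.2f]%%\n",
              x$hyper$num_trees, x$n_groups, x$label_range[2L]))
  invisible(x)
}

#' Score samples with a locked model
#'
#' Deterministic prediction of DELFI-TF (predicted MAF, percent) for new
#' samples featurized against the same tiling and healthy panel the model was
#' trained with. No component is refitted. Predictions are clipped to
#' \[0, 100\].
#'
#' @param model a `delfi_model`.
#' @param features a `delfi_features`.
#' @return tibble `sample_id patient_id delfi_tf`.
#' @export
score <- function(model, features) {
  if (ncol(features$profiles) != model$n_groups)
    delfi_error(sprintf("tiling mismatch: model expects %d profile groups, got %d",
                        model$n_groups, ncol(features$profiles)),
                "delfi_validation_error")
  X <- feature_matrix(features, model$pca)
  pred <- predict(model$forest, data = X, num.threads = 1L)$predictions
  tibble::tibble(sample_id = features$meta$sample_id,
                 patient_id = features$meta$patient_id,
                 delfi_tf = pmin(pmax(pred, 0), 100))
}

#' Leave-one-patient-out cross-validated DELFI-TF scores
#'
#' For each patient in turn, the profile PCA and the forest are refitted on
#' all other patients' samples and the held-out patient's samples are scored;
#' DELFI-TF is defined as these out-of-fold predictions. The healthy panel
#' statistics and mixture base components are not refit per fold (they derive
#' from non-cancer samples outside the labeled cohort).
#'
#' @inheritParams train
#' @return a `ScoreTable` tibble: `sample_id patient_id fold delfi_tf`
#'   plus the input's `maf_label`/`detectable` columns for convenience.
#' @export
lopo_cv <- function(features, hyper = default_hyper(), seed = 1L,
                    include_undetectable = TRUE) {
  meta <- features$meta
  patients <- unique(meta$patient_id)
  if (length(patients) < 3L)
    delfi_error("leave-one-patient-out CV needs at least 3 patients",
                "delfi_config_error")
  out <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p <- patients[i]
    hold <- meta$patient_id == p
    if (!any(hold)) {
      warning(sprintf("patient %s has no samples; skipped", p))
      next
    }
    tr <- list(meta = meta[!hold, ], profiles = features$profiles[!hold, , drop = FALSE])
    te <- list(meta = meta[hold, ], profiles = features$profiles[hold, , drop = FALSE])
    m <- train(tr, panel = NULL, hyper = hyper, seed = seed,
               include_undetectable = include_undetectable)
    sc <- score(m, te)
    sc$fold <- p
    sc$maf_label <- te$meta$maf_label
    sc$detectable <- te$meta$detectable
    out[[i]] <- sc
  }
  res <- do.call(rbind, out)
  res[match(meta$sample_id, res$sample_id), ]
}

#' Grouped feature importance
#'
#' Sums the forest's impurity importances within the three feature groups --
#' chromosomal (PA-score and the two top |z|), mixture (the 11 weights) and
#' short/long profile (the two PCs) -- and returns fractions of the total.
#'
#' @param model a `delfi_model`.
#' @return named numeric vector (`chromosomal`, `mixture`, `sl`) summing to 1.
#' @export
grouped_importance <- function(model) {
  imp <- ranger::importance(model$forest)
  g <- vapply(FEATURE_GROUPS, function(f) sum(imp[f]), numeric(1L))
  g / sum(g)
}
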