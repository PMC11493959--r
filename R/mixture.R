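# 12-component normal mixture summarizing the genome-wide fragment-length
# distribution. The components (means and sds) are fitted once on pooled
# healthy-panel lengths; per-sample scoring refits only the weights, so the
# 11 weight features are comparable across samples.

as_length_hist <- function(lengths = NULL, hist_counts = NULL) {
  if (is.null(hist_counts)) {
    stopifnot(!is.null(lengths), length(lengths) > 0L)
    hist_counts <- lengths_to_hist(lengths)
  }
  stopifnot(length(hist_counts) == diff(LENGTH_WINDOW) + 1L)
  hist_counts
}

mixture_density_matrix <- function(means, sds) {
  x <- LENGTH_WINDOW[1L]:LENGTH_WINDOW[2L]
  outer(x, seq_along(means), function(i, k) dnorm(i, means[k], sds[k]))
}

#' Fit the shared fragment-length mixture components
#'
#' Expectation-maximization fit of a k-component univariate normal mixture to
#' fragment lengths in the 50-400 bp window (lengths are tabulated to the
#' integer bp grid; the EM operates on the weighted histogram). Means are
#' initialized evenly spaced over the window, standard deviations at 15 bp,
#' weights uniform. Convergence when the relative log-likelihood change drops
#' below `tol` or after `max_iter` iterations (a warning flag is set if the
#' iteration cap is hit). Standard deviations are floored at 0.5 bp.
#' Components are sorted by mean. With k = 12 the model has
#' 12 means + 12 sds + 11 free weights = 35 free parameters.
#'
#' @param lengths numeric vector of fragment lengths (bp), or `NULL` when
#'   `hist_counts` is given.
#' @param hist_counts optional precomputed histogram over the 50:400 grid.
#' @param k number of components (default 12).
#' @param seed RNG seed (the fit itself is deterministic given the fixed
#'   initialization; accepted for interface uniformity).
#' @param max_iter,tol EM controls.
#' @return a `length_mixture`: list with `means`, `sds`, `weights` (sorted by
#'   mean), `loglik`, `converged`, `n_params`.
#' @export
fit_base_components <- function(lengths = NULL, hist_counts = NULL, k = 12L,
                                seed = 1L, max_iter = 500L, tol = 1e-6) {
  h <- as_length_hist(lengths, hist_counts)
  n <- sum(h)
  stopifnot(n > 0)
  x <- LENGTH_WINDOW[1L]:LENGTH_WINDOW[2L]
  means <- seq(LENGTH_WINDOW[1L], LENGTH_WINDOW[2L], length.out = k)
  sds <- rep(15, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- mixture_density_matrix(means, sds)
    num <- sweep(dens, 2L, w, "*")
    tot <- rowSums(num)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(h * log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- num / tot                       # E-step: responsibilities
    nk <- colSums(h * resp)
    w <- nk / n                             # M-step
    # components with essentially no responsibility keep their parameters
    live <- nk > 1e-8
    mu_new <- colSums(h * resp * x) / pmax(nk, 1e-12)
    sd_new <- sqrt(colSums(h * resp * (outer(x, mu_new, "-"))^2) / pmax(nk, 1e-12))
    means[live] <- mu_new[live]
    sds[live] <- pmax(sd_new[live], 0.5)
  }
  if (!converged)
    warning(sprintf("mixture EM did not converge in %d iterations", max_iter))
  ord <- order(means)
  means <- means[ord]
  sds <- sds[ord]
  w <- w[ord] / sum(w)
  # degenerate input (e.g. a point mass) can drive several components onto
  # the same mean at the sd floor; such coincident components are merged
  # (weight pooled on the heaviest) and means are epsilon-spaced so the
  # component ordering stays strict
  i <- 1L
  while (i < length(means)) {
    j <- i
    while (j < length(means) && means[j + 1L] - means[i] < 0.01 &&
             sds[i] <= 0.5 + 1e-9 && sds[j + 1L] <= 0.5 + 1e-9) j <- j + 1L
    if (j > i) {
      grp <- i:j
      win <- grp[which.max(w[grp])]
      pooled <- sum(w[grp])
      w[grp] <- 0
      w[win] <- pooled
    }
    i <- j + 1L
  }
  ties <- which(diff(means) < 1e-9)
  for (t in ties) means[t + 1L] <- means[t] + 1e-6
  structure(list(means = means, sds = sds, weights = w / sum(w),
                 loglik = ll_old, converged = converged,
                 n_params = as.integer(2L * k + (k - 1L))),
            class = "length_mixture")
}

#' @export
print.length_mixture <- function(x, ...) {
  cat(sprintf("<length_mixture> %d components, %d free parameters\n",
              length(x$means), x$n_params))
  print(round(rbind(mean = x$means, sd = x$sds, weight = x$weights), 3))
  invisible(x)
}

#' Re-estimate mixture weights for one sample
#'
#' With the shared component means and standard deviations frozen, the
#' per-sample weights are re-estimated by EM over the weights only (a convex
#' problem). The first 11 weights, components sorted by mean, are the model
#' features.
#'
#' @param lengths numeric vector of one sample's fragment lengths, or `NULL`.
#' @param hist_counts optional precomputed histogram over the 50:400 grid.
#' @param base a `length_mixture` of frozen components.
#' @param max_iter,tol EM controls (max absolute weight change).
#' @return numeric vector of weights summing to 1, one per component.
#' @export
sample_length_weights <- function(lengths = NULL, hist_counts = NULL, base,
                                  max_iter = 500L, tol = 1e-10) {
  h <- as_length_hist(lengths, hist_counts)
  n <- sum(h)
  if (n == 0) delfi_error("empty fragment lengths", "delfi_sample_error")
  if (n < 500) warning("fewer than 500 fragment lengths: weights are noisy")
  dens <- mixture_density_matrix(base$means, base$sds)
  w <- rep(1 / length(base$means), length(base$means))
  for (iter in seq_len(max_iter)) {
    num <- sweep(dens, 2L, w, "*")
    tot <- rowSums(num)
    tot[tot < 1e-300] <- 1e-300
    w_new <- colSums(h * num / tot) / n
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  w
}
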