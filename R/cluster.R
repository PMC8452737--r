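as_feature_matrix <- function(feats) {
  if (inherits(feats, "encoded_features")) feats$z_mean
  else as.matrix(feats)
}

#' Gaussian-mixture clustering of encoded features
#'
#' Fits a full-covariance Gaussian mixture model with `k` components to
#' the latent features (posterior means only) by expectation-
#' maximization, and labels each pixel with its maximum-responsibility
#' component. Model-based hierarchical initialization makes the fit
#' deterministic; `seed` is accepted for interface symmetry with the
#' stochastic stages.
#'
#' @param feats An [encode()] result or an `N x k` numeric matrix.
#' @param k Number of mixture components (`1 <= k <= N`).
#' @param seed Integer seed (the fit itself is deterministic).
#' @return An object of class `cluster_result`: `labels` (length `N`,
#'   values `1..k`), `k`, `bic` (on the `-2 logL + p ln N` convention;
#'   lower is better), `loglik`, `responsibilities` (`N x k`), `seed`.
#' @export
fit_gmm <- function(feats, k, seed = 1) {
  Z <- as_feature_matrix(feats)
  n <- nrow(Z)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n < k) stop(sprintf("cannot fit %d components to %d points", k, n),
                  call. = FALSE)
  set.seed(seed)
  # Mclust() resolves its helpers in the caller's frame
  mclustBIC <- mclust::mclustBIC
  # hierarchical model-based initialization is quadratic in N; above a few
  # thousand points it runs on a seeded subset (EM still uses all points)
  init <- if (n > 2000)
    list(subset = sort(sample.int(n, 2000))) else NULL
  try_fit <- function(...) {
    tryCatch(suppressWarnings(
      mclust::Mclust(Z, modelNames = "VVV", verbose = FALSE, ...)),
      error = function(e) NULL)
  }
  if (k == 1) {
    # single component: everything in cluster 1
    fit <- try_fit(G = 1)
  } else {
    fit <- try_fit(G = k, initialization = init)
    if (is.null(fit))
      # near-degenerate data: regularize the covariances with a prior
      fit <- try_fit(G = k, initialization = init,
                     prior = mclust::priorControl())
  }
  if (is.null(fit)) {
    # fully degenerate data (e.g. all points coincide): one effective
    # component carries everything
    message("degenerate features: collapsing to a single component")
    resp <- matrix(0, n, k)
    resp[, 1] <- 1
    return(structure(list(labels = rep(1L, n), k = as.integer(k),
                          bic = NA_real_, loglik = NA_real_,
                          n_params = NA_integer_,
                          responsibilities = resp,
                          seed = as.integer(seed)),
                     class = "cluster_result"))
  }
  structure(list(labels = as.integer(fit$classification), k = as.integer(k),
                 bic = -as.numeric(fit$bic), loglik = fit$loglik,
                 n_params = mclust::nMclustParams(fit$modelName, fit$d,
                                                  fit$G),
                 responsibilities = fit$z, seed = as.integer(seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("GMM clustering: %d pixels in %d clusters (BIC %.1f)\n",
              length(x$labels), x$k, x$bic))
  print(table(cluster = x$labels))
  invisible(x)
}

#' BIC scan over candidate cluster counts
#'
#' Fits one full-covariance Gaussian mixture per candidate `k` and
#' reports the Bayesian information criterion
#' `BIC = -2 logL + p ln N` (lower is better), with `p` the number of
#' free mixture parameters.
#'
#' @inheritParams fit_gmm
#' @param k_range Integer vector of candidate component counts.
#' @return Named numeric vector of BIC scores, names = `k`.
#' @export
bic_scan <- function(feats, k_range, seed = 1) {
  Z <- as_feature_matrix(feats)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || any(k_range > nrow(Z)))
    stop("k_range must lie within [1, N]", call. = FALSE)
  scores <- vapply(k_range, function(k) fit_gmm(Z, k, seed = seed)$bic,
                   numeric(1))
  names(scores) <- k_range
  if (anyNA(scores))
    warning("BIC unavailable for k = ",
            paste(k_range[is.na(scores)], collapse = ", "),
            " (degenerate fit)")
  scores
}

#' Knee-point selection of the cluster count
#'
#' Applies the Kneedle construction (sensitivity 1, no smoothing) to a
#' BIC curve: both axes are normalized to \[0, 1\]; for the expected
#' convex decreasing curve the knee is the candidate maximizing the
#' distance between the flipped normalized curve and the diagonal. If
#' the scores are not monotone decreasing, or no knee exists (a straight
#' line), the minimum-BIC candidate is returned with a warning.
#'
#' @param bic_by_k Named numeric vector from [bic_scan()] (names are the
#'   candidate `k` values); at least 3 entries.
#' @return The selected `k` (integer).
#' @examples
#' select_k_kneedle(c("2" = 100, "3" = 40, "4" = 35, "5" = 33, "6" = 32))
#' @export
select_k_kneedle <- function(bic_by_k) {
  bic_by_k <- bic_by_k[!is.na(bic_by_k)]
  if (length(bic_by_k) < 3)
    stop("need at least 3 scanned k values to locate a knee", call. = FALSE)
  ks <- as.integer(names(bic_by_k))
  if (anyNA(ks)) ks <- seq_along(bic_by_k)
  o <- order(ks)
  ks <- ks[o]
  y <- as.numeric(bic_by_k)[o]
  x_n <- (ks - ks[1]) / (ks[length(ks)] - ks[1])
  rng <- max(y) - min(y)
  if (rng == 0) {
    warning("flat BIC curve; falling back to argmin")
    return(ks[which.min(y)])
  }
  y_n <- (y - min(y)) / rng
  diffc <- (1 - y_n) - x_n   # flipped curve minus the diagonal
  # no point above the diagonal means no knee (straight or increasing
  # curve): fall back to the BIC minimum
  if (max(diffc) <= 1e-12) {
    warning("no knee on the BIC curve; falling back to argmin")
    return(ks[which.min(y)])
  }
  ks[which.max(diffc)]
}

#' Cluster encoded features with optional automated model selection
#'
#' Convenience wrapper: with numeric `k` it is [fit_gmm()]; with
#' `k = "auto"` it scans `k_range` by BIC, picks the knee point with
#' [select_k_kneedle()], and fits the selected model. The scan is stored
#' on the result (`bic_by_k`, `selected_k`).
#'
#' @inheritParams fit_gmm
#' @param k Integer cluster count, or `"auto"`.
#' @param k_range Candidates scanned when `k = "auto"`.
#' @return A `cluster_result` (see [fit_gmm()]), with `bic_by_k` and
#'   `selected_k` attached when selection was automatic.
#' @export
cluster_features <- function(feats, k = "auto", k_range = 2:12, seed = 1) {
  if (identical(k, "auto")) {
    scores <- bic_scan(feats, k_range, seed = seed)
    k_sel <- select_k_kneedle(scores)
    res <- fit_gmm(feats, k_sel, seed = seed)
    res$bic_by_k <- scores
    res$selected_k <- k_sel
    res
  } else {
    fit_gmm(feats, as.integer(k), seed = seed)
  }
}

#' Render cluster labels as per-section images
#'
#' Rasterizes per-pixel labels onto the pixel grid, one integer matrix
#' per z-section. Grid cells with no pixel are `NA`. Cluster ids are
#' 1-based, matching the "cluster #1" convention of rendered figures.
#'
#' @param labels Integer vector of cluster labels (or a `cluster_result`).
#' @param coords `N x 3` integer coordinate matrix aligned with `labels`.
#' @return A named list of matrices (rows = y, columns = x), one per
#'   section.
#' @export
label_image <- function(labels, coords) {
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  coords <- as.matrix(coords)
  if (length(labels) != nrow(coords))
    stop("labels and coords are not aligned", call. = FALSE)
  out <- list()
  for (s in sort(unique(coords[, 3]))) {
    idx <- which(coords[, 3] == s)
    xs <- coords[idx, 1]
    ys <- coords[idx, 2]
    ras <- matrix(NA_integer_, nrow = max(ys), ncol = max(xs))
    ras[cbind(ys, xs)] <- labels[idx]
    out[[paste0("section_", s)]] <- ras
  }
  out
}

#' Write cluster images as PNG
#'
#' Renders each section's label raster with a categorical palette.
#'
#' @param rasters Output of [label_image()].
#' @param path_prefix Files are written as `<path_prefix>_<section>.png`.
#' @return Written paths, invisibly.
#' @export
write_label_png <- function(rasters, path_prefix) {
  paths <- character(0)
  for (nm in names(rasters)) {
    ras <- rasters[[nm]]
    p <- paste0(path_prefix, "_", nm, ".png")
    grDevices::png(p, width = ncol(ras) * 4, height = nrow(ras) * 4)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    kmax <- max(ras, na.rm = TRUE)
    graphics::image(t(ras)[, rev(seq_len(nrow(ras))), drop = FALSE],
                    col = grDevices::hcl.colors(kmax, "Dark 3"),
                    axes = FALSE, useRaster = TRUE)
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Correlate clusters with learned-peak ion images
#'
#' For each cluster, computes the Pearson correlation between the
#' cluster's binary membership vector across pixels and the ion image
#' (intensity column) of every learned peak. Columns or memberships with
#' zero variance get `r = 0` and are flagged. Rows are sorted by
#' decreasing correlation, so the top row is the ion most colocalized
#' with the cluster.
#'
#' @param res A `cluster_result` (see [fit_gmm()]).
#' @param reduced_ds The reduced [msi_dataset()] whose rows align with
#'   `res$labels`.
#' @param peaks A [learn_peaks()] result (its `union_peak_index` columns
#'   are correlated), or an integer vector of column indices.
#' @return A named list (one element per cluster) of data frames with
#'   columns `peak_index`, `peak_mz`, `r`, `zero_variance`.
#' @export
correlate_clusters <- function(res, reduced_ds, peaks) {
  peak_idx <- if (inherits(peaks, "learned_peaks")) peaks$union_peak_index
              else as.integer(peaks)
  X <- reduced_ds$intensities
  if (nrow(X) != length(res$labels))
    stop("dataset rows do not match cluster labels", call. = FALSE)
  out <- list()
  for (cl in seq_len(res$k)) {
    member <- as.numeric(res$labels == cl)
    mvar <- stats::var(member)
    r <- numeric(length(peak_idx))
    flag <- logical(length(peak_idx))
    for (i in seq_along(peak_idx)) {
      col <- X[, peak_idx[i]]
      if (mvar == 0 || stats::var(col) == 0) {
        r[i] <- 0
        flag[i] <- TRUE
      } else {
        r[i] <- stats::cor(member, col)
      }
    }
    df <- data.frame(peak_index = peak_idx,
                     peak_mz = reduced_ds$mz[peak_idx],
                     r = r, zero_variance = flag)
    out[[paste0("cluster_", cl)]] <- df[order(-df$r), , drop = FALSE]
  }
  out
}
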