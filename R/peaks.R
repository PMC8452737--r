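#' Hidden neuron most strongly wired to a latent dimension
#'
#' For one latent (encoded) feature, finds the first-hidden-layer neuron
#' `j` with the maximum weight into that feature's posterior-mean head.
#' With `attribution = "signed"` (the default) the signed maximum is
#' taken; `"abs"` uses the maximum magnitude. Ties break toward the
#' smallest index.
#'
#' @param Wmu `hidden x k` weight matrix of the latent-mean head.
#' @param latent_i Latent dimension index (1-based).
#' @param attribution `"signed"` or `"abs"`.
#' @return Integer index of the chosen hidden neuron.
#' @export
max_weight_neuron <- function(Wmu, latent_i,
                              attribution = c("signed", "abs")) {
  attribution <- match.arg(attribution)
  if (latent_i < 1 || latent_i > ncol(Wmu))
    stop("latent_i out of range", call. = FALSE)
  col <- Wmu[, latent_i]
  if (attribution == "abs") col <- abs(col)
  which.max(col)  # first maximum on ties
}

#' Weight threshold for informative-bin selection
#'
#' The selection threshold on the input-to-hidden weight vector feeding
#' the chosen neuron: `T = mean(w) + beta * sd(w)`, with the population
#' (1/d) standard deviation. Input bins whose weight reaches `T` are
#' declared informative for the latent feature.
#'
#' @param w_col Numeric weight vector (length `d`).
#' @param beta Non-negative multiplier; 2.5 in the reference analyses,
#'   meaningful range starting at 1.
#' @return Scalar threshold.
#' @examples
#' weight_threshold(c(0, 0, 0, 10), beta = 1)  # 2.5 + 4.3301 = 6.8301
#' @export
weight_threshold <- function(w_col, beta) {
  if (any(!is.finite(w_col)))
    stop("non-finite weights", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  d <- length(w_col)
  sd_pop <- sqrt(sum((w_col - mean(w_col))^2) / d)
  mean(w_col) + beta * sd_pop
}

#' Select informative input bins per latent dimension
#'
#' For each latent feature: pick its maximum-weight hidden neuron, form
#' the threshold [weight_threshold()] on that neuron's input weight
#' vector, and keep every input bin with weight `>= T`. When
#' `attribution = "abs"`, magnitudes are thresholded instead.
#'
#' @param model A trained [msi_vae()].
#' @param beta Threshold multiplier (defaults to the model's
#'   `beta_peaks`).
#' @param attribution Overrides the model's attribution setting.
#' @return List with `per_latent` (a list, one integer bin-index vector
#'   per latent dimension), `union` (sorted unique bins), `neurons`,
#'   `thresholds`, and `beta`.
#' @export
select_bins <- function(model, beta = model$config$beta_peaks,
                        attribution = model$config$attribution) {
  Wmu <- model$params$Wmu
  W1 <- model$params$W1
  k <- ncol(Wmu)
  per_latent <- vector("list", k)
  neurons <- integer(k)
  thresholds <- numeric(k)
  for (i in seq_len(k)) {
    j <- max_weight_neuron(Wmu, i, attribution)
    w_col <- W1[, j]
    if (attribution == "abs") w_col <- abs(w_col)
    T_i <- weight_threshold(w_col, beta)
    bins <- which(w_col >= T_i)
    if (length(bins) == 0)
      warning(sprintf(
        "latent %d: threshold %.4g exceeds all weights; no bins selected",
        i, T_i))
    if (length(bins) == length(w_col))
      message(sprintf(
        "latent %d: degenerate constant weight vector; all bins selected", i))
    per_latent[[i]] <- bins
    neurons[i] <- j
    thresholds[i] <- T_i
  }
  list(per_latent = per_latent,
       union = sort(unique(unlist(per_latent))),
       neurons = neurons, thresholds = thresholds, beta = beta)
}

#' Assign m/z bins to their nearest mean-spectrum peak
#'
#' Because the model trains on un-peak-picked data, a selected bin can
#' sit on a peak flank; it is assigned to the nearest strict local
#' maximum of the mean spectrum, distance measured in bin index space,
#' equidistant ties broken toward the lower index.
#'
#' @param bins Integer vector of selected bin indices.
#' @param mean_spec A [mean_spectrum()] (or numeric vector of mean
#'   intensities).
#' @param mz Optional m/z axis for reporting.
#' @return A data frame with one row per bin: `bin_index`, `bin_mz`,
#'   `peak_index`, `peak_mz`.
#' @export
assign_bins_to_peaks <- function(bins, mean_spec, mz = NULL) {
  values <- if (inherits(mean_spec, "mean_spectrum")) mean_spec$values
            else as.numeric(mean_spec)
  if (is.null(mz) && inherits(mean_spec, "mean_spectrum")) mz <- mean_spec$mz
  maxima <- find_local_maxima(values)
  if (length(maxima) == 0)
    stop("mean spectrum has no local maxima; cannot assign peaks",
         call. = FALSE)
  peak_index <- vapply(as.integer(bins), function(b) {
    dist <- abs(maxima - b)
    maxima[which.min(dist)]  # which.min takes the first (lower) on ties
  }, integer(1))
  data.frame(bin_index = as.integer(bins),
             bin_mz = if (is.null(mz)) NA_real_ else mz[as.integer(bins)],
             peak_index = peak_index,
             peak_mz = if (is.null(mz)) NA_real_ else mz[peak_index])
}

#' Learn the m/z peaks behind each encoded feature
#'
#' The full peak-learning pipeline: select informative input bins per
#' latent dimension from the network weights ([select_bins()]), compute
#' the dataset's mean spectrum, and assign every selected bin to its
#' nearest local maximum ([assign_bins_to_peaks()]). The union of
#' assigned peaks, deduplicated and sorted, is the model's reduced peak
#' list.
#'
#' @param model A trained [msi_vae()].
#' @param ds The dataset the model was trained on (same axis and
#'   normalization state used for training).
#' @param beta Threshold multiplier (defaults to the model's
#'   `beta_peaks`).
#' @param attribution Overrides the model's attribution setting.
#' @param csv Optional path prefix: writes `<csv>_bins.csv` (one row per
#'   selected bin with its latent index, weight, threshold and assigned
#'   peak) and `<csv>_peaks.csv` (the deduplicated peak list).
#' @return An object of class `learned_peaks`: list with `per_latent`
#'   (data frames of bin-to-peak assignments per latent), `neurons`,
#'   `thresholds`, `beta`, `table` (the combined per-bin data frame),
#'   `union_peak_index` and `union_peak_mz` (sorted, unique).
#' @export
learn_peaks <- function(model, ds, beta = model$config$beta_peaks,
                        attribution = model$config$attribution,
                        csv = NULL) {
  if (inherits(ds, "msi_dataset") && length(ds$mz) != model$input_dim)
    stop(sprintf(
      "dataset has %d bins but the model was trained on %d; %s",
      length(ds$mz), model$input_dim,
      "pass the reduced training-space dataset"), call. = FALSE)
  sel <- select_bins(model, beta = beta, attribution = attribution)
  ms <- mean_spectrum(ds)
  per_latent <- vector("list", length(sel$per_latent))
  rows <- list()
  for (i in seq_along(sel$per_latent)) {
    bins <- sel$per_latent[[i]]
    if (length(bins) == 0) {
      per_latent[[i]] <- data.frame(bin_index = integer(0),
                                    bin_mz = numeric(0),
                                    peak_index = integer(0),
                                    peak_mz = numeric(0))
      next
    }
    asg <- assign_bins_to_peaks(bins, ms)
    w_col <- model$params$W1[, sel$neurons[i]]
    if (attribution == "abs") w_col <- abs(w_col)
    asg$latent_index <- i
    asg$weight <- w_col[bins]
    asg$threshold_T <- sel$thresholds[i]
    asg$beta <- beta
    per_latent[[i]] <- asg
    rows[[length(rows) + 1]] <- asg
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else per_latent[[1]]
  union_idx <- sort(unique(tab$peak_index))
  out <- structure(list(per_latent = per_latent, neurons = sel$neurons,
                        thresholds = sel$thresholds, beta = beta,
                        table = tab, union_peak_index = union_idx,
                        union_peak_mz = ds$mz[union_idx]),
                   class = "learned_peaks")
  if (!is.null(csv)) {
    utils::write.csv(tab[, c("latent_index", "bin_index", "bin_mz",
                             "peak_index", "peak_mz", "weight",
                             "threshold_T", "beta")],
                     paste0(csv, "_bins.csv"), row.names = FALSE)
    utils::write.csv(data.frame(peak_index = union_idx,
                                peak_mz = ds$mz[union_idx]),
                     paste0(csv, "_peaks.csv"), row.names = FALSE)
  }
  out
}

#' @export
print.learned_peaks <- function(x, ...) {
  cat(sprintf(
    "learned peaks (beta = %.3g): %d selected bins -> %d unique peaks\n",
    x$beta, nrow(x$table), length(x$union_peak_index)))
  for (i in seq_along(x$per_latent))
    cat(sprintf("  latent %d: neuron %d, T = %.4g, %d bins\n", i,
                x$neurons[i], x$thresholds[i], nrow(x$per_latent[[i]])))
  invisible(x)
}
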