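#' Load an MSI dataset from a supported file format
#'
#' Dispatches on the file extension: `.imzML` via [read_imzml()],
#' `.h5`/`.hdf5` via [read_msi_h5()].
#'
#' @param path Input file path.
#' @return An [msi_dataset()].
#' @export
load_msi <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "imzml" = read_imzml(path),
         "h5" = ,
         "hdf5" = read_msi_h5(path),
         stop("unsupported input format '.", ext,
              "' (expected .imzML or .h5)", call. = FALSE))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

write_run_manifest <- function(out_dir, command, config, inputs, seed,
                               timings, outputs) {
  hashes <- list()
  for (f in inputs)
    if (is.character(f) && file.exists(f))
      hashes[[f]] <- unname(tools::md5sum(f))
  manifest <- list(command = command, config = config,
                   input_md5 = hashes, seed = seed,
                   timings_sec = timings, outputs = outputs,
                   package_version = msivae_version(),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Train an autoencoder end-to-end from a file or dataset
#'
#' The full training pipeline: load, optionally reduce the axis to
#' local maxima of the mean spectrum, TIC-normalize, fit the
#' autoencoder, and measure the training reconstruction MSE. When
#' `out_dir` is given, the model archive (with the training axis map
#' frozen in, so unseen data can be projected onto the training bins),
#' a metrics JSON and a run manifest are written.
#'
#' @param input Path to `.imzML`/`.h5` data, or an [msi_dataset()].
#' @param out_dir Optional output directory (created if missing).
#' @param reduce Reduce the axis to mean-spectrum local maxima before
#'   normalization (default `TRUE`).
#' @param drop_empty Drop all-zero spectra instead of erroring.
#' @param seed RNG seed for training.
#' @param ... Further arguments to [msi_vae()] (`hidden_dim`,
#'   `latent_dim`, `epochs`, ...).
#' @return Invisibly, a list with `model`, `reduced` (the normalized
#'   training dataset), `axis_map`, `mse` (final training reconstruction
#'   MSE) and output `paths`.
#' @export
run_train <- function(input, out_dir = NULL, reduce = TRUE,
                      drop_empty = FALSE, seed = 1, ...) {
  t0 <- proc.time()[["elapsed"]]
  ds <- run_stage("load", {
    if (inherits(input, "msi_dataset")) input else load_msi(input)
  })
  axis_map <- NULL
  if (reduce) {
    red <- run_stage("reduce_to_local_maxima", reduce_to_local_maxima(ds))
    ds <- red$dataset
    axis_map <- red$axis_map
  }
  ds <- run_stage("tic_normalize", tic_normalize(ds, drop_empty = drop_empty))
  t1 <- proc.time()[["elapsed"]]
  model <- run_stage("train", msi_vae(ds, seed = seed, ...))
  model$axis_map <- axis_map
  t2 <- proc.time()[["elapsed"]]
  mse <- reconstruction_mse(ds$intensities, reconstruct(model, ds))

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$model <- file.path(out_dir, "model.h5")
    save_msi_vae(model, paths$model)
    paths$metrics <- file.path(out_dir, "metrics_train.json")
    jsonlite::write_json(
      list(final_mse = mse, n_spectra = nrow(ds$intensities),
           input_dim = model$input_dim,
           loss_history = model$history$total),
      paths$metrics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths$manifest <- write_run_manifest(
      out_dir, "train", model$config,
      inputs = if (is.character(input)) input else character(0),
      seed = seed,
      timings = list(preprocess = t1 - t0, train = t2 - t1),
      outputs = paths[c("model", "metrics")])
  }
  invisible(list(model = model, reduced = ds, axis_map = axis_map,
                 mse = mse, paths = paths))
}

#' Apply a trained model to (possibly unseen) data in chunks
#'
#' Streams the input through the trained encoder/decoder without ever
#' materializing more than one chunk of spectra in working form. Data on
#' the original (full) axis are first projected onto the model's
#' training-time axis map; each chunk is then TIC-normalized, encoded,
#' and reconstructed. Chunking is by section (z-slice) by default, or by
#' a fixed number of pixels.
#'
#' @param model A trained [msi_vae()] or the path to a saved archive.
#' @param input Path to `.imzML`/`.h5` data, or an [msi_dataset()].
#' @param chunk_size `"section"` (default) to process one z-slice at a
#'   time, or an integer number of pixels per chunk.
#' @param out_dir Optional output directory for features, metrics and
#'   manifest.
#' @param drop_empty Drop all-zero spectra instead of erroring.
#' @return Invisibly, a list with `features` (`N x k` latent means,
#'   row-aligned with the retained input pixels), `coords`, `mse`
#'   (reconstruction MSE over all processed spectra), `n` and `paths`.
#' @export
run_apply <- function(model, input, chunk_size = "section",
                      out_dir = NULL, drop_empty = FALSE) {
  if (is.character(model)) model <- run_stage("load_model",
                                              load_msi_vae(model))
  ds <- run_stage("load", {
    if (inherits(input, "msi_dataset")) input else load_msi(input)
  })
  if (length(ds$mz) != model$input_dim) {
    if (!is.null(model$axis_map)) {
      ds <- run_stage("apply_axis_map",
                      apply_axis_map(ds, model$axis_map))
    } else {
      stop(sprintf(
        "axis mismatch: model expects d = %d, data have d = %d and %s",
        model$input_dim, length(ds$mz),
        "no axis map is stored; align spectra to the training axis"),
        call. = FALSE)
    }
  }
  n <- nrow(ds$intensities)
  chunks <- if (identical(chunk_size, "section")) {
    split(seq_len(n), ds$coords[, 3])
  } else {
    split(seq_len(n), ceiling(seq_len(n) / as.integer(chunk_size)))
  }
  feats <- matrix(NA_real_, n, model$config$latent_dim)
  keep <- logical(n)
  sse <- 0
  n_entries <- 0
  for (idx in chunks) {
    sub <- msi_dataset(ds$mz, ds$intensities[idx, , drop = FALSE],
                       ds$coords[idx, , drop = FALSE],
                       source = ds$meta$source)
    sub <- tic_normalize(sub, drop_empty = drop_empty)
    # row-match retained pixels back to their chunk positions
    kept_idx <- idx
    if (nrow(sub$intensities) < length(idx)) {
      key_all <- paste(ds$coords[idx, 1], ds$coords[idx, 2],
                       ds$coords[idx, 3])
      key_kept <- paste(sub$coords[, 1], sub$coords[, 2], sub$coords[, 3])
      kept_idx <- idx[match(key_kept, key_all)]
    }
    z <- encode(model, sub)$z_mean
    xh <- reconstruct(model, sub)
    feats[kept_idx, ] <- z
    keep[kept_idx] <- TRUE
    sse <- sse + sum((sub$intensities - xh)^2)
    n_entries <- n_entries + length(sub$intensities)
  }
  feats <- feats[keep, , drop = FALSE]
  coords <- ds$coords[keep, , drop = FALSE]
  mse <- sse / n_entries

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$features <- file.path(out_dir, "encoded_features.h5")
    h5_write_file(paths$features,
                  list(z_mean = feats, coords = coords),
                  list("float64", "int32"),
                  attrs = list(version = msivae_version()))
    paths$metrics <- file.path(out_dir, "metrics_apply.json")
    jsonlite::write_json(list(mse = mse, n_spectra = nrow(feats)),
                         paths$metrics, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths$manifest <- write_run_manifest(
      out_dir, "apply", model$config,
      inputs = if (is.character(input)) input else character(0),
      seed = model$config$seed, timings = list(),
      outputs = paths[c("features", "metrics")])
  }
  invisible(list(features = feats, coords = coords, mse = mse,
                 n = nrow(feats), paths = paths))
}

#' Cross-validated training with peak-stability analysis
#'
#' Repeatedly splits the sections (z-slices) of a multi-section dataset
#' into a training and a testing fraction, trains a model per fold,
#' evaluates the reconstruction MSE on both splits, and learns the peak
#' list per fold. Peaks are compared across folds on the full (original)
#' m/z axis, yielding a peak-frequency table and the fraction of peaks
#' found in at least `folds - 1` folds (the stability fraction).
#'
#' @param input Path or [msi_dataset()] with at least 2 sections.
#' @param folds Number of cross-validation repetitions (default 5).
#' @param train_fraction Fraction of sections used for training each
#'   fold (default 0.2).
#' @param seed Base RNG seed; fold `f` trains with `seed + f`.
#' @param beta Peak-learning threshold multiplier.
#' @param out_dir Optional output directory for the fold metrics and
#'   frequency table.
#' @param ... Further arguments to [msi_vae()].
#' @return Invisibly, a list with `fold_metrics` (data frame: fold,
#'   train/test MSE, peak count), `peak_frequency` (data frame:
#'   full-axis peak index, m/z, number of folds), `stability_fraction`,
#'   and `paths`.
#' @export
run_crossvalidate <- function(input, folds = 5, train_fraction = 0.2,
                              seed = 1, beta = 2.5, out_dir = NULL, ...) {
  if (folds < 2) stop("need folds >= 2", call. = FALSE)
  ds <- if (inherits(input, "msi_dataset")) input else load_msi(input)
  sections <- sort(unique(ds$coords[, 3]))
  n_train <- max(1L, round(train_fraction * length(sections)))
  if (length(sections) < 2 || n_train >= length(sections))
    stop(sprintf(
      "cannot split %d sections into train/test folds (need more sections)",
      length(sections)), call. = FALSE)

  fold_metrics <- data.frame(fold = integer(0), train_mse = numeric(0),
                             test_mse = numeric(0), n_peaks = integer(0))
  peak_sets <- vector("list", folds)
  for (f in seq_len(folds)) {
    set.seed(seed + f)
    shuffled <- sample(sections)
    train_sec <- shuffled[seq_len(n_train)]
    in_train <- ds$coords[, 3] %in% train_sec
    train_ds <- msi_dataset(ds$mz, ds$intensities[in_train, , drop = FALSE],
                            ds$coords[in_train, , drop = FALSE],
                            source = ds$meta$source)
    test_ds <- msi_dataset(ds$mz, ds$intensities[!in_train, , drop = FALSE],
                           ds$coords[!in_train, , drop = FALSE],
                           source = ds$meta$source)
    tr <- run_train(train_ds, reduce = TRUE, seed = seed + f, ...)
    ap <- run_apply(tr$model, test_ds)
    pk <- learn_peaks(tr$model, tr$reduced, beta = beta)
    full_idx <- tr$axis_map$reduced_to_full[pk$union_peak_index]
    peak_sets[[f]] <- full_idx
    fold_metrics <- rbind(fold_metrics, data.frame(
      fold = f, train_mse = tr$mse, test_mse = ap$mse,
      n_peaks = length(full_idx)))
  }

  freq <- table(unlist(peak_sets))
  peak_frequency <- data.frame(
    peak_index = as.integer(names(freq)),
    peak_mz = ds$mz[as.integer(names(freq))],
    n_folds = as.integer(freq))
  peak_frequency <- peak_frequency[order(-peak_frequency$n_folds,
                                         peak_frequency$peak_index), ]
  stability_fraction <- if (nrow(peak_frequency))
    mean(peak_frequency$n_folds >= folds - 1) else NA_real_

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$metrics <- file.path(out_dir, "metrics_cv.json")
    jsonlite::write_json(
      list(fold_metrics = fold_metrics,
           stability_fraction = stability_fraction),
      paths$metrics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths$peaks <- file.path(out_dir, "peak_frequency.csv")
    utils::write.csv(peak_frequency, paths$peaks, row.names = FALSE)
    paths$manifest <- write_run_manifest(
      out_dir, "cv", list(folds = folds, train_fraction = train_fraction,
                          beta = beta),
      inputs = if (is.character(input)) input else character(0),
      seed = seed, timings = list(), outputs = paths[c("metrics", "peaks")])
  }
  invisible(list(fold_metrics = fold_metrics,
                 peak_frequency = peak_frequency,
                 stability_fraction = stability_fraction, paths = paths))
}
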