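#' Bookkeeping for a reduced m/z axis
#'
#' Records which columns of the original axis a reduced dataset retains,
#' so that unseen data can be projected onto the exact bins a model was
#' trained on.
#'
#' @param reduced_to_full Integer vector mapping each retained column to
#'   its (1-based) index on the original axis; strictly increasing.
#' @param full_d Original number of bins.
#' @return An object of class `axis_index_map`.
#' @export
axis_index_map <- function(reduced_to_full, full_d) {
  reduced_to_full <- as.integer(reduced_to_full)
  if (length(reduced_to_full) &&
      (is.unsorted(reduced_to_full, strictly = TRUE) ||
       (!is.na(full_d) && (reduced_to_full[1] < 1L ||
        reduced_to_full[length(reduced_to_full)] > full_d))))
    stop("axis map must be strictly increasing within [1, full_d]",
         call. = FALSE)
  structure(list(reduced_to_full = reduced_to_full,
                 full_d = as.integer(full_d)),
            class = "axis_index_map")
}

#' @export
print.axis_index_map <- function(x, ...) {
  cat(sprintf("axis index map: %d of %d bins retained\n",
              length(x$reduced_to_full), x$full_d))
  invisible(x)
}

#' Total-ion-count normalization
#'
#' Divides every pixel spectrum by its own total ion count so each row
#' sums to 1 and every entry lies in \[0, 1\] — the dynamic range the
#' sigmoid output layer of the autoencoder reconstructs. Idempotent up to
#' floating-point tolerance.
#'
#' @param ds A raw [msi_dataset()] with non-negative intensities.
#' @param drop_empty If `TRUE`, all-zero spectra (common at tissue edges)
#'   are dropped with a message; if `FALSE` (default) they are an error
#'   listing the offending pixel coordinates.
#' @return A TIC-normalized [msi_dataset()] (`meta$normalized = TRUE`).
#' @examples
#' ds <- msi_dataset(c(1, 2, 3), rbind(c(2, 2, 0), c(0, 0, 5)))
#' tic_normalize(ds)$intensities
#' @export
tic_normalize <- function(ds, drop_empty = FALSE) {
  stop_if_invalid(ds)
  tic <- rowSums(ds$intensities)
  empty <- which(tic == 0)
  if (length(empty)) {
    if (drop_empty) {
      message(sprintf("dropping %d empty spectra", length(empty)))
      ds$intensities <- ds$intensities[-empty, , drop = FALSE]
      ds$coords <- ds$coords[-empty, , drop = FALSE]
      tic <- tic[-empty]
    } else {
      shown <- utils::head(empty, 5)
      stop(sprintf(
        "all-zero spectrum at pixel(s) %s (coordinates %s)%s; use drop_empty",
        paste(shown, collapse = ", "),
        paste(apply(ds$coords[shown, , drop = FALSE], 1, paste,
                    collapse = ","), collapse = "; "),
        if (length(empty) > 5) " ..." else ""), call. = FALSE)
    }
  }
  ds$intensities <- ds$intensities / tic
  ds$meta$normalized <- TRUE
  ds
}

#' Mean spectrum of a dataset
#'
#' Column-wise arithmetic mean over all pixel spectra (zeros included).
#' The mean spectrum is the reference on which local maxima are found for
#' axis reduction and for assigning learned m/z bins to peaks.
#'
#' @param ds An [msi_dataset()] with at least one pixel.
#' @return An object of class `mean_spectrum`: list with `values`
#'   (length `d`), `mz`, and `source_normalized`.
#' @export
mean_spectrum <- function(ds) {
  if (nrow(ds$intensities) < 1)
    stop("empty dataset: no spectra to average", call. = FALSE)
  structure(list(values = colMeans(ds$intensities), mz = ds$mz,
                 source_normalized = isTRUE(ds$meta$normalized)),
            class = "mean_spectrum")
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat(sprintf("mean spectrum over %d bins (%s source), max %.4g\n",
              length(x$values),
              if (x$source_normalized) "normalized" else "raw",
              max(x$values)))
  invisible(x)
}

#' Find strict local maxima of an intensity vector
#'
#' A local maximum is a point strictly higher than both of its immediate
#' neighbors. Endpoints are never maxima, and flat plateaus yield none
#' (strict inequality on both sides).
#'
#' @param values Numeric vector, length at least 3.
#' @return Sorted integer indices (1-based) of the local maxima.
#' @examples
#' find_local_maxima(c(0, 1, 0, 2, 0))  # 2, 4
#' find_local_maxima(1:5)               # integer(0)
#' @export
find_local_maxima <- function(values) {
  d <- length(values)
  if (d < 3)
    stop("need at least 3 values to define a local maximum", call. = FALSE)
  mid <- values[2:(d - 1)]
  which(mid > values[1:(d - 2)] & mid > values[3:d]) + 1L
}

#' Reduce the m/z axis to local maxima of the mean spectrum
#'
#' High-resolution MSI axes are mostly sparse baseline; retaining only the
#' bins where the mean spectrum has a strict local maximum shrinks the
#' model's input dimension by an order of magnitude while keeping every
#' peak apex. The reduction is computed on the dataset as given (use raw
#' intensities; normalize afterwards so rows of the model input still sum
#' to 1 over the retained bins).
#'
#' @param ds An [msi_dataset()] with `d >= 3`.
#' @return A list with `dataset` (the column subset, same pixels in the
#'   same order) and `axis_map` (an [axis_index_map()]).
#' @examples
#' ds <- msi_dataset(1:5, rbind(c(0, 1, 0, 2, 0)))
#' reduce_to_local_maxima(ds)$axis_map$reduced_to_full  # 2, 4
#' @export
reduce_to_local_maxima <- function(ds) {
  ms <- mean_spectrum(ds)
  keep <- find_local_maxima(ms$values)
  if (length(keep) == 0)
    stop(paste("no local maxima found on the mean spectrum;",
               "the data look degenerate (e.g. constant spectra)"),
         call. = FALSE)
  out <- ds
  out$mz <- ds$mz[keep]
  out$intensities <- ds$intensities[, keep, drop = FALSE]
  out$meta$reduced <- TRUE
  list(dataset = out,
       axis_map = axis_index_map(keep, length(ds$mz)))
}

#' Project a dataset onto a previously computed axis map
#'
#' Applies a training-time [axis_index_map()] to new data sharing the same
#' original m/z axis, so unseen sections are reduced to exactly the bins
#' the model was trained on.
#'
#' @param ds An [msi_dataset()] on the full axis.
#' @param map An [axis_index_map()].
#' @param train_mz Optional m/z axis of the training data (full axis);
#'   when given, an axis mismatch raises an error instructing alignment.
#' @return The column-subset [msi_dataset()].
#' @export
apply_axis_map <- function(ds, map, train_mz = NULL) {
  if (!is.na(map$full_d) && length(ds$mz) != map$full_d)
    stop(sprintf(
      "axis mismatch: data have %d bins but the map was built for %d; %s",
      length(ds$mz), map$full_d,
      "align spectra to the training m/z axis first"), call. = FALSE)
  if (!is.null(train_mz) && !isTRUE(all.equal(ds$mz, train_mz)))
    stop("m/z axis differs from the training axis; align spectra first",
         call. = FALSE)
  out <- ds
  out$mz <- ds$mz[map$reduced_to_full]
  out$intensities <- ds$intensities[, map$reduced_to_full, drop = FALSE]
  out$meta$reduced <- TRUE
  out
}
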