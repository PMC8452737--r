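#' Construct an MSI dataset
#'
#' The in-memory container used throughout the package: a shared m/z axis,
#' an `N x d` matrix of non-negative spectral intensities (one pixel
#' spectrum per row), and integer pixel coordinates. The object also tracks
#' whether intensities are raw ion counts or have been TIC-normalized,
#' because the autoencoder expects inputs bounded in \[0, 1\].
#'
#' @param mz Numeric vector of `d` strictly increasing m/z values.
#' @param intensities Numeric `N x d` matrix of non-negative, finite
#'   intensities; row `i` is the spectrum of pixel `i`.
#' @param coords Integer `N x 3` matrix of pixel coordinates `(x, y, z)`.
#'   For 2D data pass `z = 1` (or omit the column; it is filled with 1).
#'   Coordinates follow the imzML convention of 1-based grid positions.
#' @param normalized Logical; `TRUE` if the rows are TIC-normalized
#'   (each summing to 1), `FALSE` for raw intensities.
#' @param source Character tag recording provenance (file path or
#'   `"memory"`).
#' @param meta Optional named list of extra provenance fields.
#'
#' @return An object of class `msi_dataset`: a list with elements `mz`,
#'   `intensities`, `coords` and `meta`.
#'
#' @examples
#' ds <- msi_dataset(mz = c(100, 200, 300),
#'                   intensities = rbind(c(0, 5, 1), c(2, 0, 0)),
#'                   coords = cbind(1:2, 1, 1))
#' ds
#' @seealso [validate_msi_dataset()], [read_imzml()], [read_msi_h5()]
#' @export
msi_dataset <- function(mz, intensities, coords = NULL, normalized = FALSE,
                        source = "memory", meta = list()) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  mz <- as.numeric(mz)
  n <- nrow(intensities)
  if (is.null(coords)) {
    coords <- cbind(seq_len(n), 1L, 1L)
  }
  coords <- as.matrix(coords)
  if (ncol(coords) == 2) coords <- cbind(coords, 1L)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y", "z")
  meta$normalized <- isTRUE(normalized)
  if (is.null(meta$source)) meta$source <- source
  structure(list(mz = mz, intensities = intensities, coords = coords,
                 meta = meta),
            class = "msi_dataset")
}

#' Validate an MSI dataset
#'
#' Checks every container invariant and reports violations instead of
#' throwing, so callers can decide whether a problem is fatal. The checks
#' are: the m/z axis is strictly increasing with at least 3 bins; the
#' intensity matrix is finite, non-negative and row-aligned with the
#' coordinates; and no two pixels share a coordinate.
#'
#' @param ds An [msi_dataset()].
#' @return A character vector of human-readable violation descriptions,
#'   each naming the broken invariant and the first offending index;
#'   `character(0)` if the dataset is valid.
#' @examples
#' ds <- msi_dataset(c(100, 200, 300), rbind(c(0, 1, 2)))
#' validate_msi_dataset(ds)  # character(0)
#' @export
validate_msi_dataset <- function(ds) {
  bad <- character(0)
  if (!inherits(ds, "msi_dataset"))
    return("not an msi_dataset object")
  d <- length(ds$mz)
  if (d < 3)
    bad <- c(bad, sprintf("mz axis too short: d = %d < 3", d))
  if (anyNA(ds$mz) || any(!is.finite(ds$mz))) {
    bad <- c(bad, "mz axis contains non-finite values")
  } else if (d >= 2) {
    dif <- diff(ds$mz)
    if (any(dif <= 0)) {
      i <- which(dif <= 0)[1]
      what <- if (dif[i] == 0) "duplicate" else "decreasing"
      bad <- c(bad, sprintf(
        "mz axis not strictly increasing (monotonicity): %s value at bin %d",
        what, i + 1L))
    }
  }
  if (ncol(ds$intensities) != d)
    bad <- c(bad, sprintf("intensities has %d columns but mz axis has %d",
                          ncol(ds$intensities), d))
  if (nrow(ds$intensities) != nrow(ds$coords))
    bad <- c(bad, sprintf("intensities has %d rows but coords has %d",
                          nrow(ds$intensities), nrow(ds$coords)))
  nf <- !is.finite(ds$intensities)
  if (any(nf)) {
    ij <- arrayInd(which(nf)[1], dim(ds$intensities))
    bad <- c(bad, sprintf(
      "non-finite intensity at pixel %d, bin %d", ij[1], ij[2]))
  } else if (any(ds$intensities < 0)) {
    ij <- arrayInd(which(ds$intensities < 0)[1], dim(ds$intensities))
    bad <- c(bad, sprintf(
      "negative intensity at pixel %d, bin %d", ij[1], ij[2]))
  }
  key <- paste(ds$coords[, 1], ds$coords[, 2], ds$coords[, 3])
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    bad <- c(bad, sprintf(
      "duplicate pixel coordinate at row %d (one spectrum per pixel)", i))
  }
  if (is.null(ds$meta$normalized))
    bad <- c(bad, "meta does not record normalization state")
  bad
}

stop_if_invalid <- function(ds) {
  bad <- validate_msi_dataset(ds)
  if (length(bad))
    stop("invalid MSI dataset: ", paste(bad, collapse = "; "), call. = FALSE)
  invisible(ds)
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("MSI dataset: %d pixels x %d m/z bins (m/z %.4g-%.4g)\n",
              nrow(x$intensities), length(x$mz), min(x$mz), max(x$mz)))
  nsec <- length(unique(x$coords[, 3]))
  cat(sprintf("  sections (z): %d | intensities: %s | source: %s\n", nsec,
              if (isTRUE(x$meta$normalized)) "TIC-normalized" else "raw",
              x$meta$source))
  invisible(x)
}

#' Number of pixels and bins of a dataset
#' @param ds An [msi_dataset()].
#' @return Integer vector `c(pixels, bins)`.
#' @export
msi_dim <- function(ds) {
  c(pixels = nrow(ds$intensities), bins = length(ds$mz))
}
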