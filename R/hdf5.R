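# Thin wrappers over the bundled HDF5 C bindings.  Datasets are stored in
# C (row-major) order so files interoperate with h5py/numpy; transposition
# happens here, once, at the boundary.

h5_write_file <- function(path, datasets, dtypes, attrs = list()) {
  stopifnot(length(datasets) == length(dtypes))
  objs <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    x <- datasets[[i]]
    if (is.matrix(x)) {
      v <- as.vector(t(x))
      if (dtypes[[i]] == "int32") storage.mode(v) <- "integer"
      else storage.mode(v) <- "double"
      attr(v, "h5dim") <- as.integer(dim(x))  # C-order: rows, cols
      objs[[i]] <- v
    } else {
      v <- as.vector(x)
      if (dtypes[[i]] == "int32") storage.mode(v) <- "integer"
      else storage.mode(v) <- "double"
      objs[[i]] <- v
    }
  }
  a_names <- names(attrs)
  .Call(C_h5_write, as.character(path), names(datasets), objs,
        as.character(unlist(dtypes)), as.character(a_names),
        unname(attrs))
  invisible(path)
}

h5_list_datasets <- function(path) .Call(C_h5_ls, as.character(path))

h5_read_dataset <- function(path, name) {
  r <- .Call(C_h5_read, as.character(path), as.character(name))
  if (length(r$dims) == 2) {
    matrix(r$data, nrow = r$dims[1], ncol = r$dims[2], byrow = TRUE)
  } else {
    r$data
  }
}

h5_read_attributes <- function(path) .Call(C_h5_read_attrs, as.character(path))

#' Write an MSI dataset to HDF5
#'
#' Stores the dataset in a flat HDF5 layout readable from any HDF5 tool
#' (including Python's h5py): `/mz` (length `d`), `/intensities`
#' (`N x d`, C order), `/coords` (`N x 3` integer), optionally
#' `/axis_map` (0-based indices into the original axis when the dataset
#' was produced by [reduce_to_local_maxima()]), and root attributes
#' `normalized`, `source`, `version`.
#'
#' @param ds An [msi_dataset()]; validated before writing.
#' @param path Output file path.
#' @param intensity_dtype Storage type for intensities, `"float32"`
#'   (default, half the file size) or `"float64"` (lossless for doubles).
#' @param mz_dtype Storage type for the m/z axis, default `"float64"`.
#' @param axis_map Optional [axis_index_map()] to serialize alongside.
#' @return `path`, invisibly.
#' @seealso [read_msi_h5()]
#' @export
write_msi_h5 <- function(ds, path, intensity_dtype = c("float32", "float64"),
                         mz_dtype = "float64", axis_map = NULL) {
  intensity_dtype <- match.arg(intensity_dtype)
  stop_if_invalid(ds)
  datasets <- list(mz = ds$mz, intensities = ds$intensities,
                   coords = ds$coords)
  dtypes <- list(mz_dtype, intensity_dtype, "int32")
  if (!is.null(axis_map)) {
    datasets$axis_map <- as.integer(axis_map$reduced_to_full) - 1L  # 0-based
    dtypes <- c(dtypes, "int32")
  }
  attrs <- list(normalized = as.integer(isTRUE(ds$meta$normalized)),
                source = as.character(ds$meta$source),
                version = msivae_version())
  if (!is.null(axis_map)) attrs$full_d <- as.integer(axis_map$full_d)
  h5_write_file(path, datasets, dtypes, attrs)
  invisible(path)
}

#' Read an MSI dataset from HDF5
#'
#' Reads a file produced by [write_msi_h5()] (or any file following the
#' same layout). Missing required members raise a schema error naming the
#' member.
#'
#' @param path Path to the HDF5 file.
#' @return An [msi_dataset()]; if the file carries an `/axis_map`, it is
#'   attached as attribute `"axis_map"` of the returned object.
#' @export
read_msi_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  present <- h5_list_datasets(path)
  for (need in c("mz", "intensities", "coords")) {
    if (!need %in% present)
      stop(sprintf("HDF5 schema error: file '%s' is missing dataset '/%s'",
                   path, need), call. = FALSE)
  }
  attrs <- h5_read_attributes(path)
  ds <- msi_dataset(mz = h5_read_dataset(path, "mz"),
                    intensities = h5_read_dataset(path, "intensities"),
                    coords = h5_read_dataset(path, "coords"),
                    normalized = isTRUE(attrs$normalized == 1L),
                    source = if (is.null(attrs$source)) path
                             else attrs$source)
  stop_if_invalid(ds)
  if ("axis_map" %in% present) {
    attr(ds, "axis_map") <- axis_index_map(
      reduced_to_full = h5_read_dataset(path, "axis_map") + 1L,
      full_d = if (is.null(attrs$full_d)) NA_integer_ else attrs$full_d)
  }
  ds
}

msivae_version <- function() {
  as.character(utils::packageVersion("msivae"))
}
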