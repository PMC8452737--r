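#' Specification of a synthetic MSI phantom
#'
#' Describes a ground-truth phantom emulating the data regime the
#' autoencoder is built for: sparse, high-dimensional, non-negative
#' spectra with multi-bin Gaussian peaks, region-specific peak panels on a
#' Voronoi tissue partition, per-pixel total-ion-count variation, and
#' additive half-normal noise.
#'
#' @param width,height Grid dimensions in pixels per section.
#' @param n_sections Number of z-slices (1 for 2D; see
#'   [generate_3d_phantom()] for multi-section volumes).
#' @param d Number of m/z bins.
#' @param mz_range Numeric length-2, low/high m/z of the shared axis.
#' @param n_regions Number of Voronoi tissue regions.
#' @param peaks_per_region Discriminative peaks planted per region.
#' @param shared_peaks Peaks common to all regions (structural ions).
#' @param peak_width_bins Gaussian sigma of the peak profile, in bins.
#' @param snr Ratio of the base peak height to the noise standard
#'   deviation; `Inf` gives noiseless spectra.
#' @param tic_cv Log-scale standard deviation of the per-pixel log-normal
#'   TIC scaling factor (0 disables TIC variation).
#' @param sparsity Fraction of each pixel's lowest-intensity bins zeroed
#'   after noise, in \[0, 1).
#' @param jitter_sd Per-section jitter (pixels) of the Voronoi seeds for
#'   multi-section phantoms; ignored when `n_sections == 1`.
#' @param seed Integer RNG seed; the phantom is deterministic given the
#'   spec.
#' @return An object of class `phantom_spec`.
#' @seealso [reference_phantom_spec()], [generate_phantom()]
#' @export
phantom_spec <- function(width = 64, height = 64, n_sections = 1,
                         d = 2000, mz_range = c(100, 1000),
                         n_regions = 5, peaks_per_region = 8,
                         shared_peaks = 10, peak_width_bins = 2,
                         snr = 20, tic_cv = 0.25, sparsity = 0.5,
                         jitter_sd = 2, seed = 11) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_sections = as.integer(n_sections), d = as.integer(d),
               mz_range = as.numeric(mz_range),
               n_regions = as.integer(n_regions),
               peaks_per_region = as.integer(peaks_per_region),
               shared_peaks = as.integer(shared_peaks),
               peak_width_bins = as.numeric(peak_width_bins),
               snr = as.numeric(snr), tic_cv = as.numeric(tic_cv),
               sparsity = as.numeric(sparsity),
               jitter_sd = as.numeric(jitter_sd), seed = as.integer(seed))
  for (f in c("width", "height", "n_sections", "d", "n_regions",
              "peaks_per_region"))
    if (spec[[f]] < 1) stop("phantom spec field '", f, "' must be >= 1",
                            call. = FALSE)
  if (spec$shared_peaks < 0)
    stop("phantom spec field 'shared_peaks' must be >= 0", call. = FALSE)
  if (spec$sparsity < 0 || spec$sparsity >= 1)
    stop("phantom spec field 'sparsity' must be in [0, 1)", call. = FALSE)
  if (spec$snr <= 0)
    stop("phantom spec field 'snr' must be > 0", call. = FALSE)
  n_peaks <- spec$n_regions * spec$peaks_per_region + spec$shared_peaks
  if (n_peaks * 6 * spec$peak_width_bins >= spec$d)
    stop("phantom spec: peaks do not fit without forced overlap ",
         "(field 'd' too small)", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

#' The frozen reference phantom
#'
#' The single named configuration used throughout the test-suite and the
#' worked examples: a 64 x 64 pixel section, 2000 bins, 5 Voronoi regions
#' with 8 discriminative peaks each plus 10 shared peaks, peak width 2
#' bins, signal-to-noise 20, seed 11.
#'
#' @param ... Overrides passed on to [phantom_spec()] (e.g. `n_sections`
#'   for the multi-section variant used in train/test experiments).
#' @return A `phantom_spec`.
#' @export
reference_phantom_spec <- function(...) {
  args <- list(width = 64, height = 64, n_sections = 1, d = 2000,
               mz_range = c(100, 1000), n_regions = 5,
               peaks_per_region = 8, shared_peaks = 10,
               peak_width_bins = 2, snr = 20, tic_cv = 0.25,
               sparsity = 0.5, seed = 11)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom spec: %dx%dx%d grid, d=%d, %d regions x %d peaks + %d shared\n",
    x$width, x$height, x$n_sections, x$d, x$n_regions, x$peaks_per_region,
    x$shared_peaks))
  cat(sprintf("  peak sigma %.3g bins, snr %.3g, tic_cv %.3g, sparsity %.3g, seed %d\n",
              x$peak_width_bins, x$snr, x$tic_cv, x$sparsity, x$seed))
  invisible(x)
}

# Place peak centers on the bin axis with a minimum spacing so profiles do
# not overlap; deterministic given the RNG state.
place_peak_centers <- function(d, n_peaks, width_bins) {
  margin <- max(3L, ceiling(3 * width_bins))
  minsep <- max(2L, ceiling(6 * width_bins))
  pool <- sample(seq.int(margin + 1L, d - margin))
  accepted <- integer(0)
  for (p in pool) {
    if (length(accepted) == n_peaks) break
    if (!length(accepted) || min(abs(accepted - p)) >= minsep)
      accepted <- c(accepted, p)
  }
  if (length(accepted) < n_peaks)
    stop("could not place ", n_peaks, " non-overlapping peaks on ", d,
         " bins", call. = FALSE)
  sort(accepted)
}

voronoi_labels <- function(width, height, centers_x, centers_y) {
  px <- rep(seq_len(width), times = height)
  py <- rep(seq_len(height), each = width)
  d2 <- outer(px, centers_x, "-")^2 + outer(py, centers_y, "-")^2
  max.col(-d2, ties.method = "first")
}

gaussian_profile <- function(d, center, sigma, height) {
  height * exp(-((seq_len(d) - center)^2) / (2 * sigma^2))
}

#' Generate a synthetic MSI phantom with known ground truth
#'
#' Builds the dataset described by a [phantom_spec()]: the tissue grid is
#' partitioned into Voronoi regions; each region's spectrum is the sum of
#' its discriminative peaks and the shared peaks (Gaussian profiles with
#' log-normal heights around a base height of 100); each pixel scales its
#' region template by a log-normal TIC factor, adds half-normal noise of
#' standard deviation `base_height / snr`, and finally zeroes its lowest
#' `sparsity` fraction of bins. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `dataset` (an [msi_dataset()]) and `truth` (class
#'   `phantom_truth`: `region_labels` per pixel, `peak_centers` — a list
#'   of bin indices per region —, `shared_centers`, and `templates`, the
#'   noiseless region spectra).
#' @examples
#' ph <- generate_phantom(phantom_spec(width = 8, height = 8, d = 300,
#'                                     n_regions = 2, peaks_per_region = 3,
#'                                     shared_peaks = 2, seed = 1))
#' ph$dataset
#' table(ph$truth$region_labels)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  set.seed(spec$seed)
  base_height <- 100

  # peak panel: first the shared peaks, then each region's block
  n_peaks <- spec$n_regions * spec$peaks_per_region + spec$shared_peaks
  centers <- place_peak_centers(spec$d, n_peaks, spec$peak_width_bins)
  centers <- sample(centers)  # decouple bin position from role
  shared_centers <- sort(centers[seq_len(spec$shared_peaks)])
  region_centers <- split(
    centers[-seq_len(spec$shared_peaks)][
      seq_len(spec$n_regions * spec$peaks_per_region)],
    rep(seq_len(spec$n_regions), each = spec$peaks_per_region))
  region_centers <- lapply(region_centers, sort)
  heights <- stats::rlnorm(n_peaks, 0, 0.25) * base_height
  names(heights) <- as.character(sort(c(shared_centers,
                                        unlist(region_centers))))
  height_of <- function(ctr) heights[as.character(ctr)]

  shared_template <- rep(0, spec$d)
  for (ctr in shared_centers)
    shared_template <- shared_template +
      gaussian_profile(spec$d, ctr, spec$peak_width_bins, height_of(ctr))
  templates <- matrix(0, spec$n_regions, spec$d)
  for (r in seq_len(spec$n_regions)) {
    tmpl <- shared_template
    for (ctr in region_centers[[r]])
      tmpl <- tmpl +
        gaussian_profile(spec$d, ctr, spec$peak_width_bins, height_of(ctr))
    templates[r, ] <- tmpl
  }

  # spatial layout, shared across sections (jittered per section in 3D)
  cx <- stats::runif(spec$n_regions, 1, spec$width)
  cy <- stats::runif(spec$n_regions, 1, spec$height)
  npx_section <- spec$width * spec$height
  n <- npx_section * spec$n_sections

  labels <- integer(n)
  coords <- matrix(0L, n, 3)
  for (s in seq_len(spec$n_sections)) {
    jx <- if (spec$n_sections > 1 && spec$jitter_sd > 0)
      stats::rnorm(spec$n_regions, 0, spec$jitter_sd) else 0
    jy <- if (spec$n_sections > 1 && spec$jitter_sd > 0)
      stats::rnorm(spec$n_regions, 0, spec$jitter_sd) else 0
    idx <- (s - 1L) * npx_section + seq_len(npx_section)
    labels[idx] <- voronoi_labels(spec$width, spec$height, cx + jx, cy + jy)
    coords[idx, 1] <- rep(seq_len(spec$width), times = spec$height)
    coords[idx, 2] <- rep(seq_len(spec$height), each = spec$width)
    coords[idx, 3] <- s
  }

  intens <- templates[labels, , drop = FALSE]
  if (spec$tic_cv > 0)
    intens <- intens * stats::rlnorm(n, 0, spec$tic_cv)
  if (is.finite(spec$snr))
    intens <- intens + abs(matrix(stats::rnorm(n * spec$d, 0,
                                               base_height / spec$snr),
                                  n, spec$d))
  if (spec$sparsity > 0) {
    nzero <- floor(spec$sparsity * spec$d)
    if (nzero > 0) {
      for (i in seq_len(n)) {
        low <- order(intens[i, ])[seq_len(nzero)]
        intens[i, low] <- 0
      }
    }
  }

  ds <- msi_dataset(mz = seq(spec$mz_range[1], spec$mz_range[2],
                             length.out = spec$d),
                    intensities = intens, coords = coords,
                    source = "phantom")
  truth <- structure(list(region_labels = labels,
                          peak_centers = region_centers,
                          shared_centers = shared_centers,
                          templates = templates, spec = spec),
                     class = "phantom_truth")
  list(dataset = ds, truth = truth)
}

#' Generate a multi-section (3D) phantom
#'
#' Same spectral ground truth as [generate_phantom()], with one Voronoi
#' layout shared across sections and per-section jitter of the region
#' seeds, so that held-out sections contain the training sections'
#' spectral phenotypes at shifted locations — the regime of a volumetric
#' specimen cut into consecutive slices.
#'
#' @param spec A [phantom_spec()] with `n_sections >= 2`.
#' @return As [generate_phantom()].
#' @export
generate_3d_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  if (spec$n_sections < 2)
    stop("a 3D phantom needs n_sections >= 2", call. = FALSE)
  generate_phantom(spec)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom truth: %d regions, %d discriminative + %d shared peaks\n",
    length(x$peak_centers),
    sum(lengths(x$peak_centers)), length(x$shared_centers)))
  invisible(x)
}
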