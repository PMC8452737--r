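test_that("phantom generation is deterministic and honours its
           declared dimensions", {
  spec <- phantom_spec(width = 10, height = 8, d = 400, n_regions = 3,
                      peaks_per_region = 3, shared_peaks = 2, seed = 21)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$truth$region_labels, b$truth$region_labels)

  expect_equal(nrow(a$dataset$intensities), 80)
  expect_length(a$dataset$mz, 400)
  expect_length(validate_msi_dataset(a$dataset), 0)
  expect_equal(sort(unique(a$truth$region_labels)), 1:3)
  expect_length(a$truth$shared_centers, 2)
  expect_equal(lengths(a$truth$peak_centers), rep(3L, 3),
               ignore_attr = TRUE)

  c <- generate_phantom(phantom_spec(width = 10, height = 8, d = 400,
                                     n_regions = 3, peaks_per_region = 3,
                                     shared_peaks = 2, seed = 22))
  expect_false(identical(a$dataset$intensities, c$dataset$intensities))
})

test_that("phantom spec invariants are enforced by name", {
  expect_error(phantom_spec(n_regions = 0), "n_regions")
  expect_error(phantom_spec(sparsity = 1), "sparsity")
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(d = 100, n_regions = 5, peaks_per_region = 8,
                            peak_width_bins = 2), "'d'")
})

test_that("the noiseless limit gives identical spectra within a region", {
  ph <- generate_phantom(phantom_spec(width = 8, height = 8, d = 300,
                                      n_regions = 2, peaks_per_region = 3,
                                      shared_peaks = 1, snr = Inf,
                                      tic_cv = 0, sparsity = 0, seed = 2))
  r1 <- which(ph$truth$region_labels == 1)
  expect_identical(ph$dataset$intensities[r1[1], ],
                   ph$dataset$intensities[r1[2], ])
  # and regions differ
  r2 <- which(ph$truth$region_labels == 2)
  expect_false(identical(ph$dataset$intensities[r1[1], ],
                         ph$dataset$intensities[r2[1], ]))
})

test_that("every planted center is a local maximum of the mean spectrum
           on the reference phantom", {
  ph <- ref_phantom()
  maxima <- find_local_maxima(mean_spectrum(ph$dataset)$values)
  centers <- c(unlist(ph$truth$peak_centers), ph$truth$shared_centers)
  expect_length(centers, 50)
  expect_true(all(vapply(centers,
                         function(ctr) any(abs(maxima - ctr) <= 1),
                         logical(1))))
})

test_that("multi-section phantoms share spectral phenotypes across
           sections", {
  spec <- phantom_spec(width = 12, height = 12, n_sections = 3, d = 300,
                       n_regions = 3, peaks_per_region = 3,
                       shared_peaks = 2, snr = Inf, tic_cv = 0,
                       sparsity = 0, jitter_sd = 2, seed = 13)
  ph <- generate_3d_phantom(spec)
  expect_equal(sort(unique(ph$dataset$coords[, 3])), 1:3)

  # noiseless limit: region-mean spectra identical across sections
  for (r in 1:3) {
    per_sec <- lapply(1:3, function(s) {
      idx <- ph$truth$region_labels == r & ph$dataset$coords[, 3] == s
      if (!any(idx)) return(NULL)
      colMeans(ph$dataset$intensities[idx, , drop = FALSE])
    })
    per_sec <- Filter(Negate(is.null), per_sec)
    for (m in per_sec[-1]) expect_equal(m, per_sec[[1]])
  }

  # jitter moves the region boundaries between sections
  areas <- sapply(1:3, function(s)
    mean(ph$truth$region_labels[ph$dataset$coords[, 3] == s] == 1))
  expect_gt(max(areas) - min(areas), 0)

  # zero jitter: identical label rasters per section
  flat <- generate_3d_phantom(phantom_spec(width = 12, height = 12,
                                           n_sections = 2, d = 300,
                                           n_regions = 3,
                                           peaks_per_region = 3,
                                           shared_peaks = 2,
                                           jitter_sd = 0, seed = 13))
  l1 <- flat$truth$region_labels[flat$dataset$coords[, 3] == 1]
  l2 <- flat$truth$region_labels[flat$dataset$coords[, 3] == 2]
  expect_identical(l1, l2)

  expect_error(generate_3d_phantom(phantom_spec(n_sections = 1)),
               "n_sections")
})

test_that("sparsity zeroes the stated fraction of bins per pixel", {
  ph <- generate_phantom(phantom_spec(width = 6, height = 6, d = 400,
                                      n_regions = 2, peaks_per_region = 3,
                                      shared_peaks = 1, sparsity = 0.4,
                                      seed = 8))
  zeros <- rowSums(ph$dataset$intensities == 0)
  expect_true(all(zeros >= floor(0.4 * 400)))
})
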