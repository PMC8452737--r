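make_blobs <- function(k, n_per = 60, sd = 0.05, dim = 3, seed = 9) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim, sd = 2), k, dim)
  # unit-separated centers
  centers <- centers * 2 / max(1e-9, min(dist(centers)))
  Z <- do.call(rbind, lapply(seq_len(k), function(c)
    matrix(rnorm(n_per * dim, mean = rep(centers[c, ], each = n_per),
                 sd = sd), n_per, dim)))
  list(z = Z, labels = rep(seq_len(k), each = n_per))
}

test_that("the GMM recovers well-separated blobs exactly", {
  b <- make_blobs(3)
  res <- fit_gmm(b$z, 3, seed = 1)
  expect_equal(adjusted_rand_index(res$labels, b$labels), 1.0)
  expect_equal(sort(unique(res$labels)), 1:3)
  expect_equal(dim(res$responsibilities), c(nrow(b$z), 3L))

  one <- fit_gmm(b$z, 1)
  expect_true(all(one$labels == 1))

  expect_error(fit_gmm(b$z[1:2, ], 5), "cannot fit")

  # duplicated points: the regularized fallback must not fail
  dup <- matrix(rep(c(0.3, 0.7), each = 40), 40, 2)
  resd <- fit_gmm(dup, 2, seed = 1)
  expect_length(resd$labels, 40)
})

test_that("the BIC scan locates the true component count", {
  b <- make_blobs(4, n_per = 80)
  # high k on few points can fail to fit; those entries become NA
  scores <- suppressWarnings(bic_scan(b$z, 1:10, seed = 1))
  expect_named(scores, as.character(1:10))
  best <- as.integer(names(which.min(scores)))
  expect_true(best %in% 3:5)

  # a single Gaussian cloud: k = 1 at or near the minimum
  set.seed(12)
  cloud <- matrix(rnorm(400), 100, 4)
  sc <- bic_scan(cloud, 1:5, seed = 1)
  expect_lte(sc["1"], min(sc) + 0.02 * abs(min(sc)))

  expect_length(bic_scan(b$z, 3, seed = 1), 1)
  expect_error(bic_scan(b$z, 0:3), "within")
})

test_that("knee-point selection follows the Kneedle construction", {
  expect_equal(select_k_kneedle(c("2" = 100, "3" = 40, "4" = 35,
                                  "5" = 33, "6" = 32)), 3L)
  # straight line: no knee, fall back to the minimum with a warning
  lin <- c("2" = 50, "3" = 40, "4" = 30, "5" = 20)
  expect_warning(k <- select_k_kneedle(lin), "falling back")
  expect_equal(k, 5L)
  # plateau jitter after the elbow must not defeat knee detection
  jit <- c("2" = 100, "3" = 40, "4" = 12, "5" = 10, "6" = 10.5,
           "7" = 10.2)
  expect_equal(select_k_kneedle(jit), 4L)
  # an increasing curve resolves to its minimum (the first point)
  incr <- c("2" = 10, "3" = 30, "4" = 20, "5" = 40)
  expect_equal(select_k_kneedle(incr), 2L)
  expect_error(select_k_kneedle(c(a = 1, b = 2)), "at least 3")
})

test_that("cluster_features with k = 'auto' scans, selects and refits", {
  b <- make_blobs(4, n_per = 70)
  res <- suppressWarnings(
    cluster_features(b$z, k = "auto", k_range = 2:8, seed = 1))
  expect_true(res$selected_k %in% 3:5)
  expect_named(res$bic_by_k, as.character(2:8))
  # a knee one below the truth merges one blob pair; agreement stays high
  expect_gte(adjusted_rand_index(res$labels, b$labels), 0.6)

  fixed <- cluster_features(b$z, k = 4, seed = 1)
  expect_equal(fixed$k, 4L)
})

test_that("label images rasterize per section with 1-based cluster ids", {
  coords <- cbind(c(1L, 2L, 1L, 2L), c(1L, 1L, 2L, 2L), 1L)
  ras <- label_image(c(1L, 1L, 2L, 2L), coords)
  expect_length(ras, 1)
  expect_equal(ras$section_1, rbind(c(1L, 1L), c(2L, 2L)))

  # two sections give two rasters; indexing back recovers the labels
  sec2 <- coords
  sec2[, 3] <- 2L
  coords3d <- rbind(coords, sec2)
  labels <- c(1L, 2L, 1L, 2L, 3L, 3L, 4L, 4L)
  ras3 <- label_image(labels, coords3d)
  expect_length(ras3, 2)
  expect_equal(ras3$section_1[cbind(coords[, 2], coords[, 1])],
               labels[1:4])
  expect_equal(ras3$section_2[cbind(coords[, 2], coords[, 1])],
               labels[5:8])

  # missing grid cells stay NA
  sparse <- label_image(c(1L, 2L), cbind(c(1L, 3L), c(1L, 2L), 1L))
  expect_true(is.na(sparse$section_1[1, 2]))
})

test_that("cluster-peak correlations match the textbook formula", {
  ph <- small_phantom()
  red <- reduce_to_local_maxima(ph$dataset)
  labels <- ph$truth$region_labels
  res <- structure(list(labels = labels,
                        k = max(labels)), class = "cluster_result")
  peak_idx <- seq_len(min(10, length(red$dataset$mz)))
  cc <- correlate_clusters(res, red$dataset, peak_idx)
  expect_length(cc, max(labels))

  X <- red$dataset$intensities
  for (cl in seq_len(max(labels))) {
    member <- as.numeric(labels == cl)
    df <- cc[[paste0("cluster_", cl)]]
    for (r in seq_len(nrow(df))) {
      col <- X[, df$peak_index[r]]
      manual <- sum((member - mean(member)) * (col - mean(col))) /
        sqrt(sum((member - mean(member))^2) * sum((col - mean(col))^2))
      expect_equal(df$r[r], manual, tolerance = 1e-12)
    }
    expect_false(is.unsorted(-df$r))
  }

  # planted colocalization: a region's own peak ranks at the top
  centers1 <- ph$truth$peak_centers[[1]]
  red_idx <- match(centers1, red$axis_map$reduced_to_full)
  red_idx <- red_idx[!is.na(red_idx)]
  cc1 <- correlate_clusters(res, red$dataset, red_idx)[["cluster_1"]]
  expect_gt(cc1$r[1], 0.5)

  # zero-variance cases flagged with r = 0
  const_ds <- red$dataset
  const_ds$intensities[, 1] <- 1
  ccz <- correlate_clusters(res, const_ds, 1L)
  expect_true(all(vapply(ccz, function(d) d$zero_variance[1], logical(1))))
  allone <- structure(list(labels = rep(1L, nrow(X)), k = 1L),
                      class = "cluster_result")
  cc_one <- correlate_clusters(allone, red$dataset, peak_idx)
  expect_true(all(cc_one$cluster_1$r == 0))
  expect_true(all(cc_one$cluster_1$zero_variance))
})
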