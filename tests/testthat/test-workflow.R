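test_that("run_train executes the full pipeline and writes artifacts", {
  ph <- small_phantom()
  out <- withr::local_tempdir()
  res <- run_train(ph$dataset, out_dir = out, seed = 2,
                   hidden_dim = 32, latent_dim = 3, epochs = 10,
                   batch_size = 64)
  expect_s3_class(res$model, "msi_vae")
  expect_true(file.exists(file.path(out, "model.h5")))
  expect_true(file.exists(file.path(out, "metrics_train.json")))
  expect_true(file.exists(file.path(out, "manifest_train.json")))

  metrics <- jsonlite::read_json(file.path(out, "metrics_train.json"))
  expect_equal(metrics$final_mse, res$mse, tolerance = 1e-12)
  expect_length(metrics$loss_history, 10)

  manifest <- jsonlite::read_json(file.path(out, "manifest_train.json"))
  expect_equal(manifest$seed, 2)
  expect_true(nzchar(manifest$package_version))

  # the archive carries the training axis map
  back <- load_msi_vae(file.path(out, "model.h5"))
  expect_identical(back$axis_map$reduced_to_full,
                   res$axis_map$reduced_to_full)
})

test_that("run_train is reproducible for a fixed seed", {
  ph <- small_phantom()
  r1 <- run_train(ph$dataset, seed = 7, hidden_dim = 16, latent_dim = 2,
                  epochs = 5, batch_size = 64)
  r2 <- run_train(ph$dataset, seed = 7, hidden_dim = 16, latent_dim = 2,
                  epochs = 5, batch_size = 64)
  expect_identical(r1$mse, r2$mse)
  expect_identical(r1$model$history, r2$model$history)
})

test_that("stage failures name the failing stage", {
  flat <- msi_dataset(1:5, matrix(1, 4, 5))
  expect_error(run_train(flat, epochs = 2),
               "stage 'reduce_to_local_maxima'")
  expect_error(run_train("/nonexistent.h5"), "stage 'load'")
})

test_that("run_apply reproduces the training MSE on the training file and
           is chunk invariant", {
  ph <- cv_phantom()
  tr <- run_train(ph$dataset, seed = 3, hidden_dim = 32, latent_dim = 3,
                  epochs = 10, batch_size = 128)

  # applying the model to its own training data reproduces the metric
  ap_self <- run_apply(tr$model, ph$dataset)
  expect_equal(ap_self$mse, tr$mse, tolerance = 1e-6)
  expect_equal(nrow(ap_self$features), nrow(ph$dataset$intensities))

  # per-section vs fixed-size vs whole-data chunking agree
  ap_rows <- run_apply(tr$model, ph$dataset, chunk_size = 97)
  ap_all <- run_apply(tr$model, ph$dataset,
                      chunk_size = nrow(ph$dataset$intensities))
  expect_lt(max(abs(ap_self$features - ap_rows$features)), 1e-5)
  expect_lt(max(abs(ap_self$features - ap_all$features)), 1e-5)
  expect_equal(ap_rows$mse, ap_all$mse, tolerance = 1e-9)

  # axis mismatch without a stored map is an instructive error
  naked <- tr$model
  naked$axis_map <- NULL
  expect_error(run_apply(naked, ph$dataset), "align spectra")
})

test_that("run_apply loads a saved archive and writes its outputs", {
  ph <- small_phantom()
  out_tr <- withr::local_tempdir()
  run_train(ph$dataset, out_dir = out_tr, seed = 1, hidden_dim = 16,
            latent_dim = 2, epochs = 5, batch_size = 64)
  in_h5 <- file.path(out_tr, "input.h5")
  write_msi_h5(ph$dataset, in_h5)

  out_ap <- withr::local_tempdir()
  ap <- run_apply(file.path(out_tr, "model.h5"), in_h5, out_dir = out_ap)
  expect_true(file.exists(file.path(out_ap, "encoded_features.h5")))
  expect_true(file.exists(file.path(out_ap, "metrics_apply.json")))
  feats <- msivae:::h5_read_dataset(file.path(out_ap,
                                              "encoded_features.h5"),
                                    "z_mean")
  expect_equal(dim(feats), dim(ap$features))
})

test_that("cross-validation splits sections by the training fraction and
           tabulates peak frequencies", {
  ph <- cv_phantom()  # 10 sections
  # beta = 1 keeps the per-fold selections populated at this small scale
  cv <- suppressWarnings(
    run_crossvalidate(ph$dataset, folds = 3, train_fraction = 0.2,
                      seed = 5, beta = 1, hidden_dim = 32, latent_dim = 3,
                      epochs = 10, batch_size = 128))
  expect_equal(nrow(cv$fold_metrics), 3)
  # 20% of 10 sections -> 2 training sections per fold
  n_per_sec <- sum(ph$dataset$coords[, 3] == 1)
  expect_true(all(cv$fold_metrics$train_mse > 0))
  expect_true(all(cv$fold_metrics$test_mse > 0))
  expect_true(all(cv$peak_frequency$n_folds >= 1 &
                    cv$peak_frequency$n_folds <= 3))
  expect_true(is.na(cv$stability_fraction) ||
                (cv$stability_fraction >= 0 && cv$stability_fraction <= 1))
  expect_gt(nrow(cv$peak_frequency), 0)

  expect_error(run_crossvalidate(small_phantom()$dataset, folds = 2),
               "sections")
  expect_error(run_crossvalidate(ph$dataset, folds = 1), "folds")
})
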