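test_that("KL term matches the closed form and a Monte-Carlo estimate", {
  expect_equal(kl_term(0, 0), 0)
  expect_equal(kl_term(1, 0), 0.5)
  expect_equal(kl_term(c(1, 0), c(0, 0)), 0.5)
  expect_error(kl_term(c(1, NaN), c(0, 0)), "non-finite")
  expect_error(kl_term(1, c(0, 0)), "equal length")

  # KL >= 0, zero only at the prior
  set.seed(7)
  for (rep in 1:50) {
    mu <- rnorm(4); lv <- rnorm(4, 0, 0.7)
    expect_gte(kl_term(mu, lv), 0)
  }
  expect_gt(kl_term(c(0.1, 0, 0), c(0, 0, 0)), 0)

  # Monte-Carlo oracle: E_q[log q(z) - log p(z)] with 1e6 samples
  set.seed(11)
  mu <- c(0.7, -0.4, 1.2)
  lv <- c(0.3, -0.5, 0.1)
  sd_q <- exp(0.5 * lv)
  z <- matrix(rnorm(3e6, mean = rep(mu, each = 1e6),
                    sd = rep(sd_q, each = 1e6)), ncol = 3)
  logq <- sapply(1:3, function(j) dnorm(z[, j], mu[j], sd_q[j], log = TRUE))
  logp <- dnorm(z, log = TRUE)
  mc <- sum(colMeans(logq - logp))
  expect_equal(kl_term(mu, lv), mc, tolerance = 0.01)
})

test_that("reconstruction term matches direct evaluation and handles
           boundary values", {
  expect_equal(reconstruction_term(c(0.5, 0.5), c(0.5, 0.5)), 2 * log(2))
  expect_lt(suppressMessages(
    reconstruction_term(c(1, 0), c(1 - 1e-9, 1e-9))), 1e-5)

  set.seed(3)
  x <- runif(10)
  xh <- runif(10, 0.01, 0.99)
  direct <- -sum(x * log(xh) + (1 - x) * log(1 - xh))
  expect_equal(reconstruction_term(x, xh), direct, tolerance = 1e-12)
  expect_equal(reconstruction_term(x, xh, type = "categorical"),
               -sum(x * log(xh)), tolerance = 1e-12)
  expect_message(reconstruction_term(c(0.5), c(1)), "clipping")
})

test_that("reparameterization is the deterministic affine map", {
  expect_equal(reparameterize(c(1, 2), c(0.4, -1), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(1, 1)), c(2, 3))
  # sampled moments match (mu, sigma^2)
  set.seed(5)
  mu <- 0.8; lv <- 0.6
  z <- reparameterize(mu, lv, rnorm(1e5))
  expect_equal(mean(z), mu, tolerance = 0.02)
  expect_equal(var(z), exp(lv), tolerance = 0.02 * exp(lv) + 0.02)
})

test_that("reconstruction_mse equals the loop-computed mean", {
  expect_equal(reconstruction_mse(matrix(0), matrix(0.5)), 0.25)
  expect_equal(reconstruction_mse(diag(3), diag(3)), 0)
  expect_error(reconstruction_mse(matrix(0, 2, 2), matrix(0, 3, 2)),
               "shape mismatch")
  set.seed(8)
  a <- matrix(runif(20), 4, 5); b <- matrix(runif(20), 4, 5)
  acc <- 0
  for (i in 1:4) for (j in 1:5) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(reconstruction_mse(a, b), acc / 20)
})

test_that("architecture shapes follow the 512/5/512 default and seeds fix
           the initialization", {
  m <- build_vae(2000)
  expect_equal(dim(m$params$Wmu), c(512L, 5L))
  expect_equal(dim(m$params$W1), c(2000L, 512L))
  expect_equal(dim(m$params$W4), c(512L, 2000L))

  m1 <- build_vae(50, hidden_dim = 8, latent_dim = 2, seed = 123)
  m2 <- build_vae(50, hidden_dim = 8, latent_dim = 2, seed = 123)
  expect_identical(m1$params$W1, m2$params$W1)
  m3 <- build_vae(50, hidden_dim = 8, latent_dim = 2, seed = 124)
  expect_false(identical(m1$params$W1, m3$params$W1))

  # untrained tiny net still produces sigmoid-range output
  tiny <- build_vae(3, hidden_dim = 4, latent_dim = 1, seed = 1)
  y <- reconstruct(tiny, matrix(c(0.2, 0.3, 0.5), 1))
  expect_length(y, 3)
  expect_true(all(y > 0 & y < 1))

  expect_error(build_vae(0), "input_dim")
  expect_error(build_vae(5, hidden_dim = 2, latent_dim = 3), "hidden_dim")
})

test_that("the batch loss decomposes additively and matches a per-spectrum
           loop", {
  set.seed(21)
  X <- matrix(runif(8 * 12), 8, 12); X <- X / rowSums(X)
  model <- msi_vae(X, hidden_dim = 6, latent_dim = 2, epochs = 3,
                   batch_size = 4, seed = 2, keep_data = FALSE)
  lb <- vae_loss(model, X)
  expect_equal(lb$total, lb$reconstruction + lb$kl, tolerance = 1e-12)

  # loop oracle: average the per-spectrum terms computed independently
  ef <- encode(model, X)
  xh <- reconstruct(model, X)
  recs <- kls <- numeric(8)
  for (i in 1:8) {
    recs[i] <- reconstruction_term(X[i, ], xh[i, ])
    kls[i] <- kl_term(ef$z_mean[i, ], ef$z_logvar[i, ])
  }
  expect_equal(lb$reconstruction, mean(recs), tolerance = 1e-10)
  expect_equal(lb$kl, mean(kls), tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  X <- matrix(runif(5 * 7), 5, 7); X <- X / rowSums(X)
  eps_draw <- matrix(rnorm(10), 5, 2)
  for (obn in c(FALSE, TRUE)) {
    model <- build_vae(7, hidden_dim = 4, latent_dim = 2, seed = 9,
                       output_batchnorm = obn)
    p <- model$params
    p$g1 <- runif(4, 0.5, 1.5); p$be1 <- rnorm(4, 0, 0.3)
    p$g3 <- runif(4, 0.5, 1.5); p$be3 <- rnorm(4, 0, 0.3)
    p$gmu <- runif(2, 0.5, 1.5); p$glv <- runif(2, 0.5, 1.5)
    if (obn) {
      p$g4 <- runif(7, 0.5, 1.5); p$be4 <- rnorm(7, 0, 0.3)
    } else {
      p$b4 <- rnorm(7, 0, 0.3)
    }
    lossf <- function(pp) {
      fw <- msivae:::vae_forward_train(pp, X, eps_draw, obn, TRUE)
      msivae:::vae_batch_loss(fw, X, "binary")$total
    }
    fw <- msivae:::vae_forward_train(p, X, eps_draw, obn, TRUE)
    g <- msivae:::vae_backward(p, X, fw, eps_draw, obn, TRUE, "binary")
    for (nm in setdiff(names(g), c("b1", "b3", "bmu", "blv",
                                   if (obn) "b4"))) {
      for (j in seq_len(min(3, length(p[[nm]])))) {
        h <- 1e-6
        pp <- p; pp[[nm]][j] <- pp[[nm]][j] + h; up <- lossf(pp)
        pp <- p; pp[[nm]][j] <- pp[[nm]][j] - h; dn <- lossf(pp)
        num <- (up - dn) / (2 * h)
        expect_equal(g[[nm]][j], num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d] (obn=%s)", nm, j, obn))
      }
    }
  }
})

test_that("training improves the loss and is reproducible given the seed", {
  ph <- small_phantom()
  nrm <- tic_normalize(reduce_to_local_maxima(ph$dataset)$dataset)
  f1 <- msi_vae(nrm, hidden_dim = 32, latent_dim = 3, epochs = 15,
                batch_size = 64, seed = 4, keep_data = FALSE)
  expect_true(all(is.finite(f1$history$total)))
  expect_lt(tail(f1$history$total, 1), f1$history$total[1])

  f2 <- msi_vae(nrm, hidden_dim = 32, latent_dim = 3, epochs = 15,
                batch_size = 64, seed = 4, keep_data = FALSE)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)

  # one optimizer step per epoch when the batch spans the data
  f3 <- msi_vae(nrm$intensities[1:32, ], hidden_dim = 8, latent_dim = 2,
                epochs = 1, batch_size = 32, seed = 1, keep_data = FALSE)
  expect_equal(nrow(f3$history), 1)
})

test_that("encoding is deterministic, duplicate-consistent and
           batch-partition invariant", {
  ph <- small_phantom()
  nrm <- tic_normalize(reduce_to_local_maxima(ph$dataset)$dataset)
  fit <- msi_vae(nrm, hidden_dim = 32, latent_dim = 3, epochs = 10,
                 batch_size = 64, seed = 4, keep_data = FALSE)

  X <- nrm$intensities
  dupl <- rbind(X[1, ], X[1, ])
  zd <- encode(fit, dupl)$z_mean
  expect_identical(zd[1, ], zd[2, ])

  z_all <- encode(fit, X)$z_mean
  z_chunks <- do.call(rbind, lapply(split(seq_len(nrow(X)),
                                          ceiling(seq_len(nrow(X)) / 32)),
                                    function(i) encode(fit, X[i, ])$z_mean))
  expect_lt(max(abs(z_all - z_chunks)), 1e-5)

  expect_error(encode(fit, matrix(0.1, 2, 7)), "dimension mismatch")

  xh <- reconstruct(fit, X)
  expect_equal(dim(xh), dim(X))
  expect_true(all(xh > 0 & xh < 1))
})

test_that("model persistence roundtrips weights bitwise", {
  ph <- small_phantom()
  nrm <- tic_normalize(reduce_to_local_maxima(ph$dataset)$dataset)
  fit <- msi_vae(nrm, hidden_dim = 16, latent_dim = 2, epochs = 5,
                 batch_size = 64, seed = 6, keep_data = FALSE)
  path <- withr::local_tempfile(fileext = ".h5")
  save_msi_vae(fit, path)
  expect_true(file.exists(paste0(path, ".json")))

  back <- load_msi_vae(path)
  for (nm in names(fit$params))
    expect_identical(unname(back$params[[nm]]), unname(fit$params[[nm]]),
                     label = paste("param", nm))
  for (nm in names(fit$bn))
    expect_identical(back$bn[[nm]], fit$bn[[nm]], label = paste("bn", nm))
  expect_identical(encode(back, nrm$intensities)$z_mean,
                   encode(fit, nrm$intensities)$z_mean)

  # wrong-dimension data still fail cleanly after a load
  expect_error(encode(back, matrix(0.5, 1, 3)), "dimension mismatch")

  # corrupted archive
  bad <- withr::local_tempfile(fileext = ".h5")
  writeBin(as.raw(1:64), bad)
  expect_error(load_msi_vae(bad))
})

test_that("model methods expose the fit like a classic modelling object", {
  set.seed(31)
  X <- matrix(runif(40 * 12), 40, 12); X <- X / rowSums(X)
  fit <- msi_vae(X, hidden_dim = 8, latent_dim = 2, epochs = 5,
                 batch_size = 20, seed = 3)
  expect_output(print(fit), "trained")
  s <- summary(fit)
  expect_s3_class(s, "summary.msi_vae")
  expect_true(is.numeric(s$train_mse))
  expect_named(coef(fit), names(fit$params), ignore.order = TRUE)
  expect_equal(dim(predict(fit, type = "latent")), c(40L, 2L))
  expect_equal(fitted(fit), predict(fit, type = "response"))
  expect_equal(residuals(fit), X - fitted(fit))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(3L, 12L))
  expect_true(all(sim > 0 & sim < 1))
})

test_that("unnormalized input is rejected", {
  expect_error(msi_vae(matrix(c(2, 0.5), 1)), "\\[0, 1\\]")
  ds <- tiny_dataset()
  expect_error(msi_vae(ds), "TIC-normalized")
})
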