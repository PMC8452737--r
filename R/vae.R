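#' Variational autoencoder building blocks
#'
#' `kl_term()` is the closed-form Kullback-Leibler divergence of a
#' diagonal Gaussian `N(mu, diag(sigma^2))` from the standard-normal
#' prior: `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)`, always >= 0 and
#' zero only for the prior itself. `reparameterize()` draws a latent
#' vector as `z = mu + exp(0.5 * logvar) * eps` with `eps ~ N(0, I)`,
#' making the sampling step differentiable in `mu` and `logvar`.
#'
#' @param z_mean,z_logvar Numeric vectors (or matrices with one latent
#'   vector per row) of equal shape: posterior mean and log-variance.
#' @param epsilon Standard-normal draw of the same shape as `z_mean`.
#' @return `kl_term()`: a scalar for vector input, a per-row vector for
#'   matrix input. `reparameterize()`: the sampled latent vector(s).
#' @examples
#' kl_term(0, 0)        # 0: identical distributions
#' kl_term(1, 0)        # 0.5
#' reparameterize(c(1, 2), c(0, 0), c(0, 0))  # equals the mean
#' @export
kl_term <- function(z_mean, z_logvar) {
  if (length(z_mean) != length(z_logvar))
    stop("z_mean and z_logvar must have equal length", call. = FALSE)
  if (any(!is.finite(z_mean)) || any(!is.finite(z_logvar)))
    stop("non-finite inputs to kl_term", call. = FALSE)
  contrib <- 0.5 * (z_mean^2 + exp(z_logvar) - z_logvar - 1)
  if (is.matrix(z_mean)) rowSums(contrib) else sum(contrib)
}

#' @rdname kl_term
#' @export
reparameterize <- function(z_mean, z_logvar, epsilon) {
  z_mean + exp(0.5 * z_logvar) * epsilon
}

#' Reconstruction loss of a decoded spectrum
#'
#' Element-wise (Bernoulli) cross-entropy between a TIC-normalized
#' spectrum `x` in \[0, 1\] and its sigmoid-decoded reconstruction,
#' summed over the m/z bins:
#' `-sum_j x_j log(xhat_j) + (1 - x_j) log(1 - xhat_j)`. Decoded values
#' at exactly 0 or 1 are clipped to `[1e-7, 1 - 1e-7]` (reported once per
#' call). With `type = "categorical"` the alternative softmax-style
#' likelihood `-sum_j x_j log(xhat_j)` is returned.
#'
#' @param x Numeric vector in \[0, 1\] (one normalized spectrum).
#' @param x_hat Decoded spectrum of equal length, values in (0, 1).
#' @param type `"binary"` (default) or `"categorical"`.
#' @return Non-negative scalar.
#' @examples
#' reconstruction_term(c(0.5, 0.5), c(0.5, 0.5))  # 2 * log(2)
#' @export
reconstruction_term <- function(x, x_hat, type = c("binary", "categorical")) {
  type <- match.arg(type)
  if (length(x) != length(x_hat))
    stop("x and x_hat must have equal length", call. = FALSE)
  eps <- 1e-7
  if (any(x_hat <= 0 | x_hat >= 1)) {
    message("clipping decoded values to [1e-07, 1 - 1e-07]")
    x_hat <- pmin(pmax(x_hat, eps), 1 - eps)
  }
  if (type == "binary")
    -sum(x * log(x_hat) + (1 - x) * log1p(-x_hat))
  else
    -sum(x * log(x_hat))
}

#' Mean squared reconstruction error
#'
#' Mean over all `N * d` entries of the squared difference between the
#' normalized data and their reconstruction — the headline
#' reconstruction-quality figure of the method.
#'
#' @param x,x_hat Numeric matrices of identical shape.
#' @return Scalar mean squared error.
#' @export
reconstruction_mse <- function(x, x_hat) {
  if (!identical(dim(as.matrix(x)), dim(as.matrix(x_hat))))
    stop("shape mismatch between x and x_hat", call. = FALSE)
  mean((x - x_hat)^2)
}

## ---- internal network machinery -------------------------------------

BN_EPS <- 1e-3     # batch-norm variance floor
BN_MOMENTUM <- 0.99
ADAM_B1 <- 0.9
ADAM_B2 <- 0.999
ADAM_EPS <- 1e-7
CLIP_EPS <- 1e-7

# add / multiply a length-f vector into every row of an m x f matrix
addrow <- function(M, v) M + rep(v, rep.int(nrow(M), length(v)))
mulrow <- function(M, v) M * rep(v, rep.int(nrow(M), length(v)))

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_vae_params <- function(input_dim, hidden_dim, latent_dim,
                            output_batchnorm, latent_batchnorm) {
  d <- input_dim; h <- hidden_dim; k <- latent_dim
  p <- list(
    W1 = glorot(d, h), b1 = rep(0, h),
    g1 = rep(1, h), be1 = rep(0, h),
    Wmu = glorot(h, k), bmu = rep(0, k),
    Wlv = glorot(h, k), blv = rep(0, k),
    W3 = glorot(k, h), b3 = rep(0, h),
    g3 = rep(1, h), be3 = rep(0, h),
    W4 = glorot(h, d), b4 = rep(0, d))
  if (latent_batchnorm) {
    p$gmu <- rep(1, k); p$bemu <- rep(0, k)
    p$glv <- rep(1, k); p$belv <- rep(0, k)
  }
  if (output_batchnorm) {
    p$g4 <- rep(1, d)
    p$be4 <- rep(0, d)
  }
  p
}

init_bn_state <- function(hidden_dim, input_dim, latent_dim,
                          output_batchnorm, latent_batchnorm) {
  s <- list(mm1 = rep(0, hidden_dim), mv1 = rep(1, hidden_dim),
            mm3 = rep(0, hidden_dim), mv3 = rep(1, hidden_dim))
  if (latent_batchnorm) {
    s$mmmu <- rep(0, latent_dim); s$mvmu <- rep(1, latent_dim)
    s$mmlv <- rep(0, latent_dim); s$mvlv <- rep(1, latent_dim)
  }
  if (output_batchnorm) {
    s$mm4 <- rep(0, input_dim)
    s$mv4 <- rep(1, input_dim)
  }
  s
}

bn_forward_train <- function(A, gamma, beta) {
  m <- nrow(A)
  mu <- colMeans(A)
  v <- pmax(colMeans(A * A) - mu^2, 0)     # population variance
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- mulrow(addrow(A, -mu), istd)
  list(y = addrow(mulrow(xhat, gamma), beta),
       xhat = xhat, istd = istd, mu = mu, v = v)
}

bn_forward_infer <- function(A, gamma, beta, mmean, mvar) {
  xhat <- mulrow(addrow(A, -mmean), 1 / sqrt(mvar + BN_EPS))
  addrow(mulrow(xhat, gamma), beta)
}

# standard batch-norm backward pass; dY is the gradient at the BN output
bn_backward <- function(dY, cache, gamma) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- mulrow(dY, gamma)
  dA <- mulrow(m * dxhat - addrow(matrix(0, m, ncol(dY)), colSums(dxhat)) -
                 mulrow(cache$xhat, colSums(dxhat * cache$xhat)),
               cache$istd / m)
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Dense biases feeding a batch-norm layer are skipped: batch norm
# subtracts the column mean, so a pre-BN bias cancels exactly (its
# gradient is identically zero).  They are kept in the parameter list (at
# zero) for the stated layer contract and for inference-mode forwards.
vae_forward_train <- function(p, X, eps_draw, output_batchnorm,
                              latent_batchnorm) {
  bn1 <- bn_forward_train(X %*% p$W1, p$g1, p$be1)
  h1 <- pmax(bn1$y, 0)
  if (latent_batchnorm) {
    bnmu <- bn_forward_train(h1 %*% p$Wmu, p$gmu, p$bemu)
    bnlv <- bn_forward_train(h1 %*% p$Wlv, p$glv, p$belv)
    mu <- bnmu$y
    lv <- bnlv$y
  } else {
    bnmu <- bnlv <- NULL
    mu <- addrow(h1 %*% p$Wmu, p$bmu)
    lv <- addrow(h1 %*% p$Wlv, p$blv)
  }
  z <- mu + exp(0.5 * lv) * eps_draw
  bn3 <- bn_forward_train(z %*% p$W3, p$g3, p$be3)
  h3 <- pmax(bn3$y, 0)
  if (output_batchnorm) {
    bn4 <- bn_forward_train(h3 %*% p$W4, p$g4, p$be4)
    pre <- bn4$y
  } else {
    bn4 <- NULL
    pre <- addrow(h3 %*% p$W4, p$b4)
  }
  y <- sigmoid(pre)
  list(bn1 = bn1, h1 = h1, bnmu = bnmu, bnlv = bnlv, mu = mu, lv = lv,
       z = z, bn3 = bn3, h3 = h3, bn4 = bn4, y = y)
}

vae_batch_loss <- function(fw, X, loss_type) {
  m <- nrow(X)
  yc <- pmin(pmax(fw$y, CLIP_EPS), 1 - CLIP_EPS)
  rec <- if (loss_type == "binary")
    -sum(X * log(yc) + (1 - X) * log1p(-yc)) / m
  else
    -sum(X * log(yc)) / m
  kl <- 0.5 * sum(fw$mu^2 + exp(fw$lv) - fw$lv - 1) / m
  list(reconstruction = rec, kl = kl, total = rec + kl)
}

vae_backward <- function(p, X, fw, eps_draw, output_batchnorm,
                         latent_batchnorm, loss_type) {
  m <- nrow(X)
  g <- list()
  # combined sigmoid + cross-entropy gradient at the pre-activation
  dpre <- if (loss_type == "binary") (fw$y - X) / m
          else (X * fw$y - X) / m
  if (output_batchnorm) {
    bb4 <- bn_backward(dpre, fw$bn4, p$g4)
    g$g4 <- bb4$dgamma; g$be4 <- bb4$dbeta
    dA4 <- bb4$dA
  } else {
    dA4 <- dpre
  }
  g$W4 <- crossprod(fw$h3, dA4)
  g$b4 <- colSums(dA4)
  dh3 <- tcrossprod(dA4, p$W4)
  dh3[fw$h3 <= 0] <- 0
  bb3 <- bn_backward(dh3, fw$bn3, p$g3)
  g$g3 <- bb3$dgamma; g$be3 <- bb3$dbeta
  g$W3 <- crossprod(fw$z, bb3$dA)
  g$b3 <- colSums(bb3$dA)
  dz <- tcrossprod(bb3$dA, p$W3)
  # reparameterized sampling + KL regularizer (at the head outputs)
  dmu <- dz + fw$mu / m
  dlv <- dz * eps_draw * 0.5 * exp(0.5 * fw$lv) + 0.5 * (exp(fw$lv) - 1) / m
  if (latent_batchnorm) {
    bbmu <- bn_backward(dmu, fw$bnmu, p$gmu)
    g$gmu <- bbmu$dgamma; g$bemu <- bbmu$dbeta
    dmu <- bbmu$dA
    bblv <- bn_backward(dlv, fw$bnlv, p$glv)
    g$glv <- bblv$dgamma; g$belv <- bblv$dbeta
    dlv <- bblv$dA
  }
  g$Wmu <- crossprod(fw$h1, dmu)
  g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(fw$h1, dlv)
  g$blv <- colSums(dlv)
  dh1 <- tcrossprod(dmu, p$Wmu) + tcrossprod(dlv, p$Wlv)
  dh1[fw$h1 <= 0] <- 0
  bb1 <- bn_backward(dh1, fw$bn1, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  g$W1 <- crossprod(X, bb1$dA)
  g$b1 <- colSums(bb1$dA)
  g
}

# Adam over one flat parameter vector (cheaper than 16 per-array updates)
adam_init <- function(pvec) {
  list(t = 0, m = numeric(length(pvec)), v = numeric(length(pvec)))
}

adam_step_vec <- function(pvec, gvec, state, lr) {
  state$t <- state$t + 1
  state$m <- ADAM_B1 * state$m + (1 - ADAM_B1) * gvec
  state$v <- ADAM_B2 * state$v + (1 - ADAM_B2) * gvec^2
  pvec <- pvec - lr * (state$m / (1 - ADAM_B1^state$t)) /
    (sqrt(state$v / (1 - ADAM_B2^state$t)) + ADAM_EPS)
  list(pvec = pvec, state = state)
}

flatten_params <- function(p, nms) {
  unlist(lapply(nms, function(nm) as.vector(p[[nm]])), use.names = FALSE)
}

unflatten_params <- function(p, nms, vec) {
  off <- 0L
  for (nm in nms) {
    n <- length(p[[nm]])
    chunk <- vec[(off + 1L):(off + n)]
    if (is.matrix(p[[nm]])) dim(chunk) <- dim(p[[nm]])
    p[[nm]] <- chunk
    off <- off + n
  }
  p
}

## ---- model construction and fitting ---------------------------------

#' Build an untrained autoencoder
#'
#' Constructs the five-layer fully connected architecture with freshly
#' initialized weights (Glorot-uniform under `seed`) but no training:
#' input (`d`) -> dense + batch norm + ReLU (`hidden_dim`) -> two linear
#' heads for the latent mean and log-variance (`latent_dim`) -> dense +
#' batch norm + ReLU (`hidden_dim`) -> dense (+ optional batch norm) +
#' sigmoid output (`d`). Mostly useful for inspecting shapes and for
#' experiments with hand-set weights; use [msi_vae()] to fit.
#'
#' @inheritParams msi_vae
#' @param input_dim Number of m/z bins the network reads (`d`).
#' @return An object of class `msi_vae` with `trained = FALSE`.
#' @export
build_vae <- function(input_dim, hidden_dim = 512, latent_dim = 5,
                      learning_rate = 0.001, batch_size = 128,
                      epochs = 100, seed = 1, beta_peaks = 2.5,
                      loss = c("binary", "categorical"),
                      output_batchnorm = FALSE,
                      latent_batchnorm = TRUE,
                      attribution = c("signed", "abs")) {
  loss <- match.arg(loss)
  attribution <- match.arg(attribution)
  if (input_dim < 1) stop("input_dim must be >= 1", call. = FALSE)
  if (hidden_dim < latent_dim || latent_dim < 1)
    stop("need hidden_dim >= latent_dim >= 1", call. = FALSE)
  if (batch_size < 1 || epochs < 1 || learning_rate <= 0)
    stop("invalid training hyperparameters", call. = FALSE)
  config <- list(hidden_dim = as.integer(hidden_dim),
                 latent_dim = as.integer(latent_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 beta_peaks = beta_peaks, loss = loss,
                 output_batchnorm = isTRUE(output_batchnorm),
                 latent_batchnorm = isTRUE(latent_batchnorm),
                 attribution = attribution)
  set.seed(seed)
  params <- init_vae_params(input_dim, hidden_dim, latent_dim,
                            config$output_batchnorm,
                            config$latent_batchnorm)
  structure(list(params = params,
                 bn = init_bn_state(hidden_dim, input_dim, latent_dim,
                                    config$output_batchnorm,
                                    config$latent_batchnorm),
                 input_dim = as.integer(input_dim), config = config,
                 history = NULL, trained = FALSE, mz = NULL,
                 axis_map = NULL),
            class = "msi_vae")
}

as_training_matrix <- function(x) {
  if (inherits(x, "msi_dataset")) {
    if (!isTRUE(x$meta$normalized))
      stop("dataset must be TIC-normalized before fitting (tic_normalize)",
           call. = FALSE)
    x$intensities
  } else {
    x <- as.matrix(x)
    if (any(x < 0) || any(x > 1))
      stop("input spectra must lie in [0, 1]; TIC-normalize first",
           call. = FALSE)
    x
  }
}

#' Fit a variational autoencoder to MSI spectra
#'
#' The package's central model: a five-layer fully connected variational
#' autoencoder trained on TIC-normalized pixel spectra (each pixel is one
#' training sample; spatial relationships are ignored). The probabilistic
#' encoder maps a spectrum to a `latent_dim`-dimensional Gaussian
#' posterior `N(mu(x), diag(sigma^2(x)))`; the decoder reconstructs the
#' spectrum from a latent sample. Training minimizes the negative
#' evidence lower bound — per-bin cross-entropy reconstruction loss
#' summed over bins, plus the closed-form KL divergence from the
#' standard-normal prior — by minibatch Adam. Batch normalization is
#' applied to the pre-activations of both hidden ReLU layers (and, by
#' default, to the sigmoid output layer); the latent heads are linear so
#' the posterior parameters are not renormalized.
#'
#' Training is exactly reproducible: weight initialization, epoch
#' shuffling and the reparameterization noise all come from R's RNG
#' seeded with `seed`.
#'
#' @param x A TIC-normalized [msi_dataset()] (typically after
#'   [reduce_to_local_maxima()]), or a numeric matrix with one spectrum
#'   per row, values in \[0, 1\].
#' @param hidden_dim Neurons in each hidden ReLU layer (default 512).
#' @param latent_dim Latent dimensions `k` (default 5).
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size Spectra per minibatch (default 128; batches of at
#'   least 2 are required for batch statistics, and `batch_size > N`
#'   falls back to whole-data batches).
#' @param epochs Training passes over the data (default 100).
#' @param seed Integer RNG seed.
#' @param beta_peaks Default multiplier for the peak-learning weight
#'   threshold (see [learn_peaks()]); in `[1, 2.5]` in the original
#'   analyses.
#' @param loss Reconstruction likelihood: `"binary"` (element-wise
#'   cross-entropy, default) or `"categorical"`.
#' @param output_batchnorm Apply batch normalization to the output
#'   pre-activation (default `FALSE`; at short training budgets the
#'   rate-limited batch-norm shift cannot reach the scale of normalized
#'   spectra, flooring the reconstruction — see the package vignette).
#' @param latent_batchnorm Apply batch normalization to the latent mean
#'   and log-variance heads (default `TRUE`); besides regularizing the
#'   posterior parameters this strongly amplifies early gradient flow
#'   into the encoder, which the weight-based peak attribution relies
#'   on.
#' @param attribution Peak attribution reads the signed maximum weight
#'   (`"signed"`, default) or the maximum magnitude (`"abs"`).
#' @param keep_data Store the training matrix in the fit (default
#'   `TRUE`), enabling `fitted()`, `residuals()` and `summary()` without
#'   re-supplying the data.
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class `msi_vae` with components `params` (all
#'   weights, biases and batch-norm parameters), `bn` (moving
#'   batch-statistics used at inference), `history` (per-epoch mean
#'   total/reconstruction/KL loss), `config`, `input_dim`, and — when
#'   the input was a dataset — `mz`. Methods: `print`, `summary`,
#'   `coef`, `plot`, `predict`, `fitted`, `residuals`, `simulate`.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(width = 12, height = 12, d = 300,
#'                                     n_regions = 3, peaks_per_region = 4,
#'                                     shared_peaks = 3, seed = 7))
#' red <- reduce_to_local_maxima(ph$dataset)
#' fit <- msi_vae(tic_normalize(red$dataset), hidden_dim = 32,
#'                latent_dim = 3, epochs = 5, seed = 1)
#' fit
#' }
#' @seealso [encode()], [reconstruct()], [learn_peaks()],
#'   [cluster_features()]
#' @export
msi_vae <- function(x, hidden_dim = 512, latent_dim = 5,
                    learning_rate = 0.001, batch_size = 128, epochs = 100,
                    seed = 1, beta_peaks = 2.5,
                    loss = c("binary", "categorical"),
                    output_batchnorm = FALSE,
                    latent_batchnorm = TRUE,
                    attribution = c("signed", "abs"),
                    keep_data = TRUE, verbose = FALSE) {
  X <- as_training_matrix(x)
  model <- build_vae(ncol(X), hidden_dim = hidden_dim,
                     latent_dim = latent_dim,
                     learning_rate = learning_rate,
                     batch_size = batch_size, epochs = epochs, seed = seed,
                     beta_peaks = beta_peaks, loss = loss,
                     output_batchnorm = output_batchnorm,
                     latent_batchnorm = latent_batchnorm,
                     attribution = attribution)
  if (inherits(x, "msi_dataset")) model$mz <- x$mz
  model <- vae_train(model, X, verbose = verbose)
  if (keep_data) model$x <- X
  model
}

# Minibatch Adam training; `model` comes from build_vae (RNG already
# seeded there, so init + shuffling + noise form one reproducible stream).
vae_train <- function(model, X, verbose = FALSE) {
  cfg <- model$config
  n <- nrow(X)
  if (n < 2) stop("need at least 2 spectra to train", call. = FALSE)
  bs <- min(cfg$batch_size, n)
  p <- model$params
  bn <- model$bn
  obn <- cfg$output_batchnorm
  lbn <- cfg$latent_batchnorm
  # biases absorbed by a following batch-norm layer are not trained
  trainables <- setdiff(names(p),
                        c("b1", "b3", if (obn) "b4",
                          if (lbn) c("bmu", "blv")))
  pvec <- flatten_params(p, trainables)
  state <- adam_init(pvec)
  hist <- matrix(NA_real_, cfg$epochs, 3,
                 dimnames = list(NULL, c("total", "reconstruction", "kl")))
  k <- cfg$latent_dim
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq.int(1, n, by = bs)
    ep <- c(0, 0)
    nb <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + bs - 1, n)]
      if (length(idx) < 2) next  # batch statistics need >= 2 spectra
      Xb <- X[idx, , drop = FALSE]
      eps_draw <- matrix(stats::rnorm(length(idx) * k), length(idx), k)
      fw <- vae_forward_train(p, Xb, eps_draw, obn, lbn)
      lb <- vae_batch_loss(fw, Xb, cfg$loss)
      if (!is.finite(lb$total))
        stop(sprintf(
          "NaN/Inf loss at epoch %d, batch %d; try a lower learning_rate",
          epoch, nb + 1L), call. = FALSE)
      g <- vae_backward(p, Xb, fw, eps_draw, obn, lbn, cfg$loss)
      up <- adam_step_vec(pvec, flatten_params(g, trainables), state,
                          cfg$learning_rate)
      pvec <- up$pvec
      state <- up$state
      p <- unflatten_params(p, trainables, pvec)
      # moving statistics for inference-mode batch norm
      bn$mm1 <- BN_MOMENTUM * bn$mm1 + (1 - BN_MOMENTUM) * fw$bn1$mu
      bn$mv1 <- BN_MOMENTUM * bn$mv1 + (1 - BN_MOMENTUM) * fw$bn1$v
      bn$mm3 <- BN_MOMENTUM * bn$mm3 + (1 - BN_MOMENTUM) * fw$bn3$mu
      bn$mv3 <- BN_MOMENTUM * bn$mv3 + (1 - BN_MOMENTUM) * fw$bn3$v
      if (lbn) {
        bn$mmmu <- BN_MOMENTUM * bn$mmmu + (1 - BN_MOMENTUM) * fw$bnmu$mu
        bn$mvmu <- BN_MOMENTUM * bn$mvmu + (1 - BN_MOMENTUM) * fw$bnmu$v
        bn$mmlv <- BN_MOMENTUM * bn$mmlv + (1 - BN_MOMENTUM) * fw$bnlv$mu
        bn$mvlv <- BN_MOMENTUM * bn$mvlv + (1 - BN_MOMENTUM) * fw$bnlv$v
      }
      if (obn) {
        bn$mm4 <- BN_MOMENTUM * bn$mm4 + (1 - BN_MOMENTUM) * fw$bn4$mu
        bn$mv4 <- BN_MOMENTUM * bn$mv4 + (1 - BN_MOMENTUM) * fw$bn4$v
      }
      ep <- ep + c(lb$reconstruction, lb$kl)
      nb <- nb + 1L
    }
    hist[epoch, ] <- c(sum(ep) / nb, ep[1] / nb, ep[2] / nb)
    if (verbose && (epoch %% 10 == 0 || epoch == 1))
      message(sprintf("epoch %3d  loss %.4f (rec %.4f, kl %.4f)",
                      epoch, hist[epoch, 1], hist[epoch, 2], hist[epoch, 3]))
  }
  model$params <- p
  model$bn <- bn
  model$history <- as.data.frame(cbind(epoch = seq_len(cfg$epochs), hist))
  model$trained <- TRUE
  model
}

## ---- inference -------------------------------------------------------

check_model_input <- function(model, x) {
  X <- as_training_matrix(x)
  if (ncol(X) != model$input_dim)
    stop(sprintf(
      "dimension mismatch: model expects d = %d but data have d = %d",
      model$input_dim, ncol(X)), call. = FALSE)
  X
}

encoder_forward_infer <- function(model, X) {
  p <- model$params
  h1 <- pmax(bn_forward_infer(addrow(X %*% p$W1, p$b1), p$g1, p$be1,
                              model$bn$mm1, model$bn$mv1), 0)
  if (isTRUE(model$config$latent_batchnorm)) {
    list(z_mean = bn_forward_infer(h1 %*% p$Wmu, p$gmu, p$bemu,
                                   model$bn$mmmu, model$bn$mvmu),
         z_logvar = bn_forward_infer(h1 %*% p$Wlv, p$glv, p$belv,
                                     model$bn$mmlv, model$bn$mvlv))
  } else {
    list(z_mean = addrow(h1 %*% p$Wmu, p$bmu),
         z_logvar = addrow(h1 %*% p$Wlv, p$blv))
  }
}

decoder_forward_infer <- function(model, Z) {
  p <- model$params
  h3 <- pmax(bn_forward_infer(addrow(Z %*% p$W3, p$b3), p$g3, p$be3,
                              model$bn$mm3, model$bn$mv3), 0)
  a4 <- addrow(h3 %*% p$W4, p$b4)
  if (model$config$output_batchnorm)
    a4 <- bn_forward_infer(a4, p$g4, p$be4, model$bn$mm4, model$bn$mv4)
  sigmoid(a4)
}

#' Encode spectra into the latent space
#'
#' Deterministic inference-mode forward pass through the probabilistic
#' encoder: batch normalization uses the moving statistics frozen at the
#' end of training, and the encoded features are the posterior means
#' `mu(x)` (no sampling), so identical spectra always map to identical
#' latent vectors regardless of how the data are batched.
#'
#' @param model A trained [msi_vae()].
#' @param x An [msi_dataset()] (normalized, on the model's axis) or
#'   matrix with `d = model$input_dim` columns.
#' @return An object of class `encoded_features`: list with `z_mean` and
#'   `z_logvar`, both `N x latent_dim` matrices in input row order.
#' @export
encode <- function(model, x) {
  X <- check_model_input(model, x)
  ef <- encoder_forward_infer(model, X)
  structure(list(z_mean = ef$z_mean, z_logvar = ef$z_logvar),
            class = "encoded_features")
}

#' @export
print.encoded_features <- function(x, ...) {
  cat(sprintf("encoded features: %d pixels x %d latent dimensions\n",
              nrow(x$z_mean), ncol(x$z_mean)))
  invisible(x)
}

#' Reconstruct spectra through the generative decoder
#'
#' Decodes the deterministic latent means back to spectra; all outputs
#' lie in (0, 1) because of the sigmoid output layer.
#'
#' @inheritParams encode
#' @return An `N x d` matrix of reconstructed normalized spectra.
#' @export
reconstruct <- function(model, x) {
  X <- check_model_input(model, x)
  decoder_forward_infer(model, encoder_forward_infer(model, X)$z_mean)
}

#' Evidence-lower-bound loss of a batch
#'
#' Evaluates the minimized VAE objective on a batch of normalized
#' spectra: the batch mean of the per-spectrum reconstruction
#' cross-entropy plus the batch mean of the per-spectrum KL divergence.
#' By default the decoder reads the deterministic latent mean; supply
#' `epsilon` to evaluate a sampled pass.
#'
#' @inheritParams encode
#' @param epsilon Optional `N x latent_dim` matrix of standard-normal
#'   draws for the reparameterized sample.
#' @return List with `reconstruction`, `kl` and `total`
#'   (`total = reconstruction + kl`).
#' @export
vae_loss <- function(model, x, epsilon = NULL) {
  X <- check_model_input(model, x)
  ef <- encoder_forward_infer(model, X)
  Z <- if (is.null(epsilon)) ef$z_mean
       else reparameterize(ef$z_mean, ef$z_logvar, epsilon)
  Y <- decoder_forward_infer(model, Z)
  Yc <- pmin(pmax(Y, CLIP_EPS), 1 - CLIP_EPS)
  m <- nrow(X)
  rec <- if (model$config$loss == "binary")
    -sum(X * log(Yc) + (1 - X) * log1p(-Yc)) / m
  else
    -sum(X * log(Yc)) / m
  kl <- mean(kl_term(ef$z_mean, ef$z_logvar))
  list(reconstruction = rec, kl = kl, total = rec + kl)
}

## ---- S3 methods ------------------------------------------------------

#' @export
print.msi_vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Variational autoencoder for MSI spectra (%s)\n",
    if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  architecture: %d -> %d -> %d -> %d -> %d (BN%s, ReLU/sigmoid)\n",
              x$input_dim, cfg$hidden_dim, cfg$latent_dim, cfg$hidden_dim,
              x$input_dim,
              if (cfg$output_batchnorm) " incl. output" else ""))
  if (isTRUE(x$trained)) {
    h <- x$history
    cat(sprintf("  %d epochs, batch %d, Adam lr %g, seed %d\n",
                cfg$epochs, cfg$batch_size, cfg$learning_rate, cfg$seed))
    cat(sprintf("  final loss %.4f (reconstruction %.4f, KL %.4f)\n",
                h$total[nrow(h)], h$reconstruction[nrow(h)],
                h$kl[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.msi_vae <- function(object, ...) {
  out <- list(config = object$config, input_dim = object$input_dim,
              n_parameters = sum(vapply(object$params, length, 0L)),
              history = object$history)
  if (!is.null(object$x)) {
    xh <- reconstruct(object, object$x)
    out$train_mse <- reconstruction_mse(object$x, xh)
    out$n_train <- nrow(object$x)
  }
  class(out) <- "summary.msi_vae"
  out
}

#' @export
print.summary.msi_vae <- function(x, ...) {
  cat(sprintf("VAE with %d trainable parameters, input d = %d\n",
              x$n_parameters, x$input_dim))
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
                h$total[1], h$total[nrow(h)], nrow(h)))
  }
  if (!is.null(x$train_mse))
    cat(sprintf("  training reconstruction MSE: %.3e over %d spectra\n",
                x$train_mse, x$n_train))
  invisible(x)
}

#' @export
coef.msi_vae <- function(object, ...) object$params

#' Predict method for MSI autoencoders
#'
#' @param object A trained [msi_vae()].
#' @param newdata Dataset or matrix on the model's axis; defaults to the
#'   stored training data.
#' @param type `"latent"` for the encoded features (posterior means), or
#'   `"response"` for the reconstructed spectra.
#' @param ... Unused.
#' @return A matrix (`N x k` for `"latent"`, `N x d` for `"response"`).
#' @export
predict.msi_vae <- function(object, newdata = NULL,
                            type = c("latent", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$x))
      stop("no newdata given and no training data stored", call. = FALSE)
    newdata <- object$x
  }
  if (type == "latent") encode(object, newdata)$z_mean
  else reconstruct(object, newdata)
}

#' @export
fitted.msi_vae <- function(object, ...) {
  predict(object, type = "response")
}

#' @export
residuals.msi_vae <- function(object, ...) {
  if (is.null(object$x))
    stop("no training data stored in the model", call. = FALSE)
  object$x - fitted(object)
}

#' Simulate spectra from the generative model
#'
#' Draws latent vectors from the standard-normal prior and decodes them,
#' producing synthetic normalized spectra from the fitted manifold.
#'
#' @param object A trained [msi_vae()].
#' @param nsim Number of spectra to draw.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return An `nsim x d` matrix.
#' @export
simulate.msi_vae <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(nsim * object$config$latent_dim), nsim,
              object$config$latent_dim)
  decoder_forward_infer(object, Z)
}

#' @export
plot.msi_vae <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history",
                               call. = FALSE)
  h <- x$history
  graphics::plot(h$epoch, h$total, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "loss",
                 main = "VAE training loss", ...)
  graphics::lines(h$epoch, h$reconstruction, lty = 2)
  graphics::legend("topright", c("total", "reconstruction"),
                   lty = c(1, 2), lwd = c(2, 1), bty = "n")
  invisible(x)
}

## ---- persistence -----------------------------------------------------

MODEL_FORMAT_VERSION <- "1"

#' Save / load a fitted autoencoder
#'
#' The model is persisted as an HDF5 archive holding every weight matrix,
#' bias, batch-norm parameter and moving statistic (float64, lossless),
#' the training history, and — when the model was fitted through
#' [run_train()] — the training-time axis map. The configuration is
#' stored both as a root attribute and as a human-readable JSON sidecar
#' (`<path>.json`). `load_msi_vae()` restores a model whose `encode()`
#' output is bit-identical to the pre-save model.
#'
#' @param model A trained [msi_vae()].
#' @param path Archive path (conventionally `.h5`).
#' @return `save_msi_vae()`: `path`, invisibly. `load_msi_vae()`: the
#'   restored `msi_vae` object.
#' @export
save_msi_vae <- function(model, path) {
  stopifnot(inherits(model, "msi_vae"))
  datasets <- list()
  for (nm in names(model$params))
    datasets[[paste0("param_", nm)]] <- model$params[[nm]]
  for (nm in names(model$bn))
    datasets[[paste0("bn_", nm)]] <- model$bn[[nm]]
  if (!is.null(model$history))
    datasets$history <- as.matrix(model$history)
  if (!is.null(model$mz)) datasets$mz <- model$mz
  if (!is.null(model$axis_map)) {
    datasets$axis_map <- as.integer(model$axis_map$reduced_to_full) - 1L
    datasets$axis_full_d <- as.integer(model$axis_map$full_d)
  }
  dtypes <- as.list(rep("float64", length(datasets)))
  names(dtypes) <- names(datasets)
  if (!is.null(datasets$axis_map)) {
    dtypes$axis_map <- "int32"
    dtypes$axis_full_d <- "int32"
  }
  cfg_json <- jsonlite::toJSON(model$config, auto_unbox = TRUE)
  h5_write_file(path, datasets, dtypes,
                attrs = list(config = as.character(cfg_json),
                             input_dim = model$input_dim,
                             trained = as.integer(isTRUE(model$trained)),
                             format_version = MODEL_FORMAT_VERSION,
                             version = msivae_version()))
  jsonlite::write_json(model$config, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_msi_vae
#' @export
load_msi_vae <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  attrs <- h5_read_attributes(path)
  if (is.null(attrs$format_version))
    stop("not a saved msi_vae archive: ", path, call. = FALSE)
  if (!identical(as.character(attrs$format_version), MODEL_FORMAT_VERSION))
    stop(sprintf(
      "model archive format version '%s' does not match this package's '%s'",
      attrs$format_version, MODEL_FORMAT_VERSION), call. = FALSE)
  config <- jsonlite::fromJSON(attrs$config)
  present <- h5_list_datasets(path)
  params <- list()
  bn <- list()
  for (nm in present) {
    if (startsWith(nm, "param_"))
      params[[sub("^param_", "", nm)]] <- h5_read_dataset(path, nm)
    if (startsWith(nm, "bn_"))
      bn[[sub("^bn_", "", nm)]] <- h5_read_dataset(path, nm)
  }
  # biases / batch-norm vectors come back as plain vectors; weight
  # matrices keep their stored shapes
  model <- structure(list(params = params, bn = bn,
                          input_dim = as.integer(attrs$input_dim),
                          config = config, history = NULL,
                          trained = isTRUE(attrs$trained == 1L),
                          mz = NULL, axis_map = NULL),
                     class = "msi_vae")
  if ("history" %in% present) {
    h <- h5_read_dataset(path, "history")
    colnames(h) <- c("epoch", "total", "reconstruction", "kl")
    model$history <- as.data.frame(h)
  }
  if ("mz" %in% present) model$mz <- h5_read_dataset(path, "mz")
  if ("axis_map" %in% present)
    model$axis_map <- axis_index_map(
      h5_read_dataset(path, "axis_map") + 1L,
      h5_read_dataset(path, "axis_full_d"))
  model
}
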