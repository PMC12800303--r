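# Encoder-based nerve-length regressor: the residual U-Net encoder followed
# by global average pooling and a dense head with a softplus output, trained
# to predict per-image nerve length (mm) directly from the image. It
# compensates for pixel-wise segmentation errors (breaks, fragments) that
# the skeleton-based estimator is sensitive to.

#' Length regressor configuration
#'
#' @param depth encoder levels (>= 2)
#' @param base_channels channels at full resolution
#' @param epochs,batch_size,learning_rate training schedule (Adam, squared
#'   error loss)
#' @param seed RNG seed
#' @return a list of class `length_regressor_config`
#' @export
length_regressor_config <- function(depth = 3L, base_channels = 8L,
                                    epochs = 60L, batch_size = 4L,
                                    learning_rate = 2e-3, seed = 1L) {
  if (depth < 2) stop("`depth` must be >= 2")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "length_regressor_config")
}

#' Build an untrained length regressor
#' @param config a [length_regressor_config()]
#' @return a list of class `length_regressor`
#' @export
build_length_regressor <- function(config) {
  stopifnot(inherits(config, "length_regressor_config"))
  set.seed(config$seed)
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1)
  D <- config$depth
  enc <- lapply(seq_len(D), function(i)
    rb_init(if (i == 1) 1L else ch[i - 1], ch[i]))
  dense <- list(w = matrix(rnorm(ch[D], 0, sqrt(1 / ch[D])), ch[D], 1),
                b = 0)
  structure(list(config = config,
                 params = list(enc = enc, dense = dense), trained = FALSE),
            class = "length_regressor")
}

regressor_fw <- function(model, x) {
  D <- model$config$depth
  caches <- list(enc = vector("list", D), pool = vector("list", D - 1))
  h <- as_cube(x)
  for (i in seq_len(D)) {
    out <- rb_fw(model$params$enc[[i]], h)
    caches$enc[[i]] <- out$cache
    h <- out$y
    if (i < D) {
      pl <- nn_pool_fw(h)
      caches$pool[[i]] <- list(idx = pl$idx, H = dim(h)[1], W = dim(h)[2])
      h <- pl$y
    }
  }
  caches$feat_dim <- dim(h)
  feat <- apply(h, 3, mean)                       # global average pooling
  z <- sum(feat * model$params$dense$w) + model$params$dense$b
  caches$feat <- feat
  caches$z <- z
  sp <- if (z > 30) z else log1p(exp(z))          # softplus: length >= 0
  list(pred = sp, caches = caches)
}

regressor_bw <- function(model, caches, gpred) {
  gz <- gpred / (1 + exp(-caches$z))              # d softplus / dz = sigmoid(z)
  gfeat <- as.vector(model$params$dense$w) * gz
  grads <- list(dense = list(w = matrix(caches$feat * gz, ncol = 1), b = gz))
  fd <- caches$feat_dim
  gh <- array(rep(gfeat, each = fd[1] * fd[2]) / (fd[1] * fd[2]), dim = fd)
  D <- model$config$depth
  grads$enc <- vector("list", D)
  for (i in rev(seq_len(D))) {
    out <- rb_bw(model$params$enc[[i]], caches$enc[[i]], gh)
    grads$enc[[i]] <- out$grads
    gh <- out$gx
    if (i > 1) {
      pc <- caches$pool[[i - 1]]
      gh <- nn_pool_bw(gh, pc$idx, pc$H, pc$W)
    }
  }
  grads[c("enc", "dense")]
}

#' Train the length regressor
#'
#' @param model a [build_length_regressor()] model
#' @param images list of [image_record()]s or matrices
#' @param lengths_mm matching ground-truth per-image lengths (mm)
#' @param verbose print per-epoch loss
#' @return the trained model with a `history` data frame
#' @export
train_length_regressor <- function(model, images, lengths_mm,
                                   verbose = FALSE) {
  stopifnot(inherits(model, "length_regressor"))
  if (length(images) == 0) stop("empty training dataset")
  if (length(images) != length(lengths_mm))
    stop("`images` and `lengths_mm` lengths differ")
  cfg <- model$config
  xs <- lapply(images, image_input)
  set.seed(cfg$seed + 1L)
  theta <- nn_flatten(model$params)
  template <- model$params
  opt <- adam_init(length(theta))
  n <- length(xs)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[seq(b0, min(b0 + cfg$batch_size - 1, n))]
      model$params <- nn_unflatten(theta, template)
      gacc <- NULL
      for (j in idx) {
        fw <- regressor_fw(model, xs[[j]])
        err <- fw$pred - lengths_mm[j]
        ep_loss <- ep_loss + err^2
        g <- nn_flatten(regressor_bw(model, fw$caches, 2 * err))
        gacc <- if (is.null(gacc)) g else gacc + g
      }
      st <- adam_step(opt, theta, gacc / length(idx), cfg$learning_rate)
      opt <- st$state
      theta <- st$theta
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n))
    if (verbose) message(sprintf("epoch %d: mse %.5f", ep, ep_loss / n))
  }
  model$params <- nn_unflatten(theta, template)
  model$trained <- TRUE
  model$history <- history
  model
}

#' Predict per-image nerve length (mm) with the regressor
#'
#' @param model a trained [build_length_regressor()]
#' @param image an [image_record()] or matrix
#' @param image_id optional identifier carried into the estimate
#' @return a `length_estimate` (method `"regression"`, `length_mm >= 0`)
#' @export
predict_length <- function(model, image, image_id = NA_character_) {
  stopifnot(inherits(model, "length_regressor"))
  fw <- regressor_fw(model, image_input(image))
  structure(list(image_id = image_id, method = "regression",
                 length_mm = fw$pred),
            class = "length_estimate")
}
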