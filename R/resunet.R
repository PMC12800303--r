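# Residual U-Net for nerve (binary) and dendritic-cell (3-class)
# segmentation. The published architecture family is parameterized by depth
# and base channel count; blocks are residual (conv-relu-conv + projected
# shortcut), downsampling is 2x2 max-pool, upsampling nearest-neighbour,
# with skip concatenation at each level and a 1x1 conv head.

#' Residual U-Net configuration
#'
#' @param depth number of resolution levels (>= 2); input height and width
#'   must be divisible by `2^(depth - 1)`
#' @param base_channels channels at the highest resolution (>= 4)
#' @param blocks_per_level residual blocks per level
#' @param head `"binary_sigmoid"` (one probability map) or `"softmax3"`
#'   (three per-pixel probabilities summing to 1)
#' @param loss loss on the logits: `"dice"`, `"bce"`, `"ce"`,
#'   `"dice_plus_bce"` or `"dice_plus_ce"`; the default compound loss is
#'   Dice plus the head's cross-entropy
#' @param epochs,batch_size,learning_rate training schedule (Adam)
#' @param seed RNG seed for init and shuffling
#' @return a list of class `resunet_config`
#' @export
resunet_config <- function(depth = 5L, base_channels = 16L,
                           blocks_per_level = 1L,
                           head = c("binary_sigmoid", "softmax3"),
                           loss = NULL, epochs = 20L, batch_size = 4L,
                           learning_rate = 1e-3, seed = 1L) {
  head <- match.arg(head)
  if (depth < 2) stop("`depth` must be >= 2")
  if (base_channels < 4) stop("`base_channels` must be >= 4")
  if (is.null(loss))
    loss <- if (head == "binary_sigmoid") "dice_plus_bce" else "dice_plus_ce"
  loss <- match.arg(loss, c("dice", "bce", "ce", "dice_plus_bce",
                            "dice_plus_ce"))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 blocks_per_level = as.integer(blocks_per_level),
                 head = head, loss = loss, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "resunet_config")
}

unet_channels <- function(config) {
  config$base_channels * 2^(seq_len(config$depth) - 1)
}

#' Build an untrained residual U-Net
#'
#' @param config a [resunet_config()]
#' @return a list of class `resunet_model` holding the config and the
#'   randomly initialized parameter tree (deterministic given `config$seed`)
#' @export
build_resunet <- function(config) {
  stopifnot(inherits(config, "resunet_config"))
  set.seed(config$seed)
  ch <- unet_channels(config)
  D <- config$depth
  nb <- config$blocks_per_level
  level_blocks <- function(cin, cout) {
    c(list(rb_init(cin, cout)),
      if (nb > 1) lapply(seq_len(nb - 1), function(i) rb_init(cout, cout)))
  }
  enc <- lapply(seq_len(D - 1), function(i)
    level_blocks(if (i == 1) 1L else ch[i - 1], ch[i]))
  bott <- level_blocks(ch[D - 1], ch[D])
  dec <- lapply(seq_len(D - 1), function(i) {
    above <- if (i == D - 1) ch[D] else ch[i + 1]
    level_blocks(above + ch[i], ch[i])
  })
  nout <- if (config$head == "binary_sigmoid") 1L else 3L
  params <- list(enc = enc, bott = bott, dec = dec,
                 head = conv_init(1L, ch[1], nout))
  structure(list(config = config, params = params, trained = FALSE),
            class = "resunet_model")
}

check_unet_shape <- function(config, shape) {
  f <- 2^(config$depth - 1)
  if (any(shape %% f != 0))
    stop("input shape (", paste(shape, collapse = "x"),
         ") must be divisible by 2^(depth-1) = ", f)
}

blocks_fw <- function(blocks, x) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    out <- rb_fw(blocks[[i]], x)
    x <- out$y
    caches[[i]] <- out$cache
  }
  list(y = x, caches = caches)
}

blocks_bw <- function(blocks, caches, gy) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    out <- rb_bw(blocks[[i]], caches[[i]], gy)
    gy <- out$gx
    grads[[i]] <- out$grads
  }
  list(gx = gy, grads = grads)
}

unet_fw <- function(model, x) {
  params <- model$params
  D <- model$config$depth
  x <- as_cube(x)
  check_unet_shape(model$config, dim(x)[1:2])
  skips <- vector("list", D - 1)
  caches <- list(enc = vector("list", D - 1), pool = vector("list", D - 1),
                 dec = vector("list", D - 1), cat_dim = vector("list", D - 1))
  h <- x
  for (i in seq_len(D - 1)) {
    out <- blocks_fw(params$enc[[i]], h)
    skips[[i]] <- out$y
    caches$enc[[i]] <- out$caches
    pl <- nn_pool_fw(out$y)
    caches$pool[[i]] <- list(idx = pl$idx, H = dim(out$y)[1], W = dim(out$y)[2])
    h <- pl$y
  }
  out <- blocks_fw(params$bott, h)
  caches$bott <- out$caches
  h <- out$y
  for (i in rev(seq_len(D - 1))) {
    up <- nn_up_fw(h)
    cat <- array(c(up, skips[[i]]),
                 dim = c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[i]])[3]))
    caches$cat_dim[[i]] <- dim(up)[3]
    out <- blocks_fw(params$dec[[i]], cat)
    caches$dec[[i]] <- out$caches
    h <- out$y
  }
  logits <- conv_fw(params$head, h)
  caches$pre_head <- h
  list(logits = logits, caches = caches)
}

unet_bw <- function(model, caches, glogits) {
  params <- model$params
  D <- model$config$depth
  hb <- conv_bw(params$head, caches$pre_head, glogits)
  grads <- list(enc = vector("list", D - 1), bott = NULL,
                dec = vector("list", D - 1), head = hb$grads)
  g <- hb$gx
  gskips <- vector("list", D - 1)
  for (i in seq_len(D - 1)) {
    out <- blocks_bw(params$dec[[i]], caches$dec[[i]], g)
    grads$dec[[i]] <- out$grads
    nup <- caches$cat_dim[[i]]
    gcat <- out$gx
    gup <- gcat[, , seq_len(nup), drop = FALSE]
    gskips[[i]] <- gcat[, , nup + seq_len(dim(gcat)[3] - nup), drop = FALSE]
    g <- nn_up_bw(gup)
  }
  out <- blocks_bw(params$bott, caches$bott, g)
  grads$bott <- out$grads
  g <- out$gx
  for (i in rev(seq_len(D - 1))) {
    pc <- caches$pool[[i]]
    g <- nn_pool_bw(g, pc$idx, pc$H, pc$W)
    g <- g + gskips[[i]]
    out <- blocks_bw(params$enc[[i]], caches$enc[[i]], g)
    grads$enc[[i]] <- out$grads
    g <- out$gx
  }
  grads
}

mask_target <- function(mask, head) {
  if (inherits(mask, "segmentation_mask")) mask <- mask$data
  if (head == "binary_sigmoid") {
    if (length(dim(mask)) == 3) mask <- mask[, , 1]
    mask
  } else {
    if (length(dim(mask)) != 3 || dim(mask)[3] != 3)
      stop("softmax3 head needs a 3-channel one-hot mask")
    mask
  }
}

image_input <- function(image) {
  if (inherits(image, "image_record")) image <- image$pixels
  as_cube(matrix(as.numeric(image) / 255, nrow(image), ncol(image)))
}

#' Train a residual U-Net
#'
#' Minimizes the configured loss with Adam; deterministic given the config
#' seed (single-threaded CPU backend, no augmentation). Records per-epoch
#' mean training loss and, when a validation set is given, validation Dice.
#'
#' @param model a [build_resunet()] model
#' @param images list of [image_record()]s or matrices
#' @param masks list of matching [segmentation_mask()]s (binary matrix or
#'   one-hot array accepted)
#' @param val_images,val_masks optional held-out set evaluated per epoch
#' @param verbose print per-epoch progress
#' @return the trained model, with a `history` data frame element
#' @export
train_resunet <- function(model, images, masks, val_images = NULL,
                          val_masks = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "resunet_model"))
  if (length(images) == 0) stop("empty training dataset")
  if (length(images) != length(masks))
    stop("`images` and `masks` lengths differ")
  cfg <- model$config
  xs <- lapply(images, image_input)
  ts <- lapply(masks, mask_target, head = cfg$head)
  set.seed(cfg$seed + 1L)
  theta <- nn_flatten(model$params)
  opt <- adam_init(length(theta))
  template <- model$params
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_dice = numeric(0))
  n <- length(xs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    bstart <- seq(1, n, by = cfg$batch_size)
    for (b0 in bstart) {
      idx <- ord[seq(b0, min(b0 + cfg$batch_size - 1, n))]
      gacc <- NULL
      model$params <- nn_unflatten(theta, template)
      for (j in idx) {
        fw <- unet_fw(model, xs[[j]])
        ls <- if (cfg$head == "binary_sigmoid")
          loss_binary(fw$logits, ts[[j]], cfg$loss)
        else loss_softmax3(fw$logits, ts[[j]], cfg$loss)
        ep_loss <- ep_loss + ls$loss
        g <- nn_flatten(unet_bw(model, fw$caches, ls$gz))
        gacc <- if (is.null(gacc)) g else gacc + g
      }
      st <- adam_step(opt, theta, gacc / length(idx), cfg$learning_rate)
      opt <- st$state
      theta <- st$theta
    }
    model$params <- nn_unflatten(theta, template)
    vd <- NA_real_
    if (!is.null(val_images)) {
      vd <- mean(vapply(seq_along(val_images), function(j) {
        pm <- predict_mask(model, val_images[[j]])
        truth <- val_masks[[j]]
        if (cfg$head == "binary_sigmoid")
          dice(pm, truth)
        else mean(c(dice(pm$data[, , 2], mask_target(truth, cfg$head)[, , 2]),
                    dice(pm$data[, , 3], mask_target(truth, cfg$head)[, , 3])))
      }, numeric(1)))
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / n, val_dice = vd))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val_dice %.3f", ep,
                      ep_loss / n, vd))
  }
  model$trained <- TRUE
  model$history <- history
  model
}

#' Predict a segmentation mask for one image
#'
#' Binary head: per-pixel probability thresholding (default 0.5). Softmax
#' head: per-pixel argmax, returned one-hot.
#'
#' @param model a trained [build_resunet()] model
#' @param image an [image_record()] or matrix
#' @param threshold probability threshold for the binary head
#' @return a [segmentation_mask()]
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  stopifnot(inherits(model, "resunet_model"))
  fw <- unet_fw(model, image_input(image))
  if (model$config$head == "binary_sigmoid") {
    p <- sigmoid(fw$logits[, , 1])
    segmentation_mask("nerve_binary",
                      matrix(as.integer(p >= threshold), nrow(p), ncol(p)))
  } else {
    p <- softmax3(fw$logits)
    am <- apply(p, c(1, 2), which.max)
    data <- array(0, dim = dim(p))
    for (ch in 1:3) data[, , ch] <- (am == ch)
    segmentation_mask("dc_onehot", data)
  }
}

#' Per-pixel probabilities for one image
#' @inheritParams predict_mask
#' @return matrix (binary head) or 3-channel array (softmax head)
#' @export
predict_probs <- function(model, image) {
  fw <- unet_fw(model, image_input(image))
  if (model$config$head == "binary_sigmoid") sigmoid(fw$logits[, , 1])
  else softmax3(fw$logits)
}

#' Subject-stratified fold assignment for k-fold cross-validation
#'
#' Every subject is placed in exactly one fold (so no image of a subject can
#' leak into another fold), fold sizes differ by at most one subject, and
#' the assignment is deterministic given the seed and independent of image
#' order.
#'
#' @param subject_ids character vector (repeats allowed; one entry per image
#'   is fine)
#' @param k number of folds
#' @param seed RNG seed
#' @return named integer vector mapping each unique subject to a fold in
#'   `0..k-1`
#' @export
make_folds <- function(subject_ids, k = 5L, seed = 1L) {
  subjects <- sort(unique(as.character(subject_ids)))
  if (length(subjects) < k)
    stop("need at least ", k, " subjects for ", k, " folds")
  set.seed(seed)
  shuffled <- sample(subjects)
  folds <- rep(seq_len(k) - 1L, length.out = length(shuffled))
  setNames(folds[match(subjects, shuffled)], subjects)
}
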