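# CPU training core shared by the segmentation U-Nets and the nerve-length
# regressor: residual conv blocks, 2x max-pool / nearest-neighbour upsample,
# sigmoid / softmax heads, Dice and cross-entropy losses with hand-written
# backprop, and Adam. Weight layout: conv weights are R arrays of dim
# (k, k, Cin, Cout); their column-major flattening matches the C++ GEMM
# kernels.

conv_init <- function(k, cin, cout) {
  list(w = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                 dim = c(k, k, cin, cout)),
       b = numeric(cout))
}

conv_fw <- function(p, x) {
  d <- dim(p$w)
  nn_conv_fw(x, matrix(p$w, d[1] * d[2] * d[3], d[4]), p$b, d[1],
             (d[1] - 1L) %/% 2L)
}

conv_bw <- function(p, x, gy) {
  d <- dim(p$w)
  out <- nn_conv_bw(x, matrix(p$w, d[1] * d[2] * d[3], d[4]), gy, d[1],
                    (d[1] - 1L) %/% 2L)
  list(gx = out$gx, grads = list(w = array(out$gw, dim = d), b = as.numeric(out$gb)))
}

as_cube <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x
}

# residual block: conv3x3 -> relu -> conv3x3, added to a (projected) shortcut,
# then relu
rb_init <- function(cin, cout) {
  p <- list(c1 = conv_init(3L, cin, cout), c2 = conv_init(3L, cout, cout))
  if (cin != cout) p$sc <- conv_init(1L, cin, cout)
  p
}

rb_fw <- function(p, x) {
  a <- conv_fw(p$c1, x)
  h <- pmax(a, 0)
  b <- conv_fw(p$c2, h)
  s <- if (is.null(p$sc)) x else conv_fw(p$sc, x)
  z <- b + s
  list(y = pmax(z, 0), cache = list(x = x, a = a, h = h, z = z))
}

rb_bw <- function(p, cache, gy) {
  gz <- gy * (cache$z > 0)
  b2 <- conv_bw(p$c2, cache$h, gz)
  ga <- b2$gx * (cache$a > 0)
  b1 <- conv_bw(p$c1, cache$x, ga)
  grads <- list(c1 = b1$grads, c2 = b2$grads)
  if (is.null(p$sc)) {
    gx <- b1$gx + gz
  } else {
    bs <- conv_bw(p$sc, cache$x, gz)
    grads$sc <- bs$grads
    gx <- b1$gx + bs$gx
  }
  list(gx = gx, grads = grads)
}

# ---- parameter tree <-> flat vector ---------------------------------------

nn_flatten <- function(p) unlist(p, use.names = FALSE)

nn_unflatten <- function(flat, template) {
  pos <- 0L
  rec <- function(t) {
    if (is.list(t)) return(lapply(t, rec))
    n <- length(t)
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(t))) dim(v) <- dim(t)
    v
  }
  rec(template)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

# ---- losses on logits ------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax3 <- function(z) {
  m <- pmax(z[, , 1], pmax(z[, , 2], z[, , 3]))
  e <- exp(z - as.vector(m))
  s <- e[, , 1] + e[, , 2] + e[, , 3]
  e / as.vector(s)
}

# binary target t in {0,1} (matrix), logits z (H, W, 1)
loss_binary <- function(z, t, loss = "dice_plus_bce", eps = 1) {
  p <- sigmoid(z[, , 1])
  n <- length(p)
  L <- 0
  gp <- matrix(0, nrow(p), ncol(p))
  if (loss %in% c("bce", "dice_plus_bce")) {
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    L <- L - mean(t * log(pc) + (1 - t) * log(1 - pc))
    gp <- gp + (pc - t) / (pc * (1 - pc)) / n
  }
  if (loss %in% c("dice", "dice_plus_bce")) {
    S <- 2 * sum(p * t) + eps
    Q <- sum(p) + sum(t) + eps
    L <- L + 1 - S / Q
    gp <- gp + (S - 2 * t * Q) / Q^2
  }
  gz <- gp * p * (1 - p)
  dim(gz) <- c(dim(gz), 1L)
  list(loss = L, gz = gz)
}

# one-hot target t (H, W, 3), logits z (H, W, 3); Dice averaged over the two
# foreground channels
loss_softmax3 <- function(z, t, loss = "dice_plus_ce", eps = 1) {
  p <- softmax3(z)
  npix <- dim(p)[1] * dim(p)[2]
  L <- 0
  gp <- array(0, dim = dim(p))
  if (loss %in% c("ce", "dice_plus_ce")) {
    pc <- pmax(p, 1e-9)
    L <- L - sum(t * log(pc)) / npix
    gp <- gp - t / pc / npix
  }
  if (loss %in% c("dice", "dice_plus_ce")) {
    for (ch in 2:3) {
      S <- 2 * sum(p[, , ch] * t[, , ch]) + eps
      Q <- sum(p[, , ch]) + sum(t[, , ch]) + eps
      L <- L + (1 - S / Q) / 2
      gp[, , ch] <- gp[, , ch] + (S - 2 * t[, , ch] * Q) / Q^2 / 2
    }
  }
  # softmax backward: gz = p * (gp - sum_c gp_c p_c)
  dot <- gp[, , 1] * p[, , 1] + gp[, , 2] * p[, , 2] + gp[, , 3] * p[, , 3]
  gz <- p * (gp - as.vector(dot))
  list(loss = L, gz = gz)
}
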