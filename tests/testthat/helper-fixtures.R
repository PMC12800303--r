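# shared fixtures: tiny rendering parameters so image-level tests stay fast

tiny_params <- function(shape = c(32L, 32L), seed = 1L, ...) {
  synth_params(image_shape = shape, seed = seed, ...)
}

# a gently curved tracing fixture with known analytic arc length
vertical_tracing <- function(x = 10, shape = c(64L, 64L)) {
  nerve_tracing(list(cbind(rep(x, 2), c(0, shape[1] - 1))), shape)
}

random_tracing <- function(shape = c(64L, 64L), n_poly = 3) {
  polys <- lapply(seq_len(n_poly), function(i) {
    n <- sample(2:8, 1)
    cbind(sample(0:(shape[2] - 1), n, TRUE),
          sample(0:(shape[1] - 1), n, TRUE))
  })
  nerve_tracing(polys, shape)
}

square_polygon <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# independent brute-force even-odd point-in-polygon oracle (crossing count
# per pixel centre, scalar loop — deliberately naive)
brute_polygon_pixels <- function(vertices, shape) {
  hits <- matrix(FALSE, shape[1], shape[2])
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      x <- c - 1; y <- r - 1
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        if ((vy[i] > y) != (vy[j] > y)) {
          xint <- (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]
          if (x < xint) inside <- !inside
        }
        j <- i
      }
      hits[r, c] <- inside
    }
  }
  which(hits, arr.ind = TRUE)
}

# independent recursive flood fill (8-connectivity) used as counting oracle
brute_count_components <- function(m, min_area = 1) {
  m <- m > 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  sizes <- integer(0)
  for (r0 in seq_len(nrow(m))) for (c0 in seq_len(ncol(m))) {
    if (!m[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    size <- 0
    while (length(queue)) {
      rc <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- rc[1] + dr; cc <- rc[2] + dc
        if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) next
        if (m[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sum(sizes >= min_area)
}
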