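# Rasterization of annotations into training masks.
#
# Stroke convention: a width-w polyline stroke covers every pixel whose
# centre has signed perpendicular offset in [-w/2, w/2) from a segment at
# axial position within the segment (butt caps at polyline ends), plus a
# round-join disk of radius w/2 (strict) at interior vertices. Polygon fill
# uses the even-odd rule on pixel centres with half-open boundaries, so
# abutting polygons do not double-cover.

# pixels covered by one stroked segment; returns (row, col) 1-based indices
stroke_segment_pixels <- function(p1, p2, half, shape) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len == 0) return(matrix(integer(0), 0, 2))
  u <- d / len
  x0 <- max(0L, floor(min(p1[1], p2[1]) - half - 1))
  x1 <- min(shape[2] - 1L, ceiling(max(p1[1], p2[1]) + half + 1))
  y0 <- max(0L, floor(min(p1[2], p2[2]) - half - 1))
  y1 <- min(shape[1] - 1L, ceiling(max(p1[2], p2[2]) + half + 1))
  if (x1 < x0 || y1 < y0) return(matrix(integer(0), 0, 2))
  xs <- seq(x0, x1)
  ys <- seq(y0, y1)
  gx <- rep(xs, each = length(ys)) - p1[1]
  gy <- rep(ys, times = length(xs)) - p1[2]
  t <- gx * u[1] + gy * u[2]           # axial position along the segment
  s <- gy * u[1] - gx * u[2]           # signed perpendicular offset
  hit <- t >= 0 & t <= len & s >= -half & s < half
  cbind(rep(ys, times = length(xs))[hit] + 1L,
        rep(xs, each = length(ys))[hit] + 1L)
}

disk_pixels <- function(centre, radius, shape) {
  x0 <- max(0L, floor(centre[1] - radius))
  x1 <- min(shape[2] - 1L, ceiling(centre[1] + radius))
  y0 <- max(0L, floor(centre[2] - radius))
  y1 <- min(shape[1] - 1L, ceiling(centre[2] + radius))
  if (x1 < x0 || y1 < y0) return(matrix(integer(0), 0, 2))
  xs <- seq(x0, x1); ys <- seq(y0, y1)
  gx <- rep(xs, each = length(ys)) - centre[1]
  gy <- rep(ys, times = length(xs)) - centre[2]
  hit <- gx^2 + gy^2 < radius^2
  cbind(rep(ys, times = length(xs))[hit] + 1L,
        rep(xs, each = length(ys))[hit] + 1L)
}

# internal: stroke a full polyline into a logical matrix
stroke_polyline <- function(mask, poly, width) {
  half <- width / 2
  shape <- dim(mask)
  n <- nrow(poly)
  for (i in seq_len(n - 1)) {
    px <- stroke_segment_pixels(poly[i, ], poly[i + 1, ], half, shape)
    if (nrow(px)) mask[px] <- 1L
  }
  if (n > 2) {
    for (i in seq(2, n - 1)) {
      px <- disk_pixels(poly[i, ], half, shape)
      if (nrow(px)) mask[px] <- 1L
    }
  }
  mask
}

#' Rasterize a nerve tracing into a binary training mask
#'
#' Each polyline is drawn as a stroked path of the given width (default 4
#' pixels, matching the width used to build nerve masks from expert
#' tracings); overlapping strokes merge by union.
#'
#' @param tracing a [nerve_tracing()]
#' @param line_width_px stroke width in pixels (>= 1)
#' @return a [segmentation_mask()] of kind `nerve_binary`
#' @export
rasterize_nerve_mask <- function(tracing, line_width_px = 4) {
  stopifnot(inherits(tracing, "nerve_tracing"))
  if (!is.numeric(line_width_px) || line_width_px < 1)
    stop("`line_width_px` must be >= 1")
  shape <- tracing$image_shape
  mask <- matrix(0L, shape[1], shape[2])
  for (poly in tracing$polylines)
    mask <- stroke_polyline(mask, poly, line_width_px)
  segmentation_mask("nerve_binary", mask)
}

# even-odd point-in-polygon on pixel centres; returns (row, col) 1-based
polygon_fill_pixels <- function(vertices, shape) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  x0 <- max(0L, floor(min(vx))); x1 <- min(shape[2] - 1L, ceiling(max(vx)))
  y0 <- max(0L, floor(min(vy))); y1 <- min(shape[1] - 1L, ceiling(max(vy)))
  if (x1 < x0 || y1 < y0) return(matrix(integer(0), 0, 2))
  xs <- seq(x0, x1); ys <- seq(y0, y1)
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- rep(FALSE, length(px))
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py[crosses] - vy[i]) / (vy[j] - vy[i]) + vx[i]
      flip <- px[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  cbind(py[inside] + 1L, px[inside] + 1L)
}

#' Rasterize a cell annotation into a 3-channel one-hot mask
#'
#' Polygon interiors are filled into channel 2 (with dendrites) or channel 3
#' (without dendrites); all remaining pixels are background (channel 1).
#' Polygons are drawn in file order and the last drawn wins where classes
#' overlap, so the per-pixel one-hot property always holds.
#'
#' @param annotation a [cell_annotation()]
#' @return a [segmentation_mask()] of kind `dc_onehot`
#' @export
rasterize_dc_mask <- function(annotation) {
  stopifnot(inherits(annotation, "cell_annotation"))
  shape <- annotation$image_shape
  lab <- matrix(0L, shape[1], shape[2])   # 0 = background, 1 = with, 2 = without
  for (p in annotation$polygons) {
    px <- polygon_fill_pixels(p$vertices, shape)
    if (nrow(px)) lab[px] <- if (p$label == "with_dendrites") 1L else 2L
  }
  data <- array(0, dim = c(shape[1], shape[2], 3))
  data[, , 1] <- (lab == 0L)
  data[, , 2] <- (lab == 1L)
  data[, , 3] <- (lab == 2L)
  segmentation_mask("dc_onehot", data)
}
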