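#' Image record
#'
#' Container for one 8-bit grayscale IVCM frame together with its subject,
#' eye and pixel-pitch metadata.
#'
#' @param pixels numeric or integer matrix with values in 0..255
#' @param subject_id opaque subject identifier
#' @param eye `"OS"` (left) or `"OD"` (right)
#' @param image_id image identifier
#' @param pixel_pitch_um micrometres per pixel (default 400/384)
#' @return an object of class `image_record`
#' @export
image_record <- function(pixels, subject_id = "unknown", eye = c("OS", "OD"),
                         image_id = "img", pixel_pitch_um = default_pixel_pitch_um()) {
  eye <- match.arg(eye)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("`pixels` must lie in [0, 255]")
  if (any(pixels != round(pixels)))
    stop("`pixels` must hold integer grey levels (8-bit)")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1 ||
      pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be a positive scalar")
  structure(
    list(pixels = pixels, subject_id = as.character(subject_id), eye = eye,
         image_id = as.character(image_id), pixel_pitch_um = pixel_pitch_um),
    class = "image_record")
}

#' Nerve tracing (ordered polylines)
#'
#' A set of manually or synthetically traced nerve paths for one image.
#' Points are continuous pixel coordinates (x = column, y = row, 0-based).
#'
#' @param polylines list of numeric matrices, each n x 2 with columns `x`, `y`
#'   and n >= 2
#' @param image_shape integer `c(height, width)`
#' @return an object of class `nerve_tracing`
#' @export
nerve_tracing <- function(polylines, image_shape = c(384L, 384L)) {
  stopifnot(is.list(polylines), length(image_shape) == 2)
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) stop("each polyline must have two columns (x, y)")
    if (nrow(p) < 2) stop("each polyline must have at least 2 points")
    colnames(p) <- c("x", "y")
    if (any(p[, "x"] < 0) || any(p[, "x"] >= image_shape[2]) ||
        any(p[, "y"] < 0) || any(p[, "y"] >= image_shape[1]))
      stop("polyline points must lie within [0, width) x [0, height)")
    p
  })
  structure(list(polylines = polylines, image_shape = as.integer(image_shape)),
            class = "nerve_tracing")
}

#' Total analytic arc length of a tracing, in pixels
#' @param tracing a [nerve_tracing()]
#' @return summed polyline arc length in pixel units
#' @export
tracing_length_px <- function(tracing) {
  stopifnot(inherits(tracing, "nerve_tracing"))
  sum(vapply(tracing$polylines, function(p) {
    d <- diff(p)
    sum(sqrt(d[, 1]^2 + d[, 2]^2))
  }, numeric(1)))
}

#' Total analytic arc length of a tracing, in millimetres
#' @inheritParams tracing_length_px
#' @param pixel_pitch_um micrometres per pixel
#' @export
tracing_length_mm <- function(tracing, pixel_pitch_um = default_pixel_pitch_um()) {
  tracing_length_px(tracing) * pixel_pitch_um / 1000
}

#' Dendritic cell polygon annotation
#'
#' Labelled polygons for one image; each polygon outlines one cell body and
#' carries one of the two morphological classes.
#'
#' @param polygons list of `list(vertices = n x 2 matrix (x, y), label = class)`
#'   with n >= 3 and label in `"with_dendrites"`, `"without_dendrites"`
#' @param image_shape integer `c(height, width)`
#' @return an object of class `cell_annotation`
#' @export
cell_annotation <- function(polygons, image_shape = c(384L, 384L)) {
  stopifnot(is.list(polygons), length(image_shape) == 2)
  polygons <- lapply(polygons, function(p) {
    v <- as.matrix(p$vertices)
    if (ncol(v) != 2) stop("polygon vertices must have two columns (x, y)")
    if (nrow(v) < 3) stop("each polygon must have at least 3 vertices")
    colnames(v) <- c("x", "y")
    if (!p$label %in% dc_classes())
      stop("polygon label must be one of: ", paste(dc_classes(), collapse = ", "))
    list(vertices = v, label = p$label)
  })
  structure(list(polygons = polygons, image_shape = as.integer(image_shape)),
            class = "cell_annotation")
}

#' The two dendritic cell morphology classes
#' @return character vector of class names
#' @export
dc_classes <- function() c("with_dendrites", "without_dendrites")

#' Per-class polygon counts of an annotation
#' @param annotation a [cell_annotation()]
#' @return named integer vector (with_dendrites, without_dendrites)
#' @export
annotation_counts <- function(annotation) {
  stopifnot(inherits(annotation, "cell_annotation"))
  labs <- vapply(annotation$polygons, `[[`, character(1), "label")
  c(with_dendrites = sum(labs == "with_dendrites"),
    without_dendrites = sum(labs == "without_dendrites"))
}

#' Segmentation mask
#'
#' Either a binary nerve mask (`nerve_binary`: a 2-D matrix of 0/1) or a
#' 3-channel one-hot dendritic cell mask (`dc_onehot`: array height x width
#' x 3 with channel 1 = background, 2 = with dendrites, 3 = without
#' dendrites; per-pixel channel sum exactly 1).
#'
#' @param kind `"nerve_binary"` or `"dc_onehot"`
#' @param data matrix (nerve) or 3-channel array (DC)
#' @return an object of class `segmentation_mask`
#' @export
segmentation_mask <- function(kind = c("nerve_binary", "dc_onehot"), data) {
  kind <- match.arg(kind)
  if (kind == "nerve_binary") {
    if (!is.matrix(data)) stop("nerve_binary mask must be a matrix")
    if (!all(data %in% c(0, 1))) stop("nerve_binary mask values must be 0/1")
    shape <- dim(data)
  } else {
    if (length(dim(data)) != 3 || dim(data)[3] != 3)
      stop("dc_onehot mask must be a height x width x 3 array")
    if (!all(data %in% c(0, 1)))
      stop("dc_onehot mask values must be 0/1")
    sums <- data[, , 1] + data[, , 2] + data[, , 3]
    if (!all(sums == 1))
      stop("dc_onehot mask must be one-hot (per-pixel channel sum 1)")
    shape <- dim(data)[1:2]
  }
  structure(list(kind = kind, data = data, image_shape = as.integer(shape)),
            class = "segmentation_mask")
}
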