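# NeuronJ .ndf and Labelme-style .json annotation I/O, plus 8-bit image I/O.
#
# Supported NDF dialect (a minimal subset of NeuronJ's data file):
#   * first line: "// NeuronJ Data File ..." (the version line)
#   * any further lines before the first tracing are header lines and are
#     preserved verbatim on round-trip
#   * each tracing starts with a line "// Tracing <name>" followed by its
#     coordinates, one number per line, alternating x then y
#   * an optional final "// End of NeuronJ Data File" line is preserved
# Coordinates are integers in files written by NeuronJ; real values are
# accepted on parse and rounded only at rasterization.

ndf_read_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) readLines(x)
  else if (length(x) == 1) strsplit(x, "\n", fixed = TRUE)[[1]]
  else as.character(x)
}

#' Parse a NeuronJ tracing file
#'
#' @param x path to a `.ndf` file, a single string of its contents, or a
#'   character vector of lines
#' @param image_shape integer `c(height, width)` of the traced image
#' @return a [nerve_tracing()]; header/footer lines and tracing names are
#'   kept as attributes so [write_ndf()] round-trips the file
#' @export
parse_ndf <- function(x, image_shape = c(384L, 384L)) {
  lines <- ndf_read_lines(x)
  if (length(lines) == 0 || all(!nzchar(lines)))
    stop("empty NDF file")
  if (!grepl("^// NeuronJ", lines[1]))
    stop("malformed NDF header at line 1: expected '// NeuronJ ...', got: ",
         lines[1])
  is_tracing <- grepl("^// Tracing", lines)
  if (!any(is_tracing)) stop("NDF file contains no tracing blocks")
  starts <- which(is_tracing)
  header <- lines[seq_len(starts[1] - 1)]
  is_end <- grepl("^// End of", lines)
  footer <- character(0)
  last <- length(lines)
  if (any(is_end)) {
    footer <- lines[which(is_end)[1]:length(lines)]
    last <- which(is_end)[1] - 1
  }
  other_comment <- grepl("^//", lines) & !is_tracing & !is_end
  other_comment[seq_len(starts[1] - 1)] <- FALSE
  if (any(other_comment))
    stop("unsupported NDF comment line inside tracing section at line ",
         which(other_comment)[1])
  bounds <- c(starts, last + 1)
  polylines <- vector("list", length(starts))
  names_tr <- sub("^// Tracing\\s*", "", lines[starts])
  for (i in seq_along(starts)) {
    body <- lines[seq(bounds[i] + 1, bounds[i + 1] - 1)]
    body <- body[nzchar(trimws(body))]
    vals <- suppressWarnings(as.numeric(body))
    if (anyNA(vals))
      stop("non-numeric coordinate in tracing block ", i, ": ",
           body[which(is.na(vals))[1]])
    if (length(vals) %% 2 != 0)
      stop("odd coordinate count (", length(vals), ") in tracing block ", i)
    if (length(vals) < 4)
      stop("tracing block ", i, " has fewer than 2 points")
    polylines[[i]] <- matrix(vals, ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("x", "y")))
  }
  tr <- nerve_tracing(polylines, image_shape)
  attr(tr, "ndf_header") <- header
  attr(tr, "ndf_footer") <- footer
  attr(tr, "ndf_names") <- names_tr
  tr
}

ndf_format_num <- function(v) {
  ifelse(v == round(v), sprintf("%d", as.integer(round(v))),
         sub("0+$", "", sprintf("%.6f", v)))
}

#' Write a nerve tracing as a NeuronJ-style .ndf file
#'
#' @param tracing a [nerve_tracing()]
#' @param path output path, or `NULL` to return the text lines invisibly
#' @return the file lines, invisibly
#' @export
write_ndf <- function(tracing, path = NULL) {
  stopifnot(inherits(tracing, "nerve_tracing"))
  header <- attr(tracing, "ndf_header")
  if (is.null(header)) header <- "// NeuronJ Data File - v1.4.3"
  nm <- attr(tracing, "ndf_names")
  if (is.null(nm)) nm <- paste0("N", seq_along(tracing$polylines))
  footer <- attr(tracing, "ndf_footer")
  if (is.null(footer)) footer <- "// End of NeuronJ Data File"
  blocks <- unlist(lapply(seq_along(tracing$polylines), function(i) {
    p <- tracing$polylines[[i]]
    c(paste("// Tracing", nm[i]), ndf_format_num(as.vector(t(p))))
  }))
  lines <- c(header, blocks, footer)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Default Labelme label-string mapping
#'
#' The two CellCounter labels (1 = with dendrites, 2 = without dendrites) and
#' common free-text variants, mapped onto the package's class names.
#' @return named character vector mapping label strings to classes
#' @export
default_label_map <- function() {
  c("1" = "with_dendrites", "with" = "with_dendrites",
    "with_dendrites" = "with_dendrites",
    "2" = "without_dendrites", "without" = "without_dendrites",
    "without_dendrites" = "without_dendrites")
}

#' Parse a Labelme-style polygon annotation document
#'
#' @param x path to a `.json` file or a JSON string
#' @param label_map named character vector mapping file label strings to the
#'   two cell classes; see [default_label_map()]
#' @param image_shape fallback `c(height, width)` when the document carries
#'   no `imageHeight`/`imageWidth`
#' @return a [cell_annotation()]
#' @export
parse_labelme <- function(x, label_map = default_label_map(),
                          image_shape = c(384L, 384L)) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (is.null(doc$shapes)) stop("Labelme document has no `shapes` list")
  h <- if (!is.null(doc$imageHeight)) doc$imageHeight else image_shape[1]
  w <- if (!is.null(doc$imageWidth)) doc$imageWidth else image_shape[2]
  polygons <- lapply(doc$shapes, function(s) {
    lab <- as.character(s$label)
    if (!lab %in% names(label_map))
      stop("unknown label '", lab, "'; permitted labels: ",
           paste(names(label_map), collapse = ", "))
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(pts) < 3)
      stop("polygon with fewer than 3 vertices (label '", lab, "')")
    list(vertices = pts, label = unname(label_map[lab]))
  })
  cell_annotation(polygons, c(h, w))
}

#' Write a cell annotation as a Labelme-style JSON document
#'
#' @param annotation a [cell_annotation()]
#' @param path output path, or `NULL` to return the JSON string
#' @param label_names labels written per class: default `"1"` for
#'   with-dendrites cells and `"2"` for without-dendrites cells
#' @return the JSON string, invisibly
#' @export
write_labelme <- function(annotation, path = NULL,
                          label_names = c(with_dendrites = "1",
                                          without_dendrites = "2")) {
  stopifnot(inherits(annotation, "cell_annotation"))
  shapes <- lapply(annotation$polygons, function(p) {
    list(label = unname(label_names[p$label]),
         points = lapply(seq_len(nrow(p$vertices)),
                         function(i) as.numeric(p$vertices[i, ])),
         shape_type = "polygon")
  })
  doc <- list(shapes = shapes,
              imageHeight = annotation$image_shape[1],
              imageWidth = annotation$image_shape[2])
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

infer_eye_from_path <- function(path) {
  parts <- strsplit(normalizePath(path, mustWork = FALSE), "[/\\\\]")[[1]]
  hit <- parts[parts %in% c("OS", "OD")]
  if (length(hit)) hit[length(hit)] else NA_character_
}

#' Read an 8-bit grayscale image (TIFF or PNG)
#'
#' Subject and eye are inferred from a `subject/OS|OD/image` folder layout
#' when not given. Inputs that are not single-channel 8-bit raise an error;
#' no silent conversion is performed.
#'
#' @param path image path (`.tif`/`.tiff`/`.png`)
#' @param subject_id,eye,image_id optional metadata overrides
#' @param pixel_pitch_um micrometres per pixel
#' @return an [image_record()]
#' @export
read_ivcm_image <- function(path, subject_id = NULL, eye = NULL,
                            image_id = NULL,
                            pixel_pitch_um = default_pixel_pitch_um()) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    if (!is.null(bps) && any(bps != 8))
      stop("not an 8-bit image: ", path, " (", bps[1], " bits per sample)")
    if (length(dim(img)) != 2)
      stop("not a single-channel grayscale image: ", path)
    px <- img[, , drop = TRUE]
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) != 2)
      stop("not a single-channel grayscale image: ", path)
    px <- img * 255
    if (any(abs(px - round(px)) > 1e-6))
      stop("not an 8-bit image: ", path)
    px <- round(px)
  } else stop("unsupported image format: ", path)
  storage.mode(px) <- "integer"
  parts <- strsplit(normalizePath(path, mustWork = FALSE), "[/\\\\]")[[1]]
  if (is.null(eye)) {
    eye <- infer_eye_from_path(path)
    if (is.na(eye)) eye <- "OS"
  }
  if (is.null(subject_id)) {
    i <- which(parts %in% c("OS", "OD"))
    subject_id <- if (length(i)) parts[max(i) - 1] else "unknown"
  }
  if (is.null(image_id))
    image_id <- tools::file_path_sans_ext(basename(path))
  image_record(px, subject_id, eye, image_id, pixel_pitch_um)
}

#' Write an image record as 8-bit grayscale TIFF or PNG
#'
#' @param record an [image_record()]
#' @param path output path; the extension selects the format
#' @return `path`, invisibly
#' @export
write_ivcm_image <- function(record, path) {
  stopifnot(inherits(record, "image_record"))
  ext <- tolower(tools::file_ext(path))
  m <- record$pixels / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else stop("unsupported image format: ", path)
  invisible(path)
}
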