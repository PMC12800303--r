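# Dendritic cell counting from one-hot masks and the per-participant
# density closed forms: per-class density = mean per-image count / area;
# total density = with-dendrites density + without-dendrites density.

#' Count cells of one class in a one-hot mask
#'
#' Cells are 8-connected components of the class channel with at least
#' `min_area_px` pixels (default 10, so single-pixel noise never counts).
#' Touching cells of the same class merge into one count; components
#' touching the image border are counted.
#'
#' @param mask a `dc_onehot` [segmentation_mask()] or a height x width x 3
#'   one-hot array
#' @param class `"with_dendrites"` or `"without_dendrites"`
#' @param min_area_px minimum component area in pixels
#' @return integer count
#' @export
count_components <- function(mask, class = c("with_dendrites",
                                             "without_dendrites"),
                             min_area_px = 10L) {
  class <- match.arg(class)
  data <- if (inherits(mask, "segmentation_mask")) mask$data else mask
  if (length(dim(data)) != 3 || dim(data)[3] != 3)
    stop("`mask` must be a 3-channel one-hot array")
  ch <- if (class == "with_dendrites") 2L else 3L
  m <- matrix(as.integer(data[, , ch] > 0), dim(data)[1], dim(data)[2])
  lab <- label_components8(m)
  if (max(lab) == 0) return(0L)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_area_px)
}

#' Per-image cell counts for both classes
#' @inheritParams count_components
#' @param image_id optional identifier
#' @return list of class `dc_counts`: `image_id`, `n_with`, `n_without`
#' @export
dc_counts_image <- function(mask, min_area_px = 10L,
                            image_id = NA_character_) {
  structure(list(image_id = image_id,
                 n_with = count_components(mask, "with_dendrites", min_area_px),
                 n_without = count_components(mask, "without_dendrites",
                                              min_area_px)),
            class = "dc_counts")
}

#' Per-participant dendritic cell densities
#'
#' Density of each class = mean per-image count / image area (mm^2); total
#' density is their exact sum. With the default 0.16 mm^2 image, one cell
#' per image equates to 6.25 cells/mm^2.
#'
#' @param counts a data frame with columns `n_with` and `n_without` (one row
#'   per image), or a list of [dc_counts_image()] results
#' @param area_mm2 image area in mm^2
#' @param subject_id optional identifier
#' @return list of class `dc_densities`: `subject_id`, `density_with`,
#'   `density_without`, `density_total` (cells/mm^2), `area_mm2`
#' @export
densities_participant <- function(counts, area_mm2 = 0.16,
                                  subject_id = NA_character_) {
  if (inherits(counts, "dc_counts")) counts <- list(counts)
  if (is.list(counts) && !is.data.frame(counts))
    counts <- data.frame(
      n_with = vapply(counts, `[[`, numeric(1), "n_with"),
      n_without = vapply(counts, `[[`, numeric(1), "n_without"))
  if (nrow(counts) < 1) stop("at least one image is required")
  if (!is.numeric(area_mm2) || area_mm2 <= 0) stop("`area_mm2` must be > 0")
  if (any(counts$n_with < 0) || any(counts$n_without < 0) ||
      any(counts$n_with != round(counts$n_with)) ||
      any(counts$n_without != round(counts$n_without)))
    stop("counts must be non-negative integers")
  dw <- mean(counts$n_with) / area_mm2
  dwo <- mean(counts$n_without) / area_mm2
  structure(list(subject_id = subject_id, density_with = dw,
                 density_without = dwo, density_total = dw + dwo,
                 area_mm2 = area_mm2),
            class = "dc_densities")
}

#' Convert a cell density to cells per image
#'
#' @param density_cells_per_mm2 density in cells/mm^2
#' @param area_mm2 image area in mm^2 (default 0.16)
#' @return cells per image (6.25 cells/mm^2 corresponds to 1 cell per image)
#' @export
cells_per_image <- function(density_cells_per_mm2, area_mm2 = 0.16) {
  if (!is.numeric(area_mm2) || area_mm2 <= 0) stop("`area_mm2` must be > 0")
  density_cells_per_mm2 * area_mm2
}
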