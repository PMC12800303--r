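# Algorithmic nerve-length estimation: topology-preserving thinning of the
# binary mask to a 1-px skeleton, spur pruning, and diagonal-weighted link
# counting, followed by the per-participant density closed form
# (density = mean per-image length / image area).

#' Skeletonize a binary nerve mask
#'
#' Zhang-Suen topology-preserving thinning: the skeleton is a subset of the
#' foreground and preserves connected components. Optionally prunes terminal
#' spurs shorter than `prune_px` pixels (default 2, half the default stroke
#' width) to suppress rasterization artefacts.
#'
#' @param mask a [segmentation_mask()] of kind `nerve_binary`, or a 0/1
#'   matrix
#' @param prune_px prune terminal branches of up to this many pixels;
#'   0 disables pruning
#' @return a 0/1 integer matrix, 1 pixel wide
#' @export
skeletonize <- function(mask, prune_px = 2L) {
  m <- if (inherits(mask, "segmentation_mask")) mask$data else mask
  storage.mode(m) <- "integer"
  sk <- thin_zhang_suen(m)
  if (prune_px > 0) sk <- prune_spurs(sk, prune_px)
  sk
}

neighbour_count <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  n <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + pad[2:(H + 1) + dr, 2:(W + 1) + dc]
  }
  n
}

# remove terminal branches of <= max_len pixels (endpoint to the pixel
# before a junction); repeated until stable
prune_spurs <- function(sk, max_len = 2L) {
  repeat {
    nc <- neighbour_count(sk)
    endpoints <- which(sk == 1L & nc == 1L, arr.ind = TRUE)
    if (nrow(endpoints) == 0) break
    removed_any <- FALSE
    for (e in seq_len(nrow(endpoints))) {
      r <- endpoints[e, 1]; c <- endpoints[e, 2]
      if (sk[r, c] == 0L) next
      path <- matrix(c(r, c), 1, 2)
      prev <- c(NA, NA)
      ok <- FALSE
      while (nrow(path) <= max_len) {
        nb <- skeleton_neighbours(sk, r, c)
        if (!is.na(prev[1]))
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nb) == 0) break                      # isolated short arc
        if (nrow(nb) > 1) {                           # current pixel is a junction
          path <- path[-nrow(path), , drop = FALSE]
          ok <- TRUE
          break
        }
        prev <- c(r, c)
        r <- nb[1, 1]; c <- nb[1, 2]
        if (neighbour_count_at(sk, r, c) > 2) { ok <- TRUE; break }
        path <- rbind(path, c(r, c))
      }
      if (ok && nrow(path) > 0 && nrow(path) <= max_len) {
        sk[path] <- 0L
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  sk
}

skeleton_neighbours <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(integer(0), 0, 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && m[rr, cc] == 1L)
      out <- rbind(out, c(rr, cc))
  }
  out
}

neighbour_count_at <- function(m, r, c) nrow(skeleton_neighbours(m, r, c))

#' Skeleton path length in millimetres
#'
#' Counts 8-neighbour adjacencies of the 1-px skeleton: orthogonal links
#' weigh 1 pixel, diagonal links weigh sqrt(2) pixels. A diagonal link whose
#' two pixels share a foreground orthogonal neighbour is a chord of an
#' L-corner already counted by its two orthogonal links and is skipped.
#' Length = (N_orth + sqrt(2) N_diag) * pitch / 1000.
#'
#' @param skeleton 0/1 matrix (1 px wide)
#' @param pixel_pitch_um micrometres per pixel
#' @return length in millimetres
#' @export
skeleton_length_mm <- function(skeleton, pixel_pitch_um = default_pixel_pitch_um()) {
  m <- skeleton
  if (inherits(m, "segmentation_mask")) m <- m$data
  storage.mode(m) <- "integer"
  H <- nrow(m); W <- ncol(m)
  if (sum(m) == 0) return(0)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  east <- pad[2:(H + 1), 3:(W + 2)]
  south <- pad[3:(H + 2), 2:(W + 1)]
  se <- pad[3:(H + 2), 3:(W + 2)]
  sw <- pad[3:(H + 2), 1:W]
  west <- pad[2:(H + 1), 1:W]
  n_orth <- sum(ctr & east) + sum(ctr & south)
  # diagonal SE: chord if shared orthogonal neighbour (E or S) is set
  n_se <- sum(ctr & se & !(east | south))
  # diagonal SW: shared orthogonal neighbours are W and S
  n_sw <- sum(ctr & sw & !(west | south))
  (n_orth + sqrt(2) * (n_se + n_sw)) * pixel_pitch_um / 1000
}

#' Per-image algorithmic nerve length estimate
#'
#' Skeletonizes the mask and measures skeleton path length. An alternative
#' proxy (`method = "pixel_count"`: foreground pixel count divided by the
#' nominal stroke width) is available behind a flag.
#'
#' @param mask a `nerve_binary` [segmentation_mask()] or 0/1 matrix
#' @param pixel_pitch_um micrometres per pixel
#' @param method `"skeleton"` (default) or `"pixel_count"`
#' @param stroke_width_px nominal stroke width for the pixel-count proxy
#' @param prune_px see [skeletonize()]
#' @return list of class `length_estimate`: `image_id`, `method`
#'   (`"algorithmic"`), `length_mm`
#' @export
cnfl_image <- function(mask, pixel_pitch_um = default_pixel_pitch_um(),
                       method = c("skeleton", "pixel_count"),
                       stroke_width_px = 4, prune_px = 2L,
                       image_id = NA_character_) {
  method <- match.arg(method)
  m <- if (inherits(mask, "segmentation_mask")) mask$data else mask
  len <- if (method == "skeleton") {
    skeleton_length_mm(skeletonize(m, prune_px), pixel_pitch_um)
  } else {
    sum(m) / stroke_width_px * pixel_pitch_um / 1000
  }
  structure(list(image_id = image_id, method = "algorithmic",
                 length_mm = len),
            class = "length_estimate")
}

#' Per-participant CNFL density
#'
#' CNFL density = mean per-image nerve length (mm) divided by the analyzed
#' image area (mm^2); with the default 384 px / 400 um field the area is
#' exactly 0.16 mm^2 per image.
#'
#' @param lengths_mm per-image nerve lengths in mm (>= 1 value)
#' @param area_mm2 image area in mm^2
#' @param subject_id optional identifier
#' @return list of class `participant_cnfl`: `subject_id`,
#'   `per_image_lengths_mm`, `avg_length_mm`, `area_mm2`, `cnfl_density`
#'   (mm/mm^2)
#' @export
cnfl_participant <- function(lengths_mm, area_mm2 = 0.16,
                             subject_id = NA_character_) {
  if (length(lengths_mm) < 1)
    stop("at least one per-image length is required")
  if (anyNA(lengths_mm) || any(lengths_mm < 0))
    stop("lengths must be non-negative and non-missing")
  if (!is.numeric(area_mm2) || area_mm2 <= 0) stop("`area_mm2` must be > 0")
  avg <- mean(lengths_mm)
  structure(list(subject_id = subject_id,
                 per_image_lengths_mm = lengths_mm,
                 avg_length_mm = avg, area_mm2 = area_mm2,
                 cnfl_density = avg / area_mm2),
            class = "participant_cnfl")
}

#' Choose between the algorithmic and regression length estimators
#'
#' Computes MAPE and MAE of each method against ground truth across the
#' dataset and selects the method with the lower MAPE (ties: lower MAE;
#' further ties: the simpler algorithmic method).
#'
#' @param pred_algorithmic,pred_regression per-image predicted lengths (mm)
#' @param truth matching ground-truth lengths (mm)
#' @return list of class `estimator_selection`: `chosen` and a `report`
#'   data frame with both methods' MAPE (%) and MAE
#' @export
select_estimator <- function(pred_algorithmic, pred_regression, truth) {
  if (length(pred_algorithmic) != length(truth) ||
      length(pred_regression) != length(truth))
    stop("prediction and truth vectors must have equal length")
  rep <- data.frame(
    method = c("algorithmic", "regression"),
    mape = c(mape(pred_algorithmic, truth), mape(pred_regression, truth)),
    mae = c(mae(pred_algorithmic, truth), mae(pred_regression, truth)))
  chosen <- if (rep$mape[2] < rep$mape[1]) "regression"
  else if (rep$mape[1] < rep$mape[2]) "algorithmic"
  else if (rep$mae[2] < rep$mae[1]) "regression"
  else "algorithmic"
  structure(list(chosen = chosen, report = rep),
            class = "estimator_selection")
}
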