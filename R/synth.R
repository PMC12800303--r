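# Synthetic IVCM-like image generator with analytically known ground truth.
#
# The generator emulates the appearance the estimation pipeline relies on:
# bright, predominantly vertical, gently curved nerve fibres and bright
# cell blobs (ovoid bodies; the with-dendrites class additionally carries
# thin radiating processes) over a noisy dark background. Nerve arc length
# is known exactly from the generating polyline, and cell counts/classes
# from the generated polygons, so every downstream stage can be validated
# without clinical data.

#' Parameters of the synthetic image generator
#'
#' Defaults describe a 384 x 384 px / 400 x 400 um field. Nerves are near
#' vertical (base deviation SD 8 degrees) with a smooth sinusoidal tangent
#' wiggle; per-image cell counts default to the symptomatic-group means
#' (1.86 with-dendrites and 9.57 without-dendrites cells per 0.16 mm^2
#' image).
#'
#' @param image_shape integer `c(height, width)` in pixels
#' @param pixel_pitch_um micrometres per pixel
#' @param nerves_per_image integer range `c(min, max)`
#' @param nerve_angle_sd_deg SD of the per-nerve base deviation from vertical
#' @param nerve_wiggle_amp_deg range of the sinusoidal tangent-wiggle amplitude
#' @param nerve_wiggle_wavelength_px range of the wiggle wavelength
#' @param nerve_width_px integer range of rendered stroke widths
#' @param nerve_intensity range of rendered nerve grey levels
#' @param dc_with_per_image,dc_without_per_image Poisson means of per-image
#'   cell counts per class
#' @param cell_radius_px range of cell body semi-axes
#' @param cell_intensity range of rendered cell grey levels
#' @param dendrite_count integer range of processes per with-dendrites cell
#' @param dendrite_len_px range of process lengths
#' @param background_level mean background grey level
#' @param background_field_amp amplitude of the smooth background field
#' @param noise_sd additive Gaussian noise SD (grey levels)
#' @param speckle_sd multiplicative speckle SD
#' @param blur_sigma Gaussian blur SD in pixels
#' @param seed default RNG seed
#' @return a list of class `synth_params`
#' @export
synth_params <- function(image_shape = c(384L, 384L),
                         pixel_pitch_um = default_pixel_pitch_um(),
                         nerves_per_image = c(2L, 5L),
                         nerve_angle_sd_deg = 8,
                         nerve_wiggle_amp_deg = c(3, 10),
                         nerve_wiggle_wavelength_px = c(150, 400),
                         nerve_width_px = c(3L, 5L),
                         nerve_intensity = c(140, 220),
                         dc_with_per_image = 1.86,
                         dc_without_per_image = 9.57,
                         cell_radius_px = c(3.5, 5.5),
                         cell_intensity = c(150, 230),
                         dendrite_count = c(2L, 4L),
                         dendrite_len_px = c(4, 10),
                         background_level = 45,
                         background_field_amp = 15,
                         noise_sd = 12,
                         speckle_sd = 0.08,
                         blur_sigma = 0.7,
                         seed = 1L) {
  p <- as.list(environment())
  rng <- function(v) length(v) == 2 && all(v >= 0) && v[2] >= v[1]
  stopifnot(length(p$image_shape) == 2, all(p$image_shape >= 16),
            p$pixel_pitch_um > 0, rng(p$nerves_per_image),
            rng(p$nerve_wiggle_amp_deg), rng(p$nerve_wiggle_wavelength_px),
            rng(p$nerve_width_px), rng(p$cell_radius_px),
            p$dc_with_per_image >= 0, p$dc_without_per_image >= 0)
  structure(p, class = "synth_params")
}

runif1 <- function(rng) runif(1, rng[1], rng[2])
runif_int <- function(rng) sample(seq(rng[1], rng[2]), 1)

# grow one nerve polyline from a random top-edge start; stops at the image
# border or when `max_len_px` arc length is consumed (last step trimmed so
# the total is exact)
grow_nerve <- function(shape, angle_sd_deg, amp_deg, wl_px,
                       max_len_px = Inf) {
  H <- shape[1]; W <- shape[2]
  margin <- 2
  x <- runif(1, margin + 2, W - margin - 3)
  y <- runif(1, 0, 2)
  theta0 <- rnorm(1, 0, angle_sd_deg * pi / 180)
  theta0 <- max(min(theta0, pi / 7), -pi / 7)
  amp <- runif1(amp_deg) * pi / 180
  wl <- runif1(wl_px)
  phase <- runif(1, 0, 2 * pi)
  ds <- 2
  pts <- matrix(c(x, y), 1, 2)
  s <- 0
  len <- 0
  repeat {
    ang <- theta0 + amp * sin(2 * pi * s / wl + phase)
    step <- min(ds, max_len_px - len)
    if (step <= 1e-9) break
    nx <- x + sin(ang) * step
    ny <- y + cos(ang) * step
    if (nx < margin || nx >= W - margin || ny >= H - margin) {
      # trim the final step to the boundary
      tmax <- 1
      if (nx < margin) tmax <- min(tmax, (x - margin) / (x - nx))
      if (nx >= W - margin) tmax <- min(tmax, (W - margin - x) / (nx - x))
      if (ny >= H - margin) tmax <- min(tmax, (H - margin - y) / (ny - y))
      tmax <- max(tmax, 0)
      if (tmax > 1e-6) {
        x2 <- x + (nx - x) * tmax
        y2 <- y + (ny - y) * tmax
        pts <- rbind(pts, c(x2, y2))
      }
      break
    }
    x <- nx; y <- ny
    s <- s + step; len <- len + step
    pts <- rbind(pts, c(x, y))
    if (len >= max_len_px - 1e-9) break
  }
  if (nrow(pts) < 2) NULL else pts
}

polyline_len <- function(p) {
  d <- diff(p)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# random cell-body polygon: jittered ellipse
cell_polygon <- function(centre, r1, r2, rot, nv = 14) {
  ang <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  rad <- 1 + runif(nv, -0.2, 0.2)
  ex <- r1 * rad * cos(ang)
  ey <- r2 * rad * sin(ang)
  x <- centre[1] + ex * cos(rot) - ey * sin(rot)
  y <- centre[2] + ex * sin(rot) + ey * cos(rot)
  cbind(x, y)
}

gaussian_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= half, exp(-d^2 / (2 * sigma^2)), 0)
  })
  K / rowSums(K)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Kr <- gaussian_band(nrow(m), sigma)
  Kc <- gaussian_band(ncol(m), sigma)
  Kr %*% m %*% t(Kc)
}

#' Generate one synthetic IVCM-like sample
#'
#' Deterministic given `(params, seed)`. The returned ground truth carries
#' the exact polyline arc length (in mm, via the pixel pitch) and the exact
#' per-class cell counts.
#'
#' @param params a [synth_params()]
#' @param seed RNG seed (defaults to `params$seed`)
#' @param n_nerves optional forced nerve count (overrides the range)
#' @param target_length_mm optional exact total nerve length to generate;
#'   nerves are grown until the target is consumed (the last one trimmed)
#' @param n_with,n_without optional forced cell counts
#' @param subject_id,eye,image_id metadata for the generated record
#' @return a list of class `synthetic_sample` with elements `image`
#'   ([image_record()]), `tracing` ([nerve_tracing()]),
#'   `true_nerve_length_mm`, `annotation` ([cell_annotation()]) and
#'   `true_counts` (named vector)
#' @export
generate_sample <- function(params = synth_params(), seed = params$seed,
                            n_nerves = NULL, target_length_mm = NULL,
                            n_with = NULL, n_without = NULL,
                            subject_id = "S01", eye = "OS",
                            image_id = "img001") {
  stopifnot(inherits(params, "synth_params"))
  set.seed(seed)
  H <- params$image_shape[1]; W <- params$image_shape[2]

  # --- nerves ---------------------------------------------------------
  polylines <- list()
  widths <- integer(0)
  if (!is.null(target_length_mm)) {
    remaining <- target_length_mm * 1000 / params$pixel_pitch_um
    guard <- 0
    while (remaining > 2 && guard < 200) {
      guard <- guard + 1
      p <- grow_nerve(c(H, W), params$nerve_angle_sd_deg,
                      params$nerve_wiggle_amp_deg,
                      params$nerve_wiggle_wavelength_px,
                      max_len_px = remaining)
      if (is.null(p)) next
      polylines[[length(polylines) + 1]] <- p
      widths <- c(widths, runif_int(params$nerve_width_px))
      remaining <- remaining - polyline_len(p)
    }
  } else {
    nn <- if (is.null(n_nerves)) runif_int(params$nerves_per_image) else n_nerves
    for (i in seq_len(nn)) {
      p <- grow_nerve(c(H, W), params$nerve_angle_sd_deg,
                      params$nerve_wiggle_amp_deg,
                      params$nerve_wiggle_wavelength_px)
      if (is.null(p)) next
      polylines[[length(polylines) + 1]] <- p
      widths <- c(widths, runif_int(params$nerve_width_px))
    }
  }
  tracing <- nerve_tracing(if (length(polylines)) polylines else list(),
                           c(H, W))
  true_len_mm <- if (length(polylines))
    sum(vapply(polylines, polyline_len, numeric(1))) *
      params$pixel_pitch_um / 1000 else 0

  # --- cells ----------------------------------------------------------
  kw <- if (is.null(n_with)) rpois(1, params$dc_with_per_image) else n_with
  kwo <- if (is.null(n_without)) rpois(1, params$dc_without_per_image) else n_without
  labels <- c(rep("with_dendrites", kw), rep("without_dendrites", kwo))
  centres <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  polygons <- list()
  kept_labels <- character(0)
  dendrites <- list()
  for (lab in labels) {
    r1 <- runif1(params$cell_radius_px)
    r2 <- runif1(params$cell_radius_px)
    rmax <- max(r1, r2) * 1.2
    placed <- FALSE
    for (try in 1:200) {
      cx <- runif(1, rmax + 8, W - rmax - 9)
      cy <- runif(1, rmax + 8, H - rmax - 9)
      if (nrow(centres)) {
        dmin <- min(sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2) -
                      radii)
        if (dmin < rmax + 3) next
      }
      centres <- rbind(centres, c(cx, cy))
      radii <- c(radii, rmax)
      placed <- TRUE
      break
    }
    if (!placed) next
    rot <- runif(1, 0, pi)
    poly <- cell_polygon(c(cx, cy), r1, r2, rot)
    polygons[[length(polygons) + 1]] <- list(vertices = poly, label = lab)
    kept_labels <- c(kept_labels, lab)
    if (lab == "with_dendrites") {
      nd <- runif_int(params$dendrite_count)
      segs <- lapply(seq_len(nd), function(i) {
        a <- runif(1, 0, 2 * pi)
        l <- runif1(params$dendrite_len_px)
        r0 <- min(r1, r2) * 0.6
        rbind(c(cx + r0 * cos(a), cy + r0 * sin(a)),
              c(cx + (r0 + l) * cos(a), cy + (r0 + l) * sin(a)))
      })
      dendrites[[length(dendrites) + 1]] <- segs
    }
  }
  annotation <- cell_annotation(polygons, c(H, W))
  true_counts <- c(with_dendrites = sum(kept_labels == "with_dendrites"),
                   without_dendrites = sum(kept_labels == "without_dendrites"))

  # --- rendering ------------------------------------------------------
  img <- matrix(params$background_level, H, W)
  if (params$background_field_amp > 0) {
    field <- gaussian_blur(matrix(rnorm(H * W), H, W), min(H, W) / 10)
    field <- field / max(sd(field), 1e-9)
    img <- img + params$background_field_amp * field
  }
  for (i in seq_along(polylines)) {
    m <- matrix(0L, H, W)
    m <- stroke_polyline(m, polylines[[i]], widths[i])
    img[m == 1L] <- pmax(img[m == 1L], runif1(params$nerve_intensity))
  }
  di <- 0
  for (i in seq_along(polygons)) {
    inten <- runif1(params$cell_intensity)
    px <- polygon_fill_pixels(polygons[[i]]$vertices, c(H, W))
    if (nrow(px)) img[px] <- pmax(img[px], inten)
    if (polygons[[i]]$label == "with_dendrites") {
      di <- di + 1
      for (seg in dendrites[[di]]) {
        m <- matrix(0L, H, W)
        m <- stroke_polyline(m, seg, 1.6)
        img[m == 1L] <- pmax(img[m == 1L], inten * 0.85)
      }
    }
  }
  if (params$speckle_sd > 0)
    img <- img * (1 + params$speckle_sd * matrix(rnorm(H * W), H, W))
  if (params$noise_sd > 0)
    img <- img + matrix(rnorm(H * W, 0, params$noise_sd), H, W)
  img <- gaussian_blur(img, params$blur_sigma)
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), H, W)

  structure(
    list(image = image_record(img, subject_id, eye, image_id,
                              params$pixel_pitch_um),
         tracing = tracing,
         true_nerve_length_mm = true_len_mm,
         annotation = annotation,
         true_counts = true_counts),
    class = "synthetic_sample")
}

rtruncnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Default two-group cohort specification
#'
#' Subject-level means and SDs of CNFL density (mm/mm^2) and of the two DC
#' densities (cells/mm^2) for a symptomatic group and a control group,
#' matching the study-population summary this generator emulates.
#' @return named list of per-group specs
#' @export
default_group_specs <- function() {
  list(
    group1 = list(cnfl_mean = 17.3, cnfl_sd = 3.8,
                  dc_with_mean = 11.6, dc_with_sd = 14.1,
                  dc_without_mean = 59.8, dc_without_sd = 53.4),
    group2 = list(cnfl_mean = 19.4, cnfl_sd = 4.0,
                  dc_with_mean = 6.6, dc_with_sd = 6.0,
                  dc_without_mean = 36.0, dc_without_sd = 42.0))
}

#' Generate a two-group synthetic cohort with subject-level structure
#'
#' Per-subject latent densities are drawn from the group distribution
#' (normal truncated at zero); per-image nerve length is the subject target
#' scaled by multiplicative noise (CV 10%), generated to the exact per-image
#' target; per-image cell counts are Poisson around the subject latent
#' density times the image area. Each subject contributes two eyes with
#' `images_per_eye` images each.
#'
#' @param group_specs per-group latent means/SDs; see [default_group_specs()]
#' @param n_subjects subjects per group (scalar or one value per group)
#' @param images_per_eye images per eye per subject
#' @param seed RNG seed
#' @param params a [synth_params()] controlling image rendering
#' @param image_cv multiplicative per-image CNFL noise (coefficient of
#'   variation)
#' @param dc_count_area_mm2 area that converts a subject's latent cell
#'   density into their expected per-image count. `NULL` (default) uses the
#'   generated image's own area. Setting it to 0.16 reproduces the full
#'   field's per-image count distribution on a smaller rendered crop
#'   (cells are discrete objects, so a scaled-down study keeps per-image
#'   counts rather than scaling them with crop area); per-image counts then
#'   refer to 0.16 mm^2 when converted back to densities
#' @return a list of class `synth_cohort`: `samples` (list of
#'   [generate_sample()] outputs), `truth` (one row per image) and
#'   `subjects` (one row per subject with latent densities)
#' @export
generate_cohort <- function(group_specs = default_group_specs(),
                            n_subjects = 4, images_per_eye = 5, seed = 1L,
                            params = synth_params(), image_cv = 0.10,
                            dc_count_area_mm2 = NULL) {
  if (any(n_subjects < 1) || images_per_eye < 1)
    stop("`n_subjects` and `images_per_eye` must be positive")
  if (length(n_subjects) == 1) n_subjects <- rep(n_subjects, length(group_specs))
  set.seed(seed)
  area <- image_area_mm2(params$image_shape, params$pixel_pitch_um)
  dc_area <- if (is.null(dc_count_area_mm2)) area else dc_count_area_mm2
  samples <- list()
  truth <- list()
  subjects <- list()
  sid <- 0
  for (g in seq_along(group_specs)) {
    gs <- group_specs[[g]]
    gname <- names(group_specs)[g]
    for (s in seq_len(n_subjects[g])) {
      sid <- sid + 1
      subject <- sprintf("S%03d", sid)
      cnfl <- rtruncnorm0(1, gs$cnfl_mean, gs$cnfl_sd)
      dw <- rtruncnorm0(1, gs$dc_with_mean, gs$dc_with_sd)
      dwo <- rtruncnorm0(1, gs$dc_without_mean, gs$dc_without_sd)
      subjects[[sid]] <- data.frame(
        subject_id = subject, group = gname, latent_cnfl = cnfl,
        latent_dc_with = dw, latent_dc_without = dwo)
      img_i <- 0
      for (eye in c("OS", "OD")) {
        for (k in seq_len(images_per_eye)) {
          img_i <- img_i + 1
          image_id <- sprintf("%s_%s_%02d", subject, eye, img_i)
          mult <- max(0.25, rnorm(1, 1, image_cv))
          tlen <- cnfl * area * mult
          nw <- rpois(1, dw * dc_area)
          nwo <- rpois(1, dwo * dc_area)
          smp_seed <- sample.int(.Machine$integer.max, 1)
          smp <- generate_sample(params, seed = smp_seed,
                                 target_length_mm = tlen,
                                 n_with = nw, n_without = nwo,
                                 subject_id = subject, eye = eye,
                                 image_id = image_id)
          samples[[length(samples) + 1]] <- smp
          truth[[length(truth) + 1]] <- data.frame(
            subject_id = subject, group = gname, eye = eye,
            image_id = image_id,
            true_length_mm = smp$true_nerve_length_mm,
            n_with = unname(smp$true_counts["with_dendrites"]),
            n_without = unname(smp$true_counts["without_dendrites"]))
        }
      }
    }
  }
  structure(list(samples = samples,
                 truth = do.call(rbind, truth),
                 subjects = do.call(rbind, subjects),
                 params = params, group_specs = group_specs,
                 images_per_eye = images_per_eye, seed = seed,
                 dc_count_area_mm2 = dc_area),
            class = "synth_cohort")
}

#' Write a synthetic cohort to disk in the per-subject folder layout
#'
#' Creates `subject/OS/*.tif` and `subject/OD/*.tif` plus matching `.ndf`
#' tracings, `.json` cell annotations and a `truth.csv` index.
#'
#' @param cohort a [generate_cohort()] result
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (smp in cohort$samples) {
    rec <- smp$image
    sub_dir <- file.path(dir, rec$subject_id, rec$eye)
    dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(sub_dir, rec$image_id)
    write_ivcm_image(rec, paste0(base, ".tif"))
    if (length(smp$tracing$polylines))
      write_ndf(smp$tracing, paste0(base, ".ndf"))
    write_labelme(smp$annotation, paste0(base, ".json"))
  }
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  invisible(dir)
}
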