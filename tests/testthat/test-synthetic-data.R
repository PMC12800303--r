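test_that("empty scenes, forced geometry and determinism behave as specified", {
  p <- tiny_params(c(64L, 64L))
  bare <- generate_sample(p, seed = 2, n_nerves = 0, n_with = 0, n_without = 0)
  expect_equal(bare$true_nerve_length_mm, 0)
  expect_equal(unname(bare$true_counts), c(0L, 0L))
  expect_length(bare$tracing$polylines, 0)

  # a full-height straight vertical nerve: arc length = (H-1) px exactly
  tall <- nerve_tracing(list(cbind(c(30, 30), c(0, 383))), c(384L, 384L))
  expect_equal(tracing_length_mm(tall), 383 * (400 / 384) / 1000)

  a <- generate_sample(p, seed = 99)
  b <- generate_sample(p, seed = 99)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$tracing$polylines, b$tracing$polylines)
  expect_identical(a$true_counts, b$true_counts)
  c2 <- generate_sample(p, seed = 100)
  expect_false(identical(a$image$pixels, c2$image$pixels))
})

test_that("ground truth is self-consistent with the generating objects", {
  p <- tiny_params(c(64L, 64L))
  smp <- generate_sample(p, seed = 5, n_with = 3, n_without = 4)
  expect_equal(smp$true_nerve_length_mm,
               tracing_length_mm(smp$tracing, p$pixel_pitch_um),
               tolerance = 1e-9)
  expect_equal(smp$true_counts, annotation_counts(smp$annotation))
  # a requested exact total length is hit exactly
  smp2 <- generate_sample(p, seed = 6, target_length_mm = 0.12)
  expect_equal(smp2$true_nerve_length_mm, 0.12, tolerance = 1e-6)
})

test_that("cohorts have the requested bookkeeping structure", {
  p <- tiny_params(c(32L, 32L))
  co <- generate_cohort(n_subjects = 2, images_per_eye = 5, seed = 4,
                        params = p)
  expect_length(co$samples, 2 * 2 * 2 * 5)  # 2 groups x 2 subjects x 2 eyes x 5
  expect_equal(length(unique(co$truth$subject_id)), 4)
  expect_true(all(table(co$truth$subject_id, co$truth$eye) == 5))
  co2 <- generate_cohort(n_subjects = 2, images_per_eye = 5, seed = 4,
                         params = p)
  expect_identical(co$truth, co2$truth)
  expect_error(generate_cohort(n_subjects = 0, params = p), "positive")
})

test_that("subject-level latent means recover the group specification", {
  p <- tiny_params(c(32L, 32L))
  co <- generate_cohort(n_subjects = 150, images_per_eye = 1, seed = 11,
                        params = p)
  gs <- default_group_specs()
  for (g in names(gs)) {
    lat <- co$subjects$latent_cnfl[co$subjects$group == g]
    se <- gs[[g]]$cnfl_sd / sqrt(length(lat))
    expect_lt(abs(mean(lat) - gs[[g]]$cnfl_mean), 3 * se)
  }
})

test_that("per-image true lengths scatter around the subject latent density", {
  p <- tiny_params(c(48L, 48L))
  co <- generate_cohort(n_subjects = 1, images_per_eye = 15, seed = 21,
                        params = p, image_cv = 0.10)
  area <- image_area_mm2(p$image_shape, p$pixel_pitch_um)
  for (s in unique(co$truth$subject_id)) {
    d <- co$truth[co$truth$subject_id == s, ]
    latent <- co$subjects$latent_cnfl[co$subjects$subject_id == s]
    implied <- mean(d$true_length_mm) / area
    expect_lt(abs(implied - latent) / latent, 4 * 0.10 / sqrt(nrow(d)) + 0.02)
  }
})

test_that("a written cohort round-trips through the documented folder layout", {
  dir <- withr::local_tempdir()
  p <- tiny_params(c(32L, 32L))
  co <- generate_cohort(n_subjects = 1, images_per_eye = 1, seed = 8,
                        params = p)
  write_cohort(co, dir)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), length(co$samples))
  row <- truth[1, ]
  img_path <- file.path(dir, row$subject_id, row$eye,
                        paste0(row$image_id, ".tif"))
  expect_true(file.exists(img_path))
  rec <- read_ivcm_image(img_path)
  expect_equal(rec$subject_id, row$subject_id)
  expect_equal(rec$eye, row$eye)
  smp <- co$samples[[1]]
  expect_identical(unname(rec$pixels), unname(smp$image$pixels))
  ann <- parse_labelme(file.path(dir, row$subject_id, row$eye,
                                 paste0(row$image_id, ".json")))
  expect_equal(annotation_counts(ann), smp$true_counts)
  ndf <- file.path(dir, row$subject_id, row$eye, paste0(row$image_id, ".ndf"))
  if (file.exists(ndf)) {
    tr <- parse_ndf(ndf, p$image_shape)
    expect_length(tr$polylines, length(smp$tracing$polylines))
  }
})
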