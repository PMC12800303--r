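test_that("parse_ndf reads tracing blocks and preserves point order", {
  txt <- c("// NeuronJ Data File - v1.4.3",
           "// Tracing N1", "0", "0", "3", "4",
           "// End of NeuronJ Data File")
  tr <- parse_ndf(txt)
  expect_length(tr$polylines, 1)
  expect_equal(unname(tr$polylines[[1]]), cbind(c(0, 3), c(0, 4)))

  txt2 <- c("// NeuronJ Data File - v1.4.3",
            "// Tracing N1", as.character(rep(1:5, each = 2)),
            "// Tracing N2", as.character(rep(1:7, each = 2)))
  tr2 <- parse_ndf(txt2)
  expect_length(tr2$polylines, 2)
  expect_equal(vapply(tr2$polylines, nrow, integer(1)), c(5L, 7L))
})

test_that("parse_ndf rejects malformed input with informative errors", {
  expect_error(parse_ndf(character(0)), "empty")
  expect_error(parse_ndf(c("not a header", "// Tracing N1", "1", "2", "3", "4")),
               "line 1")
  expect_error(parse_ndf(c("// NeuronJ Data File",
                           "// Tracing N1", "1", "2", "3")),
               "odd coordinate count.*block 1")
  expect_error(parse_ndf(c("// NeuronJ Data File",
                           "// Tracing N1", "1", "2", "x", "4")),
               "non-numeric")
})

test_that("NDF round-trips bit-identically over many random tracings", {
  set.seed(101)
  for (i in 1:100) {
    tr <- random_tracing(c(384L, 384L), n_poly = sample(1:10, 1))
    lines <- write_ndf(tr)
    tr2 <- parse_ndf(lines)
    expect_identical(write_ndf(tr2), lines)
    expect_equal(tr2$polylines, tr$polylines, ignore_attr = TRUE)
  }
  # unknown header lines are preserved verbatim
  txt <- c("// NeuronJ Data File - v1.4.3", "// Parameters", "4", "1.0",
           "// Tracing N1 default", "10", "20", "30", "40",
           "// End of NeuronJ Data File")
  expect_identical(write_ndf(parse_ndf(txt)), txt)
})

test_that("parse_labelme maps labels, counts classes, allows empty shapes", {
  shapes <- c(
    lapply(1:2, function(i) list(label = "1", points = list(
      list(10 + i, 10), list(20 + i, 10), list(15 + i, 20)))),
    lapply(1:3, function(i) list(label = "2", points = list(
      list(30, 10 * i), list(40, 10 * i), list(35, 10 * i + 5)))))
  doc <- jsonlite::toJSON(list(shapes = shapes, imageHeight = 64,
                               imageWidth = 64), auto_unbox = TRUE)
  ann <- parse_labelme(doc)
  expect_length(ann$polygons, 5)
  expect_equal(unname(annotation_counts(ann)), c(2L, 3L))
  expect_equal(ann$image_shape, c(64L, 64L))

  empty <- jsonlite::toJSON(list(shapes = list()), auto_unbox = TRUE)
  expect_length(parse_labelme(empty)$polygons, 0)
})

test_that("parse_labelme rejects degenerate polygons and unknown labels", {
  two_pts <- jsonlite::toJSON(list(shapes = list(list(label = "1",
    points = list(list(1, 1), list(2, 2))))), auto_unbox = TRUE)
  expect_error(parse_labelme(two_pts), "fewer than 3 vertices")
  bad_lab <- jsonlite::toJSON(list(shapes = list(list(label = "nerve",
    points = list(list(1, 1), list(2, 2), list(3, 1))))), auto_unbox = TRUE)
  expect_error(parse_labelme(bad_lab), "permitted labels")
  expect_error(parse_labelme(jsonlite::toJSON(list(foo = 1))), "shapes")
})

test_that("labelme documents round-trip through write_labelme", {
  set.seed(7)
  polys <- lapply(1:5, function(i) {
    list(vertices = square_polygon(5 * i, 5 * i, 4),
         label = sample(dc_classes(), 1))
  })
  ann <- cell_annotation(polys, c(64L, 64L))
  ann2 <- parse_labelme(write_labelme(ann))
  expect_equal(annotation_counts(ann2), annotation_counts(ann))
  expect_equal(lapply(ann2$polygons, `[[`, "vertices"),
               lapply(ann$polygons, `[[`, "vertices"),
               ignore_attr = TRUE)
})

test_that("8-bit images round-trip losslessly and depth is enforced", {
  dir <- withr::local_tempdir()
  set.seed(11)
  px <- matrix(sample(0:255, 384 * 384, TRUE), 384, 384)
  rec <- image_record(px, "S01", "OD", "img1")
  for (ext in c("tif", "png")) {
    f <- file.path(dir, paste0("img.", ext))
    write_ivcm_image(rec, f)
    back <- read_ivcm_image(f)
    expect_identical(unname(back$pixels), unname(px))
  }
  f16 <- file.path(dir, "deep.tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), f16, bits.per.sample = 16L)
  expect_error(read_ivcm_image(f16), "8-bit")
})

test_that("subject and eye are inferred from the OS/OD folder layout", {
  dir <- withr::local_tempdir()
  sub_dir <- file.path(dir, "S042", "OD")
  dir.create(sub_dir, recursive = TRUE)
  rec <- image_record(matrix(0L, 16, 16), "S042", "OD", "img3")
  f <- file.path(sub_dir, "img3.tif")
  write_ivcm_image(rec, f)
  back <- read_ivcm_image(f)
  expect_equal(back$eye, "OD")
  expect_equal(back$subject_id, "S042")
  expect_equal(back$image_id, "img3")
})
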