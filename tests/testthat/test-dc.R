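onehot_from_label <- function(lab) {
  data <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  data[, , 1] <- (lab == 0)
  data[, , 2] <- (lab == 1)
  data[, , 3] <- (lab == 2)
  data
}

test_that("component counting matches a brute-force flood-fill oracle", {
  lab <- matrix(0L, 48, 48)
  lab[5:10, 5:10] <- 1L
  lab[5:10, 20:25] <- 1L
  lab[30:35, 30:35] <- 1L
  m <- onehot_from_label(lab)
  expect_equal(count_components(m, "with_dendrites"), 3)
  expect_equal(count_components(m, "without_dendrites"), 0)

  # two squares joined by a single diagonal-touching pixel bridge: one
  # component under 8-connectivity
  lab2 <- matrix(0L, 32, 32)
  lab2[5:9, 5:9] <- 2L
  lab2[10, 10] <- 2L
  lab2[11:15, 11:15] <- 2L
  m2 <- onehot_from_label(lab2)
  expect_equal(count_components(m2, "without_dendrites"), 1)
  expect_equal(brute_count_components(lab2 == 2, 10), 1)

  set.seed(13)
  for (i in 1:10) {
    lab3 <- matrix(rbinom(32 * 32, 1, 0.25), 32, 32)
    m3 <- onehot_from_label(lab3)
    expect_equal(count_components(m3, "with_dendrites", min_area_px = 1),
                 brute_count_components(lab3 == 1, 1))
    expect_equal(count_components(m3, "with_dendrites", min_area_px = 5),
                 brute_count_components(lab3 == 1, 5))
  }
})

test_that("small components fall below the area threshold", {
  lab <- matrix(0L, 32, 32)
  lab[4, 4] <- 1L                 # single-pixel noise
  lab[10:13, 10:13] <- 1L         # 16 px cell
  m <- onehot_from_label(lab)
  expect_equal(count_components(m, "with_dendrites"), 1)
  expect_equal(count_components(m, "with_dendrites", min_area_px = 1), 2)
})

test_that("counting is invariant to translation and image order", {
  lab <- matrix(0L, 64, 64)
  lab[10:14, 10:14] <- 2L
  lab[40:45, 20:26] <- 2L
  shifted <- matrix(0L, 64, 64)
  shifted[15:19, 13:17] <- 2L
  shifted[45:50, 23:29] <- 2L
  expect_equal(count_components(onehot_from_label(lab), "without_dendrites"),
               count_components(onehot_from_label(shifted), "without_dendrites"))

  counts <- data.frame(n_with = c(1, 4, 2), n_without = c(3, 0, 5))
  d1 <- densities_participant(counts)
  d2 <- densities_participant(counts[c(3, 1, 2), ])
  expect_equal(d1$density_total, d2$density_total)
})

test_that("participant densities follow the closed forms exactly", {
  one <- densities_participant(data.frame(n_with = 0, n_without = 1))
  expect_equal(one$density_without, 6.25)
  expect_equal(one$density_total, 6.25)

  zero <- densities_participant(data.frame(n_with = rep(0, 10),
                                           n_without = rep(0, 10)))
  expect_equal(zero$density_total, 0)

  # inverting the symptomatic-group per-image means: 1.856 and 9.568 cells
  # per 0.16 mm^2 image give 11.6 and 59.8 cells/mm^2, total 71.4
  dens <- densities_participant(data.frame(n_with = rep(1856, 10),
                                           n_without = rep(9568, 10)),
                                area_mm2 = 160)
  expect_equal(dens$density_with, 11.6, tolerance = 1e-12)
  expect_equal(dens$density_without, 59.8, tolerance = 1e-12)
  expect_equal(dens$density_total, 71.4, tolerance = 1e-12)
  expect_equal(dens$density_total, dens$density_with + dens$density_without)

  expect_error(densities_participant(data.frame(n_with = numeric(0),
                                                n_without = numeric(0))),
               "at least one")
  expect_error(densities_participant(data.frame(n_with = -1, n_without = 0)),
               "non-negative")
})

test_that("total density additivity holds for random count tables", {
  set.seed(19)
  for (i in 1:20) {
    counts <- data.frame(n_with = rpois(10, 2), n_without = rpois(10, 9))
    dens <- densities_participant(counts)
    expect_identical(dens$density_total,
                     dens$density_with + dens$density_without)
  }
})

test_that("density converts to cells per image through the image area", {
  expect_equal(cells_per_image(6.25), 1.0)
  expect_equal(cells_per_image(0), 0)
  expect_equal(cells_per_image(20.94), 3.3504)
  expect_error(cells_per_image(1, area_mm2 = -1), "area")
})

test_that("perfect rasterized masks reproduce generated counts exactly", {
  p <- tiny_params(c(96L, 96L))
  for (seed in c(301, 302, 303)) {
    smp <- generate_sample(p, seed = seed, n_with = 3, n_without = 5)
    m <- rasterize_dc_mask(smp$annotation)
    expect_equal(count_components(m, "with_dendrites"),
                 unname(smp$true_counts["with_dendrites"]))
    expect_equal(count_components(m, "without_dendrites"),
                 unname(smp$true_counts["without_dendrites"]))
  }
})
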