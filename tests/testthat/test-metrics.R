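test_that("pixel metrics satisfy identities and the hand-counted grid", {
  set.seed(23)
  m <- matrix(rbinom(100, 1, 0.3), 10, 10)
  expect_equal(dice(m, m), 1)
  expect_equal(recall(m, m), 1)
  expect_equal(precision(m, m), 1)
  expect_equal(specificity(m, m), 1)
  expect_equal(dice(m, 1 - m), 0)

  # tp=3, fp=1, fn=1, tn=95 on a 10x10 grid
  truth <- matrix(0, 10, 10); truth[1, 1:4] <- 1
  pred <- matrix(0, 10, 10); pred[1, 1:3] <- 1; pred[2, 1] <- 1
  expect_equal(dice(pred, truth), 0.75)
  expect_equal(recall(pred, truth), 0.75)
  expect_equal(precision(pred, truth), 0.75)
  expect_equal(specificity(pred, truth), 95 / 96)
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("pixel metric dualities hold on random masks", {
  set.seed(29)
  for (i in 1:20) {
    a <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(recall(a, b), precision(b, a))
    expect_true(all(c(dice(a, b), recall(a, b), precision(a, b),
                      specificity(a, b)) >= 0))
    expect_true(all(c(dice(a, b), recall(a, b), precision(a, b),
                      specificity(a, b)) <= 1))
  }
  empty <- matrix(0, 5, 5)
  expect_equal(dice(empty, empty), 1)
  expect_equal(recall(empty, empty), 1)
  expect_equal(precision(empty, empty), 1)
})

test_that("MAPE and MAE follow their definitions", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(c(11, 18), c(10, 20)), 10)
  expect_equal(mae(c(11, 18), c(10, 20)), 1.5)
  expect_equal(mape(1, 2), 50)
  expect_equal(mape(2, 1), 100)
  expect_equal(mae(1, 2), 1)
  expect_error(mape(1:3, 1:4), "lengths differ")
  expect_warning(z <- mape(c(1, 5), c(0, 4)), "zero truth")
  expect_equal(z, 25)
})

test_that("Bland-Altman limits are the 1.96-SD closed form", {
  # differences with mean -0.01 and SD 0.13 reproduce the printed lower
  # limit of agreement of about -0.26
  a <- c(-0.14, -0.01, 0.12)
  ba <- bland_altman(a, rep(0, 3))
  expect_equal(ba$bias, -0.01)
  expect_equal(ba$sd_diff, 0.13)
  expect_equal(ba$loa_low, -0.01 - 1.96 * 0.13)
  expect_equal(round(ba$loa_low, 2), -0.26)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)

  same <- bland_altman(1:5, 1:5)
  expect_equal(unlist(same), c(bias = 0, sd_diff = 0, loa_low = 0,
                               loa_high = 0))
  expect_error(bland_altman(1, 1), "at least 2")

  set.seed(37)
  d <- rnorm(10000)
  ba2 <- bland_altman(d, rep(0, 10000))
  inside <- mean(d >= ba2$loa_low & d <= ba2$loa_high)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("ICC behaves at its analytic limits", {
  set.seed(41)
  a <- rnorm(50, 10, 2)
  expect_equal(icc_agreement(a, a)$icc, 1)
  noisy <- icc_agreement(a, a + rnorm(50, 0, 50))$icc
  expect_lt(abs(noisy), 0.25)
  # constant offset: absolute agreement penalizes bias, vanishing with it
  iccs <- vapply(c(2, 0.5, 0.05), function(cc)
    icc_agreement(a, a + cc)$icc, numeric(1))
  expect_true(all(diff(iccs) > 0))
  expect_lt(iccs[1], 1)
  expect_gt(iccs[3], 0.999)
  ci <- icc_agreement(a, a + rnorm(50))$ci
  expect_true(ci[1] <= ci[2])
})

test_that("single-rater ICC matches mean squares from base R aov", {
  set.seed(43)
  a <- rnorm(30, 5, 1.5)
  b <- a + rnorm(30, 0.3, 0.8)
  n <- 30; k <- 2
  long <- data.frame(y = c(a, b),
                     subj = factor(rep(1:n, 2)),
                     rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(y ~ subj + rater, data = long))[[1]]$`Mean Sq`
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  want <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  got <- icc_agreement(a, b)$icc
  expect_equal(got, want, tolerance = 1e-10)
  # average-measures version through the Spearman-Brown step-up
  expect_equal(icc_agreement(a, b, type = "average")$icc,
               2 * want / (1 + want), tolerance = 1e-10)
})

test_that("Pearson r and its Fisher interval match the reference implementation", {
  a <- c(1, 2, 4, 7, 8)
  expect_equal(pearson_ci(a, 2 * a + 1)$r, 1)
  expect_equal(pearson_ci(a, -a)$r, -1)
  expect_error(pearson_ci(a, rep(3, 5)), "zero variance")

  set.seed(47)
  x <- rnorm(128)
  y <- 0.9 * x + rnorm(128, 0, 0.15)
  pc <- pearson_ci(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate))
  expect_equal(pc$ci, as.numeric(ct$conf.int), tolerance = 1e-9)
  expect_equal(pc$ci,
               tanh(atanh(pc$r) + c(-1, 1) * qnorm(0.975) / sqrt(128 - 3)))
})

test_that("ICC approaches Pearson r when the columns share mean and variance", {
  set.seed(53)
  a <- rnorm(200)
  b0 <- 0.8 * a + rnorm(200, 0, 0.6)
  b <- (b0 - mean(b0)) / sd(b0) * sd(a) + mean(a)
  expect_equal(icc_agreement(a, b)$icc, pearson_ci(a, b)$r, tolerance = 0.02)
})

test_that("agreement reports bundle consistent statistics", {
  set.seed(59)
  manual <- runif(40, 10, 25)
  auto <- manual + rnorm(40, -0.1, 0.5)
  rep <- agreement_report(auto, manual)
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
  expect_equal(rep$loa_high - rep$bias, rep$bias - rep$loa_low,
               tolerance = 1e-12)
  expect_true(rep$icc >= -1 && rep$icc <= 1)
  expect_true(rep$pearson_r >= -1 && rep$pearson_r <= 1)
  expect_true(rep$mape >= 0 && rep$mae >= 0)
})
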