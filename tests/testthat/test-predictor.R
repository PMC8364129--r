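# small synthetic training sets for the regression stage

make_linear_dataset <- function(n_samples, seed = 1L, sigma = 0) {
  cfg <- generator_config(elements_cno, gamma_cno, n = c(8L, 14L), d_max = 3L)
  coef <- numeric(spec_cno$K)
  coef[match(c("n", "ms_bar", "dg_1_ex", "n_H"), spec_cno$names)] <- c(2, 0.5, -1, 0.25)
  ds <- synthetic_dataset(n_samples, cfg, spec_cno, coef, sigma = sigma, seed = seed)
  property_dataset(ds$data, spec_cno)
}

test_that("R^2 follows the printed formula", {
  y <- c(1, 2, 3)
  expect_identical(r_squared(y, y), 1)
  expect_identical(r_squared(y, rep(mean(y), 3)), 0)
  expect_identical(r_squared(y, c(1, 2, 4)), 1 - 1 / 2)
  expect_error(r_squared(c(2, 2), c(1, 2)), "zero variance")
})

test_that("training on noiseless linear data recovers the function (R^2 >= 0.99)", {
  ds <- make_linear_dataset(120, seed = 42)
  mod <- train(ds, hidden = 10L, seed = 7L)
  yhat <- predict(mod, as.matrix(ds$data[, spec_cno$names]))
  expect_gte(r_squared(ds$data$value, yhat), 0.99)
})

test_that("training is deterministic given the seed", {
  ds <- make_linear_dataset(40, seed = 9)
  m1 <- train(ds, hidden = 6L, seed = 3L, maxit = 60L)
  m2 <- train(ds, hidden = 6L, seed = 3L, maxit = 60L)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$b2, m2$b2)
})

test_that("the forward pass is piecewise linear along 1-D slices", {
  ds <- make_linear_dataset(40, seed = 5)
  mod <- train(ds, hidden = 6L, seed = 2L, maxit = 80L)
  x0 <- as.numeric(ds$data[1, spec_cno$names])
  dir <- rnorm(length(x0))
  ts <- seq(-2, 2, length.out = 401)
  vals <- vapply(ts, function(t) predict(mod, x0 + t * dir), numeric(1))
  slopes <- diff(vals) / diff(ts)
  curv <- abs(diff(slopes))
  # at most n_B = 6 break-points can be crossed; elsewhere slopes are constant
  expect_lte(sum(curv > 1e-6), mod$n_B)
})

test_that("cross-validation partitions evenly, reproduces per seed, and scores linear data", {
  ds <- make_linear_dataset(150, seed = 21)
  cv1 <- cross_validate(ds, hidden = 8L, n_folds = 5L, seed = 13L, maxit = 400L)
  cv2 <- cross_validate(ds, hidden = 8L, n_folds = 5L, seed = 13L, maxit = 400L)
  expect_identical(cv1$folds$r2, cv2$folds$r2)
  expect_lte(diff(range(cv1$folds$n_test)), 1)
  expect_identical(sum(cv1$folds$n_test), 150L)
  expect_gte(cv1$mean_r2, 0.99)
  expect_identical(glance(cv1)$best_r2, max(cv1$folds$r2))
  expect_identical(nrow(tidy(cv1)), 5L)
})

test_that("AD bounds are training min/max under the normalisation rules", {
  ds <- make_linear_dataset(30, seed = 31)
  ad <- ad_bounds(ds)
  expect_true(all(ad$lo <= ad$hi))
  expect_true(all(ad$rule[startsWith(ad$descriptor, "ce_")] == "divide_by_n"))
  expect_true(all(ad$rule[!startsWith(ad$descriptor, "ce_")] == "raw"))
  # every training record lies in its own AD
  for (i in seq_len(nrow(ds$data))) {
    x <- stats::setNames(as.numeric(ds$data[i, spec_cno$names]), spec_cno$names)
    expect_true(in_ad(x, ad))
  }
  # one-record dataset has lo = hi
  d1 <- property_dataset(ds$data[1, ], spec_cno)
  ad1 <- ad_bounds(d1)
  expect_equal(ad1$lo, ad1$hi)
  # adding records only widens the box
  d_half <- property_dataset(ds$data[1:15, ], spec_cno)
  ad_half <- ad_bounds(d_half)
  expect_true(all(ad$lo <= ad_half$lo + 1e-12))
  expect_true(all(ad$hi >= ad_half$hi - 1e-12))
})

test_that("weights survive a JSON round trip exactly", {
  ds <- make_linear_dataset(30, seed = 55)
  mod <- train(ds, hidden = 5L, seed = 4L, maxit = 60L)
  f <- tempfile(fileext = ".json")
  write_predictor_json(mod, f)
  mod2 <- read_predictor_json(f, spec = spec_cno)
  X <- as.matrix(ds$data[, spec_cno$names])
  expect_equal(predict(mod, X), predict(mod2, X), tolerance = 1e-12)
})

test_that("degenerate constant-target data warns but trains", {
  ds <- make_linear_dataset(10, seed = 77)
  ds$data$value <- 1
  d <- property_dataset(ds$data, spec_cno)
  expect_warning(train(d, hidden = 3L, seed = 1L, maxit = 20L), "constant")
})
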