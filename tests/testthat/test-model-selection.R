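test_that("LOOCV predictions match hand-fitted leave-one-out regressions", {
  # one feature, n = 4: with a single feature, a 1-component PLS fit is
  # simple linear regression, so lm() on each fold is an independent oracle
  X <- matrix(c(1, 2, 3, 5), 4, 1)
  y <- c(1.2, 1.9, 3.4, 4.8)
  got <- loocv_predictions(X, y, n_components = 1)
  expected <- vapply(1:4, function(i) {
    fold <- lm(yy ~ xx, data = data.frame(xx = X[-i, 1], yy = y[-i]))
    unname(predict(fold, data.frame(xx = X[i, 1])))
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-10)
  expect_length(got, length(y))
})

test_that("LOOCV is deterministic", {
  set.seed(31)
  X <- matrix(rnorm(60), 10, 6)
  y <- rnorm(10)
  expect_identical(loocv_predictions(X, y, 3), loocv_predictions(X, y, 3))
})

test_that("LOOCV enforces its sample and component bounds", {
  X <- matrix(rnorm(4), 2, 2)
  expect_error(loocv_predictions(X, rnorm(2), 1), "at least 3")
  X <- matrix(rnorm(12), 4, 3)
  expect_error(loocv_predictions(X, rnorm(4), 3), "1\\.\\.2")
})

test_that("r_squared is the squared correlation with its documented edge cases", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, 2 * y + 1), 1) # affine invariance
  expect_equal(r_squared(y, c(1, 3, 2)), 0.25) # hand Pearson: r = 0.5
  expect_error(r_squared(y, c(1, 1, 1)), "zero variance")
  expect_error(r_squared(y, c(1, 2)), "length mismatch")
})

test_that("cv_rmse is the root mean squared residual", {
  expect_equal(cv_rmse(c(0, 2), c(1, 1)), 1)
  expect_equal(cv_rmse(5, 2), 3)
  expect_equal(cv_rmse(c(1, 2), c(1, 2)), 0)
  expect_error(cv_rmse(c(1, 2), 1), "length mismatch")
})

test_that("metrics agree with independent textbook formulas", {
  set.seed(32)
  for (rep in 1:20) {
    y <- rnorm(15)
    yh <- rnorm(15)
    # straight-line Pearson implementation from sums
    sy <- y - mean(y)
    sh <- yh - mean(yh)
    r2_oracle <- (sum(sy * sh) / sqrt(sum(sy^2) * sum(sh^2)))^2
    expect_equal(r_squared(y, yh), r2_oracle, tolerance = 1e-12)
    expect_equal(cv_rmse(y, yh), sqrt(sum((y - yh)^2) / 15), tolerance = 1e-12)
  }
})

test_that("a rank-one predictor selects a single component, ties to fewer", {
  set.seed(33)
  t_scores <- rnorm(8)
  X <- outer(t_scores, c(1, -2)) # rank-1 design, 2 columns
  y <- 3 + 2 * t_scores          # exact one-latent-direction response
  sel <- select_n_components(X, y, max_components = 2)
  expect_identical(sel$n_components, 1L)
  grid <- attr(sel$evaluation, "grid")
  expect_length(grid, 2L) # both counts evaluated ...
  expect_equal(grid[1], grid[2], tolerance = 1e-10) # ... tie resolved to fewer
  expect_lt(sel$evaluation$cv_rmse, 1e-8)
  expect_equal(sel$evaluation$r2, 1, tolerance = 1e-8)
})

test_that("the selection grid respects min(max_components, n - 2, p)", {
  set.seed(34)
  X <- matrix(rnorm(13 * 20), 13, 20)
  y <- rnorm(13)
  sel <- select_n_components(X, y, max_components = 10)
  expect_length(attr(sel$evaluation, "grid"), 10L) # 13 samples: 1..10
  sel2 <- select_n_components(X[1:5, ], y[1:5], max_components = 10)
  expect_length(attr(sel2$evaluation, "grid"), 3L) # n - 2 binds
})

test_that("scanning fixture indices evaluates all of them in cvRMSE order", {
  set.seed(35)
  db <- suppressMessages(parse_aaindex_db(
    system.file("extdata", "aaindex_synthetic.aaindex1", package = "ftsar")
  ))
  ls <- generate_landscape(length = 60, n_mutations = 4, n_records = 10,
                           index = db[[1]], sigma = 0.5, seed = 35)
  scan <- scan_indices(ls$records, ls$wt, db)
  expect_s3_class(scan, "index_scan")
  expect_identical(nrow(scan), 3L)
  expect_false(is.unsorted(scan$cv_rmse))
  expect_true(all(scan$r2 >= 0 & scan$r2 <= 1, na.rm = TRUE))
})

test_that("the scan recovers the generating index from low-noise data", {
  ls <- generate_landscape(sigma = 0.12, seed = 1) # sigma = 0.01 * sd(y)
  decoys <- random_aaindex(5, seed = 1001)
  scan <- scan_indices(ls$records, ls$wt, c(list(ls$index), decoys))
  expect_identical(scan$accession[1], ls$index$accession)
})

test_that("an index that cannot encode is skipped with a warning", {
  set.seed(36)
  good <- toy_index("GOOD000001")
  flat <- aa_index("FLAT000001",
                   setNames(rep(1, 20), sort(AACOL)),
                   "zero-variance scale") # z-scoring impossible
  ls <- generate_landscape(length = 40, n_mutations = 3, n_records = 8,
                           index = good, sigma = 0.3, seed = 36)
  expect_warning(
    scan <- scan_indices(ls$records, ls$wt, list(good, flat)),
    "skipping index 'FLAT000001'"
  )
  expect_identical(nrow(scan), 1L)
  expect_identical(attr(scan, "skipped"), "FLAT000001")
  # at least 3 labeled records are required
  few <- ls$records[1:2, ]
  attr(few, "mutation_sets") <- attr(ls$records, "mutation_sets")[1:2]
  class(few) <- c("activity_table", "data.frame")
  expect_error(scan_indices(few, ls$wt, list(good)), "at least 3 labeled")
})
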