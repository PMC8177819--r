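# Splits and metrics against hand computations and brute-force references.

test_that("split_dataset cuts 3:1, deterministically, into a partition", {
  s <- split_dataset(1:100, seed = 3)
  expect_length(s$train, 75)
  expect_length(s$test, 25)
  expect_identical(split_dataset(1:100, seed = 3)$train, s$train)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:100)
  expect_error(split_dataset(1:3), "at least 4")
})

test_that("classification accuracy counts exact matches, NaN as wrong", {
  expect_identical(classification_accuracy(c(120, 80), c(120, 80)), 100)
  expect_identical(classification_accuracy(c(123, 80), c(120, 80)), 50)
  expect_identical(classification_accuracy(c(NaN, 80), c(120, 80)), 50)
  # missing truth drops out of the denominator
  expect_identical(classification_accuracy(c(120, 80, 5), c(120, 80, NaN)), 100)
  expect_error(classification_accuracy(1, c(1, 2)), "length")
})

test_that("MAE averages valid pairs and reports exclusions", {
  expect_identical(as.numeric(mean_absolute_error(c(123, 80), c(120, 80))), 1.5)
  expect_identical(as.numeric(mean_absolute_error(c(120, 80), c(120, 80))), 0)
  m <- mean_absolute_error(c(NaN, 85), c(120, 80))
  expect_identical(as.numeric(m), 5)
  expect_identical(attr(m, "n"), 1L)
  expect_identical(attr(m, "n_excluded"), 1L)
  m0 <- mean_absolute_error(c(NaN, NaN), c(120, 80))
  expect_true(is.na(m0))
  expect_identical(attr(m0, "n"), 0L)
})

test_that("metrics agree with a brute-force reference on random data", {
  set.seed(17)
  truth <- sample(34:203, 1000, replace = TRUE)
  pred <- ifelse(runif(1000) < 0.1, NaN,
                 truth + sample(c(0, 0, 0, -5, 7, 100), 1000, replace = TRUE))
  acc_bf <- 0
  err <- c(); n_bf <- 0
  for (i in 1:1000) {
    if (!is.nan(pred[i]) && pred[i] == truth[i]) acc_bf <- acc_bf + 1
    if (!is.nan(pred[i])) err <- c(err, abs(pred[i] - truth[i]))
  }
  expect_equal(classification_accuracy(pred, truth), 100 * acc_bf / 1000)
  expect_equal(as.numeric(mean_absolute_error(pred, truth)), mean(err))
})

test_that("evaluation report strata are consistent with the pooled roll-up", {
  set.seed(18)
  n <- 200
  manifest <- data.frame(
    filename = sprintf("f%03d.png", 1:n),
    sbp = sample(90:180, n, replace = TRUE),
    dbp = sample(40:110, n, replace = TRUE),
    hr = sample(40:180, n, replace = TRUE),
    quality = sample(QUALITY_LABELS, n, replace = TRUE))
  preds <- manifest[, c("filename", "sbp", "dbp", "hr")]
  flip <- runif(n) < 0.3
  preds$sbp[flip] <- preds$sbp[flip] + 12
  rep <- evaluation_report(manifest, preds)
  # all-correct measures score 100 / 0 everywhere
  expect_true(all(rep$accuracy[rep$measure == "DBP"] == 100))
  expect_true(all(rep$mae[rep$measure == "DBP"] == 0))
  # pooled accuracy equals the n-weighted mean of the per-label strata
  sbp <- rep[rep$measure == "SBP" & rep$stratum %in% QUALITY_LABELS, ]
  all_row <- rep[rep$measure == "SBP" & rep$stratum == "all", ]
  expect_equal(sum(sbp$accuracy * sbp$n) / sum(sbp$n), all_row$accuracy)
  # good/poor roll-up partitions the data
  expect_identical(sum(rep$n[rep$measure == "SBP" &
                               rep$stratum %in% c("good", "poor")]),
                   all_row$n)
  expect_error(evaluation_report(manifest,
                                 data.frame(filename = "zzz.png", sbp = 1,
                                            dbp = 1, hr = 1)),
               "without a manifest row")
})
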