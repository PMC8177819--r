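# Sequence coding, network mechanics and the fitted-model interface.

test_that("encode_value right-aligns with leading blanks", {
  expect_identical(encode_value(120), c(1L, 2L, 0L))
  expect_identical(encode_value(82), c(10L, 8L, 2L))
  expect_identical(encode_value(7), c(10L, 10L, 7L))
  expect_identical(encode_value(0), c(10L, 10L, 0L))
  expect_error(encode_value(1000), "999")
  expect_error(encode_value(-1), "999")
})

test_that("decode_sequence inverts encode_value and flags malformed input", {
  for (v in 0:999) expect_identical(decode_sequence(encode_value(v)), v)
  expect_true(is.nan(decode_sequence(c(10L, 10L, 10L))))
  expect_true(is.nan(decode_sequence(c(1L, 10L, 2L))))
  expect_true(is.nan(decode_sequence(c(1L, 2L, 10L))))
  expect_error(decode_sequence(c(1L, 2L)), "slot")
})

test_that("initialization is seeded and head outputs are distributions", {
  set.seed(5); p1 <- bpocr:::cnn_init_cpp()
  set.seed(5); p2 <- bpocr:::cnn_init_cpp()
  expect_identical(p1, p2)
  X <- bpocr:::frames_to_matrix(list(render_value_frame(123),
                                     render_value_frame(7)))
  pr <- bpocr:::cnn_predict_cpp(p1, X)
  for (h in 1:3) {
    block <- pr[, ((h - 1) * 11 + 1):(h * 11)]
    expect_true(all(block >= 0))
    expect_equal(rowSums(block), c(1, 1), tolerance = 1e-6)
  }
  # inference is deterministic
  expect_identical(pr, bpocr:::cnn_predict_cpp(p1, X))
  # spatial contract: three 2x2 pools take 180x80 to 22x10x128 features
  expect_identical(dim(p1$Wh), c(33L, 28160L))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(9)
  X <- bpocr:::frames_to_matrix(list(render_value_frame(120),
                                     render_value_frame(85)))
  Y <- bpocr:::labels_to_matrix(c(120, 85))
  set.seed(2)
  p <- bpocr:::cnn_init_cpp()
  g <- bpocr:::cnn_loss_grad_cpp(p, X, Y, 0:1)
  h <- 5e-3
  for (nm in c("W1", "W2", "W3", "Wh", "gamma2", "beta3", "bh")) {
    ga <- g[[paste0("d", nm)]]
    for (i in order(-abs(ga))[1:3]) {
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + h
      lp <- bpocr:::cnn_loss_grad_cpp(p2, X, Y, 0:1)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h
      lm <- bpocr:::cnn_loss_grad_cpp(p2, X, Y, 0:1)$loss
      fd <- (lp - lm) / (2 * h)
      expect_lt(abs(ga[i] - fd) / max(abs(fd), 1e-3), 0.08)
    }
  }
})

test_that("a single training example is memorized", {
  f <- render_value_frame(137)
  fit <- bp_cnn(list(f, f), c(137, 137), epochs = 40, lr = 3e-3,
                validation_split = 0.5, seed = 4)
  p <- predict(fit, f)
  expect_identical(p$value, 137)
  # checkpoint loss no worse than the first epoch's
  expect_lte(min(fit$history$train_loss), fit$history$train_loss[1])
})

test_that("confidence gating is a product threshold with correct bounds", {
  s <- structure(c(1L, 2L, 0L), confidence = c(0.9, 0.9, 0.9))
  expect_true(accept_by_confidence(s, 0))
  expect_false(accept_by_confidence(s, 1))
  expect_false(accept_by_confidence(s, 0.75))  # 0.729 < 0.75
  expect_true(accept_by_confidence(s, 0.72))
  expect_error(accept_by_confidence(s, 1.5), "tau")
})

test_that("save/load round trip preserves predictions", {
  set.seed(6)
  vals <- sample(0:999, 12, replace = TRUE)
  fit <- bp_cnn(lapply(vals, render_value_frame), vals, epochs = 1,
                batch_size = 8, seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  fit2 <- load_model(path)
  X <- lapply(sample(0:999, 6), render_value_frame)
  expect_identical(predict(fit, X, type = "prob"),
                   predict(fit2, X, type = "prob"))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), bad)
  expect_error(load_model(bad), "model file")
})

test_that("input contracts are enforced", {
  expect_error(bp_cnn(list(matrix(0, 10, 10)), 5), "80 x 180")
  expect_error(bp_cnn(list(render_value_frame(1)), numeric(0)), "differ")
  f <- render_value_frame(42)
  fit <- bp_cnn(list(f, f, render_value_frame(7), render_value_frame(8)),
                c(42, 42, 7, 8), epochs = 1, batch_size = 2,
                validation_split = 0.25, seed = 1)
  expect_error(predict(fit, list(matrix(0, 20, 20))), "80 x 180")
  pd <- predict_digits(fit, f)
  expect_length(pd, 3)
  expect_true(all(attr(pd, "confidence") >= 0 & attr(pd, "confidence") <= 1))
})

test_that("transcribe returns NaN readings on unreadable input", {
  set.seed(8)
  vals <- sample(0:999, 8, replace = TRUE)
  fit <- bp_cnn(lapply(vals, render_value_frame), vals, epochs = 1,
                batch_size = 4, seed = 2)
  blank <- matrix(0, 480, 640)
  r <- transcribe(blank, fit)
  expect_true(is.nan(r$sbp) && is.nan(r$dbp) && is.nan(r$hr))
  expect_null(r$frames)
})
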