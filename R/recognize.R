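# Multi-digit recognition. A reading is represented as a right-aligned
# sequence of three slots from {0..9, BLANK}; a convolutional network with
# three softmax heads (one per slot, 11 classes each) maps a 180x80 binary
# frame to the slot distributions, and the sequence probability model
# P(S|X) factorizes over the heads. Training maximizes log P(S|X), i.e.
# minimizes the summed per-head cross-entropy.

#' Encode a numeric value as a three-slot digit sequence
#'
#' Values are right-aligned with leading blanks, mirroring how the monitor
#' displays them: `120 -> (1, 2, 0)`, `82 -> (BLANK, 8, 2)`,
#' `7 -> (BLANK, BLANK, 7)`. The blank slot is class index 10.
#'
#' @param v integer in \[0, 999\].
#' @return integer vector of 3 slot classes (0-9 digits, 10 = blank).
#' @export
encode_value <- function(v) {
  if (length(v) != 1 || is.na(v) || v %% 1 != 0 || v < 0 || v > 999) {
    stop("v must be a single integer in [0, 999]", call. = FALSE)
  }
  digits <- as.integer(strsplit(sprintf("%d", as.integer(v)), "")[[1]])
  c(rep(BLANK, 3 - length(digits)), digits)
}

#' Decode a digit sequence to a numeric value
#'
#' Inverse of [encode_value()] for well-formed sequences (blanks only
#' leading). An all-blank sequence, or any blank appearing after a digit,
#' decodes to `NaN` — the pipeline's "could not read" value.
#'
#' @param s integer vector of 3 slot classes (0-9, 10 = blank).
#' @return the decoded integer, or `NaN`.
#' @export
decode_sequence <- function(s) {
  s <- as.integer(s)
  if (length(s) != 3 || anyNA(s) || any(s < 0 | s > BLANK)) {
    stop("s must be 3 slot classes in {0..9, 10}", call. = FALSE)
  }
  digit <- s != BLANK
  if (!any(digit)) return(NaN)
  first <- which(digit)[1]
  if (any(!digit[first:3])) return(NaN)  # blank after a digit: malformed
  as.integer(sum(s[first:3] * 10^((3 - first):0)))
}

# frames (180x80, {0,255} or {0,1}) -> integer design matrix n x 14400,
# row-major pixel order (y * W + x)
frames_to_matrix <- function(x) {
  if (is.matrix(x) && !is.list(x) && ncol(x) == 14400) {
    return(matrix(as.integer(x > 0.5), nrow(x), ncol(x)))
  }
  if (is.matrix(x) && nrow(x) == 80 && ncol(x) == 180) x <- list(x)
  if (!is.list(x)) stop("x must be a frame, list of frames, or n x 14400 matrix",
                        call. = FALSE)
  bad <- vapply(x, function(f) !is.matrix(f) || nrow(f) != 80 || ncol(f) != 180,
                logical(1))
  if (any(bad)) stop("every frame must be an 80 x 180 matrix", call. = FALSE)
  t(vapply(x, function(f) as.integer(t(f) > 127.5 * max(f) / 255),
           integer(14400)))
}

labels_to_matrix <- function(y) {
  if (is.matrix(y)) {
    stopifnot(ncol(y) == 3)
    return(matrix(as.integer(y), nrow(y), 3))
  }
  t(vapply(as.numeric(y), encode_value, integer(3)))
}

#' Fit the multi-digit convolutional recognizer
#'
#' Trains the three-block convolutional network (5x5 kernels with 32, 64
#' and 128 filters, each block followed by batch normalization, ReLU and
#' 2x2 max-pooling) with three 11-way softmax heads on labelled 180x80
#' frames, maximizing the factorized sequence log-likelihood with Adam.
#' The data are split into training and validation parts in the ratio 3:1
#' (seeded shuffle) and the returned parameters are the checkpoint with
#' minimum validation loss.
#'
#' @param x frames: a list of 80 x 180 binary matrices or an
#'   `n x 14400` design matrix (row-major pixels).
#' @param y labels: integer values in \[0, 999\] (encoded internally via
#'   [encode_value()]) or an `n x 3` slot-class matrix.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param validation_split fraction held out for validation (in (0, 1)),
#'   ignored when `val_idx` is given.
#' @param val_idx optional explicit validation indices (1-based), e.g. to
#'   keep frames from one photograph on one side of the split.
#' @param tau default confidence threshold stored with the model and used
#'   by [predict.bp_cnn()]; 0 reports every prediction.
#' @param seed optional RNG seed (applied with `set.seed`) covering
#'   initialization, the split and epoch shuffling.
#' @param verbose print per-epoch losses.
#' @return object of class `"bp_cnn"` with elements `params` (learned
#'   tensors), `history` (per-epoch losses and validation sequence
#'   accuracy), `best_epoch`, `tau`, and split bookkeeping.
#' @examples
#' \donttest{
#' set.seed(1)
#' frames <- replicate(8, {
#'   v <- sample(0:999, 1)
#'   list(frame = render_value_frame(v), value = v)
#' }, simplify = FALSE)
#' fit <- bp_cnn(lapply(frames, `[[`, "frame"),
#'               vapply(frames, `[[`, numeric(1), "value"),
#'               epochs = 2, seed = 1)
#' print(fit)
#' }
#' @export
bp_cnn <- function(x, y, epochs = 6, batch_size = 32, lr = 1e-3,
                   validation_split = 0.25, val_idx = NULL, tau = 0,
                   seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  X <- frames_to_matrix(x)
  Y <- labels_to_matrix(y)
  n <- nrow(X)
  if (n == 0 || nrow(Y) != n) stop("x and y sizes differ or are empty",
                                   call. = FALSE)
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]", call. = FALSE)
  if (is.null(val_idx)) {
    if (validation_split <= 0 || validation_split >= 1) {
      stop("validation_split must be in (0, 1)", call. = FALSE)
    }
    perm <- sample.int(n)
    n_val <- floor(n * validation_split)
    val_idx <- perm[seq_len(n_val)]
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0) stop("degenerate split: no training data",
                                   call. = FALSE)
  if (length(train_idx) == 1) train_idx <- rep(train_idx, 2)
  params <- cnn_init_cpp()
  fit <- cnn_train_cpp(params, X, Y,
                       as.integer(train_idx - 1), as.integer(val_idx - 1),
                       as.integer(epochs),
                       as.integer(min(batch_size, length(train_idx))),
                       lr, verbose)
  structure(list(params = fit$params, history = fit$history,
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 n_train = length(unique(train_idx)), n_val = length(val_idx),
                 tau = tau, epochs = epochs, batch_size = batch_size,
                 lr = lr, seed = seed),
            class = "bp_cnn")
}

#' @export
print.bp_cnn <- function(x, ...) {
  cat("Multi-digit seven-segment recognizer (bp_cnn)\n")
  cat(sprintf("  conv blocks: 3 (5x5 kernels; 32/64/128 filters; BN+ReLU+2x2 maxpool)\n"))
  cat(sprintf("  heads: 3 softmax x 11 classes (digits 0-9 + blank)\n"))
  cat(sprintf("  trained on %d frames (validated on %d), best epoch %d/%d\n",
              x$n_train, x$n_val, x$best_epoch, x$epochs))
  cat(sprintf("  best validation loss %.4f, confidence threshold tau = %g\n",
              x$best_val_loss, x$tau))
  invisible(x)
}

#' @export
summary.bp_cnn <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.bp_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 19), lty = 1, xlab = "epoch", ylab = "loss",
                    main = "bp_cnn training", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), pch = c(1, 19),
                   lty = 1, col = 1:2, bty = "n")
  invisible(x)
}

#' Predict digit sequences or values from frames
#'
#' @param object a fitted [bp_cnn()].
#' @param newdata frames in any form accepted by [bp_cnn()].
#' @param type `"value"` decodes each sequence to a number (`NaN` when the
#'   sequence is malformed or rejected by the confidence gate),
#'   `"sequence"` returns slot classes and per-slot confidences, `"prob"`
#'   the raw `n x 33` head probabilities.
#' @param tau confidence threshold overriding the model default: a
#'   prediction is accepted iff the product of its slot confidences is at
#'   least `tau`.
#' @param ... unused.
#' @return see `type`; for `"value"` a data.frame with `value`,
#'   `confidence` and `accepted`.
#' @export
predict.bp_cnn <- function(object, newdata, type = c("value", "sequence", "prob"),
                           tau = object$tau, ...) {
  type <- match.arg(type)
  X <- frames_to_matrix(newdata)
  probs <- cnn_predict_cpp(object$params, X)
  if (type == "prob") return(probs)
  n <- nrow(probs)
  slots <- matrix(0L, n, 3)
  conf <- matrix(0, n, 3)
  for (h in 1:3) {
    block <- probs[, ((h - 1) * 11 + 1):(h * 11), drop = FALSE]
    slots[, h] <- max.col(block, ties.method = "first") - 1L
    conf[, h] <- block[cbind(seq_len(n), slots[, h] + 1L)]
  }
  if (type == "sequence") return(list(slots = slots, confidence = conf))
  seq_conf <- apply(conf, 1, prod)
  accepted <- seq_conf >= tau
  value <- vapply(seq_len(n), function(i) {
    if (!accepted[i]) return(NaN)
    decode_sequence(slots[i, ])
  }, numeric(1))
  data.frame(value = value, confidence = seq_conf, accepted = accepted)
}

#' Recognize the digit sequence of a single frame
#'
#' @param model a fitted [bp_cnn()].
#' @param frame an 80 x 180 binary frame.
#' @return integer vector of 3 slot classes with attribute `"confidence"`
#'   (per-slot probabilities of the chosen classes).
#' @export
predict_digits <- function(model, frame) {
  res <- predict(model, frame, type = "sequence")
  structure(res$slots[1, ], confidence = res$confidence[1, ])
}

#' Confidence gate for a digit sequence
#'
#' The sequence confidence is the product of the three slot confidences
#' (consistent with the factorized sequence model); a sequence is accepted
#' iff it reaches the threshold. Rejected sequences decode to `NaN`
#' downstream, trading coverage for accuracy.
#'
#' @param s a sequence from [predict_digits()] (with a `"confidence"`
#'   attribute) or a numeric vector of slot confidences.
#' @param tau threshold in \[0, 1\].
#' @return `TRUE` if accepted.
#' @export
accept_by_confidence <- function(s, tau) {
  if (length(tau) != 1 || is.na(tau) || tau < 0 || tau > 1) {
    stop("tau must be a single number in [0, 1]", call. = FALSE)
  }
  conf <- attr(s, "confidence")
  if (is.null(conf)) conf <- as.numeric(s)
  prod(conf) >= tau
}

#' Render a clean normalized value frame
#'
#' Draws a value as right-aligned seven-segment glyphs directly on the
#' recognizer's 80 x 180 canvas — the idealized output of the
#' normalization stage, useful for quick model checks and examples.
#'
#' @param v integer in \[0, 999\].
#' @param digit_h glyph height in pixels.
#' @return binary 80 x 180 frame.
#' @export
render_value_frame <- function(v, digit_h = 64) {
  w <- round(0.66 * digit_h)
  sp <- max(3, round(0.1 * w))
  t <- max(2, round(0.12 * digit_h))
  glyphs <- render_value_glyphs(v, digit_h, w, sp, t, max(1, round(t / 2)))
  out <- matrix(0, 80, 180)
  y0 <- floor((80 - digit_h) / 2)
  x0 <- 180 - 8 - ncol(glyphs)
  out[(y0 + 1):(y0 + digit_h), (x0 + 1):(x0 + ncol(glyphs))] <- glyphs
  out
}

#' Transcribe a BP-monitor photograph
#'
#' End-to-end composition: enhancement, frame localization, normalization,
#' per-frame recognition, confidence gating and decoding. Localization
#' failure or gate rejection yields `NaN` for the affected value(s); an
#' unreadable image never raises an error.
#'
#' @param img image matrix / 3-channel array, or path to a PNG file.
#' @param model a fitted [bp_cnn()].
#' @param enhance_p,localize_p,normalize_p stage parameters.
#' @param tau confidence threshold (defaults to the model's).
#' @return object of class `"bp_reading"`: `sbp`, `dbp`, `hr` (numbers or
#'   `NaN`), per-value `confidence`, and the localized `frames` boxes
#'   (`NULL` on localization failure).
#' @export
transcribe <- function(img, model, enhance_p = enhance_params(),
                       localize_p = localize_params(),
                       normalize_p = normalize_params(), tau = model$tau) {
  if (is.character(img)) img <- read_image(img)
  bin <- enhance(img, enhance_p)
  fp <- localize_frames(bin, localize_p)
  out <- list(sbp = NaN, dbp = NaN, hr = NaN,
              confidence = c(sbp = NA_real_, dbp = NA_real_, hr = NA_real_),
              frames = fp)
  if (!is.null(fp)) {
    fr <- normalize_frames(bin, fp, normalize_p)
    for (measure in c("sbp", "dbp", "hr")) {
      f <- fr[[measure]]
      if (is.null(f)) next
      pred <- predict(model, f, type = "value", tau = tau)
      out[[measure]] <- pred$value[1]
      out$confidence[[measure]] <- pred$confidence[1]
    }
  }
  class(out) <- "bp_reading"
  out
}

#' @export
print.bp_reading <- function(x, ...) {
  fmt <- function(v) if (is.nan(v)) "NaN" else sprintf("%d", as.integer(v))
  cat(sprintf("BP reading: %s/%s mm Hg, HR %s bpm\n",
              fmt(x$sbp), fmt(x$dbp), fmt(x$hr)))
  if (is.null(x$frames)) cat("  (LCD frame localization failed)\n")
  invisible(x)
}

#' Save / load a fitted recognizer
#'
#' Single-file archive holding the architecture identifier, format version,
#' learned parameters and training metadata; [load_model()] validates the
#' format and restores an object whose predictions are identical to the
#' saved model's.
#'
#' @param model a [bp_cnn()] fit.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the `"bp_cnn"`
#'   object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bp_cnn"))
  saveRDS(list(format = "bpocr_bp_cnn", version = 1L,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "bpocr_bp_cnn") || !identical(obj$version, 1L)) {
    stop("not a bpocr model file (or unsupported version)", call. = FALSE)
  }
  structure(obj$model, class = "bp_cnn")
}
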