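# Experiment orchestration: synthesize a corpus, run the preprocessing /
# localization / normalization chain, train the recognizer under one of the
# two published regimes (good-only vs good+poor training), and evaluate on
# held-out good and poor test sets with stratified metrics.

#' Pipeline configuration
#'
#' Nested parameter block covering every stage; unknown keys (top level or
#' nested) are rejected before any computation so typos cannot silently
#' fall back to defaults. The effective configuration is stored in every
#' experiment's provenance.
#'
#' @param enhance an [enhance_params()].
#' @param localize a [localize_params()].
#' @param normalize a [normalize_params()].
#' @param recognize list of training settings: `epochs`, `batch_size`,
#'   `lr`, `tau`.
#' @return nested list of class `"bpocr_config"`.
#' @export
bpocr_config <- function(enhance = enhance_params(),
                         localize = localize_params(),
                         normalize = normalize_params(),
                         recognize = list()) {
  rec_defaults <- list(epochs = 3, batch_size = 32, lr = 1e-3, tau = 0)
  unknown <- setdiff(names(recognize), names(rec_defaults))
  if (length(unknown) > 0) {
    stop("unknown recognize config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rec <- utils::modifyList(rec_defaults, recognize)
  stopifnot(inherits(enhance, "enhance_params"),
            inherits(localize, "localize_params"),
            inherits(normalize, "normalize_params"))
  structure(list(enhance = enhance, localize = localize,
                 normalize = normalize, recognize = rec),
            class = "bpocr_config")
}

#' Stream a synthetic corpus through the frame-extraction pipeline
#'
#' Renders the scenes of a [synthetic_spec()] one at a time and runs each
#' through enhancement, localization and (optionally) frame normalization,
#' keeping only the per-image records and the extracted 180x80 frames —
#' never the full-resolution photographs. Deterministic under `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [bpocr_config()].
#' @param keep_frames extract and keep normalized frames (needed for
#'   training); `FALSE` runs localization only.
#' @param progress print progress every 100 scenes.
#' @return list with `images` (per-image data.frame: quality, readings,
#'   localization success and IoU against ground truth), `X` (frame design
#'   matrix) and `frames` (per-frame records: image id, measure, value).
#' @export
build_corpus <- function(spec, config = bpocr_config(), keep_frames = TRUE,
                         progress = FALSE) {
  n <- spec$n_images
  set.seed(spec$seed)
  meta <- vector("list", n)
  X <- if (keep_frames) {
    matrix(0L, 3 * n, 14400)
  }
  frame_meta <- vector("list", 3 * n)
  nf <- 0L
  for (i in seq_len(n)) {
    scene <- synth_scene(spec)
    bin <- enhance(scene$image, config$enhance)
    fp <- localize_frames(bin, config$localize)
    iou <- if (is.null(fp) || is.null(scene$lcd_box)) 0 else {
      box_iou(fp$bp, scene$lcd_box)
    }
    meta[[i]] <- data.frame(
      id = i, quality = scene$quality, group = quality_group(scene$quality),
      readability = scene$readability,
      sbp = scene$reading$sbp, dbp = scene$reading$dbp, hr = scene$reading$hr,
      localized = !is.null(fp), iou = iou, stringsAsFactors = FALSE)
    if (keep_frames && !is.null(fp) &&
        identical(scene$readability, "READABLE")) {
      fr <- normalize_frames(bin, fp, config$normalize)
      for (measure in c("sbp", "dbp", "hr")) {
        f <- fr[[measure]]
        if (is.null(f)) next
        nf <- nf + 1L
        X[nf, ] <- as.integer(t(f) > 127.5)
        frame_meta[[nf]] <- data.frame(
          id = i, measure = measure,
          value = scene$reading[[measure]], stringsAsFactors = FALSE)
      }
    }
    if (progress && i %% 100 == 0) message("  scene ", i, "/", n)
  }
  images <- do.call(rbind, meta)
  frames <- if (nf > 0) do.call(rbind, frame_meta[seq_len(nf)])
  list(images = images,
       X = if (keep_frames && nf > 0) X[seq_len(nf), , drop = FALSE],
       frames = frames)
}

#' Frame-localization recovery study
#'
#' Streams synthetic scenes through enhancement and localization and scores
#' each detected BP box against the ground truth by intersection-over-union
#' (IoU); a scene counts as recovered when IoU reaches `iou_threshold`
#' (failed localizations count 0). This is the synthetic analogue of an
#' LCD-frame extraction-accuracy measurement.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [bpocr_config()].
#' @param iou_threshold IoU needed to count a scene as recovered.
#' @return list with `success_rate` (%), `n`, per-image `details`, and the
#'   per-group rates `by_group`.
#' @export
localization_study <- function(spec, config = bpocr_config(),
                               iou_threshold = 0.8) {
  corpus <- build_corpus(spec, config, keep_frames = FALSE)
  d <- corpus$images
  d$success <- d$iou >= iou_threshold
  by_group <- tapply(d$success, d$group, mean) * 100
  list(success_rate = 100 * mean(d$success), n = nrow(d),
       by_group = by_group, details = d)
}

#' Run a training / evaluation experiment on a synthetic corpus
#'
#' Renders `spec$n_images` degraded scenes, extracts frames with the
#' package's own localization (images that fail localization drop out of
#' training, and count as unreadable at test time), splits the images 3:1
#' into train and test within each of the good / poor strata, trains the
#' recognizer, and evaluates exact-value accuracy and MAE on the held-out
#' good and poor test sets.
#'
#' Two regimes mirror the published experiments: `"good_only"` trains on
#' good-quality frames alone; `"good_and_poor"` trains on all frames with a
#' stratified 3:1 train/validation split that preserves the good/poor
#' proportions. Both regimes are evaluated on identical test sets.
#'
#' The split and all training randomness follow from `spec$seed`, so a
#' rerun with the same spec and config reproduces the experiment.
#'
#' @param spec a [synthetic_spec()].
#' @param mode `"good_and_poor"` or `"good_only"`.
#' @param config a [bpocr_config()].
#' @param out_dir optional directory for artifacts (model, report CSV,
#'   provenance JSON).
#' @param corpus optional prebuilt corpus from [build_corpus()] under the
#'   same `spec` and `config`, letting several regimes share one generation
#'   pass; when supplied, the RNG is still seeded from `spec$seed` so the
#'   split and training are reproducible.
#' @param progress print stage progress.
#' @return object of class `"bpocr_experiment"`: `model`, `report`
#'   (test-set [evaluation_report()]), `localization` (per-group extraction
#'   rates on the test images), `corpus` (image-level records), and
#'   `provenance`.
#' @export
run_experiment <- function(spec, mode = c("good_and_poor", "good_only"),
                           config = bpocr_config(), out_dir = NULL,
                           corpus = NULL, progress = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "synthetic_spec"), inherits(config, "bpocr_config"))
  if (is.null(corpus)) {
    if (progress) message("building corpus (", spec$n_images, " scenes)...")
    corpus <- build_corpus(spec, config, progress = progress)
  }
  set.seed(spec$seed + 1)  # split/training stream, same whether the corpus
                           # was supplied or built here
  images <- corpus$images
  if (is.null(corpus$frames)) stop("no frames could be extracted", call. = FALSE)

  # image-level 3:1 train/test split within each quality group
  test_ids <- integer()
  train_ids <- integer()
  for (g in unique(images$group)) {
    ids <- images$id[images$group == g]
    n_train <- floor(0.75 * length(ids))
    perm <- sample(ids)
    train_ids <- c(train_ids, perm[seq_len(n_train)])
    test_ids <- c(test_ids, perm[-seq_len(n_train)])
  }

  train_pool <- if (mode == "good_only") {
    intersect(train_ids, images$id[images$group == "good"])
  } else {
    train_ids
  }
  if (length(train_pool) < 8) {
    stop("too few training images for mode ", mode, call. = FALSE)
  }
  # image-level 3:1 train/validation split, stratified by group so poor
  # and good images contribute equal proportions to fit and validation
  fit_ids <- integer(); val_ids <- integer()
  for (g in unique(images$group[images$id %in% train_pool])) {
    ids <- intersect(train_pool, images$id[images$group == g])
    n_fit <- floor(0.75 * length(ids))
    perm <- sample(ids)
    fit_ids <- c(fit_ids, perm[seq_len(n_fit)])
    val_ids <- c(val_ids, perm[-seq_len(n_fit)])
  }
  fr <- corpus$frames
  sel <- fr$id %in% c(fit_ids, val_ids)
  Xsel <- corpus$X[sel, , drop = FALSE]
  fr_sel <- fr[sel, , drop = FALSE]
  val_idx <- which(fr_sel$id %in% val_ids)
  if (progress) {
    message("training on ", nrow(Xsel), " frames (", length(val_idx),
            " validation)...")
  }
  rec <- config$recognize
  model <- bp_cnn(Xsel, fr_sel$value, epochs = rec$epochs,
                  batch_size = rec$batch_size, lr = rec$lr, tau = rec$tau,
                  val_idx = val_idx, verbose = progress)

  # test-set predictions: recognized frames where localization succeeded,
  # NaN elsewhere
  test_images <- images[images$id %in% test_ids, , drop = FALSE]
  preds <- data.frame(filename = as.character(test_images$id),
                      sbp = NaN, dbp = NaN, hr = NaN)
  fr_test <- fr[fr$id %in% test_ids, , drop = FALSE]
  if (nrow(fr_test) > 0) {
    pv <- predict(model, corpus$X[fr$id %in% test_ids, , drop = FALSE],
                  type = "value")
    for (k in seq_len(nrow(fr_test))) {
      row <- match(as.character(fr_test$id[k]), preds$filename)
      preds[row, fr_test$measure[k]] <- pv$value[k]
    }
  }
  manifest <- data.frame(filename = as.character(test_images$id),
                         sbp = test_images$sbp, dbp = test_images$dbp,
                         hr = test_images$hr, quality = test_images$quality,
                         stringsAsFactors = FALSE)
  report <- evaluation_report(manifest, preds)
  localization <- list(
    by_group = tapply(test_images$iou >= 0.8, test_images$group, mean) * 100,
    extraction_by_group = tapply(test_images$localized, test_images$group,
                                 mean) * 100)
  provenance <- list(mode = mode, seed = spec$seed,
                     n_images = spec$n_images,
                     quality_mix = as.list(spec$quality_mix),
                     recognize = config$recognize,
                     n_train_frames = nrow(Xsel),
                     package_version = as.character(utils::packageVersion("bpocr")),
                     r_version = R.version.string)
  out <- structure(list(mode = mode, model = model, report = report,
                        localization = localization, corpus = images,
                        split = list(train = train_ids, test = test_ids,
                                     fit = fit_ids, validation = val_ids),
                        provenance = provenance),
                   class = "bpocr_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(model, file.path(out_dir, "model.rds"))
    write.csv(as.data.frame(report), file.path(out_dir, "report.csv"),
              row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.bpocr_experiment <- function(x, ...) {
  cat("bpocr experiment (", x$mode, " training)\n", sep = "")
  cat(sprintf("  corpus: %d images; training frames: %d\n",
              nrow(x$corpus), x$provenance$n_train_frames))
  cat(sprintf("  test-set frame recovery (IoU >= 0.8): good %.1f%%, poor %.1f%%\n",
              x$localization$by_group[["good"]],
              x$localization$by_group[["poor"]]))
  cat("\n")
  print(x$report)
  invisible(x)
}
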