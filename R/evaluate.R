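# Evaluation: 3:1 dataset splitting and the two headline metrics —
# exact-value classification accuracy (%) and mean absolute error (mm Hg) —
# reported per measure (SBP / DBP / HR) and per quality stratum, with a
# binary good/poor roll-up.

#' Split dataset identifiers 3:1
#'
#' Seeded uniform shuffle, then a cut at `floor(train_frac * n)`. Splitting
#' operates on whatever identifier the caller supplies; supplying one id
#' per source photograph keeps the systolic and diastolic frames of an
#' image on the same side of the split (and their counts equal).
#'
#' @param ids vector of identifiers (>= 4).
#' @param train_frac training fraction; the default 0.75 is the 3:1 ratio.
#' @param seed RNG seed for the shuffle.
#' @return object of class `"dataset_split"`: list with `train`, `test`,
#'   `train_frac`, `seed`.
#' @export
split_dataset <- function(ids, train_frac = 0.75, seed = 1) {
  if (length(ids) < 4) stop("need at least 4 ids to split", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample(ids)
  n_train <- floor(train_frac * length(ids))
  structure(list(train = perm[seq_len(n_train)],
                 test = perm[(n_train + 1):length(ids)],
                 train_frac = train_frac, seed = seed),
            class = "dataset_split")
}

#' Exact-value classification accuracy
#'
#' The fraction (in percent) of readings transcribed exactly right: a
#' prediction counts as correct only when it equals the truth in full
#' (every digit), since one wrong digit shifts the value by its order of
#' magnitude. `NaN`/`NA` predictions count as wrong; pairs with missing
#' truth are excluded from the denominator.
#'
#' @param preds,truths aligned numeric vectors.
#' @return accuracy in percent.
#' @export
classification_accuracy <- function(preds, truths) {
  if (length(preds) != length(truths)) {
    stop("preds and truths must have equal length", call. = FALSE)
  }
  valid_truth <- !is.na(truths)
  if (!any(valid_truth)) return(NA_real_)
  hit <- !is.na(preds) & valid_truth & preds == truths
  100 * sum(hit) / sum(valid_truth)
}

#' Mean absolute transcription error
#'
#' Mean of `|pred - truth|` over pairs where both values are present, in
#' the unit of the measure (mm Hg for pressures). Pairs excluded for
#' missingness are counted in the `"n_excluded"` attribute so failures are
#' not silently hidden.
#'
#' @param preds,truths aligned numeric vectors.
#' @return the MAE, with attributes `n` (pairs used) and `n_excluded`;
#'   `NA` (with `n = 0`) when no valid pair exists.
#' @export
mean_absolute_error <- function(preds, truths) {
  if (length(preds) != length(truths)) {
    stop("preds and truths must have equal length", call. = FALSE)
  }
  both <- !is.na(preds) & !is.na(truths)
  excl <- sum(!is.na(truths) & !both)
  if (!any(both)) {
    return(structure(NA_real_, n = 0L, n_excluded = excl))
  }
  structure(mean(abs(preds[both] - truths[both])),
            n = sum(both), n_excluded = excl)
}

GOOD_LABELS <- "OK"

quality_group <- function(quality) ifelse(quality %in% GOOD_LABELS, "good", "poor")

#' Stratified evaluation report
#'
#' Joins predictions to the manifest and computes, for each measure
#' (SBP, DBP, HR) in each stratum (every quality label present, the binary
#' good/poor roll-up, and the pooled total): number of readings, exact-value
#' classification accuracy (%), mean absolute error, and coverage (% of
#' readings with a non-missing prediction). HR rows are flagged
#' best-effort: the recognizer is shared with the BP frames and HR carries
#' no published reference numbers.
#'
#' @param manifest data.frame with columns `filename`, `sbp`, `dbp`, `hr`,
#'   `quality` (ground truth).
#' @param predictions data.frame with columns `filename`, `sbp`, `dbp`,
#'   `hr` (predicted values, `NaN`/`NA` where unreadable).
#' @return data.frame of class `"bp_eval_report"` with columns `measure`,
#'   `stratum`, `n`, `accuracy`, `mae`, `mae_excluded`, `coverage`.
#' @export
evaluation_report <- function(manifest, predictions) {
  need <- c("filename", "sbp", "dbp", "hr")
  stopifnot(all(need %in% names(manifest)), all(need %in% names(predictions)),
            "quality" %in% names(manifest))
  unmatched <- setdiff(predictions$filename, manifest$filename)
  if (length(unmatched) > 0) {
    stop("predictions without a manifest row: ",
         paste(head(unmatched, 3), collapse = ", "), call. = FALSE)
  }
  m <- merge(manifest, predictions, by = "filename",
             suffixes = c("_true", "_pred"))
  strata <- c(
    lapply(sort(unique(m$quality)), function(q) {
      list(name = q, rows = m$quality == q)
    }),
    list(list(name = "good", rows = quality_group(m$quality) == "good"),
         list(name = "poor", rows = quality_group(m$quality) == "poor"),
         list(name = "all", rows = rep(TRUE, nrow(m))))
  )
  out <- list()
  for (measure in c("sbp", "dbp", "hr")) {
    truths <- m[[paste0(measure, "_true")]]
    preds <- m[[paste0(measure, "_pred")]]
    for (s in strata) {
      idx <- s$rows & !is.na(truths)
      if (!any(idx)) next  # empty stratum: omitted
      mae <- mean_absolute_error(preds[idx], truths[idx])
      out[[length(out) + 1]] <- data.frame(
        measure = toupper(measure), stratum = s$name, n = sum(idx),
        accuracy = classification_accuracy(preds[idx], truths[idx]),
        mae = as.numeric(mae),
        mae_excluded = attr(mae, "n_excluded"),
        coverage = 100 * mean(!is.na(preds[idx])),
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, out)
  class(rep) <- c("bp_eval_report", "data.frame")
  rep
}

#' @export
print.bp_eval_report <- function(x, ...) {
  cat("Transcription performance by measure and quality stratum\n")
  cat("(accuracy = exact-value match %; MAE in mm Hg (bpm for HR, best-effort);\n")
  cat(" coverage = % readings with a non-missing prediction)\n\n")
  df <- as.data.frame(x)
  df$accuracy <- sprintf("%.1f", df$accuracy)
  df$mae <- ifelse(is.na(df$mae), "-", sprintf("%.2f", df$mae))
  df$coverage <- sprintf("%.1f", df$coverage)
  print(df, row.names = FALSE)
  invisible(x)
}
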