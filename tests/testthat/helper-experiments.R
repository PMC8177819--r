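# Shared heavy fixture: one synthetic corpus pushed through both training
# regimes. Built lazily on first use and reused by every test that needs a
# trained recognizer, so the suite trains exactly twice.

.fixture_env <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!exists("fx", envir = .fixture_env)) {
    spec <- synthetic_spec(2400, seed = 424242)
    config <- bpocr_config(recognize = list(epochs = 3))
    corpus <- build_corpus(spec, config)
    ex4 <- run_experiment(spec, "good_and_poor", config, corpus = corpus)
    ex3 <- run_experiment(spec, "good_only",
                          bpocr_config(recognize = list(epochs = 6)),
                          corpus = corpus)
    .fixture_env$fx <- list(spec = spec, config = config, corpus = corpus,
                            ex4 = ex4, ex3 = ex3)
  }
  .fixture_env$fx
}

report_value <- function(report, measure, stratum, column) {
  report[report$measure == measure & report$stratum == stratum, column]
}

# pooled SBP+DBP exact accuracy / MAE over a stratum, n-weighted
pooled_bp <- function(report, stratum) {
  rows <- report[report$measure %in% c("SBP", "DBP") &
                   report$stratum == stratum, ]
  list(accuracy = sum(rows$accuracy * rows$n) / sum(rows$n),
       mae = sum(rows$mae * (rows$n - rows$mae_excluded)) /
         sum(rows$n - rows$mae_excluded))
}
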