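# Shared fixture corpus, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- make_fixture(seed = 1L)
  }
  .fixture_env$corpus
}

fixture_events <- function(hybrid = "H1") {
  key <- paste0("events_", hybrid)
  if (is.null(.fixture_env[[key]])) {
    corpus <- fixture_corpus()
    .fixture_env[[key]] <- call_crossovers(
      corpus$hybrids[[hybrid]]$molecules, co_filter_params(),
      hybrid_id = hybrid)
  }
  .fixture_env[[key]]
}
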