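# tiny trained scorers shared across tests (trained once per session)
.model_cache <- new.env(parent = emptyenv())

cached_model <- function(key, builder) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- builder()
  .model_cache[[key]]
}

tiny_5mC_model <- function() cached_model("m5", function() {
  d <- simulate_mC_windows(n_per_class = 600, depth = 20, seed = 101, width = 11)
  fit_scorer(d$x, d$y, tiny_scorer_config("duplex", 11L, "5mC"),
             train_config(epochs = 25, batch_size = 64, patience = 6, seed = 102),
             quiet = TRUE)
})

tiny_6mA_model <- function() cached_model("m6", function() {
  d <- simulate_6mA_windows(n_per_class = 600, depth = 20, seed = 103, width = 11)
  fit_scorer(d$x, d$y, tiny_scorer_config("watson", 11L, "6mA"),
             train_config(epochs = 25, batch_size = 64, patience = 6, seed = 104),
             quiet = TRUE)
})
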