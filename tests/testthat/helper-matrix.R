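## The full factorial scenario run is shared by several acceptance checks;
## compute it once per test session, on first use.
full_matrix_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_scenarios(quiet = TRUE)
    }
    cache
  }
})
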