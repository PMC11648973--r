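# The full-replication drift study is the most expensive object the
# acceptance checks need; compute it once and share it across test blocks.
acceptance_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- study_config(sim = sim_config(n_replicates = 100, seed = 88),
                          n_restarts = 1)
      cache <<- run_study(cfg, progress = FALSE)
    }
    cache
  }
})
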