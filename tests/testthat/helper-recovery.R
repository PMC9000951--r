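# Multi-seed recovery runs at full read depth are expensive; compute
# them once per session and share across test files.
recovery_runs <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$runs)) {
      cache$runs <- recovery_study(seeds = 1:20, asymmetry = 0.3,
                                   shared_target_fraction = 0.5,
                                   new_target_fraction_P2 = 0.25)
    }
    cache$runs
  }
})
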