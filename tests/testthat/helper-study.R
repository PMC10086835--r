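# The three-method comparison study is expensive, and two test files assess
# different aspects of the same replicates, so it is computed once per session.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function(p, reps = 38, seed = 20251) {
  key <- paste0("p", round(p, 4))
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- suppressWarnings(
      run_study(sim_config(p = p), reps = reps, seed = seed))
  }
  .study_cache[[key]]
}
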