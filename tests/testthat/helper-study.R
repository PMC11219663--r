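# The full 200-patient synthetic study exercised by the end-to-end checks.
# Built lazily and cached so every block that needs it shares one run.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$study)) {
    cfg <- study_config(sim = sim_config(n_patients = 200, seed = 1), seed = 1)
    .study_cache$study <- suppressWarnings(suppressMessages(run_study(cfg)))
  }
  .study_cache$study
}
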