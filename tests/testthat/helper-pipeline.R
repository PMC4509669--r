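# The full-scale deployment and its processed pipeline products are expensive
# (about 1.5 min together); they are built once on first request and shared
# across the acceptance blocks.

full_pipeline <- function(seed = 20260922) {
  key <- paste0("pipe_", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- full_sim(seed)
    .fixture_env[[key]] <- suppressMessages(run_pipeline(sim))
  }
  .fixture_env[[key]]
}
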