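# Shared small fixtures; everything is generated in code at test time.

quiet_params <- function(...) {
  # zero-motion variant for resting-discharge fixtures
  stimulus_params(accel_sd_walk = 0, rot_sd_walk = 0, ...)
}

rest_trace <- function(duration = 30, seed = 1) {
  generate_stimulus("passive_low", duration, quiet_params(), seed = seed)
}

# cached condition stimuli reused across tests in one run
.stim_cache <- new.env(parent = emptyenv())
cached_stimulus <- function(condition, duration, seed) {
  key <- paste(condition, duration, seed, sep = "_")
  if (is.null(.stim_cache[[key]])) {
    .stim_cache[[key]] <- generate_stimulus(condition, duration,
                                            stimulus_params(), seed = seed)
  }
  .stim_cache[[key]]
}
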