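# Shared fixtures: small populations keep the unit tests fast; the
# acceptance tests use the full default_model().

small_model <- function(n_units = 60L) default_model(n_units)

# deterministic tiny recording table: one neuron per preferred stimulus,
# exact Gaussian tuning, no noise
tiny_recording <- function(n_stimuli = 11L, bins = c(100, 200),
                           gain = c(fixation = 1, categorization = 1,
                                    discrimination = 1)) {
  tasks <- names(gain)
  grid <- expand.grid(neuron_id = seq_len(n_stimuli), task = tasks,
                      stimulus = seq_len(n_stimuli), time_bin_ms = bins,
                      stringsAsFactors = FALSE)
  grid$rate <- gain[grid$task] *
    exp(-(grid$neuron_id - grid$stimulus)^2 / (2 * 1.8^2))
  grid
}
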