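# Shared fixtures, built in code.

flat_audiogram <- function(t, ear = "left",
                           freqs = c(125, 250, 500, 1000, 2000, 4000, 8000)) {
  audiogram(ear, freqs, rep(t, length(freqs)))
}

# Small deterministic cohort for analysis-plumbing tests.
small_cohort <- function(seed = 42, n_dfcrs = 40, n_um = 30, ...) {
  generate_cohort(sim_config(n_dfcrs = n_dfcrs, n_um = n_um, ...),
                  seed = seed)
}

# White-noise audio fixture.
noise_signal <- function(n, fs = 44100, amplitude = 0.05, seed = 7,
                         channels = 1) {
  set.seed(seed)
  audio_signal(matrix(stats::rnorm(n * channels, 0, amplitude / 3),
                      ncol = channels), fs)
}

# Long-form responses for one subject/timepoint/instrument.
long_responses <- function(instrument, values, subject_id = "S1",
                           timepoint = "T0") {
  data.frame(subject_id = subject_id, timepoint = timepoint,
             instrument = instrument,
             item_index = seq_along(values), value = values)
}
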