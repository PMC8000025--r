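# Small generator configurations used across tests. Channel counts and trial
# numbers are kept low so individual tests stay fast; tests that probe
# statistical properties state their own sizes.

tiny_config <- function(n_trials = 12, n_channels = 4, n_samples = 512,
                        probes = c("V1", "V4"), seed = 1, ...) {
  generator_config(
    n_trials_per_condition = n_trials, n_channels = n_channels,
    n_samples = n_samples, probes = probes, seed = seed,
    oscillators = list(oscillator(center = 33, bw = 8, amplitude = 8)),
    couplings = list(), ...
  )
}

# single-probe session with a gamma oscillator carrying a condition effect
gamma_effect_config <- function(n_trials, gain_rf = 1.5, offset_rf = 0,
                                n_channels = 2, seed = 1) {
  generator_config(
    n_trials_per_condition = n_trials, n_channels = n_channels,
    probes = "V1", seed = seed,
    oscillators = list(oscillator(
      center = 33, bw = 8, amplitude = 10,
      cond_gain = c(RF = gain_rf, OUT1 = 1, OUT2 = 1),
      cond_offset = c(RF = offset_rf, OUT1 = 0, OUT2 = 0))),
    couplings = list()
  )
}
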