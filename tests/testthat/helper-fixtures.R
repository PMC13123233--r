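# shared fixture builders; everything is generated in code at test time

fix_config <- function(...) erg_config(...)

# wrap a bare trace as an averaged waveform at the standard geometry
fix_waveform <- function(trace, onset_index = 32L, sampling_rate = 512,
                         adaptation = "DA", flash = 0.3, genotype = "WT") {
  ss <- sweep_set("a1", "e1", genotype,
                  stimulus_condition(adaptation, flash),
                  matrix(trace, nrow = 1L),
                  sampling_rate = sampling_rate, onset_index = onset_index)
  average_sweeps(ss)
}

# bin-aligned sinusoid on the 128-sample / 512 Hz grid (80 Hz = bin 20)
fix_sine <- function(freq = 80, amp = 10, n = 128L, fs = 512) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs)
}

# noise-free single-eye cohort for one genotype (all 6 protocol conditions)
fix_noise_free_eye <- function(genotype = "WT", config = fix_config()) {
  spec <- cohort_spec(genotype, n_animals = 1L, eyes_per_animal = 1L,
                      noise_sd = 0, animal_effect_cv = 0,
                      eye_effect_cv = 0, seed = 1L)
  generate_cohort(spec, erg_model(), config)
}

# small noisy arm for pipeline-level tests (kept small for speed)
fix_small_arm <- function(genotype = "mdx", seed = 42L, n_mutant = 4L,
                          n_wt = 4L) {
  generate_arm(genotype, seed = seed, n_mutant = n_mutant, n_wt = n_wt)
}
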