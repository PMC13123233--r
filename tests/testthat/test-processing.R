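test_that("artifact rejection follows the robust range rule", {
  cond <- stimulus_condition("DA", -1.7)
  base <- matrix(0, nrow = 8L, ncol = 128L)
  # hand-built ranges 9,10,11,10,9,11,10 and one 510 uV outlier:
  # median = 10, MAD = 1.4826 * 1 -> threshold 10 + 5 * 1.4826 = 17.41
  p2p <- c(9, 10, 11, 10, 9, 11, 10, 510)
  for (i in seq_len(8L)) base[i, 50L + i] <- p2p[i]
  ss <- sweep_set("a", "e", "WT", cond, base)
  sel <- reject_artifacts(ss, mad_k = 5)
  expect_identical(sel$rejected, 8L)
  expect_identical(sel$kept, 1:7)
  # identical sweeps: MAD = 0, nothing rejected
  ss2 <- sweep_set("a", "e", "WT", cond,
                   matrix(rep(fix_sine(), 8L), nrow = 8L, byrow = TRUE))
  expect_length(reject_artifacts(ss2, 5)$rejected, 0L)
  # single sweep: skipped with a warning
  ss3 <- sweep_set("a", "e", "WT", cond, matrix(1, 1L, 128L))
  expect_warning(sel3 <- reject_artifacts(ss3, 5), "skipped")
  expect_true(sel3$skipped)
})

test_that("sweep averaging is the pointwise mean with provenance", {
  cond <- stimulus_condition("DA", 0.3)
  v <- fix_sine(amp = 25)
  ss <- sweep_set("a", "e", "WT", cond, rbind(v, -v))
  w <- average_sweeps(ss)
  expect_equal(w$trace, rep(0, 128L))
  expect_equal(w$n_sweeps_used, 2L)
  # brute-force column means on a random fixture
  set.seed(11)
  tr <- matrix(rnorm(6L * 128L), nrow = 6L)
  ss2 <- sweep_set("a", "e", "WT", cond, tr)
  w2 <- average_sweeps(ss2, kept = c(1L, 3L, 5L))
  expect_equal(w2$trace, apply(tr[c(1, 3, 5), ], 2L, mean))
  expect_equal(w2$n_sweeps_rejected, 3L)
  # LA condition with 24 sweeps and none rejected
  la <- sweep_set("a", "e", "WT", stimulus_condition("LA", 0.3),
                  matrix(0, 24L, 128L))
  expect_equal(average_sweeps(la)$n_sweeps_used, 24L)
})

test_that("baseline window arithmetic floors to whole samples", {
  w <- fix_waveform(rep(5, 128L))
  expect_equal(compute_baseline(w, 16), 5)
  # ramp 0,1,2,... at onset 32: 16 ms @ 512 Hz -> 8 samples (floor of 8.192),
  # 1-based indices 25..32 hold values 24..31 -> mean 27.5
  ramp <- fix_waveform(as.numeric(0:127))
  expect_equal(compute_baseline(ramp, 16), 27.5)
  expect_error(compute_baseline(ramp, 200), "insufficient")
})

test_that("spectrum satisfies the closed-form sinusoid oracle and Parseval", {
  # bin-aligned 80 Hz, 10 uV: single-sided peak-amplitude magnitude is 10
  w <- fix_waveform(fix_sine(80, 10))
  spec <- erg_spectrum(w)
  expect_equal(spec$frequencies[2] - spec$frequencies[1], 4)
  i80 <- which(spec$frequencies == 80)
  expect_equal(spec$magnitudes[i80], 10, tolerance = 1e-10)
  expect_lt(max(spec$magnitudes[-i80]), 1e-9)
  # constant trace: all-zero magnitudes (mean removed)
  expect_equal(max(erg_spectrum(fix_waveform(rep(3, 128)))$magnitudes), 0)
  # Parseval: signal energy equals spectrum energy
  set.seed(5)
  x <- rnorm(128L)
  sp <- erg_spectrum(x, sampling_rate = 512)
  m <- sp$magnitudes
  n <- length(x)
  energy_spec <- n * (m[1]^2 + m[length(m)]^2 +
                        0.5 * sum(m[2:(length(m) - 1L)]^2))
  expect_equal(energy_spec, sum((x - mean(x))^2), tolerance = 1e-6)
})

test_that("OP isolation is an exact, orthogonal, idempotent bin partition", {
  cfg <- fix_config()
  # bin-aligned 80 Hz sinusoid goes entirely to the OP component
  w <- fix_waveform(fix_sine(80, 10))
  pair <- isolate_ops(w, cfg)
  expect_lt(max(abs(pair$ops - w$trace)), 0.1)
  expect_lt(max(abs(pair$slow)), 0.1)
  # conservation and energy split on arbitrary fixtures
  set.seed(21)
  for (trace in list(rnorm(128L, sd = 50),
                     fix_sine(20, 100) + fix_sine(80, 10),
                     model_waveform(erg_model(), genotype_preset("WT"), 0.3))) {
    wv <- fix_waveform(trace)
    pr <- isolate_ops(wv, cfg)
    expect_lt(max(abs(pr$slow + pr$ops - wv$trace)), 1e-9)
    x <- wv$trace - mean(wv$trace)
    expect_equal(sum((pr$slow - mean(pr$slow))^2) + sum(pr$ops^2),
                 sum(x^2), tolerance = 1e-9)
    # idempotence: re-splitting each component at the same (fixed) cutoff
    # returns it unchanged; with an adaptive cutoff the re-split may pick a
    # different spectral minimum, so the property is stated for fixed mode
    cfg_fx <- fix_config(op_split_mode = "fixed")
    pr_fx <- isolate_ops(wv, cfg_fx)
    pr_slow <- isolate_ops(fix_waveform(pr_fx$slow), cfg_fx)
    pr_ops <- isolate_ops(fix_waveform(pr_fx$ops), cfg_fx)
    expect_lt(max(abs(pr_slow$ops)), 1e-6)
    expect_lt(max(abs(pr_ops$slow - mean(pr_fx$ops))), 1e-6)
  }
  # degenerate all-zero trace yields a valid pair of zero traces
  z <- isolate_ops(fix_waveform(rep(0, 128L)), cfg)
  expect_equal(z$slow, rep(0, 128L))
  expect_equal(z$ops, rep(0, 128L))
})

test_that("adaptive cutoff finds the spectral trough, else falls back", {
  cfg_ad <- fix_config(op_split_mode = "adaptive")
  # energy at 20 Hz and 80 Hz with a trough between: cutoff inside 30-60
  w <- fix_waveform(fix_sine(20, 100) + fix_sine(80, 10))
  pair <- isolate_ops(w, cfg_ad)
  expect_gte(pair$cutoff_hz, 30)
  expect_lte(pair$cutoff_hz, 60)
  expect_lt(max(abs(pair$ops - fix_sine(80, 10))), 0.1)
  # monotone spectrum in the search band: falls back to the fixed cutoff
  w2 <- fix_waveform(fix_sine(4, 100))
  expect_equal(isolate_ops(w2, cfg_ad)$cutoff_hz, 50)
})

test_that("OP removal changes the measured b-wave by a bounded amount", {
  # on a synthetic WT trace the raw-vs-slow b difference is at most the
  # OP component's peak-to-peak excursion
  cfg <- fix_config()
  trace <- model_waveform(erg_model(), genotype_preset("WT"), 0.3)
  w <- fix_waveform(trace, onset_index = 16L)  # generator onset
  pair <- isolate_ops(w, cfg)
  slow <- pair_waveform(pair, "slow")
  baseline <- compute_baseline(slow)
  a <- measure_a_wave(slow, baseline, cfg)
  b_slow <- measure_b_wave(slow, baseline, a, cfg)$amplitude
  b_raw <- measure_b_wave(w, baseline, a, cfg)$amplitude
  expect_lte(abs(b_raw - b_slow), diff(range(pair$ops)))
  # and the isolated OPs really ride the ascending limb: the OP envelope
  # peaks before the measured b peak
  t_ms <- time_axis(w)
  t_op_peak <- t_ms[which.max(abs(pair$ops))]
  expect_lt(t_op_peak, measure_b_wave(slow, baseline, a, cfg)$implicit_time)
  expect_gt(t_op_peak, 0)
})
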