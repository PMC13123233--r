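#' Measure the scotopic a-wave
#'
#' The a-wave trough is the global minimum of the OP-removed trace within the
#' `search_ms` window after stimulus onset (ties broken by earliest time);
#' its amplitude is baseline minus trough value, its implicit time the
#' trough latency from onset. Detection requires the amplitude to exceed a
#' threshold (by default 3 x the SD of the pre-stimulus residuals of the
#' slow trace, floored at `a_min_uv`) and the trough not to sit at the
#' window edge.
#'
#' @param slow An `erg_waveform` holding the OP-removed trace.
#' @param baseline Baseline voltage (uV) from [compute_baseline()].
#' @param config An [erg_config()].
#' @return List with `amplitude` (uV), `implicit_time` (ms) — both `NA` when
#'   undetected — and logical `detected`.
#' @export
measure_a_wave <- function(slow, baseline, config = erg_config()) {
  stopifnot(inherits(slow, "erg_waveform"))
  t_ms <- time_axis(slow)
  win <- which(t_ms > 0 & t_ms <= config$a_search_ms)
  if (!length(win)) stop("a-wave search window is empty", call. = FALSE)
  i_rel <- which.min(slow$trace[win])  # first index on ties
  trough_val <- slow$trace[win[i_rel]]
  amplitude <- baseline - trough_val
  # threshold from pre-stimulus residual scatter of the slow trace
  n_win <- floor(config$baseline_window_ms * slow$sampling_rate / 1000)
  pre <- slow$trace[(slow$onset_index - n_win + 1L):slow$onset_index]
  theta <- max(3 * stats::sd(pre), config$a_min_uv)
  detected <- amplitude > theta && i_rel < length(win)
  if (!detected) {
    return(list(amplitude = NA_real_, implicit_time = NA_real_,
                detected = FALSE))
  }
  list(amplitude = amplitude, implicit_time = t_ms[win[i_rel]],
       detected = TRUE)
}

#' Measure the b-wave
#'
#' The b-wave peak is the global maximum of the OP-removed trace after the
#' a-wave trough (or after `b_search_start_ms` post-onset when no a-wave was
#' detected). Amplitude is trough-to-peak when an a-wave exists, otherwise
#' peak minus baseline; implicit time is the peak latency from stimulus
#' onset. The `at_edge` flag marks a peak at the final sample.
#'
#' @param slow An `erg_waveform` (OP-removed trace).
#' @param baseline Baseline voltage, uV.
#' @param a_result Result of [measure_a_wave()] on the same trace.
#' @param config An [erg_config()].
#' @return List with `amplitude` (uV), `implicit_time` (ms), `at_edge`.
#' @export
measure_b_wave <- function(slow, baseline, a_result, config = erg_config()) {
  stopifnot(inherits(slow, "erg_waveform"))
  t_ms <- time_axis(slow)
  t_start <- if (isTRUE(a_result$detected)) a_result$implicit_time
             else config$b_search_start_ms
  win <- which(t_ms > t_start)
  if (!length(win)) stop("b-wave search window is empty", call. = FALSE)
  i_rel <- which.max(slow$trace[win])
  peak_val <- slow$trace[win[i_rel]]
  ref <- if (isTRUE(a_result$detected)) baseline - a_result$amplitude
         else baseline
  # edge flag: the peak sits at the final sample, or the trace has not
  # fallen away from the peak level by the end of the record (flat records)
  at_edge <- win[i_rel] == length(slow$trace) ||
    slow$trace[length(slow$trace)] >= peak_val - 1e-9
  list(amplitude = peak_val - ref,
       implicit_time = t_ms[win[i_rel]],
       at_edge = at_edge)
}

#' OP spectral amplitude in a frequency band
#'
#' Maximum single-sided magnitude over the spectrum bins whose center
#' frequency lies inside `band_hz` (inclusive); the conventional band for
#' rodent scotopic OPs is 60-100 Hz.
#'
#' @param spec An `erg_spectrum`.
#' @param band_hz Two-element numeric band in Hz.
#' @return Amplitude in uV.
#' @export
measure_op_amplitude <- function(spec, band_hz = c(60, 100)) {
  stopifnot(inherits(spec, "erg_spectrum"), length(band_hz) == 2L)
  in_band <- spec$frequencies >= band_hz[1] & spec$frequencies <= band_hz[2]
  if (!any(in_band)) {
    stop("no spectrum bins inside [", band_hz[1], ", ", band_hz[2], "] Hz",
         call. = FALSE)
  }
  max(spec$magnitudes[in_band])
}

flags_string <- function(a_detected, b_edge) {
  f <- c(if (!a_detected) "a_undetected", if (b_edge) "b_at_record_edge")
  if (is.null(f)) "" else paste(f, collapse = ";")
}

#' Quantify all components of one averaged waveform
#'
#' Runs the full per-record chain: OP isolation, baseline, a-wave and b-wave
#' on the OP-removed trace, and (DA only) the OP spectral amplitude on the
#' spectrum of the mean-removed raw average. LA records carry the b-wave
#' only: photopic a-waves and OPs are not analysed.
#'
#' @param w An `erg_waveform`.
#' @param config An [erg_config()].
#' @return One-row data.frame in the measures-table layout.
#' @export
quantify_waveform <- function(w, config = erg_config()) {
  stopifnot(inherits(w, "erg_waveform"))
  pair <- isolate_ops(w, config)
  slow <- pair_waveform(pair, "slow")
  baseline <- compute_baseline(slow, config$baseline_window_ms)
  is_da <- w$condition$adaptation == "DA"
  if (is_da) {
    a <- measure_a_wave(slow, baseline, config)
  } else {
    a <- list(amplitude = NA_real_, implicit_time = NA_real_, detected = FALSE)
  }
  b <- measure_b_wave(slow, baseline, a, config)
  op <- if (is_da) {
    measure_op_amplitude(erg_spectrum(w), config$op_band_hz)
  } else {
    NA_real_
  }
  data.frame(
    animal_id = w$animal_id, eye_id = w$eye_id, genotype = w$genotype,
    adaptation = w$condition$adaptation,
    flash_strength = w$condition$flash_strength,
    baseline_uv = baseline,
    a_amp_uv = a$amplitude, a_it_ms = a$implicit_time,
    b_amp_uv = b$amplitude, b_it_ms = b$implicit_time,
    op_amp_uv = op,
    flags = flags_string(!is_da || a$detected, b$at_edge),
    n_sweeps_used = w$n_sweeps_used,
    n_sweeps_rejected = w$n_sweeps_rejected,
    stringsAsFactors = FALSE
  )
}

#' Quantify every eye x condition of a cohort
#'
#' Applies (optional) artifact rejection, sweep averaging and
#' [quantify_waveform()] to each sweep set. Missing conditions are simply
#' absent from the output (never fabricated).
#'
#' @param sweepsets List of `erg_sweepset` (e.g. from [read_waveforms()] or
#'   [generate_cohort()]).
#' @param config An [erg_config()].
#' @return data.frame, one row per eye x condition, ordered by
#'   (animal, eye, adaptation, flash).
#' @export
quantify_cohort <- function(sweepsets, config = erg_config()) {
  stopifnot(length(sweepsets) >= 1L)
  rows <- lapply(sweepsets, function(s) {
    if (config$artifact_rejection && nrow(s$traces) >= 2L) {
      sel <- reject_artifacts(s, config$mad_k)
      w <- average_sweeps(s, sel$kept)
    } else {
      w <- average_sweeps(s)
    }
    quantify_waveform(w, config)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$animal_id, out$eye_id, out$adaptation, out$flash_strength), ,
      drop = FALSE]
}
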