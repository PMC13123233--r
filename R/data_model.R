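#' Run configuration
#'
#' Houses every analysis constant: sampling, the 16 ms pre-stimulus baseline
#' window, the 50 ms a-wave search window, the 60-100 Hz OP measurement band,
#' the OP/slow split cutoff, artifact-rejection settings and the analysis
#' unit. All windows and bands are validated against the Nyquist frequency.
#'
#' @param sampling_rate Sampling rate in Hz (default 512).
#' @param record_length_ms Record length in ms (default 250).
#' @param baseline_window_ms Pre-stimulus window averaged for the baseline
#'   (default 16 ms).
#' @param a_search_ms Post-onset window searched for the a-wave trough
#'   (default 50 ms).
#' @param b_search_start_ms Search start for the b-wave peak when no a-wave
#'   was detected, relative to onset (default 10 ms, skips onset transients).
#' @param op_band_hz Two-element band (Hz) in which the OP spectral amplitude
#'   is measured (default c(60, 100)).
#' @param op_split_mode "adaptive" (default) places the slow/OP cutoff at the
#'   spectral minimum within `op_adaptive_search_hz`; "fixed" uses
#'   `op_fixed_cutoff_hz`.
#' @param op_fixed_cutoff_hz Fixed cutoff and adaptive fallback (default 50 Hz).
#' @param op_adaptive_search_hz Search band for the adaptive cutoff
#'   (default c(30, 60)).
#' @param artifact_rejection Logical; apply the robust sweep-rejection rule
#'   before averaging (default FALSE: synthetic data carry no artifacts).
#' @param mad_k Rejection threshold multiplier (default 5).
#' @param a_min_uv Absolute floor of the a-wave detection threshold in uV
#'   (default 2): on noise-free records the residual-SD rule degenerates to 0
#'   and any numerical ripple would count as an a-wave.
#' @param analysis_unit "eye" (default) or "animal" (two eyes averaged per
#'   animal before group statistics).
#' @param rng_seed Optional integer seed recorded for provenance.
#' @return Object of class `erg_config` (a list).
#' @export
erg_config <- function(sampling_rate = 512,
                       record_length_ms = 250,
                       baseline_window_ms = 16,
                       a_search_ms = 50,
                       b_search_start_ms = 10,
                       op_band_hz = c(60, 100),
                       op_split_mode = c("adaptive", "fixed"),
                       op_fixed_cutoff_hz = 50,
                       op_adaptive_search_hz = c(30, 60),
                       artifact_rejection = FALSE,
                       mad_k = 5,
                       a_min_uv = 2,
                       analysis_unit = c("eye", "animal"),
                       rng_seed = NULL) {
  op_split_mode <- match.arg(op_split_mode)
  analysis_unit <- match.arg(analysis_unit)
  nyquist <- sampling_rate / 2
  stopifnot(
    sampling_rate > 0, record_length_ms > 0,
    baseline_window_ms > 0, a_search_ms > 0, b_search_start_ms >= 0,
    length(op_band_hz) == 2L, op_band_hz[1] > 0, op_band_hz[2] > op_band_hz[1],
    mad_k > 0, a_min_uv >= 0
  )
  if (op_band_hz[2] > nyquist) {
    stop("OP band upper edge ", op_band_hz[2], " Hz exceeds Nyquist (",
         nyquist, " Hz)", call. = FALSE)
  }
  if (op_fixed_cutoff_hz >= nyquist || op_adaptive_search_hz[2] >= nyquist) {
    stop("OP split cutoff must lie below Nyquist (", nyquist, " Hz)",
         call. = FALSE)
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      record_length_ms = record_length_ms,
      baseline_window_ms = baseline_window_ms,
      a_search_ms = a_search_ms,
      b_search_start_ms = b_search_start_ms,
      op_band_hz = as.numeric(op_band_hz),
      op_split_mode = op_split_mode,
      op_fixed_cutoff_hz = op_fixed_cutoff_hz,
      op_adaptive_search_hz = as.numeric(op_adaptive_search_hz),
      artifact_rejection = isTRUE(artifact_rejection),
      mad_k = mad_k,
      a_min_uv = a_min_uv,
      analysis_unit = analysis_unit,
      rng_seed = rng_seed
    ),
    class = "erg_config"
  )
}

#' Read a run configuration from a JSON document
#'
#' The document holds any subset of the [erg_config()] arguments; missing
#' fields take their defaults.
#'
#' @param path Path to a JSON file.
#' @return An `erg_config` object.
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(erg_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(erg_config, doc)
}

#' Write a run configuration to JSON
#' @param config An `erg_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Construct a sweep set
#'
#' A sweep set holds the raw stimulus-locked voltage traces for one eye under
#' one stimulus condition, with the stimulus-onset anchor. Sample `k`
#' (1-based) maps to time `(k - 1 - onset_index) / sampling_rate * 1000` ms,
#' so the first post-onset sample sits at t = 0 and implicit times are
#' reported relative to stimulus onset.
#'
#' @param animal_id,eye_id Opaque identifiers.
#' @param genotype One of [erg_genotypes()].
#' @param condition An `erg_condition` from [stimulus_condition()].
#' @param traces Numeric matrix, sweeps in rows, samples in columns, uV.
#' @param sampling_rate Hz.
#' @param onset_index Number of pre-onset samples (0-based index of the onset
#'   sample); at least 16 ms of pre-onset record must exist.
#' @return Object of class `erg_sweepset`.
#' @export
sweep_set <- function(animal_id, eye_id, genotype, condition, traces,
                      sampling_rate = 512, onset_index = 16L) {
  genotype <- match.arg(genotype, erg_genotypes())
  stopifnot(inherits(condition, "erg_condition"), is.matrix(traces),
            nrow(traces) >= 1L)
  n_samples <- ncol(traces)
  if (onset_index <= 0 || onset_index >= n_samples) {
    stop("onset_index must lie strictly inside the record", call. = FALSE)
  }
  if (onset_index < ceiling(0.016 * sampling_rate)) {
    stop("record holds fewer than 16 ms of pre-onset samples", call. = FALSE)
  }
  structure(
    list(
      animal_id = as.character(animal_id),
      eye_id = as.character(eye_id),
      genotype = genotype,
      condition = condition,
      sampling_rate = sampling_rate,
      record_length_ms = n_samples / sampling_rate * 1000,
      onset_index = as.integer(onset_index),
      traces = traces
    ),
    class = "erg_sweepset"
  )
}

#' @export
print.erg_sweepset <- function(x, ...) {
  cat(sprintf(
    "<erg_sweepset> %s / eye %s / %s | %s %.1f log cd.s/m2 | %d sweeps x %d samples @ %g Hz\n",
    x$animal_id, x$eye_id, x$genotype, x$condition$adaptation,
    x$condition$flash_strength, nrow(x$traces), ncol(x$traces),
    x$sampling_rate))
  invisible(x)
}

#' Construct an averaged waveform
#'
#' Artifact-filtered mean trace for one eye x condition with provenance
#' (sweeps used/rejected) and the stimulus-onset anchor.
#'
#' @param sweeps Source `erg_sweepset`.
#' @param trace Numeric vector, uV.
#' @param n_used,n_rejected Sweep bookkeeping; must sum to the source count.
#' @return Object of class `erg_waveform`.
#' @export
averaged_waveform <- function(sweeps, trace, n_used, n_rejected) {
  stopifnot(inherits(sweeps, "erg_sweepset"),
            length(trace) == ncol(sweeps$traces),
            n_used >= 1L, n_used + n_rejected == nrow(sweeps$traces))
  structure(
    list(
      animal_id = sweeps$animal_id,
      eye_id = sweeps$eye_id,
      genotype = sweeps$genotype,
      condition = sweeps$condition,
      sampling_rate = sweeps$sampling_rate,
      onset_index = sweeps$onset_index,
      n_sweeps_used = as.integer(n_used),
      n_sweeps_rejected = as.integer(n_rejected),
      trace = as.numeric(trace)
    ),
    class = "erg_waveform"
  )
}

#' Sample times of a waveform or sweep set
#' @param x An `erg_waveform` or `erg_sweepset`.
#' @return Numeric vector of times in ms relative to stimulus onset.
#' @export
time_axis <- function(x) {
  n <- if (inherits(x, "erg_waveform")) length(x$trace) else ncol(x$traces)
  (seq_len(n) - 1L - x$onset_index) / x$sampling_rate * 1000
}
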