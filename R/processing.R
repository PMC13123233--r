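#' Robust sweep artifact rejection
#'
#' Offline surrogate for the recorder's online artifact gating: a sweep is
#' rejected iff its peak-to-peak range exceeds
#' `median(ranges) + mad_k * MAD(ranges)` with the MAD scaled by 1.4826.
#' A zero MAD (identical ranges) rejects nothing, and at least one sweep is
#' always kept.
#'
#' @param sweeps An `erg_sweepset`.
#' @param mad_k Positive threshold multiplier (default 5).
#' @return List with integer vectors `kept` and `rejected` (row indices) and
#'   logical `skipped` (TRUE when only one sweep was available).
#' @export
reject_artifacts <- function(sweeps, mad_k = 5) {
  stopifnot(inherits(sweeps, "erg_sweepset"), mad_k > 0)
  n <- nrow(sweeps$traces)
  if (n < 2L) {
    warning("single-sweep set: artifact rejection skipped")
    return(list(kept = seq_len(n), rejected = integer(0), skipped = TRUE))
  }
  ranges <- apply(sweeps$traces, 1L, function(v) diff(range(v)))
  med <- stats::median(ranges)
  mad <- stats::mad(ranges, constant = 1.4826)
  if (mad == 0) {
    return(list(kept = seq_len(n), rejected = integer(0), skipped = FALSE))
  }
  bad <- which(ranges > med + mad_k * mad)
  if (length(bad) == n) bad <- bad[-which.min(ranges)]  # always keep one
  list(kept = setdiff(seq_len(n), bad), rejected = bad, skipped = FALSE)
}

#' Average sweeps into a mean waveform
#'
#' Pointwise arithmetic mean over the kept sweeps, with provenance counts.
#'
#' @param sweeps An `erg_sweepset`.
#' @param kept Integer indices of sweeps to average (default all).
#' @return An `erg_waveform`.
#' @export
average_sweeps <- function(sweeps, kept = seq_len(nrow(sweeps$traces))) {
  stopifnot(inherits(sweeps, "erg_sweepset"), length(kept) >= 1L)
  trace <- colMeans(sweeps$traces[kept, , drop = FALSE])
  averaged_waveform(sweeps, trace,
                    n_used = length(kept),
                    n_rejected = nrow(sweeps$traces) - length(kept))
}

#' Pre-stimulus baseline
#'
#' Arithmetic mean of the samples in the `window_ms` interval immediately
#' before stimulus onset. Fractional sample counts floor toward zero
#' (16 ms at 512 Hz -> 8 samples).
#'
#' @param w An `erg_waveform`.
#' @param window_ms Window length in ms (default 16).
#' @return Baseline voltage in uV.
#' @export
compute_baseline <- function(w, window_ms = 16) {
  stopifnot(inherits(w, "erg_waveform"), window_ms > 0)
  n_win <- floor(window_ms * w$sampling_rate / 1000)
  if (n_win < 1L || n_win > w$onset_index) {
    stop("insufficient pre-stimulus samples for a ", window_ms,
         " ms baseline window", call. = FALSE)
  }
  idx <- (w$onset_index - n_win + 1L):w$onset_index  # samples in [-window, 0)
  mean(w$trace[idx])
}

#' Single-sided amplitude spectrum
#'
#' Discrete Fourier transform of the mean-removed trace on the single-sided
#' peak-amplitude convention: bin magnitude times 2/N for non-DC, non-Nyquist
#' bins, so a bin-aligned sinusoid of amplitude A reads A at its bin.
#' Frequency resolution is `sampling_rate / n_samples` (4 Hz for a 128-sample
#' record at 512 Hz). No taper is applied, so spectra are reproducible
#' bit-for-bit.
#'
#' @param w An `erg_waveform` (or a bare numeric trace plus `sampling_rate`).
#' @param sampling_rate Required only when `w` is a bare numeric vector.
#' @return Object of class `erg_spectrum`: list with `frequencies` (Hz) and
#'   `magnitudes` (uV), non-negative bins only.
#' @export
erg_spectrum <- function(w, sampling_rate = NULL) {
  if (inherits(w, "erg_waveform")) {
    trace <- w$trace
    fs <- w$sampling_rate
  } else {
    stopifnot(is.numeric(w), !is.null(sampling_rate))
    trace <- w
    fs <- sampling_rate
  }
  n <- length(trace)
  stopifnot(n >= 8L)
  x <- trace - mean(trace)
  X <- stats::fft(x)
  n_pos <- floor(n / 2) + 1L  # DC .. Nyquist (even n)
  mags <- Mod(X[seq_len(n_pos)]) / n
  scale2 <- rep(2, n_pos)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[n_pos] <- 1
  structure(
    list(frequencies = (seq_len(n_pos) - 1) * fs / n,
         magnitudes = mags * scale2,
         n_samples = n, sampling_rate = fs),
    class = "erg_spectrum"
  )
}

#' Isolate oscillatory potentials by a zero-phase spectral split
#'
#' Separates the averaged response into a slow (OP-removed) waveform and the
#' isolated OPs by an exact partition of DFT bins: bins strictly below the
#' cutoff go to `slow`, bins at/above it to `ops`. Symmetric bin masking
#' makes the filter zero-phase, and because the partition is exact,
#' `slow + ops` reconstructs the input to floating tolerance (the removed
#' mean is added back to `slow`). In adaptive mode the cutoff is placed at
#' the spectral minimum inside `op_adaptive_search_hz` (the trough between
#' b-wave energy and OP energy); if the spectrum is monotone there, the fixed
#' cutoff is used as fallback.
#'
#' @param w An `erg_waveform`.
#' @param config An [erg_config()]; fields `op_split_mode`,
#'   `op_fixed_cutoff_hz`, `op_adaptive_search_hz` are used.
#' @return Object of class `erg_filtered_pair`: list with `slow`, `ops`
#'   (numeric vectors, uV), `cutoff_hz` actually used, and the waveform's
#'   provenance fields.
#' @export
isolate_ops <- function(w, config = erg_config()) {
  stopifnot(inherits(w, "erg_waveform"))
  n <- length(w$trace)
  fs <- w$sampling_rate
  cutoff <- config$op_fixed_cutoff_hz
  if (config$op_split_mode == "adaptive") {
    spec <- erg_spectrum(w)
    lo <- config$op_adaptive_search_hz[1]
    hi <- config$op_adaptive_search_hz[2]
    in_band <- which(spec$frequencies >= lo & spec$frequencies <= hi)
    if (length(in_band) >= 3L) {
      m <- spec$magnitudes[in_band]
      i_min <- which.min(m)
      # interior minimum only: a monotone spectrum has no OP/b-wave trough
      if (i_min > 1L && i_min < length(in_band)) {
        cutoff <- spec$frequencies[in_band[i_min]]
      }
    }
  }
  mu <- mean(w$trace)
  x <- w$trace - mu
  X <- stats::fft(x)
  freqs_all <- (seq_len(n) - 1) * fs / n
  freqs_all[freqs_all > fs / 2] <- fs - freqs_all[freqs_all > fs / 2]
  low_mask <- freqs_all < cutoff
  slow <- Re(stats::fft(X * low_mask, inverse = TRUE)) / n + mu
  ops <- Re(stats::fft(X * !low_mask, inverse = TRUE)) / n
  structure(
    list(slow = slow, ops = ops, cutoff_hz = cutoff,
         animal_id = w$animal_id, eye_id = w$eye_id, genotype = w$genotype,
         condition = w$condition, sampling_rate = fs,
         onset_index = w$onset_index),
    class = "erg_filtered_pair"
  )
}

#' Slow component of a filtered pair as an `erg_waveform`
#' @param pair An `erg_filtered_pair`.
#' @param component "slow" or "ops".
#' @return An `erg_waveform` carrying the selected component.
#' @export
pair_waveform <- function(pair, component = c("slow", "ops")) {
  component <- match.arg(component)
  structure(
    list(animal_id = pair$animal_id, eye_id = pair$eye_id,
         genotype = pair$genotype, condition = pair$condition,
         sampling_rate = pair$sampling_rate, onset_index = pair$onset_index,
         n_sweeps_used = NA_integer_, n_sweeps_rejected = NA_integer_,
         trace = pair[[component]]),
    class = "erg_waveform"
  )
}
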