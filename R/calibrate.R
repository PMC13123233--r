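.calibration_cache <- new.env(parent = emptyenv())

calibration_scale <- function(calibration, adaptation, flash) {
  row <- calibration[calibration$adaptation == adaptation &
                       abs(calibration$flash_strength - flash) < 1e-9, ]
  stopifnot(nrow(row) == 1L)
  c(s_a = row$s_a, s_b = row$s_b, s_op = row$s_op, s_b_la = row$s_b,
    d_a = row$d_a, d_b = row$d_b)
}

# measure every protocol condition of one noise-free "eye" with the
# pipeline's own operators; returns the measures data.frame
measure_noise_free <- function(model, preset, calibration, config) {
  proto <- erg_protocol()
  onset <- default_onset_index(config)
  sets <- lapply(seq_len(nrow(proto)), function(i) {
    scale <- if (is.null(calibration)) NULL else {
      calibration_scale(calibration, proto$adaptation[i],
                        proto$flash_strength[i])
    }
    trace <- model_waveform(model, preset, proto$flash_strength[i],
                            proto$adaptation[i], scale = scale,
                            config = config)
    sweep_set("cal", "cal", preset$genotype,
              stimulus_condition(proto$adaptation[i],
                                 proto$flash_strength[i]),
              matrix(trace, nrow = 1L),
              sampling_rate = config$sampling_rate, onset_index = onset)
  })
  quantify_cohort(sets, config)
}

measured_effects <- function(mut, wt) {
  da_m <- mut[mut$adaptation == "DA", ]
  da_w <- wt[wt$adaptation == "DA", ]
  da_m <- da_m[order(da_m$flash_strength), ]
  da_w <- da_w[order(da_w$flash_strength), ]
  la_m <- mut[mut$adaptation == "LA", ]
  la_w <- wt[wt$adaptation == "LA", ]
  a_ok <- !is.na(da_m$a_amp_uv) & !is.na(da_w$a_amp_uv)
  list(
    flash = da_m$flash_strength,
    ratio_a = ifelse(a_ok, da_m$a_amp_uv / da_w$a_amp_uv, NA_real_),
    ratio_b = da_m$b_amp_uv / da_w$b_amp_uv,
    ratio_op = da_m$op_amp_uv / da_w$op_amp_uv,
    ratio_la = la_m$b_amp_uv / la_w$b_amp_uv,
    dt_a = mean(da_m$a_it_ms[a_ok] - da_w$a_it_ms[a_ok]),
    dt_b = mean(da_m$b_it_ms - da_w$b_it_ms)
  )
}

#' Calibrate a genotype preset against the pipeline's own measurements
#'
#' The presets state effects on the measurement scale (ratios of measured
#' amplitudes, differences of measured implicit times), but the model
#' components couple: the b-wave is measured trough-to-peak, so scaling the
#' a-component moves the measured b amplitude, the rising b-limb shifts the
#' measured a-trough, and the spectral split leaks a little b energy into the
#' OP band. Internal per-flash amplitude multipliers and global latency
#' shifts are therefore solved by a damped fixed-point iteration until the
#' pipeline's own measurements on noise-free traces reproduce the preset
#' targets: per-flash amplitude ratios within 0.2 percent and pooled
#' implicit-time differences within 0.4 ms (implicit times are quantized to
#' the 1.95 ms sample grid, so per-flash time matching is not meaningful;
#' pooling across strengths averages the quantization).
#'
#' Results are cached per (genotype, model, config) within the session.
#'
#' @param model An [erg_model()].
#' @param preset An `erg_preset`.
#' @param config An [erg_config()].
#' @param max_iter Iteration cap (default 60).
#' @return data.frame with one row per protocol condition and columns
#'   `adaptation`, `flash_strength`, `s_a`, `s_b`, `s_op`, `d_a`, `d_b`.
#' @export
calibrate_preset <- function(model, preset, config = erg_config(),
                             max_iter = 60L) {
  key <- paste0(preset$genotype, "|",
                paste(deparse(unclass(model)), collapse = ""), "|",
                paste(deparse(unclass(config)[1:12]), collapse = ""))
  cached <- .calibration_cache[[key]]
  if (!is.null(cached)) return(cached)

  proto <- erg_protocol()
  calib <- data.frame(
    adaptation = proto$adaptation,
    flash_strength = proto$flash_strength,
    s_a = ifelse(proto$adaptation == "DA", preset$k_a, 1),
    s_b = ifelse(proto$adaptation == "DA", preset$k_b, preset$k_b_la),
    s_op = preset$k_op,
    d_a = preset$dt_a_ms,
    d_b = ifelse(proto$adaptation == "DA", preset$dt_b_ms, 0)
  )
  if (preset$genotype == "WT") {
    .calibration_cache[[key]] <- calib
    return(calib)
  }
  wt_cal <- calibrate_preset(model, genotype_preset("WT"), config)
  wt_meas <- measure_noise_free(model, genotype_preset("WT"), wt_cal, config)

  da <- calib$adaptation == "DA"
  la <- !da
  state <- function(cal) {
    mut_meas <- measure_noise_free(model, preset, cal, config)
    eff <- measured_effects(mut_meas, wt_meas)
    amp_errs <- c(
      abs(eff$ratio_a / preset$k_a - 1),
      abs(eff$ratio_b / preset$k_b - 1),
      abs(eff$ratio_op / preset$k_op - 1),
      abs(eff$ratio_la / preset$k_b_la - 1)
    )
    time_a <- abs(eff$dt_a - preset$dt_a_ms)
    time_b <- abs(eff$dt_b - preset$dt_b_ms)
    list(eff = eff,
         amp = max(amp_errs[is.finite(amp_errs)]),
         time = max(0, c(time_a, time_b)[is.finite(c(time_a, time_b))]),
         time_a = time_a, time_b = time_b)
  }
  upd <- function(cur, ratio, target) {
    fac <- target / ratio
    fac[!is.finite(fac)] <- 1
    cur * pmin(pmax(fac, 0.5), 2)
  }
  amp_step <- function(cal, eff) {
    # per-flash multiplicative corrections; DA rows are in ascending
    # flash order in both `cal` and the measured effects
    cal$s_a[da] <- upd(cal$s_a[da], eff$ratio_a, preset$k_a)
    cal$s_b[da] <- upd(cal$s_b[da], eff$ratio_b, preset$k_b)
    cal$s_op[da] <- upd(cal$s_op[da], eff$ratio_op, preset$k_op)
    cal$s_b[la] <- upd(cal$s_b[la], eff$ratio_la, preset$k_b_la)
    cal
  }
  # phase 1: joint iteration. Latency corrections are damped and carry a
  # 0.35 ms deadband (measured implicit times are quantized to the sample
  # grid, so the pooled shift cannot be driven arbitrarily close to the
  # target), and are frozen after a few rounds so amplitudes can settle.
  for (iter in seq_len(min(12L, max_iter))) {
    st <- state(calib)
    if (st$amp < 0.005 && st$time < 0.45) {
      .calibration_cache[[key]] <- calib
      return(calib)
    }
    calib <- amp_step(calib, st$eff)
    if (iter <= 8L) {
      if (is.finite(st$eff$dt_a) && st$time_a > 0.35) {
        calib$d_a[da] <- calib$d_a[da] + 0.6 * (preset$dt_a_ms - st$eff$dt_a)
      }
      if (st$time_b > 0.35) {
        calib$d_b[da] <- calib$d_b[da] + 0.6 * (preset$dt_b_ms - st$eff$dt_b)
      }
    }
  }
  # phase 2: coordinate grid refinement of the latency shifts (the damped
  # update can stall between grid points of the quantized pooled times)
  for (comp in c("d_a", "d_b")) {
    st <- state(calib)
    terr <- if (comp == "d_a") st$time_a else st$time_b
    if (!is.finite(terr) || terr <= 0.35) next
    best_delta <- 0
    best_terr <- terr
    for (delta in seq(-2.1, 2.1, by = 0.15)) {
      cal2 <- calib
      cal2[[comp]][da] <- cal2[[comp]][da] + delta
      st2 <- state(cal2)
      terr2 <- if (comp == "d_a") st2$time_a else st2$time_b
      if (is.finite(terr2) && terr2 < best_terr - 1e-9) {
        best_terr <- terr2
        best_delta <- delta
      }
    }
    calib[[comp]][da] <- calib[[comp]][da] + best_delta
  }
  # phase 3: amplitude-only polish at fixed latencies
  for (iter in seq_len(20L)) {
    st <- state(calib)
    if (st$amp < 0.005) break
    calib <- amp_step(calib, st$eff)
  }
  st <- state(calib)
  if (st$amp > 0.02 || st$time > 0.8) {
    stop("preset calibration for ", preset$genotype,
         " did not converge (amplitude ratio error ", signif(st$amp, 3),
         ", implicit-time error ", signif(st$time, 3), " ms)",
         call. = FALSE)
  }
  .calibration_cache[[key]] <- calib
  calib
}
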