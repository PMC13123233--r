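waveform_columns <- c("animal_id", "eye_id", "genotype", "adaptation",
                      "flash_strength", "sampling_rate", "onset_index",
                      "sweep", "sample_index", "voltage_uv")

measure_columns <- c("animal_id", "eye_id", "genotype", "adaptation",
                     "flash_log_cdsm2", "baseline_uv", "a_amp_uv", "a_it_ms",
                     "b_amp_uv", "b_it_ms", "op_amp_uv", "flags")

#' Read sweep sets from a long-format waveform table
#'
#' The table is delimiter-separated UTF-8 text ('.' decimal) with header
#' columns `animal_id, eye_id, genotype, adaptation, flash_strength,
#' sampling_rate, onset_index, sweep, sample_index, voltage_uv` — one row per
#' sample. `sample_index` is 0-based; `sweep` is 1-based. The stimulus onset
#' is taken from the `onset_index` metadata column, never assumed.
#'
#' @param path Path to a CSV/TSV file (gz/bz2 variants accepted by fread).
#' @param config An [erg_config()] (reserved for dialect options).
#' @return Named list of `erg_sweepset`, one per eye x condition, sweeps
#'   ordered by sweep index; names are `animal/eye/adaptation@flash`.
#' @export
read_waveforms <- function(path, config = erg_config()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  missing_cols <- setdiff(waveform_columns, names(dt))
  if (length(missing_cols)) {
    stop("waveform table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_gt <- setdiff(unique(dt$genotype), erg_genotypes())
  if (length(bad_gt)) {
    stop("unknown genotype label(s): ", paste(bad_gt, collapse = ", "),
         call. = FALSE)
  }
  split_keys <- c("animal_id", "eye_id", "genotype", "adaptation",
                  "flash_strength", "sampling_rate", "onset_index")
  groups <- split(dt, by = split_keys, drop = TRUE)
  out <- lapply(groups, function(g) {
    data.table::setorderv(g, c("sweep", "sample_index"))
    lens <- g[, .N, by = "sweep"]$N
    if (length(unique(lens)) != 1L) {
      stop("ragged sweep lengths for eye ", g$eye_id[1], " at ",
           g$adaptation[1], " ", g$flash_strength[1], " log cd.s/m2",
           call. = FALSE)
    }
    traces <- matrix(g$voltage_uv, nrow = length(lens), ncol = lens[1],
                     byrow = TRUE)
    onset <- unique(g$onset_index)
    if (length(onset) != 1L || is.na(onset)) {
      stop("stimulus onset not inferable from metadata for eye ",
           g$eye_id[1], call. = FALSE)
    }
    sweep_set(
      animal_id = g$animal_id[1], eye_id = g$eye_id[1],
      genotype = g$genotype[1],
      condition = stimulus_condition(g$adaptation[1], g$flash_strength[1]),
      traces = traces,
      sampling_rate = g$sampling_rate[1],
      onset_index = onset
    )
  })
  names(out) <- vapply(out, function(s) {
    paste(s$animal_id, s$eye_id, condition_key(s$condition), sep = "/")
  }, character(1))
  out[order(names(out))]
}

#' Write sweep sets to a long-format waveform table
#'
#' Inverse of [read_waveforms()]. Voltages are serialized with 17 significant
#' digits so a write -> read round trip reproduces traces bit-exactly.
#'
#' @param sweepsets List of `erg_sweepset`.
#' @param path Output path (.csv).
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(sweepsets, path) {
  if (inherits(sweepsets, "erg_sweepset")) sweepsets <- list(sweepsets)
  stopifnot(length(sweepsets) >= 1L)
  parts <- lapply(sweepsets, function(s) {
    n_sweep <- nrow(s$traces); n_samp <- ncol(s$traces)
    data.table::data.table(
      animal_id = s$animal_id,
      eye_id = s$eye_id,
      genotype = s$genotype,
      adaptation = s$condition$adaptation,
      flash_strength = s$condition$flash_strength,
      sampling_rate = s$sampling_rate,
      onset_index = s$onset_index,
      sweep = rep(seq_len(n_sweep), each = n_samp),
      sample_index = rep(seq_len(n_samp) - 1L, times = n_sweep),
      voltage_uv = sprintf("%.17g", as.vector(t(s$traces)))
    )
  })
  dt <- data.table::rbindlist(parts)
  data.table::setorderv(dt, c("animal_id", "eye_id", "adaptation",
                              "flash_strength", "sweep", "sample_index"))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Write component measures to CSV
#'
#' One row per eye x condition with fixed column order
#' `animal_id, eye_id, genotype, adaptation, flash_log_cdsm2, baseline_uv,
#' a_amp_uv, a_it_ms, b_amp_uv, b_it_ms, op_amp_uv, flags`; absent values
#' (e.g. the a-wave at the two weakest flashes, or LA OP fields) are rendered
#' as empty cells. Rows are ordered by (animal, eye, adaptation, flash).
#'
#' @param measures data.frame as returned by [quantify_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measures <- function(measures, path) {
  stopifnot(is.data.frame(measures), nrow(measures) >= 1L)
  dt <- data.table::as.data.table(measures)
  names(dt)[names(dt) == "flash_strength"] <- "flash_log_cdsm2"
  missing_cols <- setdiff(measure_columns, names(dt))
  if (length(missing_cols)) {
    stop("measures table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt <- dt[, measure_columns, with = FALSE]
  data.table::setorderv(dt, c("animal_id", "eye_id", "adaptation",
                              "flash_log_cdsm2"))
  for (col in c("baseline_uv", "a_amp_uv", "a_it_ms", "b_amp_uv", "b_it_ms",
                "op_amp_uv")) {
    v <- dt[[col]]
    data.table::set(dt, j = col,
                    value = ifelse(is.na(v), "", sprintf("%.17g", v)))
  }
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read a component-measures CSV written by [write_measures()]
#' @param path Path to the CSV.
#' @return data.frame with numeric measure columns (NA for absent values) and
#'   a `flash_strength` column in log cd.s/m2.
#' @export
read_measures <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    character = c("animal_id", "eye_id", "genotype", "adaptation", "flags")))
  missing_cols <- setdiff(measure_columns, names(dt))
  if (length(missing_cols)) {
    stop("measures table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("baseline_uv", "a_amp_uv", "a_it_ms", "b_amp_uv", "b_it_ms",
                "op_amp_uv")) {
    data.table::set(dt, j = col, value = as.numeric(dt[[col]]))
  }
  df <- as.data.frame(dt)
  names(df)[names(df) == "flash_log_cdsm2"] <- "flash_strength"
  df
}
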