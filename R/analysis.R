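measure_param_column <- function(parameter) {
  switch(parameter,
    a_amp = "a_amp_uv", b_amp = "b_amp_uv", op_amp = "op_amp_uv",
    la_b_amp = "b_amp_uv", a_it = "a_it_ms", b_it = "b_it_ms",
    la_b_it = "b_it_ms",
    stop("unknown parameter: ", parameter, call. = FALSE))
}

parameter_is_amplitude <- function(parameter) {
  parameter %in% c("a_amp", "b_amp", "op_amp", "la_b_amp")
}

parameter_adaptation <- function(parameter) {
  if (startsWith(parameter, "la_")) "LA" else "DA"
}

#' Collapse eye-level measures to animal means
#'
#' Averages the measures of the two recorded eyes of each animal within each
#' condition, switching the analysis unit from eye to animal.
#'
#' @param measures Measures data.frame from [quantify_cohort()].
#' @return data.frame of the same layout with one row per animal x condition
#'   (`eye_id` set to `"both"`).
#' @export
collapse_to_animal <- function(measures) {
  keys <- c("animal_id", "genotype", "adaptation", "flash_strength")
  dt <- data.table::as.data.table(measures)
  num_cols <- intersect(
    c("baseline_uv", "a_amp_uv", "a_it_ms", "b_amp_uv", "b_it_ms",
      "op_amp_uv"), names(dt))
  out <- dt[, lapply(.SD, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }), by = keys, .SDcols = num_cols]
  out[, c("eye_id", "flags") := list("both", "")]
  as.data.frame(out)
}

extract_parameter <- function(measures, parameter, unit = "eye") {
  if (unit == "animal") measures <- collapse_to_animal(measures)
  col <- measure_param_column(parameter)
  adapt <- parameter_adaptation(parameter)
  sub <- measures[measures$adaptation == adapt, , drop = FALSE]
  if (parameter %in% c("a_amp", "a_it")) {
    # a-waves are only measurable at -1.7 log cd.s/m2 and above; rare
    # spurious detections at the weakest flashes are excluded from group
    # analyses so strata always exist in both groups
    sub <- sub[sub$flash_strength %in% a_wave_flash_strengths(), ,
               drop = FALSE]
  }
  data.frame(
    animal_id = sub$animal_id, eye_id = sub$eye_id, genotype = sub$genotype,
    flash_strength = sub$flash_strength, value = sub[[col]],
    stringsAsFactors = FALSE
  )
}

#' Normalize measures to the wild-type littermate group
#'
#' Amplitude parameters are expressed per flash strength as percent of the
#' WT group mean (WT mean = 100 percent); implicit-time parameters as the
#' difference from the WT group mean in ms (WT mean = 0 ms). Per-value
#' results are pooled per genotype as the mean across flash strengths of the
#' per-strength group means — the single-number effect summary used for
#' model comparison.
#'
#' @param measures Measures data.frame containing a WT group and at least one
#'   mutant group (WT rows are the reference and are also normalized, so WT
#'   renormalizes to exactly 100 / 0).
#' @param parameter One of `a_amp`, `b_amp`, `op_amp`, `la_b_amp` (percent of
#'   WT) or `a_it`, `b_it`, `la_b_it` (delta ms).
#' @param unit Analysis unit, "eye" or "animal".
#' @return List with `values` (per analysis-unit normalized values), `pooled`
#'   (per genotype: pooled estimate, SD and SEM across units of unit-level
#'   pooled values, n), and `unit`/`parameter` metadata.
#' @export
normalize_to_wt <- function(measures, parameter, unit = c("eye", "animal")) {
  unit <- match.arg(unit)
  df <- extract_parameter(measures, parameter, unit)
  df <- df[!is.na(df$value), , drop = FALSE]
  if (!any(df$genotype == "WT")) {
    stop("no WT reference group in the measures", call. = FALSE)
  }
  is_amp <- parameter_is_amplitude(parameter)
  out <- NULL
  for (f in sort(unique(df$flash_strength))) {
    stratum <- df[df$flash_strength == f, , drop = FALSE]
    wt <- stratum$value[stratum$genotype == "WT"]
    if (!length(wt)) {
      stop("WT group empty at flash strength ", f, " log cd.s/m2",
           call. = FALSE)
    }
    wt_mean <- mean(wt)
    if (is_amp) {
      if (wt_mean <= 0) {
        stop("non-positive WT mean amplitude at flash strength ", f,
             " log cd.s/m2", call. = FALSE)
      }
      stratum$norm <- stratum$value / wt_mean * 100
    } else {
      stratum$norm <- stratum$value - wt_mean
    }
    out <- rbind(out, stratum)
  }
  # pooled per genotype: mean across strengths of per-strength group means
  strength_means <- stats::aggregate(norm ~ genotype + flash_strength,
                                     data = out, FUN = mean)
  pooled_mean <- stats::aggregate(norm ~ genotype, data = strength_means,
                                  FUN = mean)
  names(pooled_mean)[2] <- "pooled"
  # dispersion across analysis units of unit-level across-strength means
  unit_means <- stats::aggregate(
    norm ~ genotype + animal_id + eye_id, data = out, FUN = mean)
  disp <- do.call(rbind, lapply(split(unit_means, unit_means$genotype),
    function(g) data.frame(genotype = g$genotype[1],
                           sd = stats::sd(g$norm),
                           sem = stats::sd(g$norm) / sqrt(nrow(g)),
                           n = nrow(g))))
  pooled <- merge(pooled_mean, disp, by = "genotype")
  list(values = out, pooled = pooled, unit = unit, parameter = parameter,
       scale = if (is_amp) "percent_of_wt" else "delta_ms")
}

#' Pooled littermate-normalized effect for one genotype
#'
#' Convenience wrapper around [normalize_to_wt()] returning the single pooled
#' number for one mutant genotype: mean percent of WT (amplitudes) or mean
#' delta ms (implicit times) across flash strengths.
#'
#' @inheritParams normalize_to_wt
#' @param genotype Mutant genotype to extract.
#' @return Numeric scalar.
#' @export
pooled_effect <- function(measures, parameter, genotype, unit = "eye") {
  res <- normalize_to_wt(measures, parameter, unit)
  row <- res$pooled[res$pooled$genotype == genotype, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("genotype ", genotype, " not present in measures", call. = FALSE)
  }
  row$pooled
}

#' Cross-model summary table
#'
#' Pooled littermate-normalized effects (percent of WT for amplitudes, delta
#' ms for implicit times) per genotype x parameter, with SEM across analysis
#' units, ordered by genotype severity. WT reference rows are dropped
#' (reference only). Each mutant genotype is normalized against its own WT
#' littermate arm: pass a named list of measures data.frames, one per arm.
#'
#' @param arms Named list of measures data.frames, each holding one mutant
#'   genotype plus its WT littermates; names are the mutant genotypes.
#' @param parameters Character vector of parameters to summarize.
#' @param unit Analysis unit.
#' @return data.frame with columns `genotype`, `parameter`, `scale`,
#'   `pooled`, `sem`, `n`, ordered mdx, mdx5Cv, mdx2Cv, mdx52, dmd_null.
#' @export
summarize_models <- function(arms,
                             parameters = c("a_amp", "b_amp", "op_amp",
                                            "la_b_amp", "a_it", "b_it"),
                             unit = "eye") {
  stopifnot(is.list(arms), length(arms) >= 1L, !is.null(names(arms)))
  severity <- c("mdx", "mdx5Cv", "mdx2Cv", "mdx52", "dmd_null")
  rows <- list()
  for (gt in intersect(severity, names(arms))) {
    for (p in parameters) {
      res <- tryCatch(normalize_to_wt(arms[[gt]], p, unit),
                      error = function(e) NULL)
      if (is.null(res)) next
      r <- res$pooled[res$pooled$genotype == gt, , drop = FALSE]
      if (!nrow(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = gt, parameter = p, scale = res$scale,
        pooled = r$pooled, sem = r$sem, n = r$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$genotype <- factor(out$genotype, levels = severity)
  out[order(out$genotype, match(out$parameter, parameters)), , drop = FALSE]
}
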