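#' Quantify a littermate arm (mutant cohort + WT controls)
#'
#' @param arm List with elements `mutant` and `wt`, each a list of
#'   `erg_sweepset` (as produced by [generate_arm()]).
#' @param config An [erg_config()].
#' @return Combined measures data.frame for both cohorts.
#' @export
arm_measures <- function(arm, config = erg_config()) {
  rbind(quantify_cohort(arm$mutant, config),
        quantify_cohort(arm$wt, config))
}

#' Pooled littermate-normalized effects of one mutant genotype
#'
#' Runs per-strength normalization and across-strength pooling for the five
#' headline parameters and returns them on the scale the results are usually
#' reported on: percent reduction vs WT (`100 - pooled %`) for amplitudes,
#' delta ms for implicit times.
#'
#' @param measures Combined measures data.frame (mutant + WT rows).
#' @param genotype Mutant genotype.
#' @param unit Analysis unit.
#' @return Named numeric vector with elements `b_amp_reduction_pct`,
#'   `a_it_delta_ms`, `b_it_delta_ms`, `op_amp_reduction_pct`,
#'   `la_b_amp_reduction_pct`.
#' @export
arm_effects <- function(measures, genotype, unit = "eye") {
  c(
    b_amp_reduction_pct =
      100 - pooled_effect(measures, "b_amp", genotype, unit),
    a_it_delta_ms = pooled_effect(measures, "a_it", genotype, unit),
    b_it_delta_ms = pooled_effect(measures, "b_it", genotype, unit),
    op_amp_reduction_pct =
      100 - pooled_effect(measures, "op_amp", genotype, unit),
    la_b_amp_reduction_pct =
      100 - pooled_effect(measures, "la_b_amp", genotype, unit)
  )
}
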