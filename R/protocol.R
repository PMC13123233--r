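#' Genotype vocabulary
#'
#' The closed set of genotype labels understood by the package. Keeping the
#' vocabulary closed prevents silent group mislabeling during littermate
#' normalization.
#'
#' @return Character vector of valid genotype codes.
#' @export
erg_genotypes <- function() {
  c("WT", "mdx", "mdx5Cv", "mdx2Cv", "mdx52", "dmd_null")
}

#' Flash stimulation protocol table
#'
#' Single source of truth for the dark-adapted (DA) luminance series and the
#' light-adapted (LA) condition: flash strengths in log cd.s/m2, nominal sweep
#' counts and inter-stimulus intervals. The DA series runs five strengths from
#' -3.7 to 0.3 log cd.s/m2 on a dark background; the LA condition is a single
#' 0.3 log cd.s/m2 flash on a 25 cd/m2 rod-suppressing background.
#'
#' @return data.frame with columns `adaptation`, `flash_strength`,
#'   `background_cdm2`, `n_sweeps`, `isi_s`.
#' @export
erg_protocol <- function() {
  data.frame(
    adaptation      = c(rep("DA", 5L), "LA"),
    flash_strength  = c(-3.7, -2.7, -1.7, -0.7, 0.3, 0.3),
    background_cdm2 = c(rep(0, 5L), 25),
    n_sweeps        = c(12L, 10L, 8L, 8L, 4L, 24L),
    isi_s           = c(1, 2, 5, 10, 20, 1),
    stringsAsFactors = FALSE
  )
}

#' DA flash strengths of the protocol
#' @return Numeric vector, log cd.s/m2, ascending.
#' @export
da_flash_strengths <- function() c(-3.7, -2.7, -1.7, -0.7, 0.3)

#' Flash strengths at which a scotopic a-wave is expected to be detectable
#'
#' In all genotypes the a-wave is measurable at -1.7 log cd.s/m2 and above
#' but not at the two weakest flashes.
#' @return Numeric vector, log cd.s/m2.
#' @export
a_wave_flash_strengths <- function() c(-1.7, -0.7, 0.3)

#' Construct a stimulus condition
#'
#' Validates the (adaptation, flash strength) pair against the protocol table
#' and fills in the nominal sweep count, inter-stimulus interval and
#' background luminance.
#'
#' @param adaptation "DA" or "LA".
#' @param flash_strength Flash strength in log cd.s/m2; must be one of the
#'   protocol strengths for the given adaptation state.
#' @return Object of class `erg_condition`: a list with fields `adaptation`,
#'   `flash_strength`, `background_cdm2`, `n_sweeps_nominal`, `isi_s`.
#' @examples
#' stimulus_condition("DA", -0.7)  # 8 sweeps, 10 s ISI
#' @export
stimulus_condition <- function(adaptation, flash_strength) {
  adaptation <- match.arg(adaptation, c("DA", "LA"))
  proto <- erg_protocol()
  row <- proto[proto$adaptation == adaptation &
                 abs(proto$flash_strength - flash_strength) < 1e-9, ]
  if (nrow(row) != 1L) {
    stop("flash strength ", flash_strength, " log cd.s/m2 is not part of the ",
         adaptation, " protocol", call. = FALSE)
  }
  structure(
    list(
      adaptation = adaptation,
      flash_strength = row$flash_strength,
      background_cdm2 = row$background_cdm2,
      n_sweeps_nominal = row$n_sweeps,
      isi_s = row$isi_s
    ),
    class = "erg_condition"
  )
}

condition_key <- function(condition) {
  paste0(condition$adaptation, "@", format(condition$flash_strength, nsmall = 1))
}
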