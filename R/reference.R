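#' Reference allocation grid for the demonstration cohort
#'
#' Expected outcome symbols for patients 1-8 of [fixture_cohort()] under
#' the six shipped protocols at capacity 3 with the fixture arrival order:
#' `***` allocated, `**` tied but lost the tie-break, `*` qualified but
#' allocation undetermined, `O` no ventilator. This grid is the calibration
#' target the shipped rule-set parameters were reconstructed against (the
#' source protocols are only qualitatively described, so exact point values
#' were recovered by grid search; see [calibrate()]); patient 9's outcomes
#' are deliberately absent (undefined in the reference, so never asserted).
#'
#' @return An 8-row tibble: `patient`, `age`, `sex`, `sofa`, then one
#'   symbol column per protocol id.
#' @export
reference_allocation <- function() {
  tibble::tibble(
    patient = 1:8,
    age = c(45L, 65L, 27L, 50L, 92L, 40L, 28L, 57L),
    sex = c("F", "M", "F", "M", "M", "M", "F", "M"),
    sofa = c(14L, 10L, 10L, 6L, 4L, 8L, 5L, 2L),
    MD = c("O", "O", "***", "O", "**", "***", "***", "O"),
    PA = c("O", "O", "O", "***", "***", "O", "***", "O"),
    FL = c("O", "O", "O", "***", "***", "O", "***", "O"),
    NY = c("O", "O", "O", "**", "***", "O", "***", "***"),
    CA = c("***", "O", "***", "O", "O", "O", "***", "O"),
    NE = c("O", "O", "O", "*", "*", "*", "*", "*")
  )
}
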