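# SOFA (Sequential Organ Failure Assessment) calculator.
#
# Six organ systems, each subscored 0-4; the 0-24 total is the acute-illness
# severity input every shipped triage protocol consumes. Thresholds follow
# the standard published SOFA table and are shipped as a versioned CSV so an
# alternative dialect can be swapped in. Respiration subscores 3-4 assume
# ventilatory support is in place (the cohort here is by construction
# patients needing ventilation); renal scoring takes the worse of the
# creatinine and urine-output criteria.

.sofa_systems <- c("respiration", "coagulation", "liver", "cardiovascular",
                   "cns", "renal")

.sofa_cache <- new.env(parent = emptyenv())

#' The SOFA component threshold table
#'
#' @param path optional path to an alternative threshold CSV with columns
#'   `system, measure, unit, lower, upper, score`; intervals are
#'   `[lower, upper)`.
#' @return A tibble of scoring intervals per organ-system measure.
#' @export
sofa_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.sofa_cache$thresholds)) {
      path <- system.file("extdata", "sofa_thresholds.csv",
                          package = "triagesim", mustWork = TRUE)
      .sofa_cache$thresholds <- tibble::as_tibble(
        utils::read.csv(path, stringsAsFactors = FALSE))
    }
    return(.sofa_cache$thresholds)
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

.lookup_score <- function(thresholds, system, measure, value) {
  rows <- thresholds[thresholds$system == system &
                       thresholds$measure == measure, ]
  hit <- rows$lower <= value & value < rows$upper
  if (!any(hit)) {
    stop_validation(sprintf("value %s outside the scored range for %s/%s",
                            value, system, measure))
  }
  as.integer(rows$score[hit][1])
}

#' Score one SOFA organ system
#'
#' Maps a physiological measurement to its 0-4 subscore. The measurement
#' per system: `respiration` PaO2/FiO2 ratio (mmHg); `coagulation`
#' platelets (10^3/uL); `liver` bilirubin (mg/dL); `cns` Glasgow Coma Scale
#' (3-15); `cardiovascular` mean arterial pressure (mmHg), overridden by a
#' vasopressor requirement when one is given; `renal` creatinine (mg/dL),
#' combined with 24 h urine output when supplied (the worse criterion
#' governs). Scores are monotone in severity.
#'
#' @param system one of `"respiration"`, `"coagulation"`, `"liver"`,
#'   `"cardiovascular"`, `"cns"`, `"renal"`.
#' @param value the measurement for that system (see Details).
#' @param vasopressor cardiovascular only: one of `"dopamine"`,
#'   `"dobutamine"`, `"epinephrine"`, `"norepinephrine"`.
#' @param dose vasopressor dose in ug/kg/min (required with `vasopressor`
#'   except dobutamine).
#' @param urine_output renal only: 24 h urine output in mL.
#' @param thresholds the threshold table (defaults to the shipped dialect).
#' @return Integer subscore in 0-4.
#' @examples
#' component_score("coagulation", 250)  # normal platelets -> 0
#' component_score("renal", 6.1)        # creatinine 6.1 mg/dL -> 4
#' component_score("cardiovascular", 80, vasopressor = "norepinephrine",
#'                 dose = 0.2)          # high-dose pressor -> 4
#' @export
component_score <- function(system, value = NULL, vasopressor = NULL,
                            dose = NULL, urine_output = NULL,
                            thresholds = sofa_thresholds()) {
  if (length(system) != 1 || !system %in% .sofa_systems) {
    stop_validation(paste0("unknown organ system: ", system,
                           " (expected one of ",
                           paste(.sofa_systems, collapse = ", "), ")"))
  }
  check_value <- function(v, what, min_ok = 0) {
    if (is.null(v) || length(v) != 1 || is.na(v) || !is.numeric(v) ||
        v < min_ok) {
      stop_validation(sprintf("non-physiological %s for system '%s'",
                              what, system))
    }
    v
  }
  switch(system,
    respiration = .lookup_score(thresholds, "respiration", "pao2_fio2_ratio",
                                check_value(value, "PaO2/FiO2 ratio")),
    coagulation = .lookup_score(thresholds, "coagulation", "platelets",
                                check_value(value, "platelet count")),
    liver = .lookup_score(thresholds, "liver", "bilirubin",
                          check_value(value, "bilirubin")),
    cns = {
      v <- check_value(value, "Glasgow Coma Scale", min_ok = 3)
      if (v > 15 || v != round(v)) {
        stop_validation("Glasgow Coma Scale must be an integer in 3-15")
      }
      .lookup_score(thresholds, "cns", "glasgow_coma_scale", v)
    },
    cardiovascular = {
      if (!is.null(vasopressor)) {
        .vasopressor_score(vasopressor, dose)
      } else {
        .lookup_score(thresholds, "cardiovascular", "mean_arterial_pressure",
                      check_value(value, "mean arterial pressure"))
      }
    },
    renal = {
      scores <- integer(0)
      if (!is.null(value)) {
        scores <- c(scores, .lookup_score(
          thresholds, "renal", "creatinine",
          check_value(value, "creatinine")))
      }
      if (!is.null(urine_output)) {
        scores <- c(scores, .lookup_score(
          thresholds, "renal", "urine_output",
          check_value(urine_output, "urine output")))
      }
      if (length(scores) == 0) {
        stop_validation("renal scoring needs creatinine and/or urine_output")
      }
      max(scores)  # worse criterion governs
    }
  )
}

.vasopressor_score <- function(vasopressor, dose) {
  vp <- match.arg(vasopressor, c("dopamine", "dobutamine", "epinephrine",
                                 "norepinephrine"))
  if (vp == "dobutamine") {
    return(2L)
  }
  if (is.null(dose) || length(dose) != 1 || is.na(dose) || dose <= 0) {
    stop_validation("vasopressor dose (ug/kg/min, > 0) required")
  }
  if (vp == "dopamine") {
    if (dose <= 5) 2L else if (dose <= 15) 3L else 4L
  } else {
    if (dose <= 0.1) 3L else 4L
  }
}

#' Bundle six SOFA subscores
#'
#' @param respiration,coagulation,liver,cardiovascular,cns,renal integer
#'   subscores, each in 0-4.
#' @return A named integer vector of class `sofa_components`.
#' @export
sofa_components <- function(respiration = 0, coagulation = 0, liver = 0,
                            cardiovascular = 0, cns = 0, renal = 0) {
  x <- c(respiration = respiration, coagulation = coagulation, liver = liver,
         cardiovascular = cardiovascular, cns = cns, renal = renal)
  if (anyNA(x) || any(x != round(x)) || any(x < 0) || any(x > 4)) {
    stop_validation("each SOFA subscore must be an integer in 0-4")
  }
  structure(setNames(as.integer(x), names(x)), class = "sofa_components")
}

#' Total SOFA score
#'
#' Sum of the six organ-system subscores; ranges 0 (no organ failure) to 24
#' (maximal failure in all six systems).
#'
#' @param components a [sofa_components()] object or a named numeric vector
#'   of the six subscores.
#' @return Integer total in 0-24.
#' @examples
#' total_sofa(sofa_components(cns = 1, renal = 4))
#' @export
total_sofa <- function(components) {
  if (!inherits(components, "sofa_components")) {
    components <- do.call(sofa_components, as.list(components))
  }
  sum(unclass(components))
}
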