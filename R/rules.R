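# Rule-set evaluation: exclusion screening, priority scoring with an
# itemized audit trace, and ranking a cohort into ordered priority groups.

.as_patient <- function(patient) {
  if (is.data.frame(patient)) {
    if (nrow(patient) != 1) {
      stop_contract("patient must be a single record (one row)")
    }
    patient <- as.list(patient)
  }
  patient
}

.band_points <- function(bands, value) {
  hit <- bands$min <= value & value <= bands$max
  if (!any(hit)) {
    return(NULL)
  }
  list(points = as.integer(bands$points[which(hit)[1]]),
       band = bands[which(hit)[1], ])
}

.is_frontline <- function(occupation) {
  occupation %in% c("healthcare_worker", "first_responder")
}

.new_assignment <- function(id, status, score = NULL, trace = character(),
                            terms = NULL) {
  structure(
    list(id = id, status = status, score = score, trace = trace,
         terms = terms),
    class = "sra_assignment")
}

#' Screen a patient against a protocol's exclusion rules
#'
#' A patient is excluded iff their comorbidity is on the protocol's
#' exclusion list, their SOFA total crosses the protocol's SOFA exclusion
#' threshold, or a qualification cutoff is set and not met (qualify only if
#' `sofa_total < cutoff`). The trace records the triggering rule.
#'
#' @param ruleset an `sra_protocol` (or protocol id).
#' @param patient a single patient record (one-row data frame or list).
#' @return An `sra_assignment` with status `"excluded"` or `"eligible"`
#'   (status only; no score).
#' @examples
#' screen_exclusions("FL", fixture_cohort()[8, ])$status  # excluded
#' screen_exclusions("NY", fixture_cohort()[8, ])$status  # eligible
#' @export
screen_exclusions <- function(ruleset, patient) {
  rs <- load_protocol(ruleset)
  p <- .as_patient(patient)
  if (p$comorbidity %in% rs$excluded_comorbidities) {
    return(.new_assignment(
      p$id, "excluded",
      trace = sprintf("excluded: comorbidity '%s' is on the exclusion list",
                      p$comorbidity)))
  }
  if (!is.null(rs$sofa_exclusion)) {
    se <- rs$sofa_exclusion
    crossed <- if (se$comparator == ">") {
      p$sofa_total > se$cutoff
    } else {
      p$sofa_total >= se$cutoff
    }
    if (crossed) {
      return(.new_assignment(
        p$id, "excluded",
        trace = sprintf("excluded: SOFA %d %s %d", p$sofa_total,
                        se$comparator, se$cutoff)))
    }
  }
  if (!is.null(rs$qualification_sofa_cutoff) &&
      p$sofa_total >= rs$qualification_sofa_cutoff) {
    return(.new_assignment(
      p$id, "excluded",
      trace = sprintf("excluded: SOFA %d does not meet qualification (< %d)",
                      p$sofa_total, rs$qualification_sofa_cutoff)))
  }
  .new_assignment(p$id, "eligible",
                  trace = "passed exclusion screening")
}

#' Compute a patient's priority assignment under a protocol
#'
#' Applies exclusion screening, then the frontline-exemption policy, then
#' the additive priority score: SOFA-band points, comorbidity points (by
#' severity class, with per-code overrides), age-band points, and the
#' pregnancy modifier. Lower score = higher priority. The trace itemizes
#' every term and the returned `terms` vector satisfies
#' `sum(terms) == score` (self-audit invariant).
#'
#' @inheritParams screen_exclusions
#' @return An `sra_assignment`: status `"excluded"`, `"exempt_frontline"`
#'   (no score), or `"eligible"` with an integer score, trace, and terms.
#' @examples
#' compute_priority("CA", fixture_cohort()[1, ])$status  # exempt_frontline
#' compute_priority("PA", fixture_cohort()[7, ])$score   # 1
#' @export
compute_priority <- function(ruleset, patient) {
  rs <- load_protocol(ruleset)
  p <- .as_patient(patient)
  screened <- screen_exclusions(rs, p)
  if (screened$status == "excluded") {
    return(screened)
  }
  if (rs$frontline_policy == "exemption" && .is_frontline(p$occupation)) {
    return(.new_assignment(
      p$id, "exempt_frontline",
      trace = sprintf("exempt from scoring: frontline occupation '%s'",
                      p$occupation)))
  }
  terms <- integer(0)
  trace <- character(0)
  if (!is.null(rs$sofa_bands)) {
    hit <- .band_points(rs$sofa_bands, p$sofa_total)
    if (is.null(hit)) {
      stop_config(sprintf(
        "protocol '%s': SOFA %d of patient %s falls outside sofa_bands coverage",
        rs$id, p$sofa_total, p$id))
    }
    terms["sofa_band"] <- hit$points
    trace <- c(trace, sprintf("SOFA %d in band [%d, %d]: %+d points",
                              p$sofa_total, hit$band$min, hit$band$max,
                              hit$points))
  }
  cp <- rs$comorbidity_points
  com_pts <- if (p$comorbidity %in% names(cp$overrides)) {
    cp$overrides[[p$comorbidity]]
  } else {
    cp$severity[[comorbidity_severity(p$comorbidity)]]
  }
  if (com_pts != 0) {
    terms["comorbidity"] <- com_pts
    trace <- c(trace, sprintf("comorbidity '%s' (%s): %+d points",
                              p$comorbidity,
                              comorbidity_severity(p$comorbidity), com_pts))
  }
  if (!is.null(rs$age_bands)) {
    hit <- .band_points(rs$age_bands, p$age)
    if (is.null(hit)) {
      stop_config(sprintf(
        "protocol '%s': age %d of patient %s falls outside age_bands coverage",
        rs$id, p$age, p$id))
    }
    if (hit$points != 0) {
      terms["age_band"] <- hit$points
      trace <- c(trace, sprintf("age %d in band [%d, %d]: %+d points",
                                p$age, hit$band$min, hit$band$max,
                                hit$points))
    }
  }
  if (!is.null(rs$pregnancy_modifier) && !is.na(p$pregnancy_weeks %||% NA)) {
    terms["pregnancy"] <- rs$pregnancy_modifier
    trace <- c(trace, sprintf("pregnant (%d weeks): %+d points",
                              p$pregnancy_weeks, rs$pregnancy_modifier))
  }
  score <- as.integer(sum(terms))
  trace <- c(trace, sprintf("total priority score: %d (lower = better)",
                            score))
  .new_assignment(p$id, "eligible", score = score, trace = trace,
                  terms = terms)
}

#' Rank a cohort into ordered priority groups
#'
#' Group order: frontline-exempt patients first, then eligible patients
#' grouped by equal score in ascending order (lower = better), then
#' excluded patients in a terminal group. Rule sets with a qualification
#' cutoff, no scoring criteria, and an empty tie-break chain place all
#' qualifying patients in a single undifferentiated `"qualified"` group.
#'
#' @param ruleset an `sra_protocol` (or protocol id).
#' @param cohort a patient cohort tibble.
#' @return An `sra_ranking`: list with `assignments` (tibble of id, status,
#'   score, trace) and `groups` (ordered list of `list(type, score, ids)`).
#' @examples
#' rank_cohort("NY", fixture_cohort())$groups[[1]]$ids  # top group 4,5,7,8
#' @export
rank_cohort <- function(ruleset, cohort) {
  rs <- load_protocol(ruleset)
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  assignments <- lapply(seq_len(n), function(i) {
    compute_priority(rs, cohort[i, ])
  })
  status <- vapply(assignments, `[[`, character(1), "status")
  score <- vapply(assignments, function(a) {
    if (is.null(a$score)) NA_integer_ else a$score
  }, integer(1))
  ids <- cohort$id

  qualification_only <- !is.null(rs$qualification_sofa_cutoff) &&
    length(rs$tiebreak_chain) == 0 && is.null(rs$sofa_bands)

  groups <- list()
  exempt_ids <- ids[status == "exempt_frontline"]
  if (length(exempt_ids) > 0) {
    groups <- c(groups, list(list(type = "exempt", score = NA_integer_,
                                  ids = exempt_ids)))
  }
  elig <- status == "eligible"
  if (any(elig)) {
    if (qualification_only) {
      groups <- c(groups, list(list(type = "qualified", score = NA_integer_,
                                    ids = ids[elig])))
    } else {
      for (s in sort(unique(score[elig]))) {
        groups <- c(groups, list(list(type = "score", score = s,
                                      ids = ids[elig & score == s])))
      }
    }
  }
  excl_ids <- ids[status == "excluded"]
  if (length(excl_ids) > 0) {
    groups <- c(groups, list(list(type = "excluded", score = NA_integer_,
                                  ids = excl_ids)))
  }

  structure(
    list(
      ruleset_id = rs$id,
      cohort_ids = ids,
      assignments = tibble::tibble(
        id = ids, status = status, score = score,
        trace = lapply(assignments, `[[`, "trace")),
      groups = groups,
      qualification_only = qualification_only
    ),
    class = "sra_ranking")
}

#' @export
print.sra_ranking <- function(x, ...) {
  cat(sprintf("<sra_ranking> protocol %s, %d patient(s), %d group(s)\n",
              x$ruleset_id, length(x$cohort_ids), length(x$groups)))
  for (g in x$groups) {
    lab <- if (g$type == "score") sprintf("score %d", g$score) else g$type
    cat(sprintf("  [%s] patients: %s\n", lab, paste(g$ids, collapse = ", ")))
  }
  invisible(x)
}
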