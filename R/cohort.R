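# Patient cohort: data model, demonstration fixture, synthetic generation, I/O.
#
# A cohort is a tibble with one row per patient and columns
#   id, age, sex, sofa_total, comorbidity, pregnancy_weeks, occupation,
#   ses, arrival_rank
# `arrival_rank` (1 = first to present) drives first-come-first-served
# tie-breaks. `ses` is carried as metadata and never consumed by any rule.

.cohort_cols <- c(
  "id", "age", "sex", "sofa_total", "comorbidity", "pregnancy_weeks",
  "occupation", "ses", "arrival_rank"
)

.sex_levels <- c("female", "male")
.occupations <- c("none", "healthcare_worker", "first_responder")
.ses_levels <- c("unspecified", "low")

#' Controlled vocabulary of comorbidity codes
#'
#' Each code carries a severity class used by multi-principle scoring:
#' `none`, `minor`, or `severe_life_limiting`. Dementia defaults to
#' `severe_life_limiting` globally; protocols that treat it as
#' non-qualifying override its points in their own configuration.
#'
#' @return `comorbidity_codes()` returns the character vector of valid codes.
#' @export
comorbidity_codes <- function() {
  names(.comorbidity_severity)
}

.comorbidity_severity <- c(
  none_significant  = "none",
  htn_controlled    = "minor",
  esrd              = "severe_life_limiting",
  dementia          = "severe_life_limiting",
  metastatic_cancer = "severe_life_limiting",
  ms_late_stage     = "severe_life_limiting",
  hf_nyha_iv        = "severe_life_limiting"
)

#' @rdname comorbidity_codes
#' @param code optional code(s); if omitted the full named severity map is
#'   returned.
#' @return `comorbidity_severity()` returns severity class(es).
#' @export
comorbidity_severity <- function(code = NULL) {
  if (is.null(code)) {
    return(.comorbidity_severity)
  }
  bad <- setdiff(code, names(.comorbidity_severity))
  if (length(bad) > 0) {
    stop_validation(paste0("unknown comorbidity code(s): ",
                           paste(bad, collapse = ", ")))
  }
  unname(.comorbidity_severity[code])
}

#' The nine-patient demonstration cohort
#'
#' Nine mock critically ill adults (ages 27-92, SOFA totals 2-14) spanning
#' the comorbidity vocabulary, one 30-week pregnant patient, a nurse and a
#' firefighter as frontline workers, and one low-SES flag. The default
#' arrival order places patient 4 last; the order is an assumption of the
#' shipped scenario (no timestamps exist for the cohort) and can be
#' overridden per scenario via [scenario_config()].
#'
#' @return A 9-row cohort tibble.
#' @examples
#' fixture_cohort()
#' @export
fixture_cohort <- function() {
  cohort <- tibble::tibble(
    id = 1:9,
    age = c(45L, 65L, 27L, 50L, 92L, 40L, 28L, 57L, 75L),
    sex = c("female", "male", "female", "male", "male",
            "male", "female", "male", "female"),
    sofa_total = c(14L, 10L, 10L, 6L, 4L, 8L, 5L, 2L, 8L),
    comorbidity = c("none_significant", "esrd", "none_significant",
                    "htn_controlled", "dementia", "metastatic_cancer",
                    "none_significant", "ms_late_stage", "hf_nyha_iv"),
    pregnancy_weeks = c(NA, NA, 30L, NA, NA, NA, NA, NA, NA),
    occupation = c("healthcare_worker", "none", "none", "none", "none",
                   "none", "first_responder", "none", "none"),
    ses = c("unspecified", "unspecified", "unspecified", "low", "unspecified",
            "unspecified", "unspecified", "unspecified", "unspecified"),
    # patient 4 presents last; calibrated so FCFS tie-breaks reproduce the
    # reference allocation (see reference_allocation())
    arrival_rank = c(1L, 2L, 3L, 9L, 4L, 5L, 6L, 7L, 8L)
  )
  validate_cohort(cohort)
}

#' Validate a patient cohort
#'
#' Checks the cohort invariants: required columns, SOFA totals in 0-24,
#' known comorbidity/occupation/sex/SES codes, pregnancy restricted to
#' females, gestational weeks >= 1, unique positive ids, and arrival ranks
#' forming a permutation of 1..n. Errors name the offending patient record.
#'
#' @param cohort a data frame of patients.
#' @return The cohort as a tibble, invisibly unchanged, for piping.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) {
    stop_validation("cohort must be a data frame")
  }
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(.cohort_cols, names(cohort))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("cohort is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  cohort <- cohort[.cohort_cols]
  n <- nrow(cohort)
  if (n == 0) {
    return(cohort)
  }
  for (col in c("id", "age", "sofa_total", "arrival_rank")) {
    cohort[[col]] <- as.integer(cohort[[col]])
  }
  if (!is.numeric(cohort$pregnancy_weeks) && !all(is.na(cohort$pregnancy_weeks))) {
    stop_validation("pregnancy_weeks must be numeric or missing")
  }
  cohort$pregnancy_weeks <- as.integer(cohort$pregnancy_weeks)
  cohort$ses[is.na(cohort$ses)] <- "unspecified"

  fail_row <- function(i, what) {
    stop_validation(sprintf("patient record %s (row %d): %s",
                            cohort$id[i], i, what))
  }
  if (anyNA(cohort$id) || any(cohort$id <= 0)) {
    stop_validation("patient ids must be positive integers")
  }
  if (anyDuplicated(cohort$id)) {
    stop_validation("patient ids must be unique")
  }
  for (i in seq_len(n)) {
    if (is.na(cohort$age[i]) || cohort$age[i] < 18) {
      fail_row(i, "age must be an adult age (>= 18)")
    }
    if (!cohort$sex[i] %in% .sex_levels) {
      fail_row(i, sprintf("sex '%s' is not one of %s", cohort$sex[i],
                          paste(.sex_levels, collapse = "/")))
    }
    if (is.na(cohort$sofa_total[i]) ||
        cohort$sofa_total[i] < 0 || cohort$sofa_total[i] > 24) {
      fail_row(i, sprintf("sofa_total %s outside 0-24", cohort$sofa_total[i]))
    }
    if (!cohort$comorbidity[i] %in% comorbidity_codes()) {
      fail_row(i, sprintf("unknown comorbidity code '%s'", cohort$comorbidity[i]))
    }
    if (!is.na(cohort$pregnancy_weeks[i])) {
      if (cohort$sex[i] != "female") {
        fail_row(i, "pregnancy_weeks recorded for a non-female patient")
      }
      if (cohort$pregnancy_weeks[i] < 1) {
        fail_row(i, "pregnancy_weeks must be >= 1 when present")
      }
    }
    if (!cohort$occupation[i] %in% .occupations) {
      fail_row(i, sprintf("unknown occupation '%s'", cohort$occupation[i]))
    }
    if (!cohort$ses[i] %in% .ses_levels) {
      fail_row(i, sprintf("unknown ses flag '%s'", cohort$ses[i]))
    }
  }
  if (!setequal(cohort$arrival_rank, seq_len(n)) ||
      anyDuplicated(cohort$arrival_rank)) {
    dup <- cohort$arrival_rank[duplicated(cohort$arrival_rank)]
    if (length(dup) > 0) {
      stop_validation(sprintf(
        "duplicate arrival_rank %s (patients %s)", dup[1],
        paste(cohort$id[cohort$arrival_rank == dup[1]], collapse = ", ")))
    }
    stop_validation("arrival_rank must be a permutation of 1..n")
  }
  cohort
}

.default_prevalences <- c(
  none_significant = 0.40, htn_controlled = 0.25, dementia = 0.10,
  esrd = 0.07, metastatic_cancer = 0.07, ms_late_stage = 0.05,
  hf_nyha_iv = 0.06
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the world the demonstration fixture is drawn from:
#' adults 27-92, SOFA totals uniform on 0-24, a small comorbidity
#' vocabulary with fixture-informed prevalences, pregnancy among
#' reproductive-age (18-45) females at rate 0.10, a 0.20 frontline-worker
#' fraction split evenly between healthcare workers and first responders,
#' and a 0.10 low-SES rate.
#'
#' @param n cohort size (non-negative integer).
#' @param age_range integer vector `c(min, max)`, both adult ages.
#' @param sofa_distribution probability weights over SOFA totals 0-24
#'   (length 25); default uniform.
#' @param comorbidity_prevalences named probabilities over
#'   [comorbidity_codes()], summing to 1.
#' @param pregnancy_rate probability that a female aged 18-45 is pregnant.
#' @param frontline_fraction probability of a frontline occupation.
#' @param ses_low_rate probability of the low-SES flag.
#' @param seed optional RNG seed for [generate_cohort()].
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n,
                          age_range = c(27L, 92L),
                          sofa_distribution = rep(1 / 25, 25),
                          comorbidity_prevalences = .default_prevalences,
                          pregnancy_rate = 0.10,
                          frontline_fraction = 0.20,
                          ses_low_rate = 0.10,
                          seed = NULL) {
  n <- suppressWarnings(as.integer(n))
  if (length(n) != 1 || is.na(n) || n < 0) {
    stop_config("n must be a single non-negative integer")
  }
  age_range <- as.integer(age_range)
  if (length(age_range) != 2 || anyNA(age_range) ||
      age_range[1] > age_range[2] || age_range[1] < 18) {
    stop_config("age_range must be c(min, max) with 18 <= min <= max")
  }
  if (length(sofa_distribution) != 25 || anyNA(sofa_distribution) ||
      any(sofa_distribution < 0) || sum(sofa_distribution) <= 0) {
    stop_config("sofa_distribution must be 25 non-negative weights over 0-24")
  }
  if (!setequal(names(comorbidity_prevalences), comorbidity_codes())) {
    stop_config("comorbidity_prevalences must name every comorbidity code")
  }
  comorbidity_prevalences <- comorbidity_prevalences[comorbidity_codes()]
  if (any(comorbidity_prevalences < 0) ||
      abs(sum(comorbidity_prevalences) - 1) > 1e-8) {
    stop_config("comorbidity_prevalences must be non-negative and sum to 1")
  }
  for (p in c(pregnancy_rate, frontline_fraction, ses_low_rate)) {
    if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop_config("rates must be single probabilities in [0, 1]")
    }
  }
  structure(
    list(
      n = n, age_range = age_range,
      sofa_distribution = sofa_distribution / sum(sofa_distribution),
      comorbidity_prevalences = comorbidity_prevalences,
      pregnancy_rate = pregnancy_rate,
      frontline_fraction = frontline_fraction,
      ses_low_rate = ses_low_rate,
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws `config$n` patients satisfying every cohort invariant:
#' pregnancy only among reproductive-age females, arrival ranks a random
#' permutation of 1..n, SOFA totals from the configured distribution.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A cohort tibble with `config$n` rows.
#' @examples
#' generate_cohort(cohort_config(n = 5, seed = 42))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  n <- config$n
  if (n == 0) {
    empty <- fixture_cohort()[0, ]
    return(empty)
  }
  resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]
  draw <- function() {
    age <- resample(seq(config$age_range[1], config$age_range[2]), n,
                    replace = TRUE)
    sex <- sample(.sex_levels, n, replace = TRUE)
    sofa <- sample(0:24, n, replace = TRUE, prob = config$sofa_distribution)
    comorbidity <- sample(comorbidity_codes(), n, replace = TRUE,
                          prob = config$comorbidity_prevalences)
    eligible_preg <- sex == "female" & age >= 18 & age <= 45
    pregnant <- eligible_preg & runif(n) < config$pregnancy_rate
    pregnancy_weeks <- ifelse(pregnant, sample(1:40, n, replace = TRUE),
                              NA_integer_)
    frontline <- runif(n) < config$frontline_fraction
    occupation <- ifelse(
      frontline,
      sample(c("healthcare_worker", "first_responder"), n, replace = TRUE),
      "none")
    ses <- ifelse(runif(n) < config$ses_low_rate, "low", "unspecified")
    tibble::tibble(
      id = seq_len(n), age = as.integer(age), sex = sex,
      sofa_total = as.integer(sofa), comorbidity = comorbidity,
      pregnancy_weeks = as.integer(pregnancy_weeks), occupation = occupation,
      ses = ses, arrival_rank = sample(seq_len(n)))
  }
  cohort <- if (!is.null(config$seed)) {
    withr::with_seed(config$seed, draw())
  } else {
    draw()
  }
  validate_cohort(cohort)
}

# file column order / names for the on-disk representation
.io_cols <- c("id", "age", "sex", "sofa", "comorbidity", "pregnancy_weeks",
              "occupation", "ses", "arrival_rank")

#' Read and write patient cohorts
#'
#' CSV files use the header
#' `id,age,sex,sofa,comorbidity,pregnancy_weeks,occupation,ses,arrival_rank`
#' with empty fields meaning "absent"; JSON files are an array of objects
#' with the same keys (absent keys omitted). `read_cohort(write_cohort(x))`
#' round-trips field-for-field; invalid records raise a validation error
#' naming the offending patient.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @return `read_cohort()` returns a validated cohort tibble.
#' @export
read_cohort <- function(path, format = c("csv", "json")) {
  format <- .resolve_format(path, format)
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0) {
      raw <- data.frame()
    }
  }
  if (nrow(raw) == 0) {
    return(fixture_cohort()[0, ])
  }
  missing_cols <- setdiff(setdiff(.io_cols, c("pregnancy_weeks", "ses")),
                          names(raw))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("cohort file is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  if (is.null(raw$pregnancy_weeks)) raw$pregnancy_weeks <- NA_integer_
  if (is.null(raw$ses)) raw$ses <- "unspecified"
  names(raw)[names(raw) == "sofa"] <- "sofa_total"
  validate_cohort(raw[, .cohort_cols])
}

#' @rdname read_cohort
#' @param cohort a cohort tibble.
#' @return `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json")) {
  cohort <- validate_cohort(cohort)
  format <- .resolve_format(path, format)
  out <- as.data.frame(cohort)
  names(out)[names(out) == "sofa_total"] <- "sofa"
  out <- out[.io_cols]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    rows <- lapply(seq_len(nrow(out)), function(i) {
      row <- as.list(out[i, ])
      row[!vapply(row, is.na, logical(1))]
    })
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.resolve_format <- function(path, format) {
  if (length(format) == 1) {
    return(match.arg(format, c("csv", "json")))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else "csv"
}
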