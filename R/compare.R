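# Cross-protocol analysis: the patients x protocols allocation matrix,
# concordance metrics, per-patient allocation counts, and Monte-Carlo
# estimation of allocation probability under randomized tie-breaks.

#' Build the patients-by-protocols allocation matrix
#'
#' Runs [rank_cohort()] and [allocate()] for every protocol and assembles
#' the outcome-symbol grid, one row per patient and one column per
#' protocol. The full five-valued status vectors (which distinguish
#' `excluded` from `not_allocated`, both rendered `O`) are kept in the
#' `outcomes` attribute for concordance analysis.
#'
#' @param cohort a patient cohort tibble.
#' @param rulesets list of `sra_protocol` objects, or protocol ids.
#' @param scenario a [scenario_config()].
#' @return An `sra_matrix`: tibble `id, age, sex, sofa` plus one symbol
#'   column per protocol; attributes `outcomes` (named list of full
#'   [allocate()] tibbles) and `provenance` (capacity, seed, cohort hash).
#' @examples
#' build_matrix(fixture_cohort(), list_protocols(), scenario_config())
#' @export
build_matrix <- function(cohort, rulesets = list_protocols(),
                         scenario = scenario_config()) {
  cohort <- validate_cohort(cohort)
  rulesets <- lapply(rulesets, load_protocol)
  ids <- vapply(rulesets, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_config("duplicate protocol ids in rulesets")
  }
  names(rulesets) <- ids
  mat <- tibble::tibble(
    id = cohort$id, age = cohort$age, sex = cohort$sex,
    sofa = cohort$sofa_total)
  outcomes <- list()
  for (pid in ids) {
    ranking <- rank_cohort(rulesets[[pid]], cohort)
    out <- allocate(ranking, rulesets[[pid]], cohort, scenario)
    outcomes[[pid]] <- out
    mat[[pid]] <- out$symbol
  }
  structure(
    mat,
    outcomes = outcomes,
    provenance = list(
      protocols = ids,
      n_ventilators = scenario$n_ventilators,
      rng_seed = scenario$rng_seed,
      cohort_hash = rlang::hash(as.data.frame(cohort))),
    class = c("sra_matrix", class(mat)))
}

.matrix_protocols <- function(matrix) {
  attr(matrix, "provenance")$protocols
}

.matrix_outcomes <- function(matrix) {
  out <- attr(matrix, "outcomes")
  if (is.null(out)) {
    stop_contract("not an allocation matrix built by build_matrix()")
  }
  out
}

#' Per-patient allocation counts across protocols
#'
#' @param matrix an `sra_matrix` from [build_matrix()].
#' @return A tibble `id`, `n_allocated` (protocols giving the patient a
#'   definitive allocation), `n_qualified` (protocols leaving the patient
#'   qualified but undetermined).
#' @export
allocation_counts <- function(matrix) {
  outcomes <- .matrix_outcomes(matrix)
  n_alloc <- rep(0L, nrow(matrix))
  n_qual <- rep(0L, nrow(matrix))
  for (o in outcomes) {
    n_alloc <- n_alloc + (o$status == "allocated")
    n_qual <- n_qual + (o$status == "qualified_undetermined")
  }
  tibble::tibble(
    id = matrix$id,
    n_allocated = as.integer(n_alloc),
    n_qualified = as.integer(n_qual))
}

#' Between-protocol concordance
#'
#' Two protocols are *vector-identical* when their full five-valued status
#' vectors agree for every patient, and *set-identical* when the sets of
#' definitively allocated patients agree. Both are reported: two protocols
#' can allocate to the same patients (identical sets) while disagreeing on
#' why everyone else went without (e.g. excluded vs merely outscored), and
#' the headline "no two protocols agree" claim holds at the vector level.
#'
#' @param matrix an `sra_matrix` with at least two protocol columns.
#' @return An `sra_concordance`: list with `pairs` (tibble of protocol
#'   pairs and both identity flags), `n_pairs`, `n_vector_identical`,
#'   `n_set_identical`, and `per_patient` ([allocation_counts()]).
#' @export
concordance <- function(matrix) {
  outcomes <- .matrix_outcomes(matrix)
  pids <- .matrix_protocols(matrix)
  if (length(pids) < 2) {
    stop_contract("concordance needs at least two protocol columns")
  }
  combos <- utils::combn(pids, 2)
  pairs <- tibble::tibble(
    protocol_a = combos[1, ], protocol_b = combos[2, ],
    vector_identical = logical(ncol(combos)),
    set_identical = logical(ncol(combos)))
  alloc_set <- lapply(outcomes, function(o) o$id[o$status == "allocated"])
  for (i in seq_len(ncol(combos))) {
    a <- combos[1, i]
    b <- combos[2, i]
    pairs$vector_identical[i] <-
      identical(outcomes[[a]]$status, outcomes[[b]]$status)
    pairs$set_identical[i] <- setequal(alloc_set[[a]], alloc_set[[b]])
  }
  structure(
    list(
      pairs = pairs,
      n_pairs = nrow(pairs),
      n_vector_identical = sum(pairs$vector_identical),
      n_set_identical = sum(pairs$set_identical),
      per_patient = allocation_counts(matrix)),
    class = "sra_concordance")
}

#' @export
print.sra_concordance <- function(x, ...) {
  cat(sprintf(
    "<sra_concordance> %d protocol pair(s): %d vector-identical, %d set-identical\n",
    x$n_pairs, x$n_vector_identical, x$n_set_identical))
  invisible(x)
}

#' Monte-Carlo allocation probability under randomized chance elements
#'
#' Estimates each patient's probability of receiving a ventilator under
#' one protocol when the chance elements are randomized across replicates:
#' `"lottery"` redraws every lottery tie-break, `"arrival"` permutes the
#' arrival order uniformly (randomizing FCFS tie-breaks), `"both"` does
#' both. With `"arrival"`, any lottery steps the protocol reaches still
#' draw from the replicate stream (holding them fixed is ill-defined when
#' the tied set changes with the arrival order). Scores and exclusions are
#' deterministic, so an excluded patient's probability is exactly 0.
#' Standard errors use the binomial formula.
#'
#' @param cohort a patient cohort tibble.
#' @param ruleset an `sra_protocol` or protocol id.
#' @param scenario a [scenario_config()]; its seed is ignored in favour of
#'   `seed`.
#' @param n_reps number of replicates (default 10000).
#' @param seed master seed for the replicate stream.
#' @param randomize which chance element(s) to randomize.
#' @return A tibble `id`, `prob`, `se`, `n_reps`.
#' @examples
#' chance_analysis(fixture_cohort(), "NY", scenario_config(),
#'                 n_reps = 200, seed = 7, randomize = "arrival")
#' @export
chance_analysis <- function(cohort, ruleset, scenario = scenario_config(),
                            n_reps = 10000, seed = 1L,
                            randomize = c("lottery", "arrival", "both")) {
  randomize <- match.arg(randomize)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1) {
    stop_config("n_reps must be >= 1")
  }
  rs <- load_protocol(ruleset)
  cohort <- validate_cohort(cohort)
  ranking <- rank_cohort(rs, cohort)
  n <- nrow(cohort)
  base_arrival <- .resolve_arrival(cohort, scenario)
  alloc_count <- setNames(integer(n), cohort$id)
  randomize_arrival <- randomize %in% c("arrival", "both")
  # one seeded stream drives all replicates: lottery draws come from the
  # ambient RNG inside .allocate_impl, arrival permutations from the same
  # stream
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_reps)) {
      arrival <- if (randomize_arrival) {
        setNames(sample.int(n), cohort$id)
      } else {
        base_arrival
      }
      out <- .allocate_impl(ranking, rs, cohort, arrival,
                            scenario$n_ventilators)
      won <- out$status == "allocated"
      alloc_count[won] <- alloc_count[won] + 1L
    }
  })
  prob <- alloc_count / n_reps
  tibble::tibble(
    id = cohort$id,
    prob = unname(prob),
    se = unname(sqrt(prob * (1 - prob) / n_reps)),
    n_reps = n_reps)
}

#' Export an allocation matrix
#'
#' @param matrix an `sra_matrix`.
#' @param path output path.
#' @param format `"csv"` or `"md"` (a Markdown table mirroring the
#'   reference grid layout: Patient, Age, Sex, SOFA, one symbol column per
#'   protocol).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("csv", "md")) {
  format <- match.arg(format)
  df <- as.data.frame(matrix)
  names(df)[1:4] <- c("Patient", "Age", "Sex", "SOFA")
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) {
      paste0("| ", paste(trimws(r), collapse = " | "), " |")
    })
    writeLines(c(header, sep, rows), path)
  }
  invisible(path)
}

#' Export a concordance report as JSON
#'
#' @param report an `sra_concordance`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(report, path) {
  if (!inherits(report, "sra_concordance")) {
    stop_contract("report must come from concordance()")
  }
  out <- list(
    n_pairs = report$n_pairs,
    n_vector_identical = report$n_vector_identical,
    n_set_identical = report$n_set_identical,
    pairs = report$pairs,
    per_patient = report$per_patient)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
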