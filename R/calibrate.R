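# Exhaustive grid search over bounded rule-parameter spaces.
#
# The six source protocols are only qualitatively described, so their point
# values were reconstructed: a candidate grid around each plausible
# parameterization is enumerated in full (no pruning) and every candidate
# whose simulated allocation column equals the target on the compared
# patients is returned. Non-uniqueness is surfaced, never hidden -- the
# result is always the complete solution set over the grid.

#' Define a parameter grid around a base rule set
#'
#' Each grid parameter names a rule-set field and supplies a list of
#' candidate values for it; the grid is the Cartesian product. Candidate
#' values are whole field values (e.g. a full `sofa_bands` data frame, a
#' full `tiebreak_chain` vector), so any bounded discrete neighbourhood can
#' be expressed.
#'
#' @param base an `sra_protocol` (or protocol id) every combination is
#'   derived from.
#' @param params named list; each element is a list of candidate values for
#'   that rule-set field. Empty `params` yields a grid containing only
#'   `base`.
#' @return An `sra_grid` with the combination count precomputed.
#' @examples
#' g <- parameter_grid("NY", list(pregnancy_modifier = list(NULL, -1L, -2L)))
#' grid_size(g)
#' @export
parameter_grid <- function(base, params = list()) {
  base <- load_protocol(base)
  if (length(params) > 0) {
    if (is.null(names(params)) || any(!nzchar(names(params)))) {
      stop_config("params must be a named list of candidate-value lists")
    }
    bad <- setdiff(names(params), names(base))
    if (length(bad) > 0) {
      stop_config(paste0("unknown rule-set field(s) in grid: ",
                         paste(bad, collapse = ", ")))
    }
    if (any(lengths(params) == 0)) {
      stop_config("every grid parameter needs at least one candidate value")
    }
  }
  structure(
    list(base = base, params = params,
         n_combinations = prod(lengths(params))),
    class = "sra_grid")
}

#' @rdname parameter_grid
#' @param grid an `sra_grid`.
#' @return `grid_size()` returns the total combination count.
#' @export
grid_size <- function(grid) {
  if (!inherits(grid, "sra_grid")) {
    stop_contract("grid must come from parameter_grid()")
  }
  grid$n_combinations
}

.grid_ruleset <- function(grid, idx) {
  rs <- grid$base
  for (j in seq_along(idx)) {
    field <- names(grid$params)[j]
    rs[field] <- list(grid$params[[field]][[idx[j]]])
  }
  validate_ruleset(rs)
}

#' Calibrate rule-set parameters against a target allocation column
#'
#' Enumerates every grid combination, simulates it
#' ([rank_cohort()] + [allocate()]), and returns all combinations whose
#' outcome symbols equal the target on the compared patients. Comparison is
#' restricted to the patients named in `target`, so a target that omits a
#' patient (as the reference grid omits patient 9) constrains nothing about
#' them. Combinations that fail rule-set validation (e.g. overlapping
#' bands) cannot be simulated and are counted as invalid.
#'
#' @param grid an [parameter_grid()].
#' @param cohort the cohort the target column was observed on.
#' @param scenario a [scenario_config()] (single protocol run; capacity and
#'   seed taken from here).
#' @param target named character vector of outcome symbols (`***`, `**`,
#'   `*`, `O`), names = patient ids to compare.
#' @param max_grid refuse (with the computed count) if the grid exceeds
#'   this many combinations; enumeration is deliberate brute force.
#' @return An `sra_calibration`: list with `matches` (list of full
#'   `sra_protocol` objects), `n_grid`, `n_invalid`, `n_matches`, `target`.
#' @export
calibrate <- function(grid, cohort, scenario, target, max_grid = 1e6) {
  if (!inherits(grid, "sra_grid")) {
    stop_contract("grid must come from parameter_grid()")
  }
  cohort <- validate_cohort(cohort)
  if (is.null(names(target)) || !all(names(target) %in% as.character(cohort$id))) {
    stop_config("target must be named by patient ids present in the cohort")
  }
  if (!all(target %in% c("***", "**", "*", "O"))) {
    stop_config("target symbols must be drawn from ***, **, *, O")
  }
  n_grid <- grid_size(grid)
  if (n_grid > max_grid) {
    stop_config(sprintf(
      "grid has %s combinations, above the cap of %s; tighten the grid",
      format(n_grid, big.mark = ","), format(max_grid, big.mark = ",")))
  }
  lens <- lengths(grid$params)
  idx_grid <- if (length(lens) == 0) {
    list(integer(0))
  } else {
    do.call(expand.grid, c(lapply(lens, seq_len), KEEP.OUT.ATTRS = FALSE))
  }
  n_combos <- if (is.data.frame(idx_grid)) nrow(idx_grid) else 1L
  matches <- list()
  n_invalid <- 0L
  for (i in seq_len(n_combos)) {
    idx <- if (is.data.frame(idx_grid)) as.integer(idx_grid[i, ]) else integer(0)
    rs <- tryCatch(.grid_ruleset(grid, idx),
                   triagesim_config_error = function(e) NULL)
    if (is.null(rs)) {
      n_invalid <- n_invalid + 1L
      next
    }
    out <- tryCatch({
      ranking <- rank_cohort(rs, cohort)
      allocate(ranking, rs, cohort, scenario)
    }, triagesim_config_error = function(e) NULL)
    if (is.null(out)) {
      n_invalid <- n_invalid + 1L
      next
    }
    got <- setNames(out$symbol, out$id)[names(target)]
    if (all(got == target)) {
      matches[[length(matches) + 1L]] <- rs
    }
  }
  structure(
    list(matches = matches, n_grid = n_grid, n_invalid = n_invalid,
         n_matches = length(matches), target = target),
    class = "sra_calibration")
}

#' @export
print.sra_calibration <- function(x, ...) {
  cat(sprintf(
    "<sra_calibration> %d combination(s) searched (%d invalid): %d match(es)\n",
    x$n_grid, x$n_invalid, x$n_matches))
  invisible(x)
}

#' Round-trip recovery check for the calibration search
#'
#' Simulates `ruleset` on `cohort`, uses its own outcome column as the
#' calibration target, and reports whether [calibrate()] over `grid`
#' returns a solution set containing `ruleset` (compared on the
#' rule-governing fields). A generating rule set must always be in its own
#' solution set when the grid contains it.
#'
#' @param ruleset the generating `sra_protocol` (or id).
#' @param cohort a cohort tibble.
#' @param scenario a [scenario_config()].
#' @param grid an [parameter_grid()] containing `ruleset`.
#' @return `TRUE` iff `ruleset` is among the matches.
#' @export
roundtrip_recovery <- function(ruleset, cohort, scenario, grid) {
  rs <- load_protocol(ruleset)
  cohort <- validate_cohort(cohort)
  ranking <- rank_cohort(rs, cohort)
  out <- allocate(ranking, rs, cohort, scenario)
  target <- setNames(out$symbol, out$id)
  result <- calibrate(grid, cohort, scenario, target)
  fp <- ruleset_fingerprint(rs)
  any(vapply(result$matches, ruleset_fingerprint, character(1)) == fp)
}

#' Default calibration neighbourhood for a shipped protocol
#'
#' A small bounded grid of plausible alternatives around the shipped
#' configuration of `id`: exclusion cutoffs one unit either way, adjacent
#' band cut points, nearby pregnancy modifiers, alternative comorbidity
#' treatment, and alternative tie-break chains. The shipped configuration
#' is always one of the combinations.
#'
#' @param id a shipped protocol id (see [list_protocols()]).
#' @return An `sra_grid`.
#' @export
default_calibration_grid <- function(id) {
  base <- load_protocol(id)
  bands <- function(...) {
    spec <- list(...)
    data.frame(
      min = vapply(spec, `[[`, numeric(1), 1),
      max = vapply(spec, `[[`, numeric(1), 2),
      points = vapply(spec, `[[`, numeric(1), 3))
  }
  params <- switch(id,
    MD = list(
      sofa_exclusion = list(list(comparator = ">", cutoff = 13),
                            list(comparator = ">", cutoff = 14),
                            list(comparator = ">", cutoff = 15)),
      excluded_comorbidities = list(
        c("esrd", "ms_late_stage", "hf_nyha_iv"),
        c("esrd", "ms_late_stage", "hf_nyha_iv", "metastatic_cancer")),
      pregnancy_modifier = list(-1L, -2L, -3L),
      tiebreak_chain = list(c("younger_age", "fcfs"), "fcfs")),
    PA = list(
      sofa_bands = list(
        bands(c(0, 5, 1), c(6, 8, 2), c(9, 11, 3), c(12, 24, 4)),
        bands(c(0, 5, 1), c(6, 9, 2), c(10, 11, 3), c(12, 24, 4))),
      comorbidity_points = list(
        list(severity = c(none = 0, minor = 0, severe_life_limiting = 4),
             overrides = c(dementia = 0)),
        list(severity = c(none = 0, minor = 0, severe_life_limiting = 4),
             overrides = setNames(integer(0), character(0))),
        list(severity = c(none = 0, minor = 0, severe_life_limiting = 3),
             overrides = c(dementia = 0))),
      tiebreak_chain = list(c("younger_age", "frontline", "lottery"),
                            "lottery")),
    FL = list(
      sofa_exclusion = list(list(comparator = ">=", cutoff = 9),
                            list(comparator = ">=", cutoff = 10),
                            list(comparator = ">=", cutoff = 11)),
      excluded_comorbidities = list(
        c("esrd", "metastatic_cancer", "ms_late_stage", "hf_nyha_iv"),
        c("esrd", "ms_late_stage", "hf_nyha_iv")),
      tiebreak_chain = list("fcfs", c("younger_age", "fcfs"))),
    NY = list(
      sofa_exclusion = list(list(comparator = ">", cutoff = 10),
                            list(comparator = ">", cutoff = 11),
                            list(comparator = ">", cutoff = 12)),
      sofa_bands = list(
        bands(c(0, 6, 1), c(7, 11, 2)),
        bands(c(0, 7, 1), c(8, 11, 2)),
        bands(c(0, 8, 1), c(9, 11, 2))),
      tiebreak_chain = list("fcfs", "lottery")),
    CA = list(
      pregnancy_modifier = list(-2L, -3L, -4L),
      frontline_policy = list("exemption", "tiebreak_only"),
      age_bands = list(
        bands(c(18, 49, 0), c(50, 69, 1), c(70, 84, 2), c(85, 130, 3)),
        bands(c(18, 49, 0), c(50, 69, 1), c(70, 130, 2)))),
    NE = list(
      qualification_sofa_cutoff = list(9L, 10L, 11L)),
    stop_config(paste0("no default grid for protocol id '", id, "'")))
  parameter_grid(base, params)
}
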