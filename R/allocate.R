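# Capacity-constrained allocation of ventilators to ranked priority groups.
#
# Groups are served in priority order; a group that fits the remaining
# capacity is wholly allocated; a group straddling the capacity boundary is
# resolved by the protocol's tie-break chain (younger_age -> frontline ->
# fcfs -> lottery, in whatever order the protocol lists). If the chain is
# empty or exhausted with the boundary still tied, the whole straddling
# group is marked qualified_undetermined and no ventilator is assigned from
# it (nor from any lower-priority group: no leapfrogging).

.status_symbols <- c(
  allocated = "***", tied_lost = "**", qualified_undetermined = "*",
  not_allocated = "O", excluded = "O"
)

#' Scenario configuration for an allocation run
#'
#' @param n_ventilators non-negative number of ventilators available
#'   (default 3: the shipped scenario has 3 of 30 ventilators free).
#' @param protocols protocol ids (or paths) to run.
#' @param rng_seed integer seed driving every lottery draw in the scenario.
#' @param arrival_order `NULL` to use the cohort's `arrival_rank` column,
#'   or an explicit vector of patient ids in order of arrival.
#' @return A validated `sra_scenario` list.
#' @export
scenario_config <- function(n_ventilators = 3, protocols = list_protocols(),
                            rng_seed = 1L, arrival_order = NULL) {
  n_ventilators <- as.integer(n_ventilators)
  if (length(n_ventilators) != 1 || is.na(n_ventilators) ||
      n_ventilators < 0) {
    stop_config("n_ventilators must be a single non-negative integer")
  }
  rng_seed <- as.integer(rng_seed)
  if (length(rng_seed) != 1 || is.na(rng_seed)) {
    stop_config("rng_seed must be a single integer")
  }
  structure(
    list(n_ventilators = n_ventilators, protocols = protocols,
         rng_seed = rng_seed, arrival_order = arrival_order),
    class = "sra_scenario")
}

.resolve_arrival <- function(cohort, scenario) {
  if (is.null(scenario$arrival_order)) {
    return(setNames(cohort$arrival_rank, cohort$id))
  }
  ord <- scenario$arrival_order
  if (!setequal(ord, cohort$id) || length(ord) != nrow(cohort)) {
    stop_config("explicit arrival_order must be a permutation of cohort ids")
  }
  setNames(match(cohort$id, ord), cohort$id)
}

#' Allocate ventilators to a ranked cohort
#'
#' Produces one four-valued outcome per patient: `allocated` (`***`),
#' `tied_lost` (`**`, tied at the capacity boundary but lost the
#' tie-break), `qualified_undetermined` (`*`, qualified but the protocol
#' gives no way to decide), and `not_allocated` / `excluded` (both
#' rendered `O`). Frontline-exempt patients are served first and consume
#' capacity. Lottery tie-breaks are driven by `scenario$rng_seed`, so a
#' scenario is fully reproducible.
#'
#' @param ranking the [rank_cohort()] result for the same rule set and
#'   cohort.
#' @param ruleset the `sra_protocol` that produced `ranking` (or its id).
#' @param cohort the patient cohort tibble.
#' @param scenario a [scenario_config()].
#' @return A tibble with columns `id`, `status`, `tiebreak` (the step that
#'   decided the patient's straddling group, else `NA`), and `symbol`.
#' @examples
#' cohort <- fixture_cohort()
#' allocate(rank_cohort("MD", cohort), "MD", cohort, scenario_config())
#' @export
allocate <- function(ranking, ruleset, cohort, scenario = scenario_config()) {
  rs <- load_protocol(ruleset)
  cohort <- validate_cohort(cohort)
  if (!inherits(ranking, "sra_ranking")) {
    stop_contract("ranking must be produced by rank_cohort()")
  }
  if (!identical(ranking$ruleset_id, rs$id)) {
    stop_contract(sprintf(
      "ranking was produced for protocol '%s', not '%s'",
      ranking$ruleset_id, rs$id))
  }
  if (!setequal(ranking$cohort_ids, cohort$id)) {
    stop_contract("ranking and cohort cover different patient ids")
  }
  arrival <- .resolve_arrival(cohort, scenario)
  withr::with_seed(
    scenario$rng_seed,
    .allocate_impl(ranking, rs, cohort, arrival, scenario$n_ventilators))
}

.allocate_impl <- function(ranking, rs, cohort, arrival, capacity) {
  ids <- cohort$id
  status <- setNames(rep(NA_character_, length(ids)), ids)
  tiebreak <- setNames(rep(NA_character_, length(ids)), ids)
  members_df <- function(gids) {
    idx <- match(gids, ids)
    data.frame(id = gids, age = cohort$age[idx],
               occupation = cohort$occupation[idx],
               arrival_rank = unname(arrival[as.character(gids)]))
  }
  remaining <- capacity
  stopped <- FALSE
  for (g in ranking$groups) {
    gids <- as.character(g$ids)
    if (g$type == "excluded") {
      status[gids] <- "excluded"
      next
    }
    if (stopped || remaining == 0) {
      status[gids] <- if (g$type == "qualified") {
        "qualified_undetermined"
      } else {
        "not_allocated"
      }
      next
    }
    if (length(gids) <= remaining) {
      status[gids] <- "allocated"
      remaining <- remaining - length(gids)
      next
    }
    # group straddles remaining capacity: resolve by the tie-break chain
    res <- resolve_tie(members_df(g$ids), rs$tiebreak_chain, remaining)
    if (!res$resolved) {
      status[gids] <- "qualified_undetermined"
      stopped <- TRUE
      next
    }
    status[as.character(res$winners)] <- "allocated"
    status[as.character(res$losers)] <- "tied_lost"
    tiebreak[gids] <- res$applied
    remaining <- 0L
  }
  tibble::tibble(
    id = ids,
    status = unname(status),
    tiebreak = unname(tiebreak),
    symbol = unname(.status_symbols[status]))
}

#' Resolve a tie at the capacity boundary
#'
#' Applies the tie-break chain step by step; each step discriminates only
#' among patients still tied after the earlier steps. Steps: `younger_age`
#' (ascending age), `frontline` (frontline workers first), `fcfs`
#' (ascending arrival rank), `lottery` (uniform draw without replacement
#' using the current RNG state -- [allocate()] seeds it from the scenario).
#'
#' @param members data frame of the tied patients with columns `id`, `age`,
#'   `occupation`, `arrival_rank`.
#' @param chain character vector of tie-break steps (possibly empty).
#' @param capacity remaining capacity; must satisfy
#'   `0 < capacity < nrow(members)`.
#' @return A list: `resolved` (FALSE when the chain is empty/exhausted with
#'   the boundary still tied), `winners`, `losers`, and `applied` (the step
#'   that finally discriminated).
#' @examples
#' members <- data.frame(id = c(5, 6), age = c(92, 40),
#'                       occupation = "none", arrival_rank = c(1, 2))
#' resolve_tie(members, c("younger_age", "fcfs"), 1)$winners  # 6
#' @export
resolve_tie <- function(members, chain, capacity) {
  n <- nrow(members)
  if (capacity <= 0 || capacity >= n) {
    stop_contract("resolve_tie() needs 0 < capacity < group size")
  }
  if (length(chain) == 0) {
    return(list(resolved = FALSE, winners = NULL, losers = NULL,
                applied = NA_character_))
  }
  step <- chain[[1]]
  key <- switch(step,
    younger_age = members$age,
    frontline = ifelse(.is_frontline(members$occupation), 0L, 1L),
    fcfs = members$arrival_rank,
    lottery = runif(n),
    stop_config(paste0("unknown tiebreak step: ", step)))
  winners <- members$id[0]
  applied <- step
  rem <- capacity
  for (k in sort(unique(key))) {
    grp <- members[key == k, , drop = FALSE]
    if (nrow(grp) <= rem) {
      winners <- c(winners, grp$id)
      rem <- rem - nrow(grp)
      if (rem == 0) break
    } else {
      sub <- resolve_tie(grp, chain[-1], rem)
      if (!sub$resolved) {
        return(list(resolved = FALSE, winners = NULL, losers = NULL,
                    applied = NA_character_))
      }
      winners <- c(winners, sub$winners)
      applied <- sub$applied
      rem <- 0L
      break
    }
  }
  list(resolved = TRUE, winners = winners,
       losers = setdiff(members$id, winners), applied = applied)
}
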