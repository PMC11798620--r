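# shared fixtures built in code

# minimal cohort of n interchangeable eligible patients (distinct ages and
# arrival ranks unless overridden)
quick_cohort <- function(n, age = NULL, sofa = NULL, arrival = NULL) {
  tibble::tibble(
    id = seq_len(n),
    age = as.integer(age %||% (30 + seq_len(n))),
    sex = rep(c("female", "male"), length.out = n),
    sofa_total = as.integer(sofa %||% rep(5L, n)),
    comorbidity = rep("none_significant", n),
    pregnancy_weeks = rep(NA_integer_, n),
    occupation = rep("none", n),
    ses = rep("unspecified", n),
    arrival_rank = as.integer(arrival %||% seq_len(n)))
}

# protocol that scores nothing and resolves everything by lottery: every
# patient lands in one score-0 group
lottery_protocol <- function(id = "LOT") {
  protocol_ruleset(id, label = "pure lottery", tiebreak_chain = "lottery")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random-but-valid generator configuration for property tests
random_cohort_config <- function() {
  amin <- sample(18:60, 1)
  prev <- stats::runif(7)
  prev <- setNames(prev / sum(prev), comorbidity_codes())
  cohort_config(
    n = sample(0:40, 1),
    age_range = c(amin, amin + sample(0:50, 1)),
    sofa_distribution = stats::runif(25),
    comorbidity_prevalences = prev,
    pregnancy_rate = stats::runif(1),
    frontline_fraction = stats::runif(1),
    ses_low_rate = stats::runif(1),
    seed = sample.int(1e6, 1))
}

expect_valid_cohort <- function(cohort) {
  expect_silent(validate_cohort(cohort))
}
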