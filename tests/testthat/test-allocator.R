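cohort <- fixture_cohort()
scenario <- scenario_config(n_ventilators = 3, rng_seed = 17)

outcome_of <- function(pid, scen = scenario, coh = cohort) {
  out <- allocate(rank_cohort(pid, coh), pid, coh, scen)
  setNames(out$status, out$id)
}

test_that("allocation reproduces the protocol-specific outcome patterns", {
  md <- outcome_of("MD")
  expect_setequal(names(md)[md == "allocated"], c("3", "6", "7"))
  expect_equal(unname(md["5"]), "tied_lost")
  expect_equal(unname(md[c("1", "4")]), rep("not_allocated", 2))
  expect_equal(unname(md[c("2", "8", "9")]), rep("excluded", 3))

  ny <- outcome_of("NY")
  expect_setequal(names(ny)[ny == "allocated"], c("5", "7", "8"))
  expect_equal(unname(ny["4"]), "tied_lost")

  ne <- outcome_of("NE")
  expect_equal(sum(ne == "allocated"), 0)
  expect_setequal(names(ne)[ne == "qualified_undetermined"],
                  c("4", "5", "6", "7", "8", "9"))
})

test_that("zero capacity allocates nothing but preserves status semantics", {
  scen0 <- scenario_config(n_ventilators = 0, rng_seed = 1)
  for (pid in list_protocols()) {
    out <- outcome_of(pid, scen0)
    expect_equal(sum(out == "allocated"), 0, label = pid)
  }
  expect_equal(sum(outcome_of("FL", scen0) == "excluded"), 6)
  # NE qualifiers stay qualified-undetermined even at zero capacity
  expect_equal(sum(outcome_of("NE", scen0) == "qualified_undetermined"), 6)
})

test_that("resolve_tie applies the chain step by step", {
  members <- data.frame(
    id = c(4L, 5L, 7L, 8L),
    age = c(50L, 92L, 28L, 57L),
    occupation = "none",
    arrival_rank = c(9L, 4L, 6L, 7L))
  res <- resolve_tie(members, "fcfs", 3)
  expect_setequal(res$winners, c(5, 7, 8))
  expect_equal(res$losers, 4)
  expect_equal(res$applied, "fcfs")

  two <- data.frame(id = c(5L, 6L), age = c(92L, 40L),
                    occupation = "none", arrival_rank = c(1L, 2L))
  res <- resolve_tie(two, c("younger_age", "fcfs"), 1)
  expect_equal(res$winners, 6)
  expect_equal(res$applied, "younger_age")
  # same ages fall through to the next step
  same <- two
  same$age <- c(40L, 40L)
  res <- resolve_tie(same, c("younger_age", "fcfs"), 1)
  expect_equal(res$winners, 5)
  expect_equal(res$applied, "fcfs")
  # frontline step prefers frontline workers
  fr <- two
  fr$occupation <- c("none", "first_responder")
  expect_equal(resolve_tie(fr, "frontline", 1)$winners, 6)

  expect_false(resolve_tie(two, character(0), 1)$resolved)
  expect_false(resolve_tie(same, "younger_age", 1)$resolved)
  expect_error(resolve_tie(two, "fcfs", 2),
               class = "triagesim_contract_error")
})

test_that("lottery tie-breaks are reproducible under a fixed seed", {
  two <- data.frame(id = c(101L, 102L), age = c(40L, 40L),
                    occupation = "none", arrival_rank = c(1L, 2L))
  w <- replicate(20, withr::with_seed(99, resolve_tie(two, "lottery", 1)$winners))
  expect_length(unique(w), 1)

  lot <- lottery_protocol()
  coh <- quick_cohort(6)
  scen <- scenario_config(n_ventilators = 3, rng_seed = 123)
  out1 <- allocate(rank_cohort(lot, coh), lot, coh, scen)
  out2 <- allocate(rank_cohort(lot, coh), lot, coh, scen)
  expect_identical(out1, out2)
})

test_that("ranking/cohort mismatches violate the allocate contract", {
  ranking <- rank_cohort("MD", cohort)
  expect_error(allocate(ranking, "NY", cohort, scenario),
               class = "triagesim_contract_error")
  sub <- cohort[1:5, ]
  sub$arrival_rank <- 1:5
  expect_error(allocate(ranking, "MD", sub, scenario),
               class = "triagesim_contract_error")
  expect_error(
    allocate(ranking, "MD", cohort,
             scenario_config(arrival_order = c(1, 2, 3))),
    class = "triagesim_config_error")
})

test_that("conservation and no-leapfrogging hold over random cohorts", {
  withr::with_seed(2024, {
    for (rep in 1:25) {
      coh <- generate_cohort(cohort_config(n = sample(1:20, 1),
                                           seed = sample.int(1e6, 1)))
      cap <- sample(0:5, 1)
      scen <- scenario_config(n_ventilators = cap,
                              rng_seed = sample.int(1e6, 1))
      for (pid in list_protocols()) {
        ranking <- rank_cohort(pid, coh)
        out <- allocate(ranking, pid, coh, scen)
        n_alloc <- sum(out$status == "allocated")
        expect_lte(n_alloc, cap)
        # saturation: enough eligible patients + a non-empty chain
        rs <- load_protocol(pid)
        n_elig <- sum(ranking$assignments$status != "excluded")
        if (length(rs$tiebreak_chain) > 0 && n_elig >= cap) {
          expect_equal(n_alloc, cap, label = paste(pid, "saturation"))
        }
        # no leapfrogging: an allocated patient never has a strictly worse
        # score than an eligible patient who went without
        sc <- setNames(ranking$assignments$score, ranking$assignments$id)
        st <- setNames(out$status, out$id)
        got <- sc[names(st)[st == "allocated"]]
        missed <- sc[names(st)[st %in% c("not_allocated", "tied_lost",
                                         "qualified_undetermined")]]
        got <- got[!is.na(got)]
        missed <- missed[!is.na(missed)]
        if (length(got) > 0 && length(missed) > 0) {
          expect_lte(max(got), min(missed),
                     label = paste(pid, "no leapfrogging"))
        }
      }
    }
  })
})

test_that("frontline exemption consumes capacity before scoring", {
  # CA: two exempt workers leave one ventilator for the scored pool
  ca <- outcome_of("CA")
  expect_equal(unname(ca[c("1", "7")]), rep("allocated", 2))
  expect_equal(sum(ca == "allocated"), 3)
  # with capacity 2 the exempt workers take everything
  ca2 <- outcome_of("CA", scenario_config(n_ventilators = 2, rng_seed = 17))
  expect_setequal(names(ca2)[ca2 == "allocated"], c("1", "7"))
})
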