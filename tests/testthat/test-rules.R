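cohort <- fixture_cohort()

test_that("exclusion screening follows each protocol's rules", {
  p8 <- cohort[8, ]  # late-stage MS, SOFA 2
  fl <- screen_exclusions("FL", p8)
  expect_equal(fl$status, "excluded")
  expect_match(fl$trace, "ms_late_stage")
  expect_equal(screen_exclusions("NY", p8)$status, "eligible")
  # PA has no exclusion criteria at all
  for (i in 1:9) {
    expect_equal(screen_exclusions("PA", cohort[i, ])$status, "eligible")
  }
  # SOFA threshold comparators: MD strict >, FL inclusive >=
  expect_equal(screen_exclusions("MD", cohort[1, ])$status, "eligible")  # 14
  expect_equal(screen_exclusions("FL", cohort[3, ])$status, "excluded")  # 10
  # NE qualification cutoff: qualify iff SOFA < 10
  expect_equal(screen_exclusions("NE", cohort[2, ])$status, "excluded")
  expect_equal(screen_exclusions("NE", cohort[6, ])$status, "eligible")
})

test_that("priority scoring applies bands, modifiers, and exemptions", {
  # CA exempts frontline workers from scoring entirely
  ca1 <- compute_priority("CA", cohort[1, ])
  expect_equal(ca1$status, "exempt_frontline")
  expect_null(ca1$score)
  # pregnant patient outranks (scores lower than) the older non-pregnant one
  md3 <- compute_priority("MD", cohort[3, ])
  md4 <- compute_priority("MD", cohort[4, ])
  expect_lt(md3$score, md4$score)
  expect_true(any(grepl("pregnant", md3$trace)))
  # calibrated PA band: SOFA 5, no qualifying comorbidity -> 1 point
  expect_equal(compute_priority("PA", cohort[7, ])$score, 1L)
  # PA treats dementia as non-qualifying but other severe comorbidities +4
  expect_equal(compute_priority("PA", cohort[5, ])$score, 1L)
  expect_equal(compute_priority("PA", cohort[8, ])$score, 5L)
})

test_that("status eligible if and only if a score is present", {
  for (pid in list_protocols()) {
    for (i in 1:9) {
      a <- compute_priority(pid, cohort[i, ])
      expect_identical(a$status == "eligible", !is.null(a$score))
    }
  }
})

test_that("score equals the sum of its own trace terms (self-audit)", {
  for (pid in list_protocols()) {
    for (i in 1:9) {
      a <- compute_priority(pid, cohort[i, ])
      if (a$status == "eligible") {
        expect_identical(a$score, as.integer(sum(a$terms)),
                         label = sprintf("%s patient %d", pid, i))
      }
    }
  }
})

test_that("evaluation is deterministic and order-independent", {
  a1 <- compute_priority("MD", cohort[3, ])
  a2 <- compute_priority("MD", cohort[3, ])
  expect_identical(a1, a2)
  shuffled <- cohort[c(5, 2, 9, 1, 7, 3, 8, 4, 6), ]
  r1 <- rank_cohort("MD", cohort)$assignments
  r2 <- rank_cohort("MD", shuffled)$assignments
  r2 <- r2[match(r1$id, r2$id), ]
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("ranking groups patients as each protocol prescribes", {
  # NE: single undifferentiated qualifying group, no internal ordering
  ne <- rank_cohort("NE", cohort)
  qual <- Filter(function(g) g$type == "qualified", ne$groups)
  expect_length(qual, 1)
  expect_setequal(qual[[1]]$ids, c(4, 5, 6, 7, 8, 9))
  expect_true(ne$qualification_only)
  # NY: calibrated top band holds patients 4, 5, 7, 8
  ny <- rank_cohort("NY", cohort)
  expect_setequal(ny$groups[[1]]$ids, c(4, 5, 7, 8))
  # empty cohort -> empty ranking
  empty <- rank_cohort("NY", cohort[0, ])
  expect_length(empty$groups, 0)
  expect_equal(nrow(empty$assignments), 0)
  # exempt group always precedes score groups
  ca <- rank_cohort("CA", cohort)
  expect_equal(ca$groups[[1]]$type, "exempt")
  expect_setequal(ca$groups[[1]]$ids, c(1, 7))
})

test_that("shipped configurations load and expose the expected features", {
  md <- load_protocol("MD")
  expect_s3_class(md, "sra_protocol")
  expect_true(protocol_features(md)$has_exclusions)
  expect_equal(load_protocol("NE")$tiebreak_chain, character(0))
  expect_setequal(list_protocols(), c("MD", "PA", "FL", "NY", "CA", "NE"))

  # feature-matrix conformance for all six shipped configs
  feats <- do.call(rbind, lapply(list_protocols(), protocol_features))
  expect_true(all(feats$uses_sofa))
  expect_equal(feats$has_exclusions,
               c(MD = TRUE, PA = FALSE, FL = TRUE, NY = TRUE, CA = FALSE,
                 NE = FALSE)[feats$id], ignore_attr = TRUE)
  expect_equal(feats$considers_age,
               c(MD = TRUE, PA = TRUE, FL = FALSE, NY = FALSE, CA = TRUE,
                 NE = FALSE)[feats$id], ignore_attr = TRUE)
  expect_true(feats$age_tiebreak_only[feats$id == "PA"])
  expect_false(feats$age_tiebreak_only[feats$id == "MD"])
  expect_equal(feats$considers_pregnancy,
               c(MD = TRUE, PA = FALSE, FL = FALSE, NY = FALSE, CA = TRUE,
                 NE = FALSE)[feats$id], ignore_attr = TRUE)
  expect_equal(feats$considers_frontline,
               c(MD = FALSE, PA = TRUE, FL = FALSE, NY = FALSE, CA = TRUE,
                 NE = FALSE)[feats$id], ignore_attr = TRUE)
  expect_true(feats$frontline_exemption[feats$id == "CA"])
  expect_true(feats$frontline_tiebreak_only[feats$id == "PA"])
  expect_equal(feats$has_tiebreak,
               c(MD = TRUE, PA = TRUE, FL = TRUE, NY = TRUE, CA = TRUE,
                 NE = FALSE)[feats$id], ignore_attr = TRUE)
})

test_that("malformed rule-set configurations are rejected", {
  expect_error(
    protocol_ruleset("bad", sofa_bands = data.frame(
      min = c(0, 5), max = c(6, 10), points = c(1, 2))),
    "overlap", class = "triagesim_config_error")
  expect_error(
    protocol_ruleset("bad", excluded_comorbidities = "gout"),
    class = "triagesim_config_error")
  expect_error(
    protocol_ruleset("bad", tiebreak_chain = "coin_flip"),
    class = "triagesim_config_error")
  expect_error(
    protocol_ruleset("bad", sofa_exclusion = list(comparator = "<", cutoff = 3)),
    class = "triagesim_config_error")
  expect_error(load_protocol("ZZ"), class = "triagesim_config_error")
  # patient SOFA outside band coverage -> configuration error
  narrow <- protocol_ruleset("narrow", sofa_bands = data.frame(
    min = 0, max = 5, points = 1))
  expect_error(compute_priority(narrow, cohort[1, ]),
               "coverage", class = "triagesim_config_error")
  # user-supplied file path round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_protocol(load_protocol("NY"), path)
  expect_equal(load_protocol(path)$sofa_exclusion$cutoff, 11L)
})
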