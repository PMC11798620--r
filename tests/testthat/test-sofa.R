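# Oracle for the calculator is the standard published SOFA threshold
# table; the frozen expectations below are read off that table directly.

test_that("component scores match the published threshold table", {
  # (system, value, expected subscore)
  cases <- list(
    list("coagulation", 250, 0L), list("coagulation", 150, 0L),
    list("coagulation", 149, 1L), list("coagulation", 99, 2L),
    list("coagulation", 45, 3L), list("coagulation", 10, 4L),
    list("respiration", 450, 0L), list("respiration", 350, 1L),
    list("respiration", 250, 2L), list("respiration", 150, 3L),
    list("respiration", 80, 4L),
    list("liver", 1.0, 0L), list("liver", 1.2, 1L), list("liver", 3.0, 2L),
    list("liver", 6.0, 3L), list("liver", 12.5, 4L),
    list("cns", 15, 0L), list("cns", 13, 1L), list("cns", 10, 2L),
    list("cns", 7, 3L), list("cns", 3, 4L),
    list("renal", 1.0, 0L), list("renal", 1.5, 1L), list("renal", 2.1, 2L),
    list("renal", 3.6, 3L), list("renal", 6.1, 4L),
    list("cardiovascular", 75, 0L), list("cardiovascular", 65, 1L)
  )
  for (cs in cases) {
    expect_identical(component_score(cs[[1]], cs[[2]]), cs[[3]],
                     label = paste(cs[[1]], cs[[2]]))
  }
})

test_that("vasopressor tiers override mean arterial pressure", {
  expect_identical(
    component_score("cardiovascular", vasopressor = "dobutamine"), 2L)
  expect_identical(
    component_score("cardiovascular", vasopressor = "dopamine", dose = 4), 2L)
  expect_identical(
    component_score("cardiovascular", vasopressor = "dopamine", dose = 10), 3L)
  expect_identical(
    component_score("cardiovascular", vasopressor = "dopamine", dose = 20), 4L)
  expect_identical(
    component_score("cardiovascular", vasopressor = "norepinephrine",
                    dose = 0.05), 3L)
  expect_identical(
    component_score("cardiovascular", value = 90,
                    vasopressor = "epinephrine", dose = 0.2), 4L)
})

test_that("renal scoring takes the worse of creatinine and urine output", {
  expect_identical(component_score("renal", 1.0, urine_output = 150), 4L)
  expect_identical(component_score("renal", 3.6, urine_output = 2000), 3L)
  expect_identical(component_score("renal", urine_output = 300), 3L)
  expect_error(component_score("renal"),
               class = "triagesim_validation_error")
})

test_that("invalid measurements are rejected", {
  expect_error(component_score("lungs", 100),
               class = "triagesim_validation_error")
  expect_error(component_score("coagulation", -5),
               class = "triagesim_validation_error")
  expect_error(component_score("cns", 16),
               class = "triagesim_validation_error")
  expect_error(component_score("cns", 2),
               class = "triagesim_validation_error")
})

test_that("total is the sum of six subscores with range 0-24", {
  expect_identical(total_sofa(sofa_components()), 0L)
  expect_identical(
    total_sofa(sofa_components(4, 4, 4, 4, 4, 4)), 24L)
  expect_identical(
    total_sofa(sofa_components(1, 2, 0, 3, 0, 4)), 10L)
  expect_error(sofa_components(respiration = 5),
               class = "triagesim_validation_error")
  expect_error(sofa_components(renal = -1),
               class = "triagesim_validation_error")
})

test_that("subscores are monotone in severity and totals in subscores", {
  # sweeping each measurement from benign to severe never decreases the
  # subscore
  sweeps <- list(
    respiration = seq(500, 20, by = -20),       # falling P/F ratio
    coagulation = seq(300, 5, by = -5),         # falling platelets
    liver = seq(0.2, 15, by = 0.2),             # rising bilirubin
    cns = 15:3,                                 # falling GCS
    renal = seq(0.5, 8, by = 0.1))              # rising creatinine
  for (system in names(sweeps)) {
    scores <- vapply(sweeps[[system]], function(v) component_score(system, v),
                     integer(1))
    expect_true(all(diff(scores) >= 0), label = paste("monotone", system))
    expect_true(all(scores %in% 0:4), label = paste("range", system))
  }
  # raising any one subscore raises the total by the same amount
  withr::with_seed(42, {
    for (i in 1:50) {
      x <- as.list(setNames(sample(0:3, 6, replace = TRUE),
                            c("respiration", "coagulation", "liver",
                              "cardiovascular", "cns", "renal")))
      k <- sample(names(x), 1)
      y <- x
      y[[k]] <- y[[k]] + 1L
      expect_equal(total_sofa(do.call(sofa_components, y)),
                   total_sofa(do.call(sofa_components, x)) + 1L)
    }
  })
})
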