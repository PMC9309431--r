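test_that("closed vocabularies reject unknown tokens", {
  expect_error(clinical_context("tenatoprazole"), "unknown drug")
  expect_error(clinical_context("omeprazole", "GERD"), "unknown indication")
  expect_error(recommend("XX", default_ctx()), "unknown phenotype")
  expect_error(clinical_context("omeprazole", h_pylori_positive = "yes"),
               "TRUE or FALSE")
})

test_that("published dosing rules fire for their index cases", {
  # ultrarapid metabolizer on a first-generation PPI: double the dose
  r <- recommend("UM", default_ctx("omeprazole"))
  expect_equal(r$action, "INCREASE")
  expect_equal(c(r$multiplier_low, r$multiplier_high), c(2, 2))
  expect_true(r$split_dose_allowed)

  # chronic therapy with decreased CYP2C19 function: halve the dose
  r <- recommend("PM", default_ctx("pantoprazole",
                                   chronic_over_12_weeks = TRUE))
  expect_equal(r$action, "REDUCE_CONSIDER")
  expect_equal(c(r$multiplier_low, r$multiplier_high), c(0.5, 0.5))
  expect_equal(r$preferred_agent, "rabeprazole")

  # rabeprazole is CYP2C19-independent for every phenotype
  for (ph in c("PM", "IM", "AM", "EM", "RM", "UM")) {
    r <- recommend(ph, default_ctx("rabeprazole"))
    expect_equal(r$action, "STANDARD_DOSE")
    expect_equal(r$multiplier_low, 1)
  }

  # normal/rapid metabolizers: standard dose, increase for H. pylori or
  # erosive esophagitis on a first-generation PPI
  expect_equal(recommend("EM", default_ctx("lansoprazole"))$action,
               "STANDARD_DOSE")
  r <- recommend("RM", default_ctx("lansoprazole",
                                   indication = "H_PYLORI_ERADICATION"))
  expect_equal(c(r$multiplier_low, r$multiplier_high), c(1.5, 2))
  expect_true(r$split_dose_allowed)
  r <- recommend("EM", default_ctx("omeprazole",
                                   indication = "EROSIVE_ESOPHAGITIS"))
  expect_equal(r$action, "INCREASE")
})

test_that("H. pylori eradication in ultrarapid metabolizers uses drug-specific folds", {
  hp <- function(drug) recommend("UM", default_ctx(drug,
                                                   indication = "H_PYLORI_ERADICATION"))
  expect_equal(hp("omeprazole")$multiplier_low, 3)
  expect_equal(hp("lansoprazole")$multiplier_low, 4)
  expect_equal(hp("pantoprazole")$multiplier_low, 5)
  e <- hp("esomeprazole")
  expect_equal(c(e$multiplier_low, e$multiplier_high), c(1.5, 2))
})

test_that("H. pylori-positive ultrarapid metabolizers on SUP prefer standard-dose rabeprazole", {
  r <- recommend("UM", default_ctx("omeprazole", h_pylori_positive = TRUE))
  expect_equal(r$action, "STANDARD_DOSE")
  expect_equal(r$preferred_agent, "rabeprazole")
  # the footnote is specific to prophylaxis: eradication keeps its folds
  r2 <- recommend("UM", default_ctx("omeprazole",
                                    indication = "H_PYLORI_ERADICATION",
                                    h_pylori_positive = TRUE))
  expect_equal(r2$multiplier_low, 3)
})

test_that("esomeprazole outside UM eradication gives no genotype-specific number", {
  for (ph in c("PM", "IM", "AM")) {
    r <- recommend(ph, default_ctx("esomeprazole"))
    expect_equal(r$action, "NO_SPECIFIC_RECOMMENDATION")
    expect_true(is.na(r$multiplier_low))
    expect_match(r$rationale, "CYP2C19")
  }
  expect_equal(recommend("UM", default_ctx("esomeprazole"))$action,
               "NO_SPECIFIC_RECOMMENDATION")
  expect_equal(recommend("EM", default_ctx("esomeprazole"))$action,
               "STANDARD_DOSE")
})

test_that("dexlansoprazole inherits the first-generation rules", {
  expect_equal(recommend("UM", default_ctx("dexlansoprazole"))$multiplier_low, 2)
  expect_equal(recommend("UM", default_ctx("dexlansoprazole",
                                           indication = "H_PYLORI_ERADICATION"))$multiplier_low,
               4)
  r <- recommend("IM", default_ctx("dexlansoprazole",
                                   chronic_over_12_weeks = TRUE))
  expect_equal(r$multiplier_low, 0.5)
})

test_that("genotype-independent fallbacks dominate genotype logic", {
  # hypersensitivity beats everything
  r <- recommend("UM", default_ctx("omeprazole", ppi_hypersensitivity = TRUE))
  expect_equal(r$action, "SWITCH_AGENT")
  expect_equal(r$preferred_agent, "H2RA_or_GMP")
  # no genotype / unknown phenotype / CYP interaction -> rabeprazole
  for (r in list(recommend("EM", default_ctx("omeprazole",
                                             genotype_available = FALSE)),
                 recommend("UNKNOWN", default_ctx("lansoprazole")),
                 recommend("EM", default_ctx("omeprazole",
                                             interacting_cyp_drug = TRUE)))) {
    expect_equal(r$action, "STANDARD_DOSE")
    expect_equal(r$preferred_agent, "rabeprazole")
  }
})

test_that("the AM provisional flag propagates into recommendations", {
  expect_true(recommend("AM", default_ctx("omeprazole"))$provisional)
  expect_true(recommend("AM", default_ctx("esomeprazole"))$provisional)
  expect_false(recommend("PM", default_ctx("omeprazole"))$provisional)
})

test_that("absolute doses are standard dose times the multiplier interval", {
  expect_equal(unname(absolute_dose(recommend("UM", default_ctx("omeprazole")))),
               c(40, 40))
  expect_equal(unname(absolute_dose(
    recommend("PM", default_ctx("lansoprazole",
                                chronic_over_12_weeks = TRUE)))),
    c(15, 15))
  expect_equal(unname(absolute_dose(recommend("EM", default_ctx("esomeprazole")))),
               c(20, 20))
  d <- absolute_dose(recommend("UM", default_ctx("dexlansoprazole")))
  expect_true(all(is.na(d)))
  expect_match(attr(d, "note"), "dexlansoprazole")
  d2 <- absolute_dose(recommend("PM", default_ctx("esomeprazole")))
  expect_true(all(is.na(d2)))
})

test_that("standard doses match the reference table", {
  std <- standard_doses()
  expect_equal(std$dose_mg_per_day[match(
    c("omeprazole", "lansoprazole", "pantoprazole", "esomeprazole",
      "rabeprazole"), std$drug)],
    c(20, 30, 20, 20, 20))
})

test_that("recommendation reports cover every sample and trace rule ids", {
  calls <- call_cohort(canonical_cohort())
  rep <- recommendation_report(calls, default_ctx("omeprazole"))
  expect_equal(nrow(rep), 6L)
  expect_true(all(nzchar(rep$rule_id)))
  expect_true(all(nzchar(rep$rationale)))
  # rationales map 1:1 onto the versioned rule table
  rules <- sup_rule_table()
  by_id <- setNames(lapply(rules$rules, function(r) trimws(r$rationale)),
                    vapply(rules$rules, `[[`, "", "id"))
  expect_true(all(mapply(identical, rep$rationale,
                         unlist(by_id[rep$rule_id]))))

  # unknown phenotype row resolves to CYP2C19-independent therapy
  nc <- sample_genotypes("N1", "TT", "AA")
  rep2 <- recommendation_report(call_cohort(nc), default_ctx("omeprazole"))
  expect_equal(rep2$preferred_agent, "rabeprazole")

  # uncallable samples are dosed as genotype-unavailable, never dropped
  mixed <- sample_genotypes(c("S1", "S2"), c("CC", NA), c("GG", "GA"))
  rep3 <- recommendation_report(call_cohort(mixed), default_ctx("omeprazole"))
  expect_equal(nrow(rep3), 2L)
  expect_equal(rep3$rule_id[rep3$sample_id == "S2"], "NO_GENOTYPE_RABEPRAZOLE")

  # empty cohort -> empty report; JSON rendering parses
  rep0 <- recommendation_report(call_cohort(sample_genotypes(character(0))),
                                default_ctx("omeprazole"))
  expect_equal(nrow(rep0), 0L)
  jf <- tempfile(fileext = ".json")
  write_recommendation_json(rep, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(length(parsed$recommendations), 6L)
  expect_equal(parsed$context$drug, "omeprazole")
})
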