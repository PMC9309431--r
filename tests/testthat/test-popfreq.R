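test_that("allele renormalization drops non-core alleles and reports the mass", {
  h <- renormalize_alleles(c("*1" = 0.6, "*2" = 0.2, "*17" = 0.2))
  expect_equal(unclass(h), c(h1 = 0.6, h2 = 0.2, h17 = 0.2))
  expect_warning(
    h2 <- renormalize_alleles(c("*1" = 0.57, "*2" = 0.19, "*17" = 0.19,
                                "*3" = 0.05)),
    "0.05")
  expect_equal(unclass(h2), c(h1 = 0.6, h2 = 0.2, h17 = 0.2))
  expect_error(renormalize_alleles(c("*1" = 0, "*2" = 0, "*17" = 0)),
               "sum to zero")
  expect_error(renormalize_alleles(c("*2" = 1)), "named")
})

test_that("Hardy-Weinberg expansion matches the trinomial square", {
  p <- expand_hwe(haplotype_freqs(1, 0, 0), "mono")
  expect_equal(unname(p$phenotype_freq["EM"]), 1)
  expect_equal(sum(p$phenotype_freq), 1)
  expect_equal(unname(expand_hwe(haplotype_freqs(0, 1, 0))$phenotype_freq["PM"]), 1)
  p3 <- expand_hwe(haplotype_freqs(1 / 3, 1 / 3, 1 / 3))
  expect_equal(unname(p3$phenotype_freq[c("EM", "PM", "UM")]),
               rep(1 / 9, 3))
  expect_equal(unname(p3$phenotype_freq[c("IM", "RM", "AM")]),
               rep(2 / 9, 3))
  # probability conservation over random simplex points
  set.seed(42)
  for (i in 1:200) {
    x <- stats::rexp(3)
    h <- haplotype_freqs(x[1] / sum(x), x[2] / sum(x), x[3] / sum(x))
    expect_lt(abs(sum(expand_hwe(h)$phenotype_freq) - 1), 1e-9)
  }
})

test_that("haplotype frequency estimation counts alleles with binomial errors", {
  one_em <- sample_genotypes("E1", "CC", "GG")
  h <- estimate_haplotype_freqs(one_em)
  expect_equal(unclass(h), c(h1 = 1, h2 = 0, h17 = 0), ignore_attr = TRUE)

  one_am <- sample_genotypes("A1", "CT", "GA")
  h <- estimate_haplotype_freqs(one_am)
  expect_equal(unclass(h), c(h1 = 0, h2 = 0.5, h17 = 0.5),
               ignore_attr = TRUE)

  expect_error(estimate_haplotype_freqs(sample_genotypes(character(0))),
               "no callable")

  # parameter recovery on a seeded simulated cohort
  truth <- haplotype_freqs(0.6, 0.2, 0.2)
  co <- simulate_cohort(truth, 2000, seed = 99)
  est <- estimate_haplotype_freqs(co)
  se <- attr(est, "se")
  for (k in c("h1", "h2", "h17")) {
    expect_lt(abs(est[[k]] - truth[[k]]), 4 * se[[k]])
  }
  expect_equal(attr(est, "n"), 2000L)
  expect_equal(attr(est, "n_non_canonical"), 0L)

  # non-canonical carriers are used but flagged
  nc <- sample_genotypes(c("E1", "N1"), c("CC", "CT"), c("GG", "AA"))
  est_nc <- estimate_haplotype_freqs(nc)
  expect_equal(attr(est_nc, "n_non_canonical"), 1L)
  expect_equal(unclass(est_nc), c(h1 = 0.25, h2 = 0.5, h17 = 0.25),
               ignore_attr = TRUE)
})

test_that("largest-remainder counts preserve totals", {
  expect_equal(unname(largest_remainder_counts(c(0.505, 0.495), 3)), c(2, 1))
  set.seed(7)
  for (i in 1:50) {
    f <- stats::rexp(6)
    n <- sample(10:5000, 1)
    cts <- largest_remainder_counts(f / sum(f), n)
    expect_equal(sum(cts), n)
    expect_true(all(abs(cts - f / sum(f) * n) <= 1))
  }
})

test_that("identical profiles give zero chi-square and phi", {
  a <- expand_hwe(haplotype_freqs(0.6, 0.2, 0.2), "a")
  cmp <- compare_populations(a, a, mode = "asymptotic")
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$phi, 0)
  expect_equal(cmp$dof, 5L)
  expect_equal(cmp$effect_label, "below-medium")
})

test_that("disjoint populations reach the maximal association phi = 1", {
  cmp <- compare_populations(c(A = 50, B = 0), c(A = 0, B = 50),
                             mode = "asymptotic")
  expect_equal(cmp$phi, 1)
  ex <- compare_populations(c(A = 50, B = 0), c(A = 0, B = 50),
                            mode = "exact", reps = 2000, seed = 5)
  expect_lte(ex$p_value, 1 / 2001 + 1e-12)
})

test_that("phi is invariant to common count scaling and effect bins are honored", {
  a <- c(PM = 30, IM = 50, AM = 10, EM = 80, RM = 20, UM = 10)
  b <- c(PM = 60, IM = 30, AM = 20, EM = 50, RM = 30, UM = 10)
  phi1 <- compare_populations(a, b, mode = "asymptotic")$phi
  phi7 <- compare_populations(7 * a, 7 * b, mode = "asymptotic")$phi
  expect_equal(phi1, phi7)
  expect_equal(effect_size_label(c(0.1, 0.3, 0.49, 0.5, 0.9)),
               c("below-medium", "medium", "medium", "large", "large"))
})

test_that("empty categories are pooled before testing", {
  a <- c(PM = 10, IM = 20, AM = 0, EM = 30, RM = 0, UM = 0)
  b <- c(PM = 15, IM = 15, AM = 0, EM = 30, RM = 0, UM = 0)
  cmp <- compare_populations(a, b, mode = "asymptotic")
  expect_setequal(cmp$pooled, c("AM", "RM", "UM"))
  expect_equal(cmp$dof, 2L)
  expect_error(compare_populations(c(A = 0, B = 0), c(A = 0, B = 0)),
               "zero-total")
})

test_that("cohort profiles merge the UNKNOWN mass into AM", {
  g <- rbind(
    data.frame(id = sprintf("E%02d", 1:99), g17 = "CC", g2 = "GG"),
    data.frame(id = "N1", g17 = "CT", g2 = "AA"))  # non-canonical carrier
  calls <- call_cohort(sample_genotypes(g$id, g$g17, g$g2))
  prof <- cohort_profile(calls, "experimental")
  expect_equal(unname(prof$phenotype_freq["AM"]), 0.01)
  expect_equal(unname(prof$phenotype_freq["EM"]), 0.99)
  expect_equal(sum(prof$phenotype_freq), 1)
})

test_that("profile reports are long-format and complete", {
  p <- expand_hwe(haplotype_freqs(1 / 3, 1 / 3, 1 / 3), "demo")
  rep <- profile_report(p)
  expect_equal(nrow(rep), 6L)
  expect_equal(sum(rep$frequency), 1)
  # an empty class still yields a row with zero
  mono <- expand_hwe(haplotype_freqs(1, 0, 0), "mono")
  rep2 <- profile_report(list(p, mono))
  expect_equal(nrow(rep2), 12L)
  expect_equal(rep2$frequency[rep2$population == "mono" &
                                rep2$phenotype == "PM"], 0)
  tsv <- tempfile(fileext = ".tsv")
  profile_report(p, file = tsv)
  expect_equal(nrow(read.delim(tsv)), 6L)
})

test_that("allele CSV ingestion composes into Hardy-Weinberg profiles", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("population,allele,frequency",
               "popA,*1,0.6", "popA,*2,0.2", "popA,*17,0.2",
               "popB,*1,0.57", "popB,*2,0.19", "popB,*17,0.19",
               "popB,*3,0.05"), csv)
  profs <- suppressWarnings(profiles_from_allele_csv(csv))
  expect_named(profs, c("popA", "popB"))
  # popB renormalizes to popA's frequencies
  expect_equal(profs$popA$phenotype_freq, profs$popB$phenotype_freq)
  expect_equal(unname(profs$popA$phenotype_freq["PM"]), 0.04)
})
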