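## Population haplotype/haplogenotype frequency machinery: Hardy-Weinberg
## projection of haplotype frequencies (*1, *2, *17) onto the six canonical
## haplogenotypes, allele-count estimation from cohorts, and population
## comparison by Monte Carlo exact chi-square test with Cramer's phi.

.PHENO6 <- c("PM", "IM", "AM", "EM", "RM", "UM")

## haplogenotype string for each of the six phenotype classes
.PHENO6_HG <- c(PM = "*1*1/*2*2", IM = "*1*1/*1*2", AM = "*1*17/*1*2",
                EM = "*1*1/*1*1", RM = "*1*17/*1*1", UM = "*17*17/*1*1")

#' Construct a haplotype frequency set
#'
#' Frequencies of the three star haplotypes `*1`, `*2`, `*17`.  Values are
#' renormalized to sum to exactly 1; a sum deviating from 1 by more than
#' `tol` before renormalization is an error (use [renormalize_alleles()] to
#' intentionally drop mass on other alleles).
#'
#' @param h1,h2,h17 Frequencies in `[0, 1]`.
#' @param tol Largest tolerated deviation of `h1 + h2 + h17` from 1.
#' @return A named numeric vector of class `haplotype_freqs`.
#' @export
#' @examples
#' haplotype_freqs(0.6, 0.2, 0.2)
haplotype_freqs <- function(h1, h2, h17, tol = 1e-6) {
  h <- c(h1 = as.numeric(h1), h2 = as.numeric(h2), h17 = as.numeric(h17))
  if (anyNA(h) || any(h < 0) || any(h > 1)) {
    stop("haplotype frequencies must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(h)
  if (s <= 0) stop("haplotype frequencies sum to zero", call. = FALSE)
  if (abs(s - 1) > tol) {
    stop(sprintf("haplotype frequencies sum to %.6f, not 1", s), call. = FALSE)
  }
  structure(h / s, class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat(sprintf("CYP2C19 haplotype frequencies: *1=%.4f *2=%.4f *17=%.4f\n",
              x[["h1"]], x[["h2"]], x[["h17"]]))
  se <- attr(x, "se")
  if (!is.null(se)) {
    cat(sprintf("  binomial SE: *1=%.4f *2=%.4f *17=%.4f (n=%d)\n",
                se[["h1"]], se[["h2"]], se[["h17"]], attr(x, "n")))
  }
  invisible(x)
}

#' Renormalize an allele frequency map onto *1, *2, *17
#'
#' Star alleles other than `*1`, `*2`, `*17` (e.g. a reported `*3` mass)
#' are dropped and the remaining three frequencies renormalized to sum to
#' 1; a warning records the dropped mass.
#'
#' @param raw Named numeric vector of allele frequencies; names must
#'   include `*1`, `*2`, `*17`.
#' @return A [haplotype_freqs()] object.
#' @export
#' @examples
#' suppressWarnings(renormalize_alleles(c("*1" = 0.57, "*2" = 0.19,
#'                                        "*17" = 0.19, "*3" = 0.05)))
renormalize_alleles <- function(raw) {
  need <- c("*1", "*2", "*17")
  if (is.null(names(raw)) || !all(need %in% names(raw))) {
    stop("raw must be a named vector containing *1, *2 and *17",
         call. = FALSE)
  }
  kept <- as.numeric(raw[need])
  if (anyNA(kept) || any(kept < 0)) {
    stop("allele frequencies must be non-negative numbers", call. = FALSE)
  }
  s <- sum(kept)
  if (s <= 0) stop("frequencies of *1, *2, *17 sum to zero", call. = FALSE)
  dropped <- sum(as.numeric(raw[setdiff(names(raw), need)]))
  if (dropped > 0) {
    warning(sprintf("dropped %.4g frequency mass on allele(s) %s and renormalized",
                    dropped,
                    paste(setdiff(names(raw), need), collapse = ", ")),
            call. = FALSE)
  }
  haplotype_freqs(kept[1] / s, kept[2] / s, kept[3] / s)
}

#' Project haplotype frequencies onto a population profile under HWE
#'
#' Hardy-Weinberg expansion of the trinomial `(h1 + h2 + h17)^2` gives the
#' six canonical haplogenotype (equivalently phenotype) frequencies:
#' EM = h1^2, IM = 2 h1 h2, PM = h2^2, RM = 2 h1 h17, UM = h17^2,
#' AM = 2 h2 h17.  The linkage-disequilibrium constraint makes the three
#' non-canonical haplogenotypes have frequency zero.
#'
#' @param h A [haplotype_freqs()] object (or numeric `c(h1, h2, h17)`).
#' @param name Population name carried in the profile.
#' @return An object of class `population_profile`: list with `name`,
#'   `haplogenotype_freq` (named over the six canonical haplogenotype
#'   strings), and `phenotype_freq` (named over PM, IM, AM, EM, RM, UM).
#' @export
#' @examples
#' expand_hwe(haplotype_freqs(0.6, 0.2, 0.2), "demo")
expand_hwe <- function(h, name = "population") {
  if (!inherits(h, "haplotype_freqs")) {
    h <- haplotype_freqs(h[[1]], h[[2]], h[[3]])
  }
  h1 <- h[["h1"]]; h2 <- h[["h2"]]; h17 <- h[["h17"]]
  pheno <- c(PM = h2^2, IM = 2 * h1 * h2, AM = 2 * h2 * h17,
             EM = h1^2, RM = 2 * h1 * h17, UM = h17^2)
  structure(list(
    name = name,
    haplogenotype_freq = setNames(pheno[.PHENO6], unname(.PHENO6_HG[.PHENO6])),
    phenotype_freq = pheno[.PHENO6]
  ), class = "population_profile")
}

#' @export
print.population_profile <- function(x, ...) {
  cat("Population profile:", x$name, "\n")
  print(round(x$phenotype_freq, 4))
  invisible(x)
}

#' Estimate haplotype frequencies from a genotyped cohort
#'
#' Allele-counting estimator valid under the linkage-disequilibrium
#' assumption: `h17` is the frequency of T alleles at rs12248560, `h2` the
#' frequency of A alleles at rs4244285, and `h1 = 1 - h17 - h2`.  Binomial
#' standard errors are attached.  Samples carrying a non-canonical
#' haplogenotype are counted in the allele tallies but flagged in the
#' `n_non_canonical` attribute, since the estimator's phasing assumption
#' does not hold for them.
#'
#' @param cohort Cohort data frame; only samples with both slots typed are
#'   used (at least one is required).
#' @return A [haplotype_freqs()] object with attributes `se` (named
#'   standard errors), `n` (callable samples used) and `n_non_canonical`.
#' @export
estimate_haplotype_freqs <- function(cohort) {
  cohort <- validate_cohort(cohort)
  ok <- !is.na(cohort$rs12248560) & !is.na(cohort$rs4244285)
  cohort <- cohort[ok, , drop = FALSE]
  n <- nrow(cohort)
  if (n == 0L) stop("no callable samples in cohort", call. = FALSE)
  count_alt <- function(gt, rsid) {
    alt <- .SNP_MARKERS[[rsid]]$alt
    sum(vapply(strsplit(gt, ""), function(a) sum(a == alt), 0L))
  }
  n_t <- count_alt(cohort$rs12248560, "rs12248560")
  n_a <- count_alt(cohort$rs4244285, "rs4244285")
  h17 <- n_t / (2 * n)
  h2 <- n_a / (2 * n)
  h1 <- 1 - h17 - h2
  if (h1 < 0) {
    stop("allele counts violate the linkage-disequilibrium assumption ",
         "(h1 < 0); the cohort cannot be summarized by three haplotypes",
         call. = FALSE)
  }
  hg <- call_haplogenotype(cohort$rs12248560, cohort$rs4244285)
  out <- haplotype_freqs(h1, h2, h17)
  attr(out, "se") <- c(h1 = sqrt(h1 * (1 - h1) / (2 * n)),
                       h2 = sqrt(h2 * (1 - h2) / (2 * n)),
                       h17 = sqrt(h17 * (1 - h17) / (2 * n)))
  attr(out, "n") <- n
  attr(out, "n_non_canonical") <- sum(!is_canonical_haplogenotype(hg))
  out
}

#' Convert a frequency vector to counts with a fixed total
#'
#' Largest-remainder allocation: counts are `floor(freq * n)` plus one unit
#' for the categories with the largest remainders, so the counts sum to
#' exactly `n`.  Ties are broken by category order.
#'
#' @param freq Numeric frequency vector (renormalized internally).
#' @param n Total count to allocate.
#' @return Integer vector of the same length and names as `freq`.
#' @export
largest_remainder_counts <- function(freq, n) {
  stopifnot(n >= 0, all(freq >= 0), sum(freq) > 0)
  freq <- freq / sum(freq)
  raw <- freq * n
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(freq))
}

.profile_counts <- function(x, n, who) {
  if (inherits(x, "population_profile")) {
    if (is.null(n)) stop("sample size for ", who, " must be given (or set ",
                         "equal_n) when a profile is supplied", call. = FALSE)
    return(largest_remainder_counts(x$phenotype_freq, n))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    if (any(x < 0) || anyNA(x)) stop(who, " counts must be non-negative",
                                     call. = FALSE)
    return(setNames(as.integer(round(x)), names(x)))
  }
  stop(who, " must be a population_profile or a named count vector",
       call. = FALSE)
}

#' Compare two population profiles with an exact chi-square test
#'
#' Builds a 2 x k contingency table of phenotype-class counts and computes
#' the Pearson chi-square statistic, a p-value (seeded Monte Carlo
#' conditional test with fixed margins in `"exact"` mode, chi-square
#' distribution in `"asymptotic"` mode), and Cramer's phi
#' `sqrt(chi2 / (N * (min(r, c) - 1)))` with the effect-size bins
#' below-medium (< 0.3), medium (0.3 to < 0.5), and large (>= 0.5).
#' Profiles supplied as frequencies are converted to counts by
#' largest-remainder allocation at the given sample sizes (the equal-n
#' convention: phi is unchanged by the common n).  Categories with zero
#' counts in both populations are pooled out of the table.
#'
#' @param a,b Population profiles ([expand_hwe()], [cohort_profile()]) or
#'   named count vectors over the same categories.
#' @param n_a,n_b Sample sizes used to realize frequency profiles as
#'   counts; ignored for count input.  Default `equal_n` for both.
#' @param mode `"exact"` (Monte Carlo, default) or `"asymptotic"`.
#' @param reps Monte Carlo replicates in exact mode.
#' @param seed Integer seed for the Monte Carlo draw (required in exact
#'   mode for reproducibility).
#' @param equal_n Default common sample size when profiles are given
#'   without explicit sizes.
#' @return An object of class `cyp2c19_comparison`: list with `chi2`,
#'   `dof`, `p_value`, `phi`, `effect_label`, `n_a`, `n_b`, `mode`,
#'   `table` (the contingency table used), and `pooled` (names of
#'   categories dropped as empty).
#' @export
compare_populations <- function(a, b, n_a = NULL, n_b = NULL,
                                mode = c("exact", "asymptotic"),
                                reps = 100000, seed = NULL,
                                equal_n = 10000) {
  mode <- match.arg(mode)
  if (inherits(a, "population_profile") && is.null(n_a)) n_a <- equal_n
  if (inherits(b, "population_profile") && is.null(n_b)) n_b <- equal_n
  ca <- .profile_counts(a, n_a, "a")
  cb <- .profile_counts(b, n_b, "b")
  if (!identical(sort(names(ca)), sort(names(cb)))) {
    stop("the two populations must be tabulated over the same categories",
         call. = FALSE)
  }
  cb <- cb[names(ca)]
  tab <- rbind(a = ca, b = cb)
  if (sum(tab) == 0) stop("zero-total contingency table", call. = FALSE)
  empty <- colSums(tab) == 0
  pooled <- colnames(tab)[empty]
  tab <- tab[, !empty, drop = FALSE]
  if (ncol(tab) < 2L) {
    stop("fewer than 2 non-empty categories; populations cannot be compared",
         call. = FALSE)
  }
  if (mode == "exact") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    ht <- suppressWarnings(stats::chisq.test(tab, simulate.p.value = TRUE,
                                             B = as.integer(reps)))
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  chi2 <- unname(ht$statistic)
  n_total <- sum(tab)
  phi <- sqrt(chi2 / (n_total * (min(dim(tab)) - 1)))
  structure(list(
    chi2 = chi2,
    dof = (nrow(tab) - 1L) * (ncol(tab) - 1L),
    p_value = unname(ht$p.value),
    phi = phi,
    effect_label = effect_size_label(phi),
    n_a = sum(ca),
    n_b = sum(cb),
    mode = mode,
    reps = if (mode == "exact") reps else NA_integer_,
    table = tab,
    pooled = pooled
  ), class = "cyp2c19_comparison")
}

#' Label a Cramer's phi effect size
#'
#' Bins: `medium` for 0.3 <= phi < 0.5, `large` for phi >= 0.5, and
#' `below-medium` otherwise (the scale defines only the upper two bins).
#'
#' @param phi Numeric vector of phi values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
effect_size_label <- function(phi) {
  stopifnot(all(phi >= 0 & phi <= 1 + 1e-12))
  ifelse(phi >= 0.5, "large", ifelse(phi >= 0.3, "medium", "below-medium"))
}

#' @export
print.cyp2c19_comparison <- function(x, ...) {
  cat(sprintf(
    "chi2 = %.4g (dof = %d), p = %.4g [%s], Cramer's phi = %.3f (%s); n = %d vs %d\n",
    x$chi2, x$dof, x$p_value, x$mode, x$phi, x$effect_label, x$n_a, x$n_b))
  if (length(x$pooled)) cat("pooled empty categories:",
                            paste(x$pooled, collapse = ", "), "\n")
  invisible(x)
}

#' Build an observed population profile from cohort calls
#'
#' Phenotype-class frequencies among callable samples.  By default the
#' UNKNOWN mass (carriers of non-canonical haplogenotypes, seen in
#' experimentally typed cohorts) is merged into the AM class, matching the
#' convention used when such cohorts are displayed next to
#' Hardy-Weinberg-projected profiles.
#'
#' @param calls A `cyp2c19_calls` object.
#' @param name Population name.
#' @param merge_unknown Merge the UNKNOWN class into AM (default TRUE).
#' @return A `population_profile`.
#' @export
cohort_profile <- function(calls, name = "cohort", merge_unknown = TRUE) {
  stopifnot(inherits(calls, "cyp2c19_calls"))
  counts <- calls$counts
  n <- sum(counts)
  if (n == 0L) stop("no callable samples", call. = FALSE)
  pheno <- counts[.PHENO6]
  if (merge_unknown) {
    pheno["AM"] <- pheno["AM"] + counts[["UNKNOWN"]]
  } else if (counts[["UNKNOWN"]] > 0) {
    warning("dropping ", counts[["UNKNOWN"]], " UNKNOWN sample(s) from the ",
            "profile", call. = FALSE)
    n <- n - counts[["UNKNOWN"]]
  }
  freq <- pheno / n
  structure(list(
    name = name,
    haplogenotype_freq = setNames(unname(freq), unname(.PHENO6_HG[.PHENO6])),
    phenotype_freq = setNames(as.numeric(freq), .PHENO6)
  ), class = "population_profile")
}

#' Long-format report over population profiles
#'
#' One row per population and phenotype class, suitable for tabulation or
#' a stacked-bar figure.
#'
#' @param profiles A `population_profile` or list of them.
#' @param file Optional TSV output path.
#' @return Data frame with columns `population`, `phenotype`, `frequency`.
#' @export
profile_report <- function(profiles, file = NULL) {
  if (inherits(profiles, "population_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("at least one profile is required", call. = FALSE)
  out <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(population = p$name,
               phenotype = factor(.PHENO6, levels = .PHENO6),
               frequency = as.numeric(p$phenotype_freq[.PHENO6]),
               row.names = NULL)
  }))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Stacked-bar figure of population phenotype profiles
#'
#' @param profiles A `population_profile` or list of them.
#' @param file Optional output path (`ggplot2::ggsave` formats).
#' @return The ggplot object, invisibly.
#' @export
plot_profiles <- function(profiles, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_profiles requires the ggplot2 package", call. = FALSE)
  }
  rep <- profile_report(profiles)
  p <- ggplot2::ggplot(rep, ggplot2::aes(x = population, y = frequency,
                                         fill = phenotype)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "frequency",
                  fill = "predictive\nphenotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 4)
  invisible(p)
}

#' Read a population allele-frequency CSV
#'
#' Expects columns `population`, `allele`, `frequency` -- the dialect a
#' database export of CYP2C19 star-allele frequencies can be massaged into.
#'
#' @param path CSV path.
#' @return Named list (one element per population) of named allele
#'   frequency vectors.
#' @export
read_allele_freq_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "allele", "frequency")
  if (!all(need %in% names(raw))) {
    stop("allele frequency CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  split_pop <- split(raw, raw$population)
  lapply(split_pop, function(d) setNames(as.numeric(d$frequency), d$allele))
}

#' Hardy-Weinberg profiles for every population in an allele CSV
#'
#' Composes [read_allele_freq_csv()], [renormalize_alleles()] and
#' [expand_hwe()].
#'
#' @param path CSV path (see [read_allele_freq_csv()]).
#' @return Named list of `population_profile` objects.
#' @export
profiles_from_allele_csv <- function(path) {
  pops <- read_allele_freq_csv(path)
  out <- lapply(names(pops), function(nm) {
    expand_hwe(renormalize_alleles(pops[[nm]]), name = nm)
  })
  setNames(out, names(pops))
}
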