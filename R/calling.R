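## Haplogenotype construction and predictive-phenotype classification.
##
## A haplogenotype pairs the star genotype at rs12248560 (*1/*17 axis) with
## the star genotype at rs4244285 (*1/*2 axis), written "<g17>/<g2>", e.g.
## "*1*17/*1*2".  Because *2 and *17 are in linkage disequilibrium (they do
## not co-occur on one haplotype), 6 of the 9 combinations are phaseable
## into a unique pair of star haplotypes and carry a defined predictive
## phenotype; the remaining 3 would require a cis *2-*17 haplotype and are
## classified UNKNOWN.

.G17_LEVELS <- c("*1*1", "*1*17", "*17*17")   # CC, CT, TT at rs12248560
.G2_LEVELS <- c("*1*1", "*1*2", "*2*2")       # GG, GA, AA at rs4244285

#' Phenotype labels used by the classifier
#'
#' PM poor, IM intermediate, AM ambivalent (provisional), EM extensive,
#' RM rapid, UM ultrarapid, plus UNKNOWN for the three non-phaseable
#' haplogenotypes.
#' @export
phenotype_levels <- function() c("PM", "IM", "AM", "EM", "RM", "UM", "UNKNOWN")

#' The full haplogenotype reference table
#'
#' Enumerates all 9 combinations of the two marker genotypes with, for each:
#' the display string, whether it is canonical (phaseable under the linkage
#' disequilibrium constraint), the predictive phenotype, the provisional
#' flag (TRUE only for AM), and -- for canonical rows -- the unique inferred
#' star-haplotype pair.
#'
#' @return A 9-row data frame with columns `g17`, `g2`, `haplogenotype`,
#'   `canonical`, `phenotype`, `provisional`, `hap_1`, `hap_2`.
#' @export
#' @examples
#' haplogenotype_table()
haplogenotype_table <- function() {
  grid <- expand.grid(g2 = .G2_LEVELS, g17 = .G17_LEVELS,
                      stringsAsFactors = FALSE)[, c("g17", "g2")]
  hg <- paste0(grid$g17, "/", grid$g2)
  pheno <- c(
    "*1*1/*1*1" = "EM", "*1*1/*1*2" = "IM", "*1*1/*2*2" = "PM",
    "*1*17/*1*1" = "RM", "*1*17/*1*2" = "AM", "*1*17/*2*2" = "UNKNOWN",
    "*17*17/*1*1" = "UM", "*17*17/*1*2" = "UNKNOWN", "*17*17/*2*2" = "UNKNOWN"
  )
  haps <- list(
    "*1*1/*1*1" = c("*1", "*1"), "*1*1/*1*2" = c("*1", "*2"),
    "*1*1/*2*2" = c("*2", "*2"), "*1*17/*1*1" = c("*1", "*17"),
    "*1*17/*1*2" = c("*17", "*2"), "*17*17/*1*1" = c("*17", "*17")
  )
  data.frame(
    g17 = grid$g17,
    g2 = grid$g2,
    haplogenotype = hg,
    canonical = !is.na(match(hg, names(haps))),
    phenotype = unname(pheno[hg]),
    provisional = unname(pheno[hg]) == "AM",
    hap_1 = vapply(hg, function(h) if (h %in% names(haps)) haps[[h]][1] else NA_character_, "", USE.NAMES = FALSE),
    hap_2 = vapply(hg, function(h) if (h %in% names(haps)) haps[[h]][2] else NA_character_, "", USE.NAMES = FALSE),
    row.names = NULL
  )
}

#' Call a haplogenotype from the two marker genotypes
#'
#' Deterministic total map from canonical genotype strings to the paired
#' star notation: rs12248560 CC/CT/TT become `*1*1`/`*1*17`/`*17*17` and
#' rs4244285 GG/GA/AA become `*1*1`/`*1*2`/`*2*2`.  Vectorized; a missing
#' slot is an uncallable error.
#'
#' @param rs12248560,rs4244285 Canonical genotype strings (see
#'   [normalize_genotype()]).
#' @return Character vector of haplogenotype strings, e.g. `"*1*17/*1*2"`.
#' @export
#' @examples
#' call_haplogenotype("CT", "GA")
call_haplogenotype <- function(rs12248560, rs4244285) {
  g17 <- .G17_LEVELS[match(normalize_genotype(rs12248560, "rs12248560"),
                           .genotype_levels("rs12248560"))]
  g2 <- .G2_LEVELS[match(normalize_genotype(rs4244285, "rs4244285"),
                         .genotype_levels("rs4244285"))]
  if (anyNA(g17) || anyNA(g2)) {
    stop("uncallable: missing genotype slot(s); both markers must be typed",
         call. = FALSE)
  }
  paste0(g17, "/", g2)
}

#' Is a haplogenotype canonical (phaseable)?
#' @param hg Haplogenotype string(s).
#' @return Logical vector.
#' @export
is_canonical_haplogenotype <- function(hg) {
  tab <- haplogenotype_table()
  i <- match(hg, tab$haplogenotype)
  if (anyNA(i)) {
    stop("unknown haplogenotype: ", paste(hg[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  tab$canonical[i]
}

#' Infer the star-haplotype pair of a canonical haplogenotype
#'
#' Under the linkage-disequilibrium constraint (no haplotype carries both
#' the `*2` and `*17` defining variants) each of the 6 canonical
#' haplogenotypes has exactly one consistent phasing.
#'
#' @param hg A single haplogenotype string.
#' @return An unordered pair, as a length-2 character vector of star
#'   haplotypes drawn from `*1`, `*2`, `*17`.
#' @export
#' @examples
#' infer_haplotypes("*1*17/*1*2")  # c("*17", "*2")
infer_haplotypes <- function(hg) {
  stopifnot(length(hg) == 1L)
  tab <- haplogenotype_table()
  i <- match(hg, tab$haplogenotype)
  if (is.na(i)) stop("unknown haplogenotype: ", hg, call. = FALSE)
  if (!tab$canonical[i]) {
    stop("cannot phase ", hg, ": it would require a haplotype carrying both ",
         "the *2 and *17 variants, excluded by their linkage disequilibrium",
         call. = FALSE)
  }
  c(tab$hap_1[i], tab$hap_2[i])
}

#' Reconstruct marker genotypes from a star-haplotype pair
#'
#' Inverse of [infer_haplotypes()]: `*17` contributes a T at rs12248560,
#' `*2` an A at rs4244285, `*1` the reference base at both.
#'
#' @param haps Length-2 character vector of star haplotypes.
#' @return Named list with canonical `rs12248560` and `rs4244285` genotypes.
#' @export
haplotypes_to_genotypes <- function(haps) {
  if (length(haps) != 2L || !all(haps %in% c("*1", "*2", "*17"))) {
    stop("haps must be two of *1, *2, *17", call. = FALSE)
  }
  n_t <- sum(haps == "*17")
  n_a <- sum(haps == "*2")
  list(rs12248560 = .genotype_levels("rs12248560")[n_t + 1L],
       rs4244285 = .genotype_levels("rs4244285")[n_a + 1L])
}

#' Classify the predictive metabolizer phenotype of a haplogenotype
#'
#' Total over all 9 haplogenotypes: `*17*17/*1*1` is UM, `*1*17/*1*1` RM,
#' `*1*1/*1*1` EM, `*1*1/*1*2` IM, `*1*1/*2*2` PM, `*1*17/*1*2` AM
#' (a provisional class -- the increased-function `*17` allele may not
#' compensate for the no-function `*2` allele), and the three non-canonical
#' combinations are UNKNOWN.
#'
#' @param hg Haplogenotype string(s).
#' @return Character vector of phenotype labels (see [phenotype_levels()]).
#' @export
#' @examples
#' classify_phenotype("*1*1/*2*2")  # "PM"
classify_phenotype <- function(hg) {
  tab <- haplogenotype_table()
  i <- match(hg, tab$haplogenotype)
  if (anyNA(i)) {
    stop("unknown haplogenotype: ", paste(hg[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  tab$phenotype[i]
}

#' Is a phenotype label provisional?
#'
#' Only AM is provisional: the haplogenotype combines alleles with opposing
#' functional effects and its metabolizer status awaits experimental
#' confirmation by therapeutic drug monitoring.
#' @param phenotype Character vector of phenotype labels.
#' @return Logical vector.
#' @export
phenotype_is_provisional <- function(phenotype) {
  bad <- setdiff(phenotype, phenotype_levels())
  if (length(bad)) stop("unknown phenotype: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  phenotype == "AM"
}

#' Call haplogenotypes and phenotypes for a cohort
#'
#' Calls every sample with both marker slots typed; samples with a missing
#' slot are reported in `$uncallable` (never silently dropped).
#'
#' @param cohort Cohort data frame (see [sample_genotypes()]).
#' @return An object of class `cyp2c19_calls`: a list with
#'   \describe{
#'     \item{calls}{data frame `sample_id`, `rs12248560`, `rs4244285`,
#'       `haplogenotype`, `canonical`, `phenotype`, `provisional`.}
#'     \item{uncallable}{data frame `sample_id`, `reason`.}
#'     \item{counts}{named integer vector over the 7 phenotype labels,
#'       summing to the number of callable samples.}
#'   }
#' @export
call_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  ok <- !is.na(cohort$rs12248560) & !is.na(cohort$rs4244285)
  callable <- cohort[ok, , drop = FALSE]
  calls <- data.frame(
    sample_id = callable$sample_id,
    rs12248560 = callable$rs12248560,
    rs4244285 = callable$rs4244285,
    haplogenotype = character(nrow(callable)),
    canonical = logical(nrow(callable)),
    phenotype = character(nrow(callable)),
    provisional = logical(nrow(callable)),
    row.names = NULL
  )
  if (nrow(callable)) {
    calls$haplogenotype <- call_haplogenotype(callable$rs12248560,
                                              callable$rs4244285)
    calls$canonical <- is_canonical_haplogenotype(calls$haplogenotype)
    calls$phenotype <- classify_phenotype(calls$haplogenotype)
    calls$provisional <- phenotype_is_provisional(calls$phenotype)
  }
  un <- cohort[!ok, , drop = FALSE]
  reason <- character(nrow(un))
  if (nrow(un)) {
    reason <- paste0("missing genotype at ",
                     ifelse(is.na(un$rs12248560) & is.na(un$rs4244285),
                            "rs12248560 and rs4244285",
                            ifelse(is.na(un$rs12248560), "rs12248560",
                                   "rs4244285")))
  }
  counts <- table(factor(calls$phenotype, levels = phenotype_levels()))
  structure(list(
    calls = calls,
    uncallable = data.frame(sample_id = un$sample_id, reason = reason,
                            row.names = NULL),
    counts = setNames(as.integer(counts), names(counts))
  ), class = "cyp2c19_calls")
}

#' @export
print.cyp2c19_calls <- function(x, ...) {
  cat("CYP2C19 cohort calls:", nrow(x$calls), "called,",
      nrow(x$uncallable), "uncallable\n")
  cat("Phenotype counts:\n")
  print(x$counts)
  invisible(x)
}

#' Write cohort calls to a TSV file
#'
#' @param calls A `cyp2c19_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  stopifnot(inherits(calls, "cyp2c19_calls"))
  utils::write.table(
    calls$calls[, c("sample_id", "haplogenotype", "phenotype", "provisional",
                    "canonical")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
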