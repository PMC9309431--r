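## The two CYP2C19 markers the toolkit understands.  rs12248560 (c.-806C>T)
## defines the gain-of-function *17 allele; rs4244285 (c.681G>A) defines the
## loss-of-function *2 allele.  CHROM/POS are GRCh38 and are written to VCF
## output as informational metadata only -- marker matching is always by rsID.
.SNP_MARKERS <- list(
  rs12248560 = list(rsid = "rs12248560", ref = "C", alt = "T",
                    chrom = "10", pos = 94761900L, star = "*17",
                    hgvs = "NM_000769.2:c.-806C>T"),
  rs4244285  = list(rsid = "rs4244285", ref = "G", alt = "A",
                    chrom = "10", pos = 94781859L, star = "*2",
                    hgvs = "NM_000769.2:c.681G>A")
)

.SUPPORTED_RSIDS <- names(.SNP_MARKERS)

#' Supported CYP2C19 marker definitions
#'
#' Returns the reference/alternate allele definitions for the two single
#' nucleotide polymorphisms used throughout the package: rs12248560 (C>T,
#' tagging the increased-function `*17` allele) and rs4244285 (G>A, tagging
#' the no-function `*2` allele).
#'
#' @return A data frame with one row per marker and columns `rsid`, `ref`,
#'   `alt`, `star_allele`, and `hgvs`.
#' @export
#' @examples
#' snp_markers()
snp_markers <- function() {
  data.frame(
    rsid = vapply(.SNP_MARKERS, `[[`, "", "rsid"),
    ref = vapply(.SNP_MARKERS, `[[`, "", "ref"),
    alt = vapply(.SNP_MARKERS, `[[`, "", "alt"),
    star_allele = vapply(.SNP_MARKERS, `[[`, "", "star"),
    hgvs = vapply(.SNP_MARKERS, `[[`, "", "hgvs"),
    row.names = NULL
  )
}

## Canonical genotype strings per marker, reference allele written first.
.genotype_levels <- function(rsid) {
  m <- .SNP_MARKERS[[rsid]]
  c(paste0(m$ref, m$ref), paste0(m$ref, m$alt), paste0(m$alt, m$alt))
}

#' Normalize a genotype token for one marker
#'
#' Accepts an unphased two-allele token in any case and allele order
#' (optionally separated by `/` or `|`; any phase information is discarded)
#' and returns the canonical reference-first genotype string, e.g. `"CT"`
#' for rs12248560 or `"GA"` for rs4244285.  Tokens equal to `missing_token`
#' (case-insensitively), `""`, `"."`, `"./."` or `NA` normalize to `NA`.
#' Alleles outside the marker's allele domain are an error, never silently
#' recoded.
#'
#' @param gt Character vector of genotype tokens.
#' @param rsid One of `"rs12248560"` or `"rs4244285"`.
#' @param missing_token Token representing a missing genotype (default
#'   `"NA"`).
#' @return Character vector of canonical genotypes, `NA` where missing.
#' @export
#' @examples
#' normalize_genotype(c("tc", "C/T", "NA"), "rs12248560")
normalize_genotype <- function(gt, rsid, missing_token = "NA") {
  rsid <- match.arg(rsid, .SUPPORTED_RSIDS)
  m <- .SNP_MARKERS[[rsid]]
  gt <- as.character(gt)
  out <- rep(NA_character_, length(gt))
  tok <- toupper(trimws(gt))
  miss <- is.na(tok) | tok %in% c(toupper(missing_token), "", ".", "./.", ".|.")
  for (i in which(!miss)) {
    alleles <- strsplit(gsub("[/|]", "", tok[i]), "")[[1]]
    if (length(alleles) != 2L || !all(alleles %in% c(m$ref, m$alt))) {
      stop(sprintf("invalid genotype '%s' for %s (alleles must be %s/%s)",
                   gt[i], rsid, m$ref, m$alt), call. = FALSE)
    }
    n_alt <- sum(alleles == m$alt)
    out[i] <- .genotype_levels(rsid)[n_alt + 1L]
  }
  out
}

#' Construct a validated sample-genotype cohort table
#'
#' The cohort container used by all downstream modules: one row per sample,
#' with canonical unphased genotypes at the two markers (`NA` where a slot
#' was not typed).  A sample with any missing slot is retained -- it is
#' reportable but not haplogenotype-callable.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param rs12248560,rs4244285 Genotype tokens (normalized via
#'   [normalize_genotype()]), recycled `NA` if omitted.
#' @param missing_token Token representing missing genotypes.
#' @return A data frame with columns `sample_id`, `rs12248560`, `rs4244285`.
#' @export
#' @examples
#' sample_genotypes("S1", "CT", "GA")
sample_genotypes <- function(sample_id, rs12248560 = NA, rs4244285 = NA,
                             missing_token = "NA") {
  sample_id <- as.character(sample_id)
  if (anyNA(sample_id) || any(!nzchar(sample_id))) {
    stop("sample_id must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(sample_id)
  df <- data.frame(
    sample_id = sample_id,
    rs12248560 = normalize_genotype(rep_len(rs12248560, n), "rs12248560",
                                    missing_token),
    rs4244285 = normalize_genotype(rep_len(rs4244285, n), "rs4244285",
                                   missing_token),
    row.names = NULL
  )
  df
}

## Validate a data frame as a genotype cohort (re-normalizes so externally
## assembled frames are accepted).
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame", call. = FALSE)
  need <- c("sample_id", "rs12248560", "rs4244285")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0L) {
    return(sample_genotypes(character(0)))
  }
  sample_genotypes(cohort$sample_id, cohort$rs12248560, cohort$rs4244285)
}
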