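## Genotype file I/O: VCF v4.x (read via vcfR, written as plain text) and a
## simple sample x rsID genotype table (CSV/TSV).  Marker records in VCF are
## located by rsID in the ID column; build-specific chrom/pos matching is
## available only through an explicit `loci` override.

.table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a sample-by-rsID genotype table
#'
#' Expects a CSV (`.csv`) or TSV file with exactly the columns `sample_id`,
#' `rs12248560`, `rs4244285` (any case, any order).  Genotype cells hold two
#' alleles in any order and case ("CT", "tc", "GG") or the missing token.
#'
#' @param path Path to the file.
#' @param missing_token Cell value denoting a missing genotype.
#' @return A validated cohort data frame (see [sample_genotypes()]).
#' @export
read_genotype_table <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = .table_sep(path),
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, na.strings = character(0))
  names(raw) <- tolower(names(raw))
  need <- c("sample_id", "rs12248560", "rs4244285")
  extra <- setdiff(names(raw), need)
  if (length(extra)) {
    stop("unknown column(s) in genotype table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- sample_genotypes(raw$sample_id, missing_token = missing_token)
  for (rsid in c("rs12248560", "rs4244285")) {
    out[[rsid]] <- vapply(seq_len(nrow(raw)), function(i) {
      tryCatch(normalize_genotype(raw[[rsid]][i], rsid, missing_token),
               error = function(e) {
                 stop(sprintf("row %d (sample %s): %s", i, raw$sample_id[i],
                              conditionMessage(e)), call. = FALSE)
               })
    }, character(1))
  }
  out
}

#' Write a cohort to a genotype table
#'
#' Inverse of [read_genotype_table()]; round-trip safe.
#'
#' @param cohort Cohort data frame.
#' @param path Output path (`.csv` for comma-separated, anything else TSV).
#' @param missing_token Token written for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(cohort, path, missing_token = "NA") {
  cohort <- validate_cohort(cohort)
  out <- cohort
  out$rs12248560[is.na(out$rs12248560)] <- missing_token
  out$rs4244285[is.na(out$rs4244285)] <- missing_token
  utils::write.table(out, path, sep = .table_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes for the two CYP2C19 markers from a VCF
#'
#' Parses a VCF v4.x file with vcfR and extracts the GT field at the two
#' supported markers.  Records are matched by rsID in the ID column unless a
#' positional override is supplied via `loci`.  Phase separators (`|`) are
#' accepted and discarded; multi-allelic records are decomposed and only the
#' marker's defined ALT allele is honored -- a genotype calling any other
#' allele is an allele-domain error naming the sample and rsID.  A marker
#' with no record yields a missing genotype for every sample.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @param samples Optional character vector restricting to these sample ids
#'   (an absent id is an error).
#' @param loci Optional positional override: a named list like
#'   `list(rs12248560 = list(chrom = "10", pos = 94761900))`; matching then
#'   uses CHROM/POS for that marker instead of the ID column.
#' @return A validated cohort data frame.
#' @export
read_genotype_vcf <- function(path, samples = NULL, loci = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- v@fix
  gt <- v@gt
  sample_ids <- if (!is.null(gt) && ncol(gt) > 1L) colnames(gt)[-1L] else character(0)
  if (!is.null(samples)) {
    absent <- setdiff(samples, sample_ids)
    if (length(absent)) {
      stop("sample(s) not present in VCF: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    sample_ids <- samples
  }
  cohort <- sample_genotypes(sample_ids)
  if (length(sample_ids) == 0L || is.null(fix) || nrow(fix) == 0L) {
    return(cohort)
  }

  for (rsid in .SUPPORTED_RSIDS) {
    ov <- loci[[rsid]]
    idx <- if (!is.null(ov)) {
      which(fix[, "CHROM"] == as.character(ov$chrom) &
              as.integer(fix[, "POS"]) == as.integer(ov$pos))
    } else {
      which(!is.na(fix[, "ID"]) & fix[, "ID"] == rsid)
    }
    if (length(idx) > 1L) {
      stop("ambiguous VCF: ", length(idx), " records match ", rsid,
           call. = FALSE)
    }
    if (length(idx) == 0L) next  # marker absent -> stays missing
    alleles <- c(fix[idx, "REF"], strsplit(fix[idx, "ALT"], ",", fixed = TRUE)[[1]])
    cohort[[rsid]] <- vapply(sample_ids, function(sid) {
      .vcf_gt_to_genotype(gt[idx, sid], alleles, rsid, sid)
    }, character(1), USE.NAMES = FALSE)
  }
  cohort
}

## Decode one GT subfield ("0/1", "1|1", "./.", possibly with trailing
## FORMAT fields) into a canonical genotype string or NA.
.vcf_gt_to_genotype <- function(cell, alleles, rsid, sample_id) {
  m <- .SNP_MARKERS[[rsid]]
  if (is.na(cell)) return(NA_character_)
  gt_str <- strsplit(cell, ":", fixed = TRUE)[[1]][1]
  parts <- strsplit(gt_str, "[/|]")[[1]]
  if (any(parts == ".") || length(parts) == 0L) return(NA_character_)
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
    stop(sprintf("unparseable GT '%s' for sample %s at %s", cell, sample_id,
                 rsid), call. = FALSE)
  }
  i <- as.integer(parts) + 1L
  if (any(i > length(alleles))) {
    stop(sprintf("GT '%s' for sample %s at %s indexes an undeclared allele",
                 cell, sample_id, rsid), call. = FALSE)
  }
  called <- alleles[i]
  bad <- setdiff(called, c(m$ref, m$alt))
  if (length(bad)) {
    stop(sprintf(
      "allele-domain error: sample %s carries allele '%s' at %s (expected %s/%s)",
      sample_id, bad[1], rsid, m$ref, m$alt), call. = FALSE)
  }
  normalize_genotype(paste(called, collapse = ""), rsid)
}

#' Write a cohort as a minimal VCF v4.3 file
#'
#' Emits a plain-text VCF carrying the two marker records with GT genotypes
#' for every sample (missing slots become `./.`).  With an empty cohort a
#' valid header-only file is written.  Round-trip safe with
#' [read_genotype_vcf()].
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  header <- c(
    "##fileformat=VCFv4.3",
    paste0("##source=cyp2c19sup-", as.character(utils::packageVersion("cyp2c19sup"))),
    "##reference=GRCh38",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  chrom_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", if (nrow(cohort)) c("FORMAT", cohort$sample_id)),
                      collapse = "\t")
  records <- character(0)
  if (nrow(cohort)) {
    records <- vapply(.SUPPORTED_RSIDS, function(rsid) {
      m <- .SNP_MARKERS[[rsid]]
      gts <- vapply(cohort[[rsid]], function(g) {
        if (is.na(g)) return("./.")
        n_alt <- sum(strsplit(g, "")[[1]] == m$alt)
        c("0/0", "0/1", "1/1")[n_alt + 1L]
      }, character(1), USE.NAMES = FALSE)
      paste(c(m$chrom, m$pos, rsid, m$ref, m$alt, ".", "PASS", ".", "GT", gts),
            collapse = "\t")
    }, character(1), USE.NAMES = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, chrom_line, records), con)
  invisible(path)
}

#' Read an I/O configuration file
#'
#' YAML configuration recognized keys: `missing_token` (string) and `loci`
#' (per-rsID `chrom`/`pos` overrides for positional VCF matching).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `missing_token` and `loci`.
#' @export
read_io_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(missing_token = cfg$missing_token %||% "NA",
              loci = cfg$loci %||% NULL)
  if (!is.null(out$loci)) {
    bad <- setdiff(names(out$loci), .SUPPORTED_RSIDS)
    if (length(bad)) {
      stop("loci override for unsupported rsID: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out
}
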