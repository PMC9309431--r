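# In-code fixtures shared across the suite.

# genotype strings for every haplogenotype row of the reference table
genotypes_for_table <- function(tab = haplogenotype_table()) {
  g17_map <- c("*1*1" = "CC", "*1*17" = "CT", "*17*17" = "TT")
  g2_map <- c("*1*1" = "GG", "*1*2" = "GA", "*2*2" = "AA")
  data.frame(haplogenotype = tab$haplogenotype,
             rs12248560 = unname(g17_map[tab$g17]),
             rs4244285 = unname(g2_map[tab$g2]),
             row.names = NULL)
}

# one sample per canonical haplogenotype
canonical_cohort <- function() {
  tab <- haplogenotype_table()
  g <- genotypes_for_table(tab[tab$canonical, ])
  sample_genotypes(paste0("C", seq_len(nrow(g))), g$rs12248560, g$rs4244285)
}

# one sample per haplogenotype (9 rows), plus optional missing-slot samples
all9_cohort <- function() {
  g <- genotypes_for_table()
  sample_genotypes(paste0("A", seq_len(nrow(g))), g$rs12248560, g$rs4244285)
}

write_text_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# minimal two-record VCF with arbitrary GT cells
vcf_lines <- function(samples, gt12248560, gt4244285,
                      alt12248560 = "T", alt4244285 = "A",
                      extra_records = character(0)) {
  c("##fileformat=VCFv4.3",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(c("10", "94761900", "rs12248560", "C", alt12248560, ".", "PASS",
            ".", "GT", gt12248560), collapse = "\t"),
    paste(c("10", "94781859", "rs4244285", "G", alt4244285, ".", "PASS",
            ".", "GT", gt4244285), collapse = "\t"),
    extra_records)
}

# independent allele mapping used as a phasing oracle: what bases each star
# haplotype carries at (rs12248560, rs4244285)
oracle_hap_bases <- list("*1" = c("C", "G"), "*2" = c("C", "A"),
                         "*17" = c("T", "G"))

default_ctx <- function(drug = "omeprazole", ...) {
  clinical_context(drug = drug, ...)
}
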