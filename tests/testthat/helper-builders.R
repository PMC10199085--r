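# In-code builders for genotype and annotation fixtures.

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                      "Description=\"Genotype\">"),
               lines), path)
  path
}

vcf_header_line <- function(samples) {
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", samples), collapse = "\t")
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# blank annotation row(s) with sensible defaults, overridable per column
make_annotation <- function(n = 1, ...) {
  df <- data.frame(
    gene = rep("ABCB4", n), transcript = "", protein_change = "X1Y",
    cdna_change = "", dbsnp = "", consequence = "missense_variant",
    af_gnomad = NA_real_, af_cohort = 0.001,
    polyphen = NA_real_, sift = NA_real_, cadd = NA_real_,
    revel = NA_real_, metalr = NA_character_, metasvm = NA_character_,
    mcap = NA_real_,
    literature_known = FALSE, clinvar = "", acmg_codes = "",
    phenotype_groups = "", zygosity = "het",
    het_n = NA_real_, hom_n = NA_real_,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df$protein_change <- make.unique(df$protein_change, sep = "_")
  df$variant_id <- variant_id(df$gene, df$protein_change, df$cdna_change)
  df
}

# the combined printed variant tables, classified
combined_fixture <- function() {
  classify_variants(rbind(chol_fixture("phenotype_variants"),
                          chol_fixture("lof_variants")))
}

# one burden replicate on a single-gene simulated cohort; returns p (NA on
# empty collapse)
burden_rep_p <- function(cfg, gene = cfg$genes[1]) {
  sim <- simulate_cohort(cfg)
  res <- cmc_exact(sim$genotypes, gene, sim$truth$case)
  if (is_empty_collapse(res)) NA_real_ else res$p_value
}

calibration_config <- function(seed, or = 1) {
  sim_config(n_samples = 2000, seed = seed, genes = "ABCB11",
             n_variants = 20, af_range = c(1e-4, 0.01), prevalence = 0.5,
             or = c(ABCB11 = or), frac_tsba_missing = 0, p_pathogenic = 0)
}

recovery_config <- function(seed, or = 4, focal = "ABCB11") {
  cfg_or <- stats::setNames(or, focal)
  sim_config(seed = seed, or = cfg_or)
}
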