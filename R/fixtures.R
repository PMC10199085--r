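#' Packaged in-print fixtures
#'
#' Loads the tables shipped with the package: the ICP case report
#' (volunteers with an ICP diagnosis, their variants and highest total serum
#' bile acid concentration), the phenotype-associated non-synonymous variant
#' table, the loss-of-function variant table and the candidate-gene
#' description table. Printed allele-frequency strings are preserved to all
#' printed digits in the underlying TSV files.
#'
#' @param which One of `"icp_cases"`, `"phenotype_variants"`,
#'   `"lof_variants"`, `"gene_candidates"`.
#' @return A data.frame; the two variant tables are parsed with
#'   [read_annotation_table()] and so carry `variant_id` and typed columns.
#' @export
chol_fixture <- function(which = c("icp_cases", "phenotype_variants",
                                   "lof_variants", "gene_candidates")) {
  which <- match.arg(which)
  file <- switch(which,
    icp_cases          = "table2_icp_cases.tsv",
    phenotype_variants = "table3_phenotype_variants.tsv",
    lof_variants       = "table4_lof_variants.tsv",
    gene_candidates    = "table5_gene_candidates.tsv")
  path <- system.file("extdata", file, package = "cholvar", mustWork = TRUE)
  if (which %in% c("phenotype_variants", "lof_variants")) {
    read_annotation_table(path)
  } else if (which == "icp_cases") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(volunteer_id = "character"))
    df$highest_tsba <- as.numeric(df$highest_tsba)
    df
  } else {
    gene_registry()
  }
}

#' Copy the packaged table fixtures to a directory
#'
#' Emits byte-stable copies of the four packaged TSV fixtures, e.g. to seed a
#' pipeline run directory.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
emit_table_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c("table2_icp_cases.tsv", "table3_phenotype_variants.tsv",
             "table4_lof_variants.tsv", "table5_gene_candidates.tsv")
  out <- file.path(dir, files)
  for (i in seq_along(files)) {
    src <- system.file("extdata", files[i], package = "cholvar",
                       mustWork = TRUE)
    file.copy(src, out[i], overwrite = TRUE)
  }
  invisible(out)
}
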