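ANNOTATION_COLUMNS <- c(
  "gene", "transcript", "protein_change", "cdna_change", "dbsnp",
  "consequence", "af_gnomad", "af_cohort",
  "polyphen", "sift", "cadd", "revel", "metalr", "metasvm", "mcap",
  "literature_known", "clinvar", "acmg_codes", "phenotype_groups",
  "zygosity", "het_n", "hom_n")

PREDICTOR_TOOLS <- c("polyphen", "sift", "cadd", "revel",
                     "metalr", "metasvm", "mcap")

#' Build the stable variant identifier
#'
#' Variants are keyed `"GENE:protein_change"`; when the protein-level label is
#' absent or uninformative (splice variants reported only at cDNA level) the
#' cDNA change is used instead, e.g. `"ABCB11:c.2611-2A>T"`.
#'
#' @param gene,protein_change,cdna_change Character vectors (recycled).
#' @return Character vector of identifiers.
#' @export
variant_id <- function(gene, protein_change, cdna_change = "") {
  protein_change[is.na(protein_change)] <- ""
  cdna_change[is.na(cdna_change)] <- ""
  label <- ifelse(!nzchar(protein_change) | grepl("?", protein_change,
                                                  fixed = TRUE),
                  ifelse(nzchar(cdna_change), cdna_change, protein_change),
                  protein_change)
  paste(gene, label, sep = ":")
}

#' Read an annotated-variant table
#'
#' Reads a TSV of annotated variants (one row per variant) into a typed
#' data.frame. Empty allele-frequency cells become `NA` ("no recorded
#' frequency"), never 0 — absence of a gnomAD frequency is itself an analysis
#' signal (a cohort-private variant). Phenotype labels are validated against
#' [phenotype_vocabulary()], and allele frequencies against \[0, 1\].
#'
#' @param path Path to a tab-separated file with the fixed header
#'   (gene, transcript, protein_change, cdna_change, dbsnp, consequence,
#'   af_gnomad, af_cohort, the seven predictor columns, literature_known,
#'   clinvar, acmg_codes, phenotype_groups, zygosity, het_n, hom_n; an
#'   optional printed_verdict column is kept when present).
#' @return data.frame with one row per variant, a `variant_id` column, and
#'   `phenotype_groups` as a `;`-separated string (`""` for none).
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = "character")
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  chr_cols <- c("gene", "transcript", "protein_change", "cdna_change",
                "dbsnp", "consequence", "clinvar", "acmg_codes",
                "phenotype_groups", "zygosity")
  for (cc in chr_cols) df[[cc]][is.na(df[[cc]])] <- ""
  num_cols <- c("af_gnomad", "af_cohort", PREDICTOR_TOOLS, "het_n", "hom_n")
  num_cols <- setdiff(num_cols, c("metalr", "metasvm"))  # categorical D/T or score
  for (nc in num_cols) df[[nc]] <- as.numeric(df[[nc]])
  df$literature_known <- as.logical(df$literature_known)
  df$literature_known[is.na(df$literature_known)] <- FALSE

  for (af in c("af_gnomad", "af_cohort")) {
    v <- df[[af]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop(af, " out of [0, 1] on row(s) ", paste(bad, collapse = ", "),
           " (value ", paste(v[bad], collapse = ", "), ")", call. = FALSE)
  }

  vocab <- phenotype_vocabulary()
  groups <- parse_phenotype_groups(df$phenotype_groups)
  unknown <- setdiff(unique(unlist(groups)), vocab)
  if (length(unknown))
    stop("unknown phenotype label(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(vocab, collapse = ", "), call. = FALSE)

  df$variant_id <- variant_id(df$gene, df$protein_change, df$cdna_change)
  if (anyDuplicated(df$variant_id))
    stop("duplicate variant_id: ",
         paste(unique(df$variant_id[duplicated(df$variant_id)]),
               collapse = ", "), call. = FALSE)
  df
}

# ";"-separated phenotype cell -> list of label vectors ("none"/"" -> empty)
parse_phenotype_groups <- function(x) {
  if (length(x) == 0) return(list())
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(g) {
    g <- trimws(g)
    setdiff(g[nzchar(g)], "none")
  })
}

#' Extract the seven-tool in-silico predictor panel from a variant row
#'
#' @param record One annotation row (data.frame or named list).
#' @return Named list with one entry per tool (`polyphen`, `sift`, `cadd`,
#'   `revel`, `metalr`, `metasvm`, `mcap`); numeric score, categorical call
#'   ("D"/"T") for the meta-predictors, or `NA` when missing.
#' @export
predictor_panel <- function(record) {
  panel <- lapply(PREDICTOR_TOOLS, function(t) {
    v <- record[[t]]
    if (is.null(v) || length(v) == 0) NA else v[[1]]
  })
  names(panel) <- PREDICTOR_TOOLS
  panel
}

#' Read an EHR phenotype table
#'
#' @param path TSV with columns `sample_id`, `sex` (F/M/unknown), `icd10`
#'   (`;`-separated codes), `tsba` (`;`-separated total serum bile acid
#'   measurements, umol/L) and `icp_verified` (logical; clinician
#'   verification of the ICP diagnosis).
#' @return data.frame with list-columns `icd10_codes` and `tsba_measurements`
#'   plus a `highest_tsba` convenience column (`NA` when no measurement).
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = "character")
  need <- c("sample_id", "sex", "icd10", "tsba", "icp_verified")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in phenotype table", call. = FALSE)
  df$sex[is.na(df$sex)] <- "unknown"
  df$icd10_codes <- lapply(strsplit(ifelse(is.na(df$icd10), "", df$icd10),
                                    ";", fixed = TRUE),
                           function(x) trimws(x[nzchar(trimws(x))]))
  df$tsba_measurements <- lapply(
    strsplit(ifelse(is.na(df$tsba), "", df$tsba), ";", fixed = TRUE),
    function(x) as.numeric(x[nzchar(trimws(x))]))
  bad <- vapply(df$tsba_measurements,
                function(v) length(v) && any(v < 0), logical(1))
  if (any(bad))
    stop("negative TSBA value for sample(s) ",
         paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  df$icp_verified <- as.logical(df$icp_verified)
  df$icp_verified[is.na(df$icp_verified)] <- FALSE
  df$highest_tsba <- vapply(df$tsba_measurements, function(v)
    if (length(v)) max(v) else NA_real_, numeric(1))
  df
}

#' Write an annotation or report table as TSV
#'
#' Stable column order, tab-separated, no quoting — suitable for diff-based
#' regression checks.
#'
#' @param df data.frame (list-columns are collapsed with `;`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  flat <- df
  for (nm in names(flat)) {
    if (is.list(flat[[nm]]))
      flat[[nm]] <- vapply(flat[[nm]], function(x)
        paste(x, collapse = ";"), character(1))
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
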