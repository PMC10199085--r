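#' Deleteriousness thresholds for the seven in-silico predictors
#'
#' Default cutoffs follow each tool's published recommendation: SIFT calls a
#' substitution deleterious at score <= 0.05 (low = damaging), PolyPhen-2 at
#' probability >= 0.446, CADD at phred >= 20, REVEL at >= 0.5, M-CAP at
#' >= 0.025; MetaLR and MetaSVM are categorical ("D" damaging / "T"
#' tolerated) but a numeric score >= 0.5 is also accepted.
#'
#' @param sift,polyphen,cadd,revel,mcap Numeric cutoffs.
#' @param metalr,metasvm Damaging category label.
#' @return Named list of thresholds with the comparison direction baked into
#'   [predictor_call()].
#' @export
predictor_thresholds <- function(sift = 0.05, polyphen = 0.446, cadd = 20,
                                 revel = 0.5, mcap = 0.025,
                                 metalr = "D", metasvm = "D") {
  stopifnot(sift >= 0, sift <= 1, polyphen >= 0, polyphen <= 1,
            cadd >= 0, revel >= 0, revel <= 1, mcap >= 0, mcap <= 1)
  list(sift = sift, polyphen = polyphen, cadd = cadd, revel = revel,
       mcap = mcap, metalr = metalr, metasvm = metasvm)
}

#' Call one predictor as deleterious / tolerated / unknown
#'
#' @param tool One of `"polyphen"`, `"sift"`, `"cadd"`, `"revel"`,
#'   `"metalr"`, `"metasvm"`, `"mcap"`.
#' @param value Score (numeric) or category ("D"/"T") for the meta
#'   predictors; `NA` for missing.
#' @param thresholds See [predictor_thresholds()].
#' @return `"deleterious"`, `"tolerated"` or `"unknown"`.
#' @export
predictor_call <- function(tool, value, thresholds = predictor_thresholds()) {
  if (!tool %in% PREDICTOR_TOOLS)
    stop("unknown predictor tool: '", tool, "'", call. = FALSE)
  if (is.null(value) || length(value) == 0 || is.na(value)) return("unknown")
  if (tool %in% c("metalr", "metasvm")) {
    if (is.character(value) && !nzchar(value)) return("unknown")
    if (is.character(value))
      return(if (toupper(value) == toupper(thresholds[[tool]]))
        "deleterious" else "tolerated")
    return(if (as.numeric(value) >= 0.5) "deleterious" else "tolerated")
  }
  value <- as.numeric(value)
  hit <- switch(tool,
    sift     = value <= thresholds$sift,    # low SIFT = damaging
    polyphen = value >= thresholds$polyphen,
    cadd     = value >= thresholds$cadd,
    revel    = value >= thresholds$revel,
    mcap     = value >= thresholds$mcap)
  if (hit) "deleterious" else "tolerated"
}

#' Unanimous in-silico consensus
#'
#' TRUE only when all seven predictors are present and all seven call the
#' variant deleterious ("prediction of 7"): a single missing or tolerated
#' call breaks unanimity.
#'
#' @param panel Named list from [predictor_panel()].
#' @param thresholds See [predictor_thresholds()].
#' @return Logical scalar.
#' @export
unanimous_insilico <- function(panel, thresholds = predictor_thresholds()) {
  calls <- vapply(PREDICTOR_TOOLS, function(t)
    predictor_call(t, panel[[t]], thresholds), character(1))
  all(calls == "deleterious")
}

#' Apply the inclusion rule to one variant
#'
#' A variant enters the analysis when it is protein-altering (missense or
#' loss-of-function; synonymous variants are excluded upstream), passes the
#' minor-allele-frequency gate (MAF < `maf_cutoff`, on the gnomAD frequency
#' when recorded, else the cohort frequency), and meets at least one of four
#' criteria: (1) an associated phenotype in the carriers' health records;
#' (2) known in the literature; (3) cohort-private — no recorded gnomAD
#' frequency but present in the cohort; (4) unanimously deleterious across
#' all seven in-silico predictors. A common variant (MAF gate failed) is
#' retained only for criterion 1 and flagged `maf_exempt`: a phenotype link
#' observed in this cohort is reported regardless of population frequency.
#'
#' @param record One annotation row, already classified (needs
#'   `consequence_class`).
#' @param thresholds Predictor thresholds, see [predictor_thresholds()].
#' @param maf_cutoff MAF gate, default 0.05.
#' @param maf_exemption Keep phenotype-linked common variants (default TRUE).
#' @return List with `included` (logical), `reasons` (character subset of
#'   `has_phenotype`, `literature_known`, `cohort_private`,
#'   `unanimous_insilico`), `maf_pass` and `maf_exempt` (logicals).
#' @export
passes_inclusion <- function(record, thresholds = predictor_thresholds(),
                             maf_cutoff = 0.05, maf_exemption = TRUE) {
  cls <- record$consequence_class
  if (is.null(cls))
    stop("record lacks consequence_class; run classify_variants() first",
         call. = FALSE)
  protein_altering <- cls == "missense" || is_lof(cls)

  af <- if (!is.na(record$af_gnomad)) record$af_gnomad else record$af_cohort
  maf_pass <- is.na(af) || af < maf_cutoff

  groups <- parse_phenotype_groups(record$phenotype_groups)[[1]]
  reasons <- c(
    has_phenotype      = length(groups) > 0,
    literature_known   = isTRUE(record$literature_known),
    cohort_private     = is.na(record$af_gnomad) && !is.na(record$af_cohort),
    unanimous_insilico = unanimous_insilico(predictor_panel(record),
                                            thresholds))
  maf_exempt <- !maf_pass && maf_exemption && reasons[["has_phenotype"]]
  included <- protein_altering && any(reasons) && (maf_pass || maf_exempt)
  list(included = included,
       reasons = names(reasons)[reasons],
       maf_pass = maf_pass,
       maf_exempt = maf_exempt)
}

#' Filter a variant table by the inclusion rule
#'
#' Row order is preserved; the operation is idempotent (filtering the
#' filtered subset returns it unchanged).
#'
#' @param records Classified annotation data.frame (a `consequence_class`
#'   column is added via [classify_variants()] when absent).
#' @inheritParams passes_inclusion
#' @return List with `records` (the included subset, plus `included`,
#'   `reasons`, `maf_pass`, `maf_exempt` columns), `decisions` (all rows with
#'   the same columns) and `gene_counts` (named integer vector of included
#'   variants per gene).
#' @export
filter_table <- function(records, thresholds = predictor_thresholds(),
                         maf_cutoff = 0.05, maf_exemption = TRUE) {
  if (is.null(records$consequence_class))
    records <- classify_variants(records)
  n <- nrow(records)
  records$included <- logical(n)
  records$reasons <- character(n)
  records$maf_pass <- logical(n)
  records$maf_exempt <- logical(n)
  for (i in seq_len(n)) {
    d <- passes_inclusion(records[i, , drop = FALSE], thresholds,
                          maf_cutoff, maf_exemption)
    records$included[i] <- d$included
    records$reasons[i] <- paste(d$reasons, collapse = ";")
    records$maf_pass[i] <- d$maf_pass
    records$maf_exempt[i] <- d$maf_exempt
  }
  kept <- records[records$included, , drop = FALSE]
  counts <- table(factor(kept$gene, levels = unique(records$gene)))
  list(records = kept, decisions = records,
       gene_counts = stats::setNames(as.integer(counts), names(counts)))
}
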