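#' Case-selection criteria for EHR phenotype linkage
#'
#' Intrahepatic cholestasis of pregnancy (ICP) is ascertained from
#' electronic health records through either a raised total serum bile acid
#' (TSBA) concentration or a diagnosis code. Thresholds are inclusive
#' (>=): 10 umol/L defines a raised TSBA, 40 umol/L severe disease.
#'
#' @param tsba_threshold Raised-TSBA threshold, umol/L (default 10).
#' @param severe_threshold Severe-disease threshold, umol/L (default 40).
#' @param icd10_code Diagnosis code for liver disease in pregnancy
#'   (default `"O26.6"`).
#' @param require_clinician_verification Restrict code-based selection to
#'   records flagged as clinician-verified.
#' @return Named list of criteria.
#' @export
linkage_criteria <- function(tsba_threshold = 10, severe_threshold = 40,
                             icd10_code = "O26.6",
                             require_clinician_verification = FALSE) {
  stopifnot(tsba_threshold > 0, severe_threshold > tsba_threshold)
  list(tsba_threshold = tsba_threshold, severe_threshold = severe_threshold,
       icd10_code = icd10_code,
       require_clinician_verification = require_clinician_verification)
}

#' Select ICP cases from phenotype records
#'
#' `by_code` selects samples bearing the diagnosis code; `by_ba` selects
#' samples whose highest TSBA reaches the threshold; `union` combines both.
#' The report also lists the two discordance strata a bidirectional
#' phenotype-genotype analysis needs: code-positive samples with no bile
#' acid measurement (missed by a laboratory-driven secondary analysis) and
#' BA-positive samples without the code (raised bile acids with an
#' uncertain or absent diagnosis).
#'
#' @param records Phenotype data.frame from [read_phenotype_table()].
#' @param criteria See [linkage_criteria()].
#' @param strategy `"by_code"`, `"by_ba"` or `"union"`.
#' @return List with `selected` (sample ids), `highest_tsba` (named numeric,
#'   all input samples), `code_positive_ba_missing`,
#'   `ba_positive_code_negative`, and `strategy`.
#' @export
select_icp_cases <- function(records, criteria = linkage_criteria(),
                             strategy = c("by_code", "by_ba", "union")) {
  strategy <- match.arg(strategy)
  bad <- vapply(records$tsba_measurements,
                function(v) length(v) && any(v < 0), logical(1))
  if (any(bad))
    stop("negative TSBA value for sample(s) ",
         paste(records$sample_id[bad], collapse = ", "), call. = FALSE)
  highest <- stats::setNames(records$highest_tsba, records$sample_id)
  has_code <- vapply(records$icd10_codes, function(codes)
    criteria$icd10_code %in% codes, logical(1))
  if (criteria$require_clinician_verification)
    has_code <- has_code & records$icp_verified
  ba_pos <- !is.na(highest) & highest >= criteria$tsba_threshold
  sel <- switch(strategy,
                by_code = has_code,
                by_ba = ba_pos,
                union = has_code | ba_pos)
  list(selected = records$sample_id[sel],
       highest_tsba = highest,
       code_positive_ba_missing = records$sample_id[has_code & is.na(highest)],
       ba_positive_code_negative = records$sample_id[ba_pos & !has_code],
       strategy = strategy)
}

#' Flag severe disease from the highest TSBA
#'
#' @param highest_tsba Numeric vector of highest TSBA per sample (umol/L).
#' @param criteria See [linkage_criteria()].
#' @return Logical vector; `NA` (unknown, not `FALSE`) where no measurement
#'   exists.
#' @export
flag_severe <- function(highest_tsba, criteria = linkage_criteria()) {
  ifelse(is.na(highest_tsba), NA, highest_tsba >= criteria$severe_threshold)
}

#' Per-gene variant counts by phenotype group
#'
#' A variant linked to several phenotype groups counts once in each group;
#' variants without a phenotype are not counted.
#'
#' @param records Annotation data.frame with `gene` and `phenotype_groups`.
#' @return Integer matrix, genes x phenotype groups (controlled vocabulary
#'   minus `"none"`).
#' @export
genotype_phenotype_counts <- function(records) {
  vocab <- setdiff(phenotype_vocabulary(), "none")
  genes <- unique(records$gene)
  m <- matrix(0L, length(genes), length(vocab),
              dimnames = list(genes, vocab))
  groups <- parse_phenotype_groups(records$phenotype_groups)
  for (i in seq_len(nrow(records))) {
    for (g in groups[[i]]) m[records$gene[i], g] <- m[records$gene[i], g] + 1L
  }
  m
}

#' Assemble the ICP case report
#'
#' One row per selected sample carrying at least one included variant,
#' listing every carried variant with its zygosity and consequence type,
#' plus the sample's highest TSBA. Samples carrying no variant are reported
#' in a separate annex, mirroring a case-report table where every printed
#' row documents at least one variant.
#'
#' @param carried Long-format data.frame of carried variants with columns
#'   `volunteer_id`, `gene`, `protein_change`, `zygosity`, `type` and
#'   optionally `highest_tsba` — e.g. the packaged ICP case fixture, or the
#'   output of [carried_variants()].
#' @param selected Optional vector of selected sample ids; defaults to the
#'   ids present in `carried`. Ids in `selected` with no row in `carried`
#'   go to the annex.
#' @return List with `rows` (one element per volunteer: `volunteer_id`,
#'   `highest_tsba`, `variants` data.frame) and `no_variant` (ids).
#' @export
icp_case_report <- function(carried, selected = NULL) {
  if (is.null(selected)) selected <- unique(carried$volunteer_id)
  unknown <- setdiff(unique(carried$volunteer_id), selected)
  if (length(unknown))
    stop("carried variants for unselected sample id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rows <- lapply(selected[selected %in% carried$volunteer_id], function(id) {
    sub <- carried[carried$volunteer_id == id, , drop = FALSE]
    tsba <- if ("highest_tsba" %in% names(sub))
      suppressWarnings(max(sub$highest_tsba, na.rm = TRUE)) else NA_real_
    if (!is.finite(tsba)) tsba <- NA_real_
    list(volunteer_id = id, highest_tsba = tsba,
         variants = sub[, intersect(c("gene", "protein_change", "zygosity",
                                      "type"), names(sub)), drop = FALSE])
  })
  list(rows = rows,
       no_variant = setdiff(selected, carried$volunteer_id))
}

#' Carried included variants per sample, from genotypes
#'
#' Joins a genotype matrix against an included-variant table to produce the
#' long format [icp_case_report()] consumes. Variant keys of the matrix
#' must match the annotation `variant_id`.
#'
#' @param gm A [genotype_matrix()].
#' @param records Annotation data.frame (included variants), with
#'   `variant_id`, `gene`, `protein_change` and (optionally)
#'   `consequence_class`.
#' @param phenotypes Optional phenotype table supplying `highest_tsba`.
#' @param samples Sample ids to report (default all in `gm`).
#' @return Long-format data.frame of carried variants.
#' @export
carried_variants <- function(gm, records, phenotypes = NULL, samples = NULL) {
  if (is.null(samples)) samples <- gm$sample_ids
  missing_ids <- setdiff(samples, gm$sample_ids)
  if (length(missing_ids))
    stop("sample id(s) absent from genotype matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  keys <- intersect(gm$variant_keys, records$variant_id)
  out <- list()
  for (id in samples) {
    g <- gm$allele_counts[match(id, gm$sample_ids), keys]
    hit <- which(!is.na(g) & g >= 1L)
    if (length(hit) == 0) next
    rec <- records[match(keys[hit], records$variant_id), , drop = FALSE]
    type <- if (!is.null(rec$consequence_class)) rec$consequence_class
            else rec$consequence
    out[[length(out) + 1L]] <- data.frame(
      volunteer_id = id, gene = rec$gene,
      protein_change = rec$protein_change,
      zygosity = ifelse(g[hit] == 2L, "hom", "het"),
      type = type, stringsAsFactors = FALSE)
  }
  carried <- if (length(out)) do.call(rbind, out) else
    data.frame(volunteer_id = character(), gene = character(),
               protein_change = character(), zygosity = character(),
               type = character(), stringsAsFactors = FALSE)
  if (!is.null(phenotypes)) {
    carried$highest_tsba <-
      phenotypes$highest_tsba[match(carried$volunteer_id,
                                    phenotypes$sample_id)]
  }
  carried
}
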