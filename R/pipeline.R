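#' Run configuration for the full pipeline
#'
#' Accepts a YAML file path or a named list. Recognised fields:
#' `annotation` (path, required), `vcf` and `phenotypes` (paths, optional —
#' burden and linkage stages are skipped without them), `out_dir`
#' (required), `seed`, an `inclusion` block (`maf_cutoff`, `maf_exemption`,
#' `thresholds` overriding [predictor_thresholds()]), `acmg_mode`, a
#' `burden` block (`af_threshold`, `alpha`, `alternative`) and a `linkage`
#' block (`tsba_threshold`, `severe_threshold`, `icd10_code`,
#' `require_clinician_verification`, `strategy`).
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated configuration list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path")
  if (is.null(config$annotation))
    stop("config needs an 'annotation' table path", call. = FALSE)
  if (is.null(config$out_dir))
    stop("config needs an 'out_dir'", call. = FALSE)
  for (p in c("annotation", "vcf", "phenotypes")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop("config path for '", p, "' does not exist: ", config[[p]],
           call. = FALSE)
  }
  config$seed <- config$seed %||% 1L
  config$acmg_mode <- config$acmg_mode %||% "strict"
  config
}

#' Run the analysis pipeline
#'
#' Stages run in order: consequence classification, inclusion filtering,
#' ACMG-AMP verdicts, per-gene burden testing (only when genotypes and
#' phenotypes are supplied), and phenotype linkage. Each stage's output is
#' persisted as TSV under `out_dir`, and a run log records the row counts
#' entering and leaving every stage.
#'
#' @param config See [run_config()].
#' @return List with `included`, `verdicts`, `burden` (list of
#'   `burden_result` / `empty_collapse` per gene, or `NULL`), `linkage`
#'   (or `NULL`), `summary` (per-gene matrix from [render_summary()]) and
#'   `log` (data.frame: stage, n_in, n_out).
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- data.frame(stage = character(), n_in = integer(),
                    n_out = integer(), note = character())
  note <- function(stage, n_in, n_out, msg = "") {
    log[nrow(log) + 1L, ] <<- list(stage, n_in, n_out, msg)
  }

  records <- read_annotation_table(config$annotation)

  classified <- classify_variants(records)
  note("consequence", nrow(records), nrow(classified))

  incl <- config$inclusion %||% list()
  thr <- do.call(predictor_thresholds, incl$thresholds %||% list())
  filt <- filter_table(classified, thresholds = thr,
                       maf_cutoff = incl$maf_cutoff %||% 0.05,
                       maf_exemption = incl$maf_exemption %||% TRUE)
  note("prioritize", nrow(classified), nrow(filt$records))
  write_tsv(filt$decisions, file.path(config$out_dir, "inclusion.tsv"))

  verdicts <- acmg_verdicts(filt$records, mode = config$acmg_mode)
  note("acmg", nrow(filt$records), nrow(verdicts))
  write_tsv(verdicts, file.path(config$out_dir, "verdicts.tsv"))

  burden <- NULL
  phenotypes <- NULL
  if (!is.null(config$phenotypes))
    phenotypes <- read_phenotype_table(config$phenotypes)
  if (!is.null(config$vcf)) {
    if (is.null(phenotypes))
      stop("stage 'burden': a phenotype table is required to define case ",
           "status when a VCF is supplied", call. = FALSE)
    gm <- read_vcf(config$vcf)
    bcfg <- do.call(burden_config, config$burden %||% list())
    crit <- do.call(linkage_criteria,
                    (config$linkage %||% list())[
                      intersect(names(config$linkage %||% list()),
                                names(formals(linkage_criteria)))])
    sel <- select_icp_cases(phenotypes, crit,
                            strategy = (config$linkage %||%
                                          list())$strategy %||% "by_code")
    cases <- gm$sample_ids %in% sel$selected
    burden <- lapply(gene_registry()$symbol, function(g)
      tryCatch(cmc_exact(gm, g, cases, bcfg),
               error = function(e) structure(
                 list(gene = g, reason = conditionMessage(e)),
                 class = "empty_collapse")))
    names(burden) <- gene_registry()$symbol
    tested <- !vapply(burden, is_empty_collapse, logical(1))
    note("burden", length(burden), sum(tested))
    btab <- data.frame(
      gene = names(burden),
      p_value = vapply(burden, function(b)
        if (is_empty_collapse(b)) NA_real_ else b$p_value, numeric(1)),
      n_variants = vapply(burden, function(b)
        if (is_empty_collapse(b)) NA_integer_ else b$n_variants_collapsed,
        integer(1)))
    write_tsv(btab, file.path(config$out_dir, "burden.tsv"))
  } else {
    note("burden", 0L, 0L, "skipped: no VCF supplied")
  }

  linkage <- NULL
  if (!is.null(phenotypes)) {
    crit <- do.call(linkage_criteria,
                    (config$linkage %||% list())[
                      intersect(names(config$linkage %||% list()),
                                names(formals(linkage_criteria)))])
    linkage <- select_icp_cases(phenotypes, crit,
                                strategy = (config$linkage %||%
                                              list())$strategy %||% "by_code")
    note("phenolink", nrow(phenotypes), length(linkage$selected))
    write_tsv(data.frame(sample_id = linkage$selected),
              file.path(config$out_dir, "icp_cases.tsv"))
  } else {
    note("phenolink", 0L, 0L, "skipped: no phenotype table supplied")
  }

  summary <- render_summary(list(decisions = filt$decisions,
                                 verdicts = verdicts))
  write_tsv(as.data.frame(summary), file.path(config$out_dir, "summary.tsv"))
  utils::write.csv(log, file.path(config$out_dir, "run_log.csv"),
                   row.names = FALSE)

  out <- list(included = filt$records, verdicts = verdicts, burden = burden,
              linkage = linkage, summary = summary, log = log)
  check_summary_consistency(out)
  out
}

#' Per-gene summary matrix
#'
#' One row per registry gene: variants seen, variants after inclusion,
#' verdict tallies (engine verdicts over the included set) and phenotype
#' tallies.
#'
#' @param outputs List with `decisions` (all rows, from [filter_table()])
#'   and `verdicts` (included rows with `engine_verdict`).
#' @return Integer matrix, genes x summary columns.
#' @export
render_summary <- function(outputs) {
  genes <- gene_registry()$symbol
  dec <- outputs$decisions
  ver <- outputs$verdicts
  vocab <- setdiff(phenotype_vocabulary(), "none")
  cols <- c("n_variants", "n_included",
            "P", "LP", "VUS", "LB", "B", vocab)
  m <- matrix(0L, length(genes), length(cols),
              dimnames = list(genes, cols))
  short <- c(Pathogenic = "P", `Likely pathogenic` = "LP", VUS = "VUS",
             `Likely benign` = "LB", Benign = "B")
  pheno <- if (!is.null(ver) && nrow(ver))
    genotype_phenotype_counts(ver) else NULL
  for (g in genes) {
    if (!is.null(dec)) {
      m[g, "n_variants"] <- sum(dec$gene == g)
      m[g, "n_included"] <- sum(dec$gene == g & dec$included)
    }
    if (!is.null(ver) && nrow(ver)) {
      vg <- ver$engine_verdict[ver$gene == g]
      for (v in names(short)) m[g, short[[v]]] <- sum(vg == v)
      if (g %in% rownames(pheno)) m[g, vocab] <- pheno[g, vocab]
    }
  }
  m
}

# summary tallies must equal column sums of the row-level outputs
check_summary_consistency <- function(out) {
  s <- out$summary
  stopifnot(sum(s[, "n_included"]) ==
              sum(out$included$gene %in% rownames(s)),
            sum(s[, c("P", "LP", "VUS", "LB", "B")]) ==
              sum(out$verdicts$gene %in% rownames(s)))
  invisible(TRUE)
}
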