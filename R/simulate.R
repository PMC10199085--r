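#' Simulation configuration for a synthetic candidate-gene cohort
#'
#' Defaults describe the study conditions the package's analyses assume: a
#' cohort of 5236 unrelated volunteers, an ICP prevalence of 1.54%, a
#' female fraction of 0.60 (so female non-cases number about 3048), and
#' per-gene variant counts matching the five candidate genes' observed
#' non-synonymous totals (ABCB4 68, ABCB11 77, ATP8B1 50, NR1H4 22,
#' TJP2 83). Allele frequencies are drawn log-uniformly on
#' \[1e-4, 0.05\]; 34% of variants are cohort-private (no reference
#' population frequency). Total serum bile acids are log-normal
#' (sigma = 0.6 on the log scale) with the case location calibrated so that
#' 90% of cases exceed the 10 umol/L diagnostic threshold and 90% of
#' controls fall below it.
#'
#' @param n_samples Cohort size.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   outputs bit-identically.
#' @param genes Gene symbols (subset of [gene_registry()]).
#' @param n_variants Integer vector of per-gene variant counts (recycled).
#' @param af_range Allele-frequency range for the log-uniform spectrum.
#' @param frac_private Fraction of variants with no reference-population AF.
#' @param prevalence Case prevalence.
#' @param or Named numeric vector of per-gene carrier enrichment odds
#'   ratios; genes not named get 1.
#' @param female_fraction Fraction of female samples (cases are all female).
#' @param tsba_sigma Log-scale standard deviation of the TSBA model.
#' @param tsba_case_coverage Fraction of cases whose TSBA location is
#'   calibrated to exceed the diagnostic threshold (default 0.9).
#' @param frac_tsba_missing Fraction of cases with no recorded TSBA
#'   measurement (diagnosis code only).
#' @param p_pathogenic Probability a variant is planted pathogenic (drives
#'   the simulated predictor panels and evidence codes).
#' @param rare_af_threshold True-AF cutoff defining the carrier collapse the
#'   case-status model acts on (matches the burden test's default).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 5236, seed = 1,
                       genes = gene_registry()$symbol,
                       n_variants = c(ABCB4 = 68, ABCB11 = 77, ATP8B1 = 50,
                                      NR1H4 = 22, TJP2 = 83)[genes],
                       af_range = c(1e-4, 0.05),
                       frac_private = 0.34,
                       prevalence = 0.0154,
                       or = NULL,
                       female_fraction = 0.60,
                       tsba_sigma = 0.6,
                       tsba_case_coverage = 0.9,
                       frac_tsba_missing = 0.1,
                       p_pathogenic = 0.1,
                       rare_af_threshold = 0.01) {
  stopifnot(prevalence > 0, prevalence < 1, n_samples >= 2,
            af_range[1] > 0, af_range[2] <= 0.5,
            af_range[1] <= af_range[2])
  n_variants <- rep_len(as.integer(n_variants), length(genes))
  names(n_variants) <- genes
  or_full <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(or)) {
    if (is.null(names(or)) && length(or) == length(genes)) names(or) <- genes
    bad <- setdiff(names(or), genes)
    if (length(bad)) stop("or named for unknown gene(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(or < 0)) stop("odds ratios must be >= 0", call. = FALSE)
    or_full[names(or)] <- or
  }
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 genes = genes, n_variants = n_variants, af_range = af_range,
                 frac_private = frac_private, prevalence = prevalence,
                 or = or_full, female_fraction = female_fraction,
                 tsba_sigma = tsba_sigma,
                 tsba_case_coverage = tsba_case_coverage,
                 frac_tsba_missing = frac_tsba_missing,
                 p_pathogenic = p_pathogenic,
                 rare_af_threshold = rare_af_threshold),
            class = "sim_config")
}

#' Simulate a candidate-gene cohort with ground truth
#'
#' Generates per-variant genotypes under Hardy-Weinberg equilibrium at each
#' variant's drawn allele frequency (allele count ~ Binomial(2, q)), case
#' status through a logistic link on the per-gene rare-carrier indicators
#' (the intercept is solved numerically so the expected prevalence matches
#' the configuration, whatever enrichment is planted), and total serum bile
#' acids from the calibrated log-normal model. Annotation rows (consequence
#' labels, predictor panels, evidence codes, cohort/reference frequencies)
#' and EHR-style phenotype rows (sex, diagnosis codes, TSBA measurements)
#' are emitted alongside full ground-truth bookkeeping.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]), `annotations`,
#'   `phenotypes` (data.frames), and `truth` (list: `af`, `pathogenic`,
#'   `case`, `carrier` matrix per gene, `intercept`, `config`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  reg <- gene_registry()
  genes_v <- rep(config$genes, config$n_variants)
  m <- length(genes_v)

  # allele-frequency spectrum: log-uniform
  af <- exp(stats::runif(m, log(config$af_range[1]),
                         log(config$af_range[2])))
  # HWE genotypes: one Binomial(2, q) draw per sample x variant
  ac <- matrix(stats::rbinom(n * m, 2L, rep(af, each = n)), nrow = n)

  # synthetic protein-change labels; keys follow the GENE:protein_change rule
  aa_to <- c("A", "S", "T", "V", "M", "R")[1 + (seq_len(m) %% 6)]
  protein_change <- paste0("G", seq_len(m) * 3L, aa_to)
  keys <- variant_id(genes_v, protein_change)
  sample_ids <- sprintf("S%05d", seq_len(n))
  chrom <- reg$chromosome[match(genes_v, reg$symbol)]
  meta <- data.frame(chrom = chrom,
                     pos = 1000L + 10L * seq_len(m),
                     ref = "A", alt = "G", gene = genes_v,
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(ac, sample_ids, keys, meta)

  # per-gene rare-carrier indicator the case-status model acts on
  carrier <- vapply(config$genes, function(g) {
    idx <- which(genes_v == g & af <= config$rare_af_threshold)
    if (length(idx) == 0) rep(FALSE, n)
    else rowSums(ac[, idx, drop = FALSE] >= 1L) > 0
  }, logical(n))
  if (is.null(dim(carrier))) carrier <- matrix(carrier, nrow = n)
  colnames(carrier) <- config$genes

  degenerate <- config$or != 1 & colSums(carrier) == 0
  if (any(degenerate))
    warning("planted enrichment on gene(s) with no expected carriers: ",
            paste(config$genes[degenerate], collapse = ", "), call. = FALSE)

  # logistic case model; intercept solved so mean risk = prevalence
  eta_slope <- drop(carrier %*% log(config$or))
  f <- function(a) mean(stats::plogis(a + eta_slope)) - config$prevalence
  intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  case <- stats::runif(n) < stats::plogis(intercept + eta_slope)

  # sex: cases female; controls fill the configured female fraction
  n_female_target <- round(config$female_fraction * n)
  sex <- rep("M", n)
  sex[case] <- "F"
  need <- max(0, n_female_target - sum(case))
  ctrl_idx <- which(!case)
  if (need > 0 && length(ctrl_idx))
    sex[sample(ctrl_idx, min(need, length(ctrl_idx)))] <- "F"

  # TSBA: log-normal; case location puts `tsba_case_coverage` of cases
  # above the 10 umol/L threshold, controls the mirror image below
  thr <- 10
  z <- stats::qnorm(config$tsba_case_coverage)
  mu_case <- log(thr) + z * config$tsba_sigma
  mu_ctrl <- log(thr) - z * config$tsba_sigma
  tsba <- exp(stats::rnorm(n, ifelse(case, mu_case, mu_ctrl),
                           config$tsba_sigma))
  tsba_missing <- case & (stats::runif(n) < config$frac_tsba_missing)

  phenotypes <- data.frame(
    sample_id = sample_ids, sex = sex,
    icd10 = ifelse(case, "O26.6", ""),
    tsba = ifelse(tsba_missing, "", formatC(tsba, digits = 6, format = "g")),
    icp_verified = case, stringsAsFactors = FALSE)

  annotations <- simulate_annotations(config, genes_v, keys, protein_change,
                                      af, gm)

  truth <- list(af = stats::setNames(af, keys),
                pathogenic = stats::setNames(annotations$planted_pathogenic,
                                             keys),
                case = stats::setNames(case, sample_ids),
                carrier = carrier,
                intercept = intercept,
                config = config)
  annotations$planted_pathogenic <- NULL
  list(genotypes = gm, annotations = annotations$table,
       phenotypes = phenotypes, truth = truth)
}

# annotation rows consistent with the genotypes: cohort AF from the matrix,
# reference AF hidden for the cohort-private fraction, predictor panels and
# evidence codes driven by the planted pathogenicity flag
simulate_annotations <- function(config, genes_v, keys, protein_change,
                                 af, gm) {
  m <- length(keys)
  emp_af <- variant_af(gm)
  private <- stats::runif(m) < config$frac_private
  pathogenic <- stats::runif(m) < config$p_pathogenic

  draw_score <- function(delet, lo_d, hi_d, lo_t, hi_t) {
    ifelse(delet, stats::runif(m, lo_d, hi_d), stats::runif(m, lo_t, hi_t))
  }
  # per-tool deleterious call probability .95 for pathogenic, .1 otherwise
  del <- function() stats::runif(m) < ifelse(pathogenic, 0.95, 0.10)

  codes <- ifelse(pathogenic,
                  ifelse(private, "PVS1, PM2, PP3", "PM1, PM2, PP2, PP3"),
                  ifelse(emp_af > 0.01, "BA1, BP4", "PM2"))
  tab <- data.frame(
    gene = genes_v,
    transcript = paste0("SIM:", keys),
    protein_change = protein_change,
    cdna_change = "",
    dbsnp = ifelse(private, "", paste0("rs", 1e6 + seq_len(m))),
    consequence = "missense_variant",
    af_gnomad = ifelse(private, NA_real_, af),
    af_cohort = emp_af,
    polyphen = round(draw_score(del(), 0.7, 1, 0, 0.4), 4),
    sift = round(draw_score(del(), 0, 0.04, 0.2, 1), 4),
    cadd = round(draw_score(del(), 22, 35, 0, 15), 2),
    revel = round(draw_score(del(), 0.6, 1, 0, 0.4), 4),
    metalr = ifelse(del(), "D", "T"),
    metasvm = ifelse(del(), "D", "T"),
    mcap = round(draw_score(del(), 0.03, 0.6, 0, 0.02), 4),
    literature_known = !private & stats::runif(m) < 0.2,
    clinvar = "",
    acmg_codes = codes,
    phenotype_groups = "",
    zygosity = "het",
    het_n = NA_real_, hom_n = NA_real_,
    stringsAsFactors = FALSE)
  tab$variant_id <- variant_id(tab$gene, tab$protein_change)
  list(table = tab, planted_pathogenic = pathogenic)
}

#' Plant a co-carrier group into a genotype matrix
#'
#' Forces `k` chosen variants to be carried (heterozygously) by exactly the
#' same `m` samples and by nobody else, so that [co_carrier_groups()] must
#' recover them as one group — a synthetic mirror of variants observed in
#' linkage disequilibrium.
#'
#' @param gm A [genotype_matrix()].
#' @param variant_keys At least two variant keys in `gm`.
#' @param sample_ids At least one sample id in `gm`.
#' @return The modified [genotype_matrix()].
#' @export
plant_co_carriers <- function(gm, variant_keys, sample_ids) {
  if (length(variant_keys) < 2)
    stop("a co-carrier group needs k >= 2 variants", call. = FALSE)
  if (length(sample_ids) < 1)
    stop("a co-carrier group needs m >= 1 carriers", call. = FALSE)
  vi <- match(variant_keys, gm$variant_keys)
  si <- match(sample_ids, gm$sample_ids)
  if (anyNA(vi)) stop("unknown variant key(s)", call. = FALSE)
  if (anyNA(si)) stop("unknown or excess sample id(s)", call. = FALSE)
  gm$allele_counts[, vi] <- 0L
  gm$allele_counts[si, vi] <- 1L
  gm
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf`, `annotations.tsv`, `phenotypes.tsv` and `truth.json`
#' under `dir`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$genotypes, paths["vcf"])
  write_tsv(sim$annotations, paths["annotations"])
  write_tsv(sim$phenotypes, paths["phenotypes"])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$carrier <- as.data.frame(truth$carrier)
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
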