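#' Burden-test configuration
#'
#' @param af_threshold Allele-frequency qualification for collapsing:
#'   variants with AF <= threshold enter the carrier collapse (default 0.01).
#' @param alpha Significance level used by calibration summaries.
#' @param af_source `"cohort"` (AF computed from the analyzed genotypes,
#'   default) or `"annotation"` (externally supplied AF per variant).
#' @param alternative `"two.sided"` (minimum-likelihood convention) or
#'   `"greater"`.
#' @return Named list.
#' @export
burden_config <- function(af_threshold = 0.01, alpha = 0.05,
                          af_source = c("cohort", "annotation"),
                          alternative = c("two.sided", "greater")) {
  stopifnot(af_threshold > 0, af_threshold < 1, alpha > 0, alpha < 1)
  list(af_threshold = af_threshold, alpha = alpha,
       af_source = match.arg(af_source),
       alternative = match.arg(alternative))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by direct hypergeometric summation. Conditional on the
#' table margins, the first cell follows a hypergeometric distribution; the
#' two-sided p sums the probabilities of all tables whose point probability
#' does not exceed that of the observed table, within a relative tolerance
#' of 1e-7 (the minimum-likelihood convention used by standard exact-test
#' implementations). With `alternative = "greater"` the upper tail is
#' summed instead.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out
#'   \[\[a, b\], \[c, d\]\].
#' @param alternative `"two.sided"` or `"greater"`.
#' @return p-value in (0, 1\]; degenerate margins give 1 by convention.
#' @export
#' @examples
#' fisher_exact_2x2(3, 0, 0, 3)  # 0.1
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- if (alternative == "two.sided") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    sum(probs[support >= a])
  }
  min(p, 1)
}

#' Collapse a gene's rare variants to a per-sample carrier indicator
#'
#' A variant qualifies when its allele frequency is at or below the
#' configured threshold (cohort AF derived from the matrix by default). A
#' sample is a carrier when it holds at least one alternate allele at any
#' qualifying variant. Missing genotypes count as non-carrying at that
#' variant.
#'
#' @param gm A [genotype_matrix()], or one already restricted to a gene.
#' @param gene Gene symbol used to subset `gm` (skipped when `NULL`).
#' @param config See [burden_config()].
#' @param annotation_af Numeric AF per variant of `gm` (after gene subset),
#'   required when `config$af_source == "annotation"`.
#' @return Logical carrier vector named by sample, with attribute
#'   `n_variants` (number of qualifying variants collapsed); or an
#'   `empty_collapse` object when no variant qualifies.
#' @export
collapse_carriers <- function(gm, gene = NULL, config = burden_config(),
                              annotation_af = NULL) {
  if (!is.null(gene)) gm <- subset_gene(gm, gene)
  af <- if (config$af_source == "annotation") {
    if (is.null(annotation_af) ||
        length(annotation_af) != length(gm$variant_keys))
      stop("af_source='annotation' needs one annotation_af per variant",
           call. = FALSE)
    annotation_af
  } else {
    variant_af(gm)
  }
  qual <- which(!is.na(af) & af <= config$af_threshold)
  if (length(qual) == 0) {
    return(structure(list(gene = gene, reason = "no qualifying variants"),
                     class = "empty_collapse"))
  }
  ac <- gm$allele_counts[, qual, drop = FALSE]
  carriers <- rowSums(ac >= 1L, na.rm = TRUE) > 0
  names(carriers) <- gm$sample_ids
  attr(carriers, "n_variants") <- length(qual)
  carriers
}

#' Is this an empty-collapse signal?
#' @param x Object returned by [collapse_carriers()] or [cmc_exact()].
#' @return Logical scalar.
#' @export
is_empty_collapse <- function(x) inherits(x, "empty_collapse")

#' Collapsed-carrier (CMC) exact burden test for one gene
#'
#' Collapses the gene's qualifying rare variants to a carrier indicator and
#' tests carrier status against case status in a 2x2 exact test: the burden
#' is the proportion of cases versus controls holding at least one
#' alternate allele.
#'
#' @param gm A [genotype_matrix()].
#' @param gene Gene symbol.
#' @param case_labels Logical vector aligned to `gm$sample_ids`
#'   (TRUE = case).
#' @param config See [burden_config()].
#' @param annotation_af Optional per-variant AF, see [collapse_carriers()].
#' @return A `burden_result`: list with `gene`, `table` (2x2 integer matrix,
#'   carrier status x case status), `p_value`, `n_variants_collapsed`; or an
#'   `empty_collapse` object when nothing can be tested.
#' @export
cmc_exact <- function(gm, gene, case_labels, config = burden_config(),
                      annotation_af = NULL) {
  if (length(case_labels) != length(gm$sample_ids))
    stop("case_labels must align with the matrix samples", call. = FALSE)
  case_labels <- as.logical(case_labels)
  if (all(case_labels) || !any(case_labels))
    stop("both a case and a control group are required", call. = FALSE)
  carriers <- collapse_carriers(gm, gene, config, annotation_af)
  if (is_empty_collapse(carriers)) return(carriers)
  if (!any(carriers)) {
    return(structure(list(gene = gene, reason = "no carriers in either group"),
                     class = "empty_collapse"))
  }
  tab <- matrix(c(sum(carriers & case_labels), sum(carriers & !case_labels),
                  sum(!carriers & case_labels), sum(!carriers & !case_labels)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("carrier", "non_carrier"),
                                c("case", "control")))
  p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                        alternative = config$alternative)
  structure(list(gene = gene, table = tab, p_value = p,
                 n_variants_collapsed = attr(carriers, "n_variants")),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("CMC burden:", x$gene, "- p =", format.pval(x$p_value, digits = 4),
      "(", x$n_variants_collapsed, "variants collapsed )\n")
  print(x$table)
  invisible(x)
}

#' Compare rare-variant counts between two cohorts
#'
#' Fisher exact comparison of the proportion of variant-bearing cases in
#' two cohorts (e.g. this cohort's ICP cases against an external disease
#' cohort), on the table \[\[k1, n1 - k1\], \[k2, n2 - k2\]\].
#'
#' @param k1,n1 Variant count and total for cohort 1.
#' @param k2,n2 Variant count and total for cohort 2.
#' @param label Optional comparison label.
#' @return List with the counts, `label` and `p_value`.
#' @export
cohort_variant_comparison <- function(k1, n1, k2, n2, label = "") {
  if (k1 > n1 || k2 > n2 || any(c(k1, n1, k2, n2) < 0))
    stop("need 0 <= k <= n in both cohorts", call. = FALSE)
  p <- fisher_exact_2x2(k1, n1 - k1, k2, n2 - k2)
  list(label = label, k1 = k1, n1 = n1, k2 = k2, n2 = n2, p_value = p)
}

#' Group variants carried by exactly the same samples
#'
#' An exact-carrier-set proxy for linkage disequilibrium: variants whose
#' carrier sets are identical (and non-empty) are grouped. Only groups of
#' two or more variants are reported; groups are maximal and ordered by
#' their first variant key's position in the matrix.
#'
#' @param gm A [genotype_matrix()].
#' @return List of character vectors (variant keys), possibly empty.
#' @export
co_carrier_groups <- function(gm) {
  ac <- gm$allele_counts
  sig <- vapply(seq_len(ncol(ac)), function(j) {
    idx <- which(!is.na(ac[, j]) & ac[, j] >= 1L)
    if (length(idx) == 0) NA_character_ else paste(idx, collapse = ",")
  }, character(1))
  keep <- !is.na(sig)
  groups <- split(gm$variant_keys[keep], sig[keep])
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0) return(list())
  first_pos <- vapply(groups, function(g)
    min(match(g, gm$variant_keys)), integer(1))
  groups <- groups[order(first_pos)]
  names(groups) <- NULL
  groups
}
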