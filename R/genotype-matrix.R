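#' Construct a genotype matrix
#'
#' Container for per-sample alternate-allele counts over a set of biallelic
#' variants. Rows are samples, columns variants; entries are 0, 1, 2 or `NA`
#' (missing call). Per-variant metadata (chromosome, position, ref, alt, gene)
#' travels with the object so it can be written back to VCF.
#'
#' @param allele_counts Integer matrix, samples x variants, values in
#'   \{0, 1, 2, NA\}.
#' @param sample_ids Character vector, one per row.
#' @param variant_keys Character vector, one per column; unique keys such as
#'   `"ABCB11:N591S"` or `"chr2:1000:A:G"`.
#' @param meta Optional data.frame with one row per variant (columns `chrom`,
#'   `pos`, `ref`, `alt`, `gene`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(allele_counts, sample_ids, variant_keys,
                            meta = NULL) {
  allele_counts <- as.matrix(allele_counts)
  storage.mode(allele_counts) <- "integer"
  if (nrow(allele_counts) != length(sample_ids))
    stop("allele_counts rows must match sample_ids", call. = FALSE)
  if (ncol(allele_counts) != length(variant_keys))
    stop("allele_counts columns must match variant_keys", call. = FALSE)
  bad <- allele_counts[!is.na(allele_counts)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("allele counts must lie in {0, 1, 2}", call. = FALSE)
  if (anyDuplicated(variant_keys))
    stop("variant_keys must be unique", call. = FALSE)
  if (is.null(meta)) {
    meta <- data.frame(chrom = rep(".", length(variant_keys)),
                       pos = seq_along(variant_keys),
                       ref = "A", alt = "T",
                       gene = NA_character_)
  }
  dimnames(allele_counts) <- list(sample_ids, variant_keys)
  structure(list(allele_counts = allele_counts,
                 sample_ids = as.character(sample_ids),
                 variant_keys = as.character(variant_keys),
                 meta = meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$sample_ids), " samples x ",
      length(x$variant_keys), " variants\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$allele_counts)

#' Per-variant alternate allele frequency
#'
#' AF is computed over called genotypes only: missing calls drop out of both
#' the numerator and the denominator.
#'
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector of allele frequencies in \[0, 1\] (`NaN` for a
#'   variant with no called genotypes).
#' @export
variant_af <- function(gm) {
  ac <- gm$allele_counts
  called <- colSums(!is.na(ac))
  colSums(ac, na.rm = TRUE) / (2 * called)
}

#' Carrier and allele tallies for one variant
#'
#' @param genotypes Integer vector of allele counts in \{0, 1, 2\}; `NA`
#'   entries (missing calls) are ignored.
#' @return Named integer vector with components `het_count`, `hom_count`,
#'   `allele_count` (= het + 2 hom) and `carrier_count` (= het + hom).
#' @export
#' @examples
#' carrier_and_allele_counts(c(0, 1, 2, 1, NA))
carrier_and_allele_counts <- function(genotypes) {
  genotypes <- genotypes[!is.na(genotypes)]
  if (length(genotypes) && (min(genotypes) < 0 || max(genotypes) > 2))
    stop("allele counts must lie in {0, 1, 2}", call. = FALSE)
  het <- sum(genotypes == 1L)
  hom <- sum(genotypes == 2L)
  c(het_count = het, hom_count = hom,
    allele_count = het + 2L * hom, carrier_count = het + hom)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.x, GT subfield required) into a [genotype_matrix()].
#' Multiallelic records are split into one matrix column per alternate
#' allele; for each split column the allele count is the number of sample
#' alleles equal to that alternate. Missing genotypes (`./.`) are `NA` and are
#' excluded from the allele-frequency denominator. Variant keys come from the
#' ID column when present (suffixed `_alt<k>` for split alleles), otherwise
#' `chrom:pos:ref:alt`. When the ID has the form `GENE:label` and GENE is in
#' the candidate registry, the gene is recorded in the metadata.
#'
#' @param path Path to an (optionally gzipped) VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(vcf@fix) == 0) {                      # empty body
    return(genotype_matrix(matrix(integer(), 0, 0), character(), character(),
                           meta = data.frame(chrom = character(),
                                             pos = integer(),
                                             ref = character(),
                                             alt = character(),
                                             gene = character())))
  }
  fix <- as.data.frame(vcf@fix[, c("CHROM", "POS", "ID", "REF", "ALT"),
                               drop = FALSE], stringsAsFactors = FALSE)
  if (ncol(vcf@gt) < 2)
    stop("VCF has no sample genotype columns", call. = FALSE)
  fmt <- vcf@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("VCF FORMAT lacks a GT field", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)

  registry <- gene_registry()$symbol
  keys <- character(0); genes <- character(0)
  chroms <- character(0); poss <- integer(0)
  refs <- character(0); alts <- character(0)
  cols <- list()

  # split each record on its alternate alleles
  allele_mat <- function(gtrow, k) {
    # gtrow: character GT strings for one site; k: alt allele index
    vapply(gtrow, function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_integer_)
      sum(al == as.character(k))
    }, integer(1), USE.NAMES = FALSE)
  }

  for (i in seq_len(nrow(fix))) {
    alt_alleles <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    id <- fix$ID[i]
    for (k in seq_along(alt_alleles)) {
      key <- if (!is.na(id) && nzchar(id) && id != ".") {
        if (length(alt_alleles) > 1) paste0(id, "_alt", k) else id
      } else {
        paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alt_alleles[k], sep = ":")
      }
      gene <- NA_character_
      if (!is.na(id) && grepl(":", id, fixed = TRUE)) {
        cand <- sub(":.*$", "", id)
        if (cand %in% registry) gene <- cand
      }
      cols[[length(cols) + 1L]] <- allele_mat(gt[i, ], k)
      keys <- c(keys, key); genes <- c(genes, gene)
      chroms <- c(chroms, fix$CHROM[i]); poss <- c(poss, as.integer(fix$POS[i]))
      refs <- c(refs, fix$REF[i]); alts <- c(alts, alt_alleles[k])
    }
  }
  ac <- do.call(cbind, cols)
  genotype_matrix(ac, samples, keys,
                  meta = data.frame(chrom = chroms, pos = poss, ref = refs,
                                    alt = alts, gene = genes,
                                    stringsAsFactors = FALSE))
}

#' Write a genotype matrix to a VCF file
#'
#' Emits minimal VCF 4.2 text with a single GT FORMAT field; every variant is
#' written as a biallelic record. Together with [read_vcf()] this round-trips
#' genotype content for biallelic records.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  body <- vapply(seq_along(gm$variant_keys), function(j) {
    g <- gm$allele_counts[, j]
    gt <- ifelse(is.na(g), "./.", gtcode[as.character(g)])
    paste(c(gm$meta$chrom[j], gm$meta$pos[j], gm$variant_keys[j],
            gm$meta$ref[j], gm$meta$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Restrict a genotype matrix to one gene's variants
#'
#' @param gm A [genotype_matrix()].
#' @param gene Gene symbol; matched against the matrix metadata (or, as a
#'   fallback, against a `GENE:` prefix on the variant key).
#' @return A [genotype_matrix()] with the subset of columns.
#' @export
subset_gene <- function(gm, gene) {
  hit <- !is.na(gm$meta$gene) & gm$meta$gene == gene
  if (!any(hit)) hit <- startsWith(gm$variant_keys, paste0(gene, ":"))
  genotype_matrix(gm$allele_counts[, hit, drop = FALSE], gm$sample_ids,
                  gm$variant_keys[hit], gm$meta[hit, , drop = FALSE])
}
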