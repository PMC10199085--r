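#' The five cholestasis candidate genes
#'
#' Returns the packaged registry of candidate genes implicated in cholestatic
#' liver disease. Each gene maps to a progressive familial intrahepatic
#' cholestasis (PFIC) subtype: ATP8B1/PFIC-1 (FIC1 flippase), ABCB11/PFIC-2
#' (bile salt export pump, BSEP), ABCB4/PFIC-3 (phosphatidylcholine floppase),
#' TJP2/PFIC-4 (tight junction protein 2) and NR1H4/PFIC-5 (farnesoid X
#' receptor, FXR).
#'
#' @return A data.frame with one row per gene and columns `symbol`,
#'   `chromosome`, `chromosome_band`, `product`, `omim_id`, `exons`,
#'   `length_kb`, `associated_disease`.
#' @export
#' @examples
#' gene_registry()
gene_registry <- function() {
  path <- system.file("extdata", "table5_gene_candidates.tsv",
                      package = "cholvar", mustWork = TRUE)
  reg <- utils::read.delim(path, colClasses = c(
    symbol = "character", chromosome = "character",
    chromosome_band = "character", product = "character",
    omim_id = "integer", exons = "integer", length_kb = "numeric",
    associated_disease = "character"))
  reg$product[is.na(reg$product)] <- ""
  stopifnot(!anyDuplicated(reg$symbol), all(reg$exons > 0),
            all(reg$length_kb > 0))
  reg
}

#' Look up one candidate gene
#'
#' @param symbol Gene symbol, e.g. `"ABCB11"`.
#' @return One registry row (see [gene_registry()]).
#' @export
gene_info <- function(symbol) {
  reg <- gene_registry()
  hit <- match(symbol, reg$symbol)
  if (is.na(hit)) {
    stop("unknown candidate gene: '", symbol, "' (registry has ",
         paste(reg$symbol, collapse = ", "), ")", call. = FALSE)
  }
  reg[hit, , drop = FALSE]
}

#' Controlled phenotype vocabulary
#'
#' Phenotype groups a variant may be linked to through the carriers'
#' electronic health records.
#'
#' @return Character vector of allowed phenotype labels.
#' @export
phenotype_vocabulary <- function() {
  c("ICP", "gallstone", "cholangiocarcinoma", "cirrhosis", "neoplasm", "none")
}
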