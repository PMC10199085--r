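ACMG_VOCAB <- c("PVS1",
                paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

VERDICT_LEVELS <- c("Benign", "Likely benign", "VUS", "Likely pathogenic",
                    "Pathogenic")

#' Parse an ACMG-AMP evidence-code string
#'
#' Whitespace-tolerant, order-insensitive; duplicates collapse. Codes are
#' validated against the standard vocabulary (PVS1, PS1-PS4, PM1-PM6,
#' PP1-PP5, BA1, BS1-BS4, BP1-BP7).
#'
#' @param text Comma-separated codes, e.g. `"PM1, PM2, PP2, PP3"`; empty or
#'   `NA` means no evidence.
#' @return Character vector of unique codes (possibly empty).
#' @export
parse_acmg_codes <- function(text) {
  if (length(text) != 1) stop("parse_acmg_codes() takes a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  codes <- toupper(trimws(strsplit(text, ",", fixed = TRUE)[[1]]))
  codes <- codes[nzchar(codes)]
  bad <- setdiff(codes, ACMG_VOCAB)
  if (length(bad))
    stop("unknown ACMG-AMP code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unique(codes)
}

acmg_counts <- function(codes) {
  c(pvs = sum(startsWith(codes, "PVS")),
    ps  = sum(grepl("^PS[0-9]$", codes)),
    pm  = sum(grepl("^PM[0-9]$", codes)),
    pp  = sum(grepl("^PP[0-9]$", codes)),
    ba  = sum(codes == "BA1"),
    bs  = sum(grepl("^BS[0-9]$", codes)),
    bp  = sum(grepl("^BP[0-9]$", codes)))
}

# pathogenic-side combining clauses -> "Pathogenic", "Likely pathogenic" or ""
acmg_pathogenic_tier <- function(n) {
  path <- (n["pvs"] >= 1 && (n["ps"] >= 1 || n["pm"] >= 2 ||
                             (n["pm"] == 1 && n["pp"] >= 1) || n["pp"] >= 2)) ||
          n["ps"] >= 2 ||
          (n["ps"] == 1 && (n["pm"] >= 3 ||
                            (n["pm"] == 2 && n["pp"] >= 2) ||
                            (n["pm"] == 1 && n["pp"] >= 4)))
  if (path) return("Pathogenic")
  lp <- (n["pvs"] >= 1 && n["pm"] == 1) ||
        (n["ps"] == 1 && n["pm"] >= 1 && n["pm"] <= 2) ||
        (n["ps"] == 1 && n["pp"] >= 2) ||
        n["pm"] >= 3 ||
        (n["pm"] == 2 && n["pp"] >= 2) ||
        (n["pm"] == 1 && n["pp"] >= 4)
  if (lp) "Likely pathogenic" else ""
}

# benign-side combining clauses -> "Benign", "Likely benign" or ""
acmg_benign_tier <- function(n) {
  if (n["ba"] >= 1 || n["bs"] >= 2) return("Benign")
  if ((n["bs"] >= 1 && n["bp"] >= 1) || n["bp"] >= 2) return("Likely benign")
  ""
}

#' Combine ACMG-AMP evidence codes into a five-tier verdict
#'
#' Implements the standard combining rules. Pathogenic requires PVS1 plus
#' (>= 1 PS, >= 2 PM, 1 PM + 1 PP, or >= 2 PP), or >= 2 PS, or 1 PS plus
#' (>= 3 PM, 2 PM + >= 2 PP, or 1 PM + >= 4 PP). Likely pathogenic: PVS1 +
#' 1 PM; 1 PS + 1-2 PM; 1 PS + >= 2 PP; >= 3 PM; 2 PM + >= 2 PP; or 1 PM +
#' >= 4 PP. Benign: BA1 (stand-alone) or >= 2 BS. Likely benign: 1 BS + 1 BP
#' or >= 2 BP. Anything else is a variant of uncertain significance (VUS).
#'
#' When a pathogenic-tier and a benign-tier rule fire simultaneously the
#' verdict depends on `mode`: `"strict"` defaults to VUS with
#' `conflict_flag = TRUE`; `"paper_tolerant"` lets the benign-side rule win
#' (still flagged), matching published tables that report likely-benign
#' calls despite co-occurring pathogenic evidence. BA1 is stand-alone Benign
#' in both modes, overriding any co-occurring pathogenic evidence.
#'
#' @param codes Character vector of codes, or a single comma-separated
#'   string (parsed via [parse_acmg_codes()]).
#' @param mode `"strict"` or `"paper_tolerant"`.
#' @return List with `verdict` (one of Pathogenic, Likely pathogenic, VUS,
#'   Likely benign, Benign) and `conflict_flag` (logical).
#' @export
#' @examples
#' acmg_combine(c("PVS1", "PM2", "PP3"))   # Pathogenic
#' acmg_combine("PM1, PM2, PP2, PP3")      # Likely pathogenic
#' acmg_combine("BA1, PVS1")               # Benign (stand-alone BA1)
acmg_combine <- function(codes, mode = c("strict", "paper_tolerant")) {
  mode <- match.arg(mode)
  if (length(codes) == 1 && (is.na(codes) || grepl(",", codes) ||
                             !codes %in% ACMG_VOCAB))
    codes <- parse_acmg_codes(codes)
  bad <- setdiff(codes, ACMG_VOCAB)
  if (length(bad))
    stop("unknown ACMG-AMP code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- acmg_counts(unique(codes))
  if (n["ba"] >= 1)
    return(list(verdict = "Benign", conflict_flag = FALSE))
  ptier <- acmg_pathogenic_tier(n)
  btier <- acmg_benign_tier(n)
  if (nzchar(ptier) && nzchar(btier)) {
    verdict <- if (mode == "strict") "VUS" else btier
    return(list(verdict = verdict, conflict_flag = TRUE))
  }
  verdict <- if (nzchar(ptier)) ptier else if (nzchar(btier)) btier else "VUS"
  list(verdict = verdict, conflict_flag = FALSE)
}

#' Verdicts for every row of a variant table
#'
#' @param records data.frame with an `acmg_codes` column.
#' @param mode Passed to [acmg_combine()].
#' @return The table with `engine_verdict` and `conflict_flag` columns.
#' @export
acmg_verdicts <- function(records, mode = c("strict", "paper_tolerant")) {
  mode <- match.arg(mode)
  res <- lapply(records$acmg_codes, acmg_combine, mode = mode)
  records$engine_verdict <- vapply(res, `[[`, character(1), "verdict")
  records$conflict_flag <- vapply(res, `[[`, logical(1), "conflict_flag")
  records
}

# printed verdict labels -> canonical tier
normalize_verdict <- function(x) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[key %in% c("p", "pathogenic")] <- "Pathogenic"
  out[key %in% c("lp", "likely pathogenic")] <- "Likely pathogenic"
  out[key %in% c("vus", "uncertain significance")] <- "VUS"
  out[key %in% c("lb", "likely benign")] <- "Likely benign"
  out[key %in% c("b", "benign")] <- "Benign"
  out
}

#' Compare engine verdicts with printed verdicts
#'
#' Applies [acmg_combine()] to every row carrying both an evidence-code set
#' and a printed verdict, and reports concordance. Rows without a printed
#' verdict are skipped.
#'
#' @param records data.frame with `acmg_codes` and `printed_verdict` columns.
#' @param mode Passed to [acmg_combine()].
#' @return List with `n_match`, `n_mismatch` and `mismatches` (data.frame
#'   with `variant_id`, `acmg_codes`, `printed`, `engine`).
#' @export
validate_against_printed <- function(records,
                                     mode = c("strict", "paper_tolerant")) {
  mode <- match.arg(mode)
  if (is.null(records$printed_verdict) || nrow(records) == 0)
    return(list(n_match = 0L, n_mismatch = 0L,
                mismatches = data.frame(variant_id = character(),
                                        acmg_codes = character(),
                                        printed = character(),
                                        engine = character())))
  printed <- normalize_verdict(records$printed_verdict)
  keep <- !is.na(printed)
  records <- records[keep, , drop = FALSE]
  printed <- printed[keep]
  engine <- vapply(records$acmg_codes, function(cs)
    acmg_combine(cs, mode = mode)$verdict, character(1), USE.NAMES = FALSE)
  hit <- engine == printed
  mism <- data.frame(variant_id = records$variant_id[!hit],
                     acmg_codes = records$acmg_codes[!hit],
                     printed = printed[!hit], engine = engine[!hit],
                     stringsAsFactors = FALSE)
  list(n_match = sum(hit), n_mismatch = sum(!hit), mismatches = mism)
}
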