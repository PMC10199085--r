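LOF_CLASSES <- c("frameshift", "stop_gained", "splice_acceptor",
                 "start_lost_frameshift")
CONSEQUENCE_CLASSES <- c(LOF_CLASSES, "missense", "synonymous", "other")

#' Classify a variant's molecular consequence
#'
#' Maps an annotation consequence label (free text, e.g. `"Frameshift_variant
#' & splice_region_variant"`) and/or HGVS-style change strings to one of the
#' consequence classes: `missense`, `synonymous`, the four loss-of-function
#' subclasses (`frameshift`, `stop_gained`, `splice_acceptor`,
#' `start_lost_frameshift`), or `other`.
#'
#' Precedence: a combined frameshift + start-lost label is
#' `start_lost_frameshift`; any other label containing "frameshift" is
#' `frameshift` (this deliberately folds frameshift + splice-region composites
#' into frameshift); stop-gained labels, then splice-acceptor labels. When the
#' label is uninformative the HGVS strings are parsed: an `fs`/`fsTer` suffix
#' is a frameshift, a `Ter`/`*`/`x` substitution a premature stop, a cDNA
#' change at the -1/-2 intronic position a splice-acceptor disruption, an
#' identical-residue substitution synonymous, and a plain residue substitution
#' missense. Unparseable input maps to `other` with a warning — never a silent
#' drop.
#'
#' @param consequence_label Free-text consequence (may be `""`).
#' @param protein_change Short HGVS-p label, e.g. `"G1254S"`, `"R595*"`,
#'   `"S99x"` (may be `""`).
#' @param cdna_change HGVS-c string, e.g. `"c.2611-2A>T"` (may be `""`).
#' @return A single class label (character).
#' @export
#' @examples
#' classify_consequence("Frameshift", "S99x")
#' classify_consequence("", "p.Arg595Ter")
#' classify_consequence("", "", "c.2611-2A>T")
classify_consequence <- function(consequence_label = "", protein_change = "",
                                 cdna_change = "") {
  lab <- tolower(gsub("[-_ ]+", "_", consequence_label %||% ""))
  p <- trimws(protein_change %||% "")
  p <- sub("^p\\.", "", p)
  cd <- trimws(cdna_change %||% "")

  if (grepl("frameshift", lab) && grepl("start_lost", lab))
    return("start_lost_frameshift")
  if (grepl("frameshift", lab)) return("frameshift")
  if (grepl("stop_gained|stop.gain|nonsense", lab)) return("stop_gained")
  if (grepl("splice_acceptor", lab)) return("splice_acceptor")
  if (grepl("missense|non_synonymous", lab)) return("missense")
  if (grepl("synonymous", lab)) return("synonymous")

  # fall back to the HGVS strings
  if (grepl("fs(Ter[0-9]*)?$", p, ignore.case = TRUE) ||
      grepl("fster[0-9]*$", tolower(p)))
    return("frameshift")
  if (grepl("^[A-Za-z]{1,3}[0-9]+(Ter|\\*|x|X)$", p))
    return("stop_gained")
  if (grepl("^c\\.[0-9]+-[12]([ACGT_]|del|dup|>)", cd) ||
      grepl("^c\\.[0-9]+-[12]$", cd))
    return("splice_acceptor")
  m <- regmatches(p, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$", p))[[1]]
  if (length(m) == 4) {
    aa_from <- normalize_aa(m[2]); aa_to <- normalize_aa(m[4])
    if (!is.na(aa_from) && !is.na(aa_to)) {
      if (aa_from == aa_to) return("synonymous")
      return("missense")
    }
  }
  warning("unparseable consequence for '", consequence_label, "'/'",
          protein_change, "'/'", cdna_change, "'; classed as 'other'",
          call. = FALSE)
  "other"
}

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")

normalize_aa <- function(a) {
  if (nchar(a) == 1 && toupper(a) %in% AA3) return(toupper(a))
  key <- paste0(toupper(substr(a, 1, 1)), tolower(substr(a, 2, 3)))
  if (key %in% names(AA3)) return(unname(AA3[key]))
  NA_character_
}

#' Classify every row of a variant table
#'
#' @param records Annotation data.frame (see [read_annotation_table()]).
#' @return The table with a `consequence_class` column appended.
#' @export
classify_variants <- function(records) {
  records$consequence_class <- vapply(seq_len(nrow(records)), function(i)
    classify_consequence(records$consequence[i],
                         records$protein_change[i],
                         records$cdna_change[i]),
    character(1))
  records
}

#' Is a consequence class loss-of-function?
#'
#' LoF = frameshift, premature stop, splice-acceptor disruption, or combined
#' start-loss/frameshift.
#'
#' @param class Character vector of consequence classes.
#' @return Logical vector.
#' @export
is_lof <- function(class) {
  stopifnot(all(class %in% CONSEQUENCE_CLASSES))
  class %in% LOF_CLASSES
}

#' Tally loss-of-function variants by subclass
#'
#' For reporting, combined start-loss/frameshift variants count within the
#' frameshift subclass (as do frameshift + splice-region composites, which
#' [classify_consequence()] already folds into `frameshift`).
#'
#' @param classes Character vector of consequence classes (or a classified
#'   table from [classify_variants()]).
#' @return Named integer vector: `frameshift`, `stop_gained`,
#'   `splice_acceptor`, `total`.
#' @export
tally_lof <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$consequence_class
  stopifnot(all(classes %in% CONSEQUENCE_CLASSES))
  fs <- sum(classes %in% c("frameshift", "start_lost_frameshift"))
  sg <- sum(classes == "stop_gained")
  sa <- sum(classes == "splice_acceptor")
  c(frameshift = fs, stop_gained = sg, splice_acceptor = sa,
    total = fs + sg + sa)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
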