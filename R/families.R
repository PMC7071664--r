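#' CAZy family label utilities
#'
#' CAZy families are labelled by a class prefix (GH, GT, PL, CE, AA, CBM)
#' followed by a family number, optionally with a subfamily suffix
#' ("GH5_13"). Annotation tools emit variants of these labels (e.g. HMM
#' profile names carry a trailing ".hmm"); these helpers canonicalize them.
#'
#' @param label character vector of raw family labels.
#' @param level `"subfamily"` keeps subfamily suffixes ("GH5_13"),
#'   `"family"` collapses them to the family ("GH5").
#' @return `canonical_family()` returns canonicalized labels (`NA` where the
#'   label is not a valid CAZy label); `cazy_class()` the class prefix;
#'   `is_cazy_label()` / `is_pfam_accession()` logical vectors.
#' @examples
#' canonical_family("GH13.hmm")
#' canonical_family("GH5_13", level = "family")
#' cazy_class(c("GH13", "CBM35"))
#' @export
canonical_family <- function(label, level = c("subfamily", "family")) {
  level <- match.arg(level)
  x <- sub("\\.hmm$", "", trimws(as.character(label)))
  x[!is_cazy_label(x)] <- NA_character_
  if (level == "family") x <- sub("_[0-9]+$", "", x)
  x
}

#' @rdname canonical_family
#' @export
is_cazy_label <- function(label) {
  grepl("^(GH|GT|PL|CE|AA|CBM)[0-9]+(_[0-9]+)?$", as.character(label))
}

#' @rdname canonical_family
#' @export
cazy_class <- function(label) {
  m <- regmatches(label, regexpr("^(GH|GT|PL|CE|AA|CBM)", as.character(label)))
  out <- rep(NA_character_, length(label))
  out[is_cazy_label(label)] <- m[is_cazy_label(label)]
  out
}

#' @rdname canonical_family
#' @param x character vector of candidate Pfam accessions.
#' @export
is_pfam_accession <- function(x) {
  grepl("^PF[0-9]{5}$", as.character(x))
}

# Canonical CAZy classes in reporting order.
CAZY_CLASSES <- c("GH", "GT", "PL", "CE", "AA", "CBM")
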