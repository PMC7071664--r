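# Three-tool consensus CAZyme calling.
#
# The CAZome is defined conservatively: an (ORF, family) assignment is kept
# only when all three evidence streams (HMM domain search, sequence
# similarity, peptide signatures) report that family on that ORF. Counts are
# modules (HMM domain hits), not genes.

#' Order family labels by class then family number
#' @noRd
order_families <- function(fams) {
  cls <- match(cazy_class(fams), CAZY_CLASSES)
  num <- as.numeric(sub("^[A-Z]+([0-9]+).*$", "\\1", fams))
  sub <- suppressWarnings(as.numeric(sub("^.*_([0-9]+)$", "\\1", fams)))
  sub[!grepl("_", fams)] <- 0
  fams[order(cls, num, sub)]
}

#' Call consensus CAZymes from three evidence streams
#'
#' Keeps only the (ORF, family) assignments reported by all three tools
#' (`hmm`, `similarity`, `peptide`); everything else is retained in a
#' partial-evidence side channel (see [partial_calls()]) for reporting but is
#' never counted. Agreement is evaluated at family level by default, so
#' subfamily disagreements (GH5_13 vs GH5_4) still agree at GH5; set
#' `agreement = "subfamily"` for strict subfamily matching. The
#' `module_count` of a call is the number of HMM-tool domain hits of that
#' family on the ORF (CAZymes are counted as functional modules, not genes).
#'
#' Similarity hits pass an e-value gate before consensus (default 1e-50, the
#' conventional gate for the similarity stream); peptide hits are not
#' filtered by default but `peptide_min_score` can impose a floor.
#'
#' @param hits data.frame of domain hits as returned by
#'   [read_domain_hits()] (rows from all three tools, rbind-ed).
#' @param sample_id either a single sample id applied to all calls, or a
#'   data.frame with columns `orf_id`, `sample_id` mapping ORFs to samples.
#' @param agreement `"family"` (default) or `"subfamily"` agreement level.
#' @param similarity_evalue e-value gate applied to similarity hits.
#' @param peptide_min_score optional score floor for peptide hits.
#' @return data.frame of class `"cazyme_calls"` with columns `orf_id`,
#'   `family` (at the agreement level), `subfamily` (the most specific
#'   HMM-reported label, e.g. `"GH5_13"`, kept for subfamily-resolution
#'   reports), `hmm`, `similarity`, `peptide` (logical evidence flags, all
#'   `TRUE` for consensus calls), `module_count`, `sample_id`. The
#'   partial-evidence table is attached as attribute `"partial"`.
#' @examples
#' hits <- data.frame(
#'   orf_id = "orf1", tool = c("hmm", "similarity", "peptide"),
#'   label = "GH13", evalue = c(1e-60, 1e-80, NA), score = c(50, 200, 30),
#'   start = NA_integer_, end = NA_integer_
#' )
#' call_consensus(hits)
#' @export
call_consensus <- function(hits, sample_id = "sample1",
                           agreement = c("family", "subfamily"),
                           similarity_evalue = 1e-50,
                           peptide_min_score = NULL) {
  agreement <- match.arg(agreement)
  empty <- structure(
    data.frame(orf_id = character(), family = character(),
               subfamily = character(), hmm = logical(),
               similarity = logical(), peptide = logical(),
               module_count = integer(), sample_id = character(),
               stringsAsFactors = FALSE),
    partial = data.frame(orf_id = character(), family = character(),
                         hmm = logical(), similarity = logical(),
                         peptide = logical(), stringsAsFactors = FALSE),
    class = c("cazyme_calls", "data.frame"))
  if (is.null(hits) || !nrow(hits)) return(empty)
  stopifnot(all(c("orf_id", "tool", "label", "evalue") %in% names(hits)))

  drop <- (hits$tool == "similarity" & (is.na(hits$evalue) |
                                          hits$evalue > similarity_evalue))
  if (!is.null(peptide_min_score)) {
    drop <- drop | (hits$tool == "peptide" &
                      (is.na(hits$score) | hits$score < peptide_min_score))
  }
  hits <- hits[!drop, , drop = FALSE]
  if (!nrow(hits)) return(empty)

  hits$family <- canonical_family(hits$label, level = agreement)
  hits <- hits[!is.na(hits$family), , drop = FALSE]
  if (!nrow(hits)) return(empty)

  key <- paste(hits$orf_id, hits$family, sep = "\r")
  tool_of <- function(t) tapply(hits$tool == t, key, any)
  ev <- data.frame(
    hmm = as.logical(tool_of("hmm")),
    similarity = as.logical(tool_of("similarity")),
    peptide = as.logical(tool_of("peptide"))
  )
  uk <- strsplit(names(tool_of("hmm")), "\r", fixed = TRUE)
  ev$orf_id <- vapply(uk, `[[`, character(1L), 1L)
  ev$family <- vapply(uk, `[[`, character(1L), 2L)

  full <- ev$hmm & ev$similarity & ev$peptide
  partial <- ev[!full, c("orf_id", "family", "hmm", "similarity", "peptide"),
                drop = FALSE]
  rownames(partial) <- NULL

  calls <- ev[full, , drop = FALSE]
  if (nrow(calls)) {
    hmm_hits <- hits[hits$tool == "hmm", , drop = FALSE]
    hkey <- paste(hmm_hits$orf_id, hmm_hits$family, sep = "\r")
    ckey <- paste(calls$orf_id, calls$family, sep = "\r")
    mc <- table(hkey)
    calls$module_count <- as.integer(mc[ckey])
    # most specific HMM-reported label, for subfamily-resolution reporting
    sub <- tapply(canonical_family(hmm_hits$label, level = "subfamily"),
                  hkey, function(s) sort(unique(s))[1L])
    calls$subfamily <- as.character(sub[ckey])
    if (is.data.frame(sample_id)) {
      calls$sample_id <- sample_id$sample_id[match(calls$orf_id,
                                                   sample_id$orf_id)]
      if (anyNA(calls$sample_id)) {
        stop("sample_id mapping is missing ORFs: ",
             paste(utils::head(calls$orf_id[is.na(calls$sample_id)]),
                   collapse = ", "))
      }
    } else {
      calls$sample_id <- as.character(sample_id)
    }
  } else {
    calls$module_count <- integer()
    calls$subfamily <- character()
    calls$sample_id <- character()
  }
  calls <- calls[order(calls$orf_id, calls$family),
                 c("orf_id", "family", "subfamily", "hmm", "similarity",
                   "peptide", "module_count", "sample_id"), drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, partial = partial, class = c("cazyme_calls", "data.frame"))
}

#' Partial-evidence side channel of a consensus call set
#'
#' Returns the (ORF, family) pairs supported by only one or two tools. These
#' are reported, never counted.
#'
#' @param calls object returned by [call_consensus()].
#' @return data.frame with evidence flags.
#' @export
partial_calls <- function(calls) {
  attr(calls, "partial")
}

#' Tally family module counts into a family-by-sample matrix
#'
#' Cell (family, sample) is the sum of `module_count` over calls, so the
#' matrix total conserves the total number of modules. Marginals per CAZy
#' class (GH/GT/PL/CE/AA/CBM) are available via [class_marginals()].
#'
#' @param calls consensus calls ([call_consensus()]).
#' @param meta sample metadata declaring the sample universe (data.frame
#'   with at least `sample_id`; typically from [read_sample_meta()]).
#' @param level `"family"` collapses subfamily labels; `"subfamily"` keeps
#'   them.
#' @return object of class `"FamilyCountMatrix"`: a list with `raw`
#'   (integer matrix, families x samples), `normalized` (`NULL` until
#'   [normalize_counts()] is applied), and `group_reference`.
#' @export
count_families <- function(calls, meta, level = c("family", "subfamily")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  samples <- as.character(meta$sample_id)
  unknown <- setdiff(unique(calls$sample_id), samples)
  if (length(unknown)) {
    stop("calls reference unknown sample_id(s): ",
         paste(unknown, collapse = ", "))
  }
  fam <- if (level == "subfamily" && !is.null(calls$subfamily)) {
    calls$subfamily
  } else {
    canonical_family(calls$family, level = level)
  }
  fams <- order_families(unique(fam))
  raw <- matrix(0L, nrow = length(fams), ncol = length(samples),
                dimnames = list(fams, samples))
  if (nrow(calls)) {
    agg <- stats::aggregate(calls$module_count,
                            by = list(family = fam, sample = calls$sample_id),
                            FUN = sum)
    raw[cbind(agg$family, agg$sample)] <- as.integer(agg$x)
  }
  structure(list(raw = raw, normalized = NULL, group_reference = NULL),
            class = "FamilyCountMatrix")
}

#' @export
print.FamilyCountMatrix <- function(x, ...) {
  cat(sprintf("FamilyCountMatrix: %d families x %d samples, %d modules%s\n",
              nrow(x$raw), ncol(x$raw), sum(x$raw),
              if (is.null(x$normalized)) "" else " (normalized)"))
  invisible(x)
}

#' Per-class marginals of a family count matrix
#'
#' @param x a `FamilyCountMatrix`.
#' @param which `"raw"` or `"normalized"`.
#' @return matrix with one row per CAZy class.
#' @export
class_marginals <- function(x, which = c("raw", "normalized")) {
  which <- match.arg(which)
  m <- x[[which]]
  if (is.null(m)) stop("matrix has no ", which, " slot yet")
  cls <- cazy_class(rownames(m))
  t(vapply(CAZY_CLASSES, function(cl) colSums(m[cls == cl, , drop = FALSE]),
           numeric(ncol(m))))
}

#' Partition family repertoires into host-only, microbiota-only and shared
#'
#' Set algebra on canonical family labels: `host_only = host \ microbiota`,
#' `microbiota_only = microbiota \ host`, `shared` the intersection, and the
#' union size. Always satisfies
#' `length(host_only) + length(microbiota_only) + length(shared) ==
#' union_size`.
#'
#' @param microbiota_families,host_families character vectors of canonical
#'   family labels (e.g. rownames of the metagenome / transcriptome count
#'   matrices).
#' @return list with `host_only`, `microbiota_only`, `shared` (sorted label
#'   vectors) and `union_size`.
#' @export
partition_families <- function(microbiota_families, host_families) {
  m <- unique(as.character(microbiota_families))
  h <- unique(as.character(host_families))
  list(
    host_only = order_families(setdiff(h, m)),
    microbiota_only = order_families(setdiff(m, h)),
    shared = order_families(intersect(m, h)),
    union_size = length(union(m, h))
  )
}
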