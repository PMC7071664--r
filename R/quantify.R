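# Library-size normalization of family module counts.

#' Normalize family counts by ORF library size
#'
#' For each sample, raw module counts are divided by the sample's number of
#' ORFs (relative abundance) and multiplied by the lowest ORF count among
#' the samples of the same normalization group, so the group's smallest
#' library is the common reference:
#'
#' `normalized(f, s) = raw(f, s) / n_orfs(s) * min(n_orfs over group(s))`
#'
#' The sample that attains the group minimum keeps its raw counts unchanged.
#' Groups default to `meta$norm_group` when present, otherwise to
#' `meta$dataset_kind` strata (metagenomes and transcriptomes are normalized
#' on separate references); pass `groups` to override.
#'
#' @param x a `FamilyCountMatrix` from [count_families()].
#' @param meta sample metadata with `sample_id` and positive `n_orfs`.
#' @param groups optional named character vector or data.frame
#'   (`sample_id`, `group`) assigning each sample to a normalization group.
#' @return the `FamilyCountMatrix` with `normalized` filled in (reals, never
#'   rounded; the report layer rounds for display) and `group_reference`, a
#'   data.frame of per-group reference ORF counts. The raw matrix is
#'   untouched.
#' @export
normalize_counts <- function(x, meta, groups = NULL) {
  stopifnot(inherits(x, "FamilyCountMatrix"))
  validate_sample_meta(meta)
  samples <- colnames(x$raw)
  mi <- match(samples, meta$sample_id)
  if (anyNA(mi)) {
    stop("samples missing from metadata: ",
         paste(samples[is.na(mi)], collapse = ", "))
  }
  n_orfs <- meta$n_orfs[mi]
  if (any(n_orfs <= 0)) stop("n_orfs must be positive")

  grp <- if (is.null(groups)) {
    if ("norm_group" %in% names(meta)) meta$norm_group[mi]
    else meta$dataset_kind[mi]
  } else if (is.data.frame(groups)) {
    g <- groups$group[match(samples, groups$sample_id)]
    if (anyNA(g)) stop("samples missing from normalization groups: ",
                       paste(samples[is.na(g)], collapse = ", "))
    g
  } else {
    g <- groups[samples]
    if (anyNA(g)) stop("samples missing from normalization groups: ",
                       paste(samples[is.na(unname(g))], collapse = ", "))
    unname(g)
  }

  ref <- tapply(n_orfs, grp, min)
  scale <- as.numeric(ref[grp]) / n_orfs
  x$normalized <- sweep(x$raw, 2L, scale, `*`)
  x$group_reference <- data.frame(
    group = names(ref),
    reference_n_orfs = as.integer(ref),
    n_samples = as.integer(table(grp)[names(ref)]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  x
}

#' Write a family count matrix as wide TSV
#'
#' @param x a `FamilyCountMatrix`.
#' @param path output path.
#' @param which `"raw"` or `"normalized"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, which = c("raw", "normalized")) {
  which <- match.arg(which)
  m <- x[[which]]
  if (is.null(m)) stop("matrix has no ", which, " slot yet")
  d <- data.frame(family = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write_tsv(d, path)
}
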