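# Naive lowest-common-ancestor taxonomic attribution.
#
# Lineages are semicolon-delimited paths from domain downward; positions are
# compared rank-aligned (position 1 = domain, 2 = phylum, ...). A missing
# intermediate rank (empty token) is a wildcard that never breaks a common
# prefix. No min-support or top-percent weighting is applied: the assignment
# is the plain longest common prefix of the retained hits.

CANONICAL_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

split_lineage <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the longest common prefix of the lineages: a single hit yields
#' its full lineage, disagreement at the first position yields the root
#' (empty lineage, "unassigned"), and empty input yields the root with
#' support 0. Empty tokens act as wildcards: they match whatever name the
#' other lineages carry at that position.
#'
#' @param lineages character vector of semicolon-delimited lineages (one per
#'   retained hit of a single ORF).
#' @return list with `lineage` (semicolon-delimited common prefix, `""` for
#'   root) and `support` (number of hits used).
#' @examples
#' lca(c("Bacteria;Proteobacteria;Rhizobiales",
#'       "Bacteria;Proteobacteria;Vibrionales"))
#' @export
lca <- function(lineages) {
  toks <- lapply(lineages, split_lineage)
  toks <- toks[lengths(toks) > 0L]
  n <- length(toks)
  if (n == 0L) return(list(lineage = "", support = 0L))
  depth <- min(lengths(toks))
  out <- character()
  for (i in seq_len(depth)) {
    names_i <- vapply(toks, `[[`, character(1L), i)
    distinct <- unique(names_i[nzchar(names_i)])
    if (length(distinct) > 1L) break
    out <- c(out, if (length(distinct)) distinct else "")
  }
  # trim trailing wildcard-only positions
  while (length(out) && !nzchar(out[length(out)])) out <- utils::head(out, -1L)
  list(lineage = paste(out, collapse = ";"), support = n)
}

#' Assign taxa to ORFs by LCA over their retained hits
#'
#' @param lineages data.frame from [read_lineages()] (`orf_id`, `hit_rank`,
#'   `evalue`, `lineage`).
#' @return data.frame `orf_id`, `assigned_lineage` (`""` = root/unassigned),
#'   `support`.
#' @export
assign_taxa <- function(lineages) {
  if (!nrow(lineages)) {
    return(data.frame(orf_id = character(), assigned_lineage = character(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  per <- split(lineages$lineage, lineages$orf_id)
  res <- lapply(per, lca)
  data.frame(
    orf_id = names(per),
    assigned_lineage = vapply(res, `[[`, character(1L), "lineage"),
    support = vapply(res, `[[`, integer(1L), "support"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Taxon-by-CAZy-class community profile
#'
#' Aggregates CAZyme module counts by the taxon of the encoding ORF at a
#' requested rank. ORFs whose assignment does not resolve to that rank
#' (including unassigned ORFs and ORFs with no lineage at all) are counted
#' under `"unknown"`, so column sums conserve the total modules of the
#' profiled calls.
#'
#' @param assignments data.frame from [assign_taxa()].
#' @param calls consensus calls ([call_consensus()]).
#' @param level rank to profile at, one of `r toString(CANONICAL_RANKS)`
#'   (positional: rank i is the i-th lineage field).
#' @return data.frame `taxon` x CAZy class module counts plus a `total`
#'   column.
#' @export
profile_community <- function(assignments, calls,
                              level = c("phylum", "domain", "class", "order",
                                        "family", "genus", "species")) {
  level <- match.arg(level)
  pos <- match(level, CANONICAL_RANKS)
  if (!nrow(calls)) {
    out <- data.frame(taxon = character(), stringsAsFactors = FALSE)
    for (cl in CAZY_CLASSES) out[[cl]] <- numeric()
    out$total <- numeric()
    return(out)
  }
  ai <- match(calls$orf_id, assignments$orf_id)
  lin <- assignments$assigned_lineage[ai]
  taxon <- vapply(lin, function(l) {
    t <- if (is.na(l)) character() else split_lineage(l)
    if (length(t) >= pos && nzchar(t[pos])) t[pos] else "unknown"
  }, character(1L), USE.NAMES = FALSE)
  cls <- cazy_class(canonical_family(calls$family, level = "family"))
  agg <- stats::aggregate(calls$module_count,
                          by = list(taxon = taxon, class = cls), FUN = sum)
  taxa <- sort(unique(agg$taxon))
  out <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (cl in CAZY_CLASSES) {
    v <- agg$x[match(paste(taxa, cl), paste(agg$taxon, agg$class))]
    out[[cl]] <- ifelse(is.na(v), 0, v)
  }
  out$total <- rowSums(out[, CAZY_CLASSES, drop = FALSE])
  out
}
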