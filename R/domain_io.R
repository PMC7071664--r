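# Readers and writers for the external evidence tables.
#
# All coordinates are 1-based inclusive (GFF convention). Readers are
# lenient by default: malformed rows are skipped with a warning that lists
# the offending line numbers; strict = TRUE turns those warnings into errors.

.io_problem <- function(what, lines, strict) {
  msg <- sprintf("%s at line%s %s", what,
                 if (length(lines) > 1L) "s" else "",
                 paste(lines, collapse = ", "))
  if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
}

#' Read per-ORF CAZyme domain evidence
#'
#' Parses one of the three evidence dialects produced by CAZyme annotation
#' tools into a common domain-hit table:
#'
#' * `hmm_domtbl` — HMMER3 `--domtblout` layout (whitespace-delimited, 22
#'   fixed columns plus free-text description). The target name is the dbCAN
#'   profile (e.g. `"GH13.hmm"`), the query is the ORF; the independent
#'   i-Evalue and alignment coordinates on the query are kept.
#' * `similarity_tab` — 12-column BLAST/DIAMOND `outfmt 6` tabular layout;
#'   the family label is taken from the subject id after its last `"|"`.
#' * `peptide_tab` — peptide-signature hits as a 3+ column TSV with header
#'   `orf_id`, `family`, `score` (a Hotpep-like schema; the score is kept in
#'   the `score` column and `evalue` is `NA`).
#'
#' Labels are canonicalized with [canonical_family()] (trailing `".hmm"`
#' stripped, subfamily suffixes preserved). Rows whose label is not a valid
#' CAZy label, or whose e-value is missing/negative, are skipped with a
#' warning naming the line numbers (an error when `strict = TRUE`).
#'
#' @param path path to the evidence file.
#' @param dialect one of `"hmm_domtbl"`, `"similarity_tab"`, `"peptide_tab"`.
#' @param strict logical; malformed rows become errors instead of warnings.
#' @return data.frame with columns `orf_id`, `tool` (one of `"hmm"`,
#'   `"similarity"`, `"peptide"`), `label`, `evalue`, `score`, `start`,
#'   `end`. Attribute `n_skipped` counts skipped rows.
#' @export
read_domain_hits <- function(path,
                             dialect = c("hmm_domtbl", "similarity_tab",
                                         "peptide_tab"),
                             strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read evidence file: ", path)
  lines <- readLines(path)
  empty <- data.frame(orf_id = character(), tool = character(),
                      label = character(), evalue = numeric(),
                      score = numeric(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)

  tool <- switch(dialect, hmm_domtbl = "hmm", similarity_tab = "similarity",
                 peptide_tab = "peptide")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  body <- lines[keep]
  if (dialect == "peptide_tab" && length(body) &&
      grepl("^orf_id\\t", body[1L])) {
    body <- body[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(body)) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }

  parse_one <- function(line) {
    if (dialect == "hmm_domtbl") {
      f <- strsplit(trimws(line), "[ \t]+")[[1L]]
      if (length(f) < 22L) return(NULL)
      list(orf = f[4L], label = f[1L], evalue = suppressWarnings(as.numeric(f[13L])),
           score = suppressWarnings(as.numeric(f[14L])),
           start = suppressWarnings(as.integer(f[18L])),
           end = suppressWarnings(as.integer(f[19L])))
    } else if (dialect == "similarity_tab") {
      f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 12L) return(NULL)
      lab <- utils::tail(strsplit(f[2L], "|", fixed = TRUE)[[1L]], 1L)
      list(orf = f[1L], label = lab,
           evalue = suppressWarnings(as.numeric(f[11L])),
           score = suppressWarnings(as.numeric(f[12L])),
           start = suppressWarnings(as.integer(f[7L])),
           end = suppressWarnings(as.integer(f[8L])))
    } else {
      f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L) return(NULL)
      list(orf = f[1L], label = f[2L], evalue = NA_real_,
           score = suppressWarnings(as.numeric(f[3L])),
           start = NA_integer_, end = NA_integer_)
    }
  }

  parsed <- lapply(body, parse_one)
  bad_shape <- vapply(parsed, is.null, logical(1L))
  lab <- vapply(parsed, function(p) if (is.null(p)) NA_character_ else p$label,
                character(1L))
  canon <- canonical_family(lab)
  ev <- vapply(parsed, function(p) if (is.null(p)) NA_real_ else p$evalue,
               numeric(1L))
  bad_label <- !bad_shape & is.na(canon)
  bad_evalue <- !bad_shape & !bad_label & dialect != "peptide_tab" &
    (is.na(ev) | ev < 0)
  bad <- bad_shape | bad_label | bad_evalue
  if (any(bad)) .io_problem(sprintf("%d malformed %s row(s) skipped", sum(bad),
                                    dialect),
                            lineno[bad], strict)
  ok <- which(!bad)
  out <- data.frame(
    orf_id = vapply(parsed[ok], `[[`, character(1L), "orf"),
    tool = rep(tool, length(ok)),
    label = canon[ok],
    evalue = ev[ok],
    score = vapply(parsed[ok], `[[`, numeric(1L), "score"),
    start = vapply(parsed[ok], `[[`, integer(1L), "start"),
    end = vapply(parsed[ok], `[[`, integer(1L), "end"),
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read gene models from a GFF3 file
#'
#' Genes are grouped per contig and assigned a `gene_index` by ascending
#' start coordinate (1-based inclusive), so that adjacency on the contig can
#' be evaluated by index difference. Records with `start > end` are skipped
#' with a warning (fatal when `strict = TRUE`); duplicated `orf_id`s on one
#' contig are tolerated with a warning; genes overlapping their predecessor
#' are kept and flagged in the `overlaps` column.
#'
#' @param path path to a GFF3 file whose records carry an `ID` attribute
#'   naming the ORF.
#' @param strict logical; coordinate violations and duplicate ids become
#'   errors.
#' @return data.frame with columns `contig_id`, `gene_index`, `start`,
#'   `end`, `strand`, `orf_id`, `overlaps`.
#' @export
read_gene_table <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read gene table: ", path)
  lines <- readLines(path)
  body <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  st <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 5L) f[4L] else NA_character_, character(1L))))
  en <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 5L) f[5L] else NA_character_, character(1L))))
  bad <- nfield < 9L | is.na(st) | is.na(en) | st > en | st < 1
  if (any(bad)) {
    .io_problem(sprintf("%d invalid gene record(s) skipped", sum(bad)),
                which(body)[bad], strict)
    keep <- lines
    keep[which(body)[bad]] <- NA
    tmp <- tempfile(fileext = ".gff3")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(keep[!is.na(keep)], tmp)
    path <- tmp
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) {
    return(data.frame(contig_id = character(), gene_index = integer(),
                      start = integer(), end = integer(), strand = character(),
                      orf_id = character(), overlaps = logical(),
                      stringsAsFactors = FALSE))
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("gene_%06d", seq_along(gr))
  g <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    orf_id = ids,
    stringsAsFactors = FALSE
  )
  g$strand[!g$strand %in% c("+", "-")] <- "+"
  g <- g[order(g$contig_id, g$start, g$end, g$orf_id), , drop = FALSE]
  idx <- stats::ave(g$start, g$contig_id, FUN = seq_along)
  g$gene_index <- as.integer(idx)
  prev_end <- stats::ave(g$end, g$contig_id,
                         FUN = function(e) c(-Inf, utils::head(cummax(e), -1L)))
  g$overlaps <- g$start <= prev_end
  key <- paste(g$contig_id, g$orf_id, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    msg <- sprintf("duplicate orf_id on one contig: %s",
                   paste(unique(g$orf_id[dup]), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  rownames(g) <- NULL
  g[, c("contig_id", "gene_index", "start", "end", "strand", "orf_id",
        "overlaps")]
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_table()]: well-formed tables round-trip.
#'
#' @param genes data.frame as returned by [read_gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "cazomer"
  gr$type <- "gene"
  gr$ID <- genes$orf_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read per-ORF Pfam conserved-domain hits
#'
#' TSV with header `orf_id`, `accession`, `evalue`. Hits above the e-value
#' cutoff (the screen default mirrors the conserved-domain search cutoff of
#' 1e-4) are dropped; rows with an invalid Pfam accession are skipped with a
#' warning.
#'
#' @param path path to the TSV.
#' @param evalue_cutoff numeric; hits with larger e-value are dropped.
#' @param strict logical; malformed rows become errors.
#' @return data.frame `orf_id`, `accession`, `evalue`.
#' @export
read_pfam_hits <- function(path, evalue_cutoff = 1e-4, strict = FALSE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("orf_id", "accession", "evalue")
  if (!all(need %in% names(d))) {
    stop("Pfam hit table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !is_pfam_accession(d$accession) | is.na(d$evalue) | d$evalue < 0
  if (any(bad)) {
    .io_problem(sprintf("%d invalid Pfam hit(s) skipped", sum(bad)),
                which(bad) + 1L, strict)
  }
  d <- d[!bad & d$evalue <= evalue_cutoff, need, drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read ranked taxonomy lineages for CAZyme ORFs
#'
#' TSV with header `orf_id`, `hit_rank`, `evalue`, `lineage`, where
#' `lineage` is a semicolon-delimited path from domain downward
#' (`"Bacteria;Proteobacteria;Rhizobiales"`). Hits with e-value above the
#' cutoff are dropped; at most `k` hits are retained per ORF, best e-value
#' first, and re-ranked 1..n. Records with an empty lineage are dropped with
#' a warning.
#'
#' @param path path to the TSV.
#' @param k maximum number of hits kept per ORF (the screen keeps the top
#'   five by default).
#' @param evalue_cutoff numeric e-value cutoff (default 1e-4).
#' @return data.frame `orf_id`, `hit_rank`, `evalue`, `lineage`.
#' @export
read_lineages <- function(path, k = 5L, evalue_cutoff = 1e-4) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(lineage = "character"))
  need <- c("orf_id", "hit_rank", "evalue", "lineage")
  if (!all(need %in% names(d))) {
    stop("lineage table must have columns: ", paste(need, collapse = ", "))
  }
  empty <- is.na(d$lineage) | trimws(d$lineage) == ""
  if (any(empty)) {
    warning(sprintf("%d lineage record(s) with empty lineage dropped",
                    sum(empty)), call. = FALSE)
    d <- d[!empty, , drop = FALSE]
  }
  d <- d[!is.na(d$evalue) & d$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(d)) return(d[, need])
  d <- d[order(d$orf_id, d$evalue, d$hit_rank), , drop = FALSE]
  rank_new <- stats::ave(d$evalue, d$orf_id, FUN = seq_along)
  d <- d[rank_new <= k, , drop = FALSE]
  d$hit_rank <- as.integer(stats::ave(d$evalue, d$orf_id, FUN = seq_along))
  rownames(d) <- NULL
  d[, need]
}

#' Read per-sample metadata
#'
#' TSV with header `sample_id`, `host_species`, `origin`
#' (laboratory/field), `sex` (male/female), `tissue`
#' (caeca/hindgut/non_digestive/whole), `dataset_kind`
#' (metagenome/transcriptome), `n_orfs` (ORF library size, the
#' normalization unit). An optional `norm_group` column overrides the
#' default normalization grouping.
#'
#' @param path path to the TSV.
#' @return validated data.frame.
#' @export
read_sample_meta <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "host_species", "origin", "sex", "tissue",
            "dataset_kind", "n_orfs")
  if (!all(need %in% names(d))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  }
  validate_sample_meta(d)
  d
}

validate_sample_meta <- function(meta) {
  stopifnot(is.data.frame(meta), nrow(meta) > 0L)
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  chk <- function(col, allowed) {
    bad <- !meta[[col]] %in% allowed
    if (any(bad)) stop(sprintf("invalid %s value(s): %s", col,
                               paste(unique(meta[[col]][bad]), collapse = ", ")))
  }
  chk("origin", c("laboratory", "field"))
  chk("sex", c("male", "female"))
  chk("tissue", c("caeca", "hindgut", "non_digestive", "whole"))
  chk("dataset_kind", c("metagenome", "transcriptome"))
  if (any(is.na(meta$n_orfs)) || any(meta$n_orfs <= 0)) {
    stop("n_orfs must be a positive integer for every sample")
  }
  invisible(meta)
}

# ---- format writers (used by the synthetic generator; kept here so the
# ---- writers and readers share one definition of each dialect) ----

write_domtbl <- function(hits, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"
  ), con)
  if (nrow(hits)) {
    lines <- sprintf(
      "%s.hmm - %d %s - %d %.1e %.1f 0.0 %d %d %.1e %.1e %.1f 0.0 1 %d %d %d %d %d 0.90 -",
      hits$label, hits$tlen, hits$orf_id, hits$qlen, hits$evalue, hits$score,
      hits$dom_i, hits$dom_n, hits$evalue, hits$evalue, hits$score,
      hits$tlen, hits$start, hits$end, hits$start, hits$end)
    writeLines(lines, con)
  }
  invisible(path)
}

write_outfmt6 <- function(hits, path) {
  lines <- if (nrow(hits)) {
    sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.1e\t%.1f",
            hits$orf_id, paste0(hits$subject, "|", hits$label), hits$pident,
            hits$length, 0L, 0L, hits$start, hits$end, 1L, hits$length,
            hits$evalue, hits$score)
  } else character()
  writeLines(lines, path)
  invisible(path)
}

write_peptide_tab <- function(hits, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("orf_id\tfamily\tscore", con)
  if (nrow(hits)) {
    writeLines(sprintf("%s\t%s\t%.1f", hits$orf_id, hits$label, hits$score),
               con)
  }
  invisible(path)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
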