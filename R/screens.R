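# Gene-cluster screens on assembled contigs.
#
# Two screens operate on gene-ordered contigs (gene_index assigned by
# ascending start): polysaccharide utilization loci (PULs), marked by a
# sequential susC-susD gene pair, and cellulosomes, marked by cohesin,
# dockerin and S-layer homology (SLH) domains co-located with CAZymes.

#' Default Pfam marker accessions for the locus screens
#'
#' susC = TonB-dependent receptor (PF00593), susD = SusD-like glycan-binding
#' protein (PF07980), cohesin = PF00963, SLH = PF00395. The dockerin
#' accession defaults to the standard Pfam dockerin repeat (PF00404) but is
#' deliberately a plain config value: published marker lists occasionally
#' repeat the cohesin accession for the dockerin, so the screen never
#' hard-codes it.
#'
#' @return named character vector.
#' @export
default_markers <- function() {
  c(susC = "PF00593", susD = "PF07980",
    cohesin = "PF00963", dockerin = "PF00404", slh = "PF00395")
}

# orf -> set of marker names present, given pfam hits
.marker_orfs <- function(pfam_hits, accession) {
  unique(pfam_hits$orf_id[pfam_hits$accession == accession])
}

# orf -> collapsed "+"-separated CAZy family string from calls, at
# subfamily resolution where the calls carry it ("GH5_13")
.fams_by_orf <- function(calls) {
  if (is.null(calls) || !nrow(calls)) return(character())
  fam <- if (!is.null(calls$subfamily)) calls$subfamily else
    canonical_family(calls$family, level = "subfamily")
  vapply(split(fam, calls$orf_id),
         function(f) paste(order_families(unique(f)), collapse = " + "),
         character(1L))
}

#' Screen contigs for PUL candidates (sequential susC-susD pairs)
#'
#' A candidate is one pair of genes, adjacent in gene order
#' (`|gene_index difference| == 1`), where one gene bears the susC marker
#' domain and the other the susD marker. Either order is accepted and strand
#' is ignored by default; `strict = TRUE` additionally requires the
#' canonical tandem layout (susC immediately upstream of susD on the same
#' strand). Gene order is always recomputed from coordinates, so the result
#' is invariant to shuffling of the input rows.
#'
#' Contigs that carry susC and/or susD but no adjacent pair are tallied as
#' orphan-bearing contigs in the `orphans` element — on real assemblies these
#' vastly outnumber pair-bearing contigs because PULs fragment across contig
#' boundaries.
#'
#' @param genes gene table from [read_gene_table()].
#' @param pfam_hits Pfam hit table from [read_pfam_hits()].
#' @param calls optional consensus calls used to list co-localized CAZymes.
#' @param markers named vector with `susC` and `susD` accessions.
#' @param window co-localization window in bp around the pair for CAZyme
#'   genes; `NULL` (default) uses the whole contig, which suits short
#'   metagenome contigs.
#' @param strict logical; require susC-then-susD tandem on one strand.
#' @return list of class `"pul_screen"`: `candidates` (one row per pair:
#'   contig, susC/susD gene ids, span, co-localized CAZyme ORFs/families),
#'   `orphans` (contig, n_susC, n_susD), `n_marker_contigs`.
#' @export
screen_pul <- function(genes, pfam_hits, calls = NULL,
                       markers = default_markers(), window = NULL,
                       strict = FALSE) {
  stopifnot(all(c("susC", "susD") %in% names(markers)))
  g <- genes[order(genes$contig_id, genes$start, genes$end, genes$orf_id), ,
             drop = FALSE]
  g$gene_index <- as.integer(stats::ave(g$start, g$contig_id, FUN = seq_along))
  susC_orfs <- .marker_orfs(pfam_hits, markers[["susC"]])
  susD_orfs <- .marker_orfs(pfam_hits, markers[["susD"]])
  g$is_susC <- g$orf_id %in% susC_orfs
  g$is_susD <- g$orf_id %in% susD_orfs
  fams <- .fams_by_orf(calls)

  cand <- list()
  orphan <- list()
  for (ct in unique(g$contig_id[g$is_susC | g$is_susD])) {
    gc <- g[g$contig_id == ct, , drop = FALSE]
    n <- nrow(gc)
    pair_rows <- NULL
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        a <- gc[i, ]; b <- gc[i + 1L, ]
        ok <- if (strict) {
          a$is_susC && b$is_susD && !(a$is_susD || b$is_susC) &&
            a$strand == b$strand
        } else {
          (a$is_susC && b$is_susD) || (a$is_susD && b$is_susC)
        }
        if (ok) pair_rows <- rbind(pair_rows, data.frame(i = i, j = i + 1L))
      }
    }
    if (is.null(pair_rows)) {
      orphan[[ct]] <- data.frame(contig_id = ct,
                                 n_susC = sum(gc$is_susC),
                                 n_susD = sum(gc$is_susD),
                                 stringsAsFactors = FALSE)
      next
    }
    for (r in seq_len(nrow(pair_rows))) {
      a <- gc[pair_rows$i[r], ]; b <- gc[pair_rows$j[r], ]
      susC_gene <- if (a$is_susC) a else b
      susD_gene <- if (a$is_susC) b else a
      span <- c(min(a$start, b$start), max(a$end, b$end))
      near <- if (is.null(window)) rep(TRUE, nrow(gc)) else {
        gc$end >= span[1L] - window & gc$start <= span[2L] + window
      }
      caz <- gc$orf_id[near & gc$orf_id %in% names(fams)]
      caz <- setdiff(caz, c(susC_gene$orf_id, susD_gene$orf_id))
      if (length(caz)) span <- range(c(span, gc$start[gc$orf_id %in% caz],
                                       gc$end[gc$orf_id %in% caz]))
      cand[[length(cand) + 1L]] <- data.frame(
        contig_id = ct,
        susC_orf = susC_gene$orf_id, susD_orf = susD_gene$orf_id,
        span_start = span[1L], span_end = span[2L],
        n_cazymes = length(caz),
        cazyme_orfs = paste(caz, collapse = ","),
        cazyme_families = paste(fams[caz], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else
    data.frame(contig_id = character(), susC_orf = character(),
               susD_orf = character(), span_start = integer(),
               span_end = integer(), n_cazymes = integer(),
               cazyme_orfs = character(), cazyme_families = character(),
               stringsAsFactors = FALSE)
  orphans <- if (length(orphan)) do.call(rbind, orphan) else
    data.frame(contig_id = character(), n_susC = integer(),
               n_susD = integer(), stringsAsFactors = FALSE)
  rownames(candidates) <- rownames(orphans) <- NULL
  structure(list(candidates = candidates, orphans = orphans,
                 n_marker_contigs = length(unique(c(candidates$contig_id,
                                                    orphans$contig_id)))),
            class = "pul_screen")
}

#' @export
print.pul_screen <- function(x, ...) {
  cat(sprintf(
    "PUL screen: %d candidate pair(s) on %d contig(s); %d orphan contig(s); %d marker-bearing contig(s)\n",
    nrow(x$candidates), length(unique(x$candidates$contig_id)),
    nrow(x$orphans), x$n_marker_contigs))
  invisible(x)
}

#' Screen contigs for cellulosome components
#'
#' Lists, per contig, the genes bearing cohesin, dockerin and SLH marker
#' domains. Module totals count domain hits (a gene with two dockerin
#' repeats contributes two modules). Genes bearing both a dockerin domain
#' and at least one CAZy family are emitted as enzyme-dockerin fusions — the
#' direct evidence for cellulosome-bound CAZymes — in a report joined, when
#' metadata and contig taxonomy are supplied, to host, origin, sex, tissue
#' and taxon.
#'
#' @param genes gene table from [read_gene_table()].
#' @param pfam_hits Pfam hit table from [read_pfam_hits()].
#' @param calls optional consensus calls; needed for fusion detection.
#' @param markers named vector with `cohesin`, `dockerin`, `slh` accessions
#'   (see [default_markers()]).
#' @param meta optional sample metadata; `orf_samples` maps ORFs to samples.
#' @param orf_samples optional data.frame `orf_id`, `sample_id`.
#' @param contig_taxa optional data.frame `contig_id`, `taxon`.
#' @return list of class `"cellulosome_screen"`: `candidates` (per-contig
#'   marker gene lists and counts), `fusions` (one row per dockerin-CAZyme
#'   gene), and `totals` (dockerin/cohesin/SLH module and contig counts).
#' @export
screen_cellulosome <- function(genes, pfam_hits, calls = NULL,
                               markers = default_markers(), meta = NULL,
                               orf_samples = NULL, contig_taxa = NULL) {
  stopifnot(all(c("cohesin", "dockerin", "slh") %in% names(markers)))
  acc <- markers[c("cohesin", "dockerin", "slh")]
  hit <- pfam_hits[pfam_hits$accession %in% acc, , drop = FALSE]
  hit$kind <- names(acc)[match(hit$accession, acc)]
  hit <- hit[hit$orf_id %in% genes$orf_id, , drop = FALSE]

  orf_contig <- genes$contig_id[match(hit$orf_id, genes$orf_id)]
  fams <- .fams_by_orf(calls)

  contigs <- sort(unique(orf_contig))
  candidates <- do.call(rbind, lapply(contigs, function(ct) {
    h <- hit[orf_contig == ct, , drop = FALSE]
    lst <- function(k) paste(sort(unique(h$orf_id[h$kind == k])),
                             collapse = ",")
    data.frame(contig_id = ct,
               n_dockerin = sum(h$kind == "dockerin"),
               n_cohesin = sum(h$kind == "cohesin"),
               n_slh = sum(h$kind == "slh"),
               dockerin_orfs = lst("dockerin"), cohesin_orfs = lst("cohesin"),
               slh_orfs = lst("slh"), stringsAsFactors = FALSE)
  }))
  if (is.null(candidates)) {
    candidates <- data.frame(contig_id = character(), n_dockerin = integer(),
                             n_cohesin = integer(), n_slh = integer(),
                             dockerin_orfs = character(),
                             cohesin_orfs = character(),
                             slh_orfs = character(), stringsAsFactors = FALSE)
  }

  dock_orfs <- unique(hit$orf_id[hit$kind == "dockerin"])
  fus_orfs <- sort(intersect(dock_orfs, names(fams)))
  fusions <- data.frame(
    orf_id = fus_orfs,
    contig_id = genes$contig_id[match(fus_orfs, genes$orf_id)],
    families = unname(fams[fus_orfs]),
    stringsAsFactors = FALSE)
  fusions$taxon <- if (!is.null(contig_taxa)) {
    contig_taxa$taxon[match(fusions$contig_id, contig_taxa$contig_id)]
  } else {
    rep(NA_character_, nrow(fusions))
  }
  if (!is.null(orf_samples) && !is.null(meta)) {
    sid <- orf_samples$sample_id[match(fusions$orf_id, orf_samples$orf_id)]
    mi <- match(sid, meta$sample_id)
    fusions <- cbind(data.frame(host_species = meta$host_species[mi],
                                origin = meta$origin[mi], sex = meta$sex[mi],
                                tissue = meta$tissue[mi],
                                stringsAsFactors = FALSE),
                     fusions)
  }
  rownames(fusions) <- NULL

  structure(list(
    candidates = candidates,
    fusions = fusions,
    totals = c(dockerin_modules = sum(hit$kind == "dockerin"),
               cohesin_modules = sum(hit$kind == "cohesin"),
               slh_modules = sum(hit$kind == "slh"),
               dockerin_cohesin_contigs =
                 length(unique(orf_contig[hit$kind %in%
                                            c("dockerin", "cohesin")])),
               slh_contigs = length(unique(orf_contig[hit$kind == "slh"])),
               fusion_genes = nrow(fusions))
  ), class = "cellulosome_screen")
}

#' @export
print.cellulosome_screen <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "Cellulosome screen: %d dockerin + %d cohesin module(s) on %d contig(s); %d SLH contig(s); %d CAZyme-dockerin fusion gene(s)\n",
    t[["dockerin_modules"]], t[["cohesin_modules"]],
    t[["dockerin_cohesin_contigs"]], t[["slh_contigs"]],
    t[["fusion_genes"]]))
  invisible(x)
}

#' Text rendering of a PUL gene map
#'
#' Renders the gene order of a candidate's contig as labels: `susC`, `susD`,
#' the CAZy families of consensus-called genes, and `unk` for everything
#' else.
#'
#' @param pul one row of `screen_pul()$candidates`.
#' @param genes gene table.
#' @param calls optional consensus calls for family labels.
#' @return single character string, e.g. `"unk - susC - susD - GH43"`.
#' @export
render_pul_map <- function(pul, genes, calls = NULL) {
  gc <- genes[genes$contig_id == pul$contig_id, , drop = FALSE]
  gc <- gc[order(gc$start), , drop = FALSE]
  fams <- .fams_by_orf(calls)
  lab <- ifelse(gc$orf_id == pul$susC_orf, "susC",
                ifelse(gc$orf_id == pul$susD_orf, "susD",
                       ifelse(gc$orf_id %in% names(fams),
                              fams[gc$orf_id], "unk")))
  paste(lab, collapse = " - ")
}

#' Curated inventory of dockerin-bearing CAZyme genes
#'
#' A packaged table of 30 enzyme-dockerin fusion genes observed in isopod
#' gut metagenomes (host species, origin, sex, tissue, closest assigned
#' taxon, CAZy families — multi-module genes use `"GH26 + CBM35"` notation).
#' Useful as a realistic `fusion_table` for
#' [synthetic_scenario()]'s cellulosome layout.
#'
#' @return data.frame with columns `host_species`, `origin`, `sex`,
#'   `tissue`, `taxon`, `families`.
#' @export
dockerin_fusion_inventory <- function() {
  utils::read.delim(system.file("extdata", "dockerin_cazyme_fusions.tsv",
                                package = "cazomer", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
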