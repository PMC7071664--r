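# End-to-end orchestration: annotate -> quantify -> classify -> taxonomy ->
# locus screens, with a provenance manifest and publication-style summary tables.

#' Assemble and validate a pipeline configuration
#'
#' Referenced files are checked at validation time; thresholds must be
#' positive. `activities` and `contig_taxa` are optional inputs.
#'
#' @param hmm,similarity,peptide paths to the three evidence tables.
#' @param genes path to the GFF3 gene models.
#' @param pfam path to the Pfam hit TSV.
#' @param lineages path to the lineage TSV.
#' @param samples path to the sample metadata TSV.
#' @param orf_samples path to the ORF-to-sample mapping TSV.
#' @param activities optional path to activity predictions.
#' @param contig_taxa optional path to precomputed contig taxonomy.
#' @param out_dir output directory for the report bundle.
#' @param similarity_evalue e-value gate for similarity hits.
#' @param lineage_evalue e-value cutoff for lineage hits.
#' @param top_k lineage hits retained per ORF.
#' @param markers named marker accessions (see [default_markers()]).
#' @param norm_groups optional normalization grouping (see
#'   [normalize_counts()]).
#' @param class_map optional path to a custom lignocellulose class map.
#' @param profile_rank rank for the community profile.
#' @param strict strict parsing mode for the readers.
#' @param scenario_id optional scenario tag carried into the bundle so
#'   [score_against_truth()] can refuse mismatched manifests.
#' @return validated list of class `"run_config"`.
#' @export
pipeline_config <- function(hmm, similarity, peptide, genes, pfam, lineages,
                            samples, orf_samples, activities = NULL,
                            contig_taxa = NULL, out_dir = tempfile("cazome_"),
                            similarity_evalue = 1e-50, lineage_evalue = 1e-4,
                            top_k = 5L, markers = default_markers(),
                            norm_groups = NULL, class_map = NULL,
                            profile_rank = "phylum", strict = FALSE,
                            scenario_id = NULL) {
  cfg <- list(hmm = hmm, similarity = similarity, peptide = peptide,
              genes = genes, pfam = pfam, lineages = lineages,
              samples = samples, orf_samples = orf_samples,
              activities = activities, contig_taxa = contig_taxa,
              out_dir = out_dir, similarity_evalue = similarity_evalue,
              lineage_evalue = lineage_evalue, top_k = as.integer(top_k),
              markers = markers, norm_groups = norm_groups,
              class_map = class_map, profile_rank = profile_rank,
              strict = strict, scenario_id = scenario_id)
  required <- c("hmm", "similarity", "peptide", "genes", "pfam", "lineages",
                "samples", "orf_samples")
  for (f in required) {
    if (is.null(cfg[[f]])) stop("missing required input: ", f)
    if (!file.exists(cfg[[f]])) {
      stop(sprintf("input '%s' does not exist: %s", f, cfg[[f]]))
    }
  }
  for (f in c("activities", "contig_taxa")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop(sprintf("input '%s' does not exist: %s", f, cfg[[f]]))
    }
  }
  stopifnot(similarity_evalue > 0, lineage_evalue > 0, top_k > 0)
  structure(cfg, class = "run_config")
}

#' Convenience: pipeline configuration for a generated scenario directory
#'
#' @param dir directory written by [generate_holobiont()].
#' @param ... overrides passed to [pipeline_config()].
#' @return a `"run_config"`.
#' @export
scenario_config <- function(dir, ...) {
  p <- function(f) file.path(dir, f)
  sid <- if (file.exists(p("manifest.json"))) {
    read_manifest(dir)$scenario_id
  } else NULL
  pipeline_config(hmm = p("hmm_hits.txt"), similarity = p("similarity_hits.tsv"),
                  peptide = p("peptide_hits.tsv"), genes = p("genes.gff3"),
                  pfam = p("pfam_hits.tsv"), lineages = p("lineages.tsv"),
                  samples = p("samples.tsv"), orf_samples = p("orf_samples.tsv"),
                  activities = p("activities.tsv"),
                  contig_taxa = p("contig_taxa.tsv"), scenario_id = sid, ...)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full CAZome pipeline
#'
#' Executes consensus calling, module counting and normalization,
#' lignocellulose classification, LCA taxonomy and community profiling, and
#' both locus screens; writes every result table as TSV into
#' `config$out_dir` together with a JSON run manifest (package version,
#' thresholds, input checksums, and named counters for every filtered
#' record — nothing is dropped silently). Deterministic given inputs and
#' configuration. Any stage failure aborts with a stage-tagged message.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"cazome_bundle"` with elements `calls`, `counts`
#'   (a `FamilyCountMatrix`, normalized), `classified`, `ligno_summary`,
#'   `assignments`, `profile`, `pul`, `cellulosome`, `meta`, `orf_samples`,
#'   `manifest`, `paths`, `scenario_id`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  counters <- list()
  note <- function(name, value) counters[[name]] <<- value

  inputs <- .stage("read", {
    hits <- list(
      hmm = read_domain_hits(config$hmm, "hmm_domtbl", strict = config$strict),
      similarity = read_domain_hits(config$similarity, "similarity_tab",
                                    strict = config$strict),
      peptide = read_domain_hits(config$peptide, "peptide_tab",
                                 strict = config$strict))
    for (t in names(hits)) {
      note(paste0("skipped_", t, "_rows"), attr(hits[[t]], "n_skipped"))
    }
    list(hits = do.call(rbind, hits),
         genes = read_gene_table(config$genes, strict = config$strict),
         pfam = read_pfam_hits(config$pfam),
         lineages = read_lineages(config$lineages, k = config$top_k,
                                  evalue_cutoff = config$lineage_evalue),
         meta = read_sample_meta(config$samples),
         orf_samples = utils::read.delim(config$orf_samples,
                                         stringsAsFactors = FALSE),
         activities = if (!is.null(config$activities)) {
           utils::read.delim(config$activities, stringsAsFactors = FALSE)
         },
         contig_taxa = if (!is.null(config$contig_taxa)) {
           utils::read.delim(config$contig_taxa, stringsAsFactors = FALSE)
         })
  })

  calls <- .stage("consensus", call_consensus(
    inputs$hits, sample_id = inputs$orf_samples,
    similarity_evalue = config$similarity_evalue))
  note("consensus_calls", nrow(calls))
  note("partial_evidence_pairs", nrow(partial_calls(calls)))

  counts <- .stage("quantify", normalize_counts(
    count_families(calls, inputs$meta), inputs$meta,
    groups = config$norm_groups))

  map <- .stage("classify", load_class_map(config$class_map))
  classified <- .stage("classify",
                       classify_calls(calls, inputs$activities, map))
  ligno <- summarize_classes(classified, inputs$meta)

  assignments <- .stage("taxonomy", assign_taxa(inputs$lineages))
  profile <- .stage("taxonomy", profile_community(assignments, calls,
                                                  level = config$profile_rank))

  pul <- .stage("screen_pul", screen_pul(inputs$genes, inputs$pfam,
                                         calls = calls,
                                         markers = config$markers))
  cel <- .stage("screen_cellulosome", screen_cellulosome(
    inputs$genes, inputs$pfam, calls = calls, markers = config$markers,
    meta = inputs$meta, orf_samples = inputs$orf_samples,
    contig_taxa = inputs$contig_taxa))
  note("pul_candidates", nrow(pul$candidates))
  note("pul_orphan_contigs", nrow(pul$orphans))
  note("dockerin_cazyme_fusions", nrow(cel$fusions))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  paths <- c(calls = p("calls.tsv"), partial = p("partial_calls.tsv"),
             raw = p("family_counts_raw.tsv"),
             normalized = p("family_counts_normalized.tsv"),
             classified = p("classified_calls.tsv"),
             profile = p("community_profile.tsv"),
             pul = p("pul_candidates.tsv"), orphans = p("pul_orphans.tsv"),
             cellulosome = p("cellulosome_contigs.tsv"),
             fusions = p("cellulosome_fusions.tsv"))
  .stage("write", {
    write_tsv(as.data.frame(calls), paths[["calls"]])
    write_tsv(partial_calls(calls), paths[["partial"]])
    write_count_matrix(counts, paths[["raw"]], "raw")
    write_count_matrix(counts, paths[["normalized"]], "normalized")
    write_tsv(classified, paths[["classified"]])
    write_tsv(profile, paths[["profile"]])
    write_tsv(pul$candidates, paths[["pul"]])
    write_tsv(pul$orphans, paths[["orphans"]])
    write_tsv(cel$candidates, paths[["cellulosome"]])
    write_tsv(cel$fusions, paths[["fusions"]])
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("cazomer")),
    thresholds = list(similarity_evalue = config$similarity_evalue,
                      lineage_evalue = config$lineage_evalue,
                      top_k = config$top_k,
                      markers = as.list(config$markers)),
    input_md5 = as.list(tools::md5sum(unlist(config[c(
      "hmm", "similarity", "peptide", "genes", "pfam", "lineages",
      "samples", "orf_samples")]))),
    counters = counters
  )
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  structure(list(calls = calls, counts = counts, classified = classified,
                 ligno_summary = ligno, assignments = assignments,
                 profile = profile, pul = pul, cellulosome = cel,
                 meta = inputs$meta, orf_samples = inputs$orf_samples,
                 manifest = manifest,
                 paths = c(paths, manifest = p("run_manifest.json")),
                 scenario_id = config$scenario_id),
            class = "cazome_bundle")
}

#' Headline summary of a pipeline bundle
#'
#' Recomputes, from the bundle tables alone, the numbers a holobiont CAZome
#' report leads with: total modules and their split between metagenomes
#' (microbiota) and transcriptomes (host), the family partition
#' (host-only / microbiota-only / shared / union), per-class family
#' richness, the lignocellulose watchlist totals, the percentage of
#' activity-predicted modules that are lignocellulolytic (one decimal), and
#' optionally the watchlist-richness ratio of a focal host species to the
#' mean of the others (one decimal). Percentages on an empty bundle are
#' reported as `NA`, not 0. Internal values stay unrounded; only the
#' percentage/ratio fields are display-rounded.
#'
#' @param bundle a `"cazome_bundle"` from [run_pipeline()].
#' @param focal_species optional host species for the richness ratio.
#' @return list of class `"cazome_summary"`.
#' @export
summarize_cazome <- function(bundle, focal_species = NULL) {
  m <- bundle$counts$raw
  meta <- bundle$meta
  kind <- meta$dataset_kind[match(colnames(m), meta$sample_id)]
  mod_total <- sum(m)
  mods_by_kind <- vapply(c("metagenome", "transcriptome"), function(k)
    sum(m[, kind == k, drop = FALSE]), numeric(1L))
  fams_in <- function(k) {
    sub <- m[, kind == k, drop = FALSE]
    rownames(sub)[rowSums(sub) > 0]
  }
  part <- partition_families(fams_in("metagenome"), fams_in("transcriptome"))
  class_richness <- table(factor(cazy_class(rownames(m)[rowSums(m) > 0]),
                                 levels = CAZY_CLASSES))
  lig <- bundle$ligno_summary
  wl_class <- table(factor(cazy_class(unique(canonical_family(
    bundle$classified$family[bundle$classified$watchlist %in% TRUE],
    level = "family"))), levels = CAZY_CLASSES))
  ratio <- if (!is.null(focal_species)) {
    ligno_richness_ratio(bundle$classified, meta, focal_species)
  }
  structure(list(
    total_modules = mod_total,
    microbiota_modules = unname(mods_by_kind["metagenome"]),
    host_modules = unname(mods_by_kind["transcriptome"]),
    family_union = part$union_size,
    host_only_families = length(part$host_only),
    microbiota_only_families = length(part$microbiota_only),
    shared_families = length(part$shared),
    class_richness = class_richness,
    watchlist_families = lig$n_watchlist_families,
    watchlist_families_by_class = wl_class,
    watchlist_modules = lig$n_watchlist_modules,
    predicted_modules = lig$n_predicted_modules,
    pct_lignocellulolytic = lig$pct_lignocellulolytic,
    pct_other_substrate = lig$pct_other_substrate,
    richness_ratio = if (is.null(ratio)) NA_real_ else ratio$ratio,
    richness_by_species = if (is.null(ratio)) NULL else ratio$richness,
    pul_candidates = nrow(bundle$pul$candidates),
    pul_orphan_contigs = nrow(bundle$pul$orphans),
    sus_marker_contigs = bundle$pul$n_marker_contigs,
    cellulosome_totals = bundle$cellulosome$totals
  ), class = "cazome_summary")
}

#' @export
print.cazome_summary <- function(x, ...) {
  cat(sprintf("CAZome: %d modules (%d microbiota + %d host) in %d families\n",
              x$total_modules, x$microbiota_modules, x$host_modules,
              x$family_union))
  cat(sprintf("  families: %d host-only, %d microbiota-only, %d shared\n",
              x$host_only_families, x$microbiota_only_families,
              x$shared_families))
  cat(sprintf("  lignocellulose watchlist: %d families, %d modules (%d predicted: %s%% lignocellulolytic, %s%% other)\n",
              x$watchlist_families, x$watchlist_modules, x$predicted_modules,
              format(x$pct_lignocellulolytic), format(x$pct_other_substrate)))
  if (!is.na(x$richness_ratio)) {
    cat(sprintf("  watchlist richness ratio (focal vs mean others): %.1f\n",
                x$richness_ratio))
  }
  cat(sprintf("  PULs: %d sequential susC-susD pair(s), %d orphan contig(s) of %d marker contig(s)\n",
              x$pul_candidates, x$pul_orphan_contigs, x$sus_marker_contigs))
  t <- x$cellulosome_totals
  cat(sprintf("  cellulosomes: %d dockerin / %d cohesin modules, %d SLH contig(s), %d CAZyme-dockerin fusion(s)\n",
              t[["dockerin_modules"]], t[["cohesin_modules"]],
              t[["slh_contigs"]], t[["fusion_genes"]]))
  invisible(x)
}
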