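# Synthetic holobiont datasets with known ground truth.
#
# The generator emulates the statistical structure the pipeline consumes:
# assembled contigs carrying ordered gene models, three independent CAZyme
# evidence streams with a configurable inter-tool agreement rate, Pfam
# marker hits for planted susC-susD pairs / orphan decoys / cellulosome
# components, ranked taxonomy lineages, and per-sample metadata. Everything
# is a pure function of the scenario (same seed, same bytes), and every
# planted truth item is listed in a manifest so each pipeline stage can be
# scored.

default_family_pool <- function() {
  c("GH13", "GH18", "GT2", "GT1", "GH5", "GH9", "GH43", "GH16", "GH3",
    "CE1", "CE10", "AA3", "AA10", "CBM35", "PL9", "GH2", "GH35", "GH26",
    "CBM32", "GH130")
}

default_taxa_pool <- function() {
  c("Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Flavobacterium",
    "Bacteria;Bacteroidetes;Cytophagia;Cytophagales;Cyclobacteriaceae;Algoriphagus",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Rhizobiaceae;Rhizobium",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Vibrionales;Vibrionaceae;Vibrio",
    "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Burkholderiaceae;Polynucleobacter",
    "Bacteria;Actinobacteria;Actinomycetia;Micrococcales;Micrococcaceae;Arthrobacter",
    "Bacteria;Planctomycetes;Planctomycetia;Planctomycetales;Planctomycetaceae;Planctomyces",
    "Bacteria;Armatimonadetes;Armatimonadia;Armatimonadales;Armatimonadaceae;Armatimonas")
}

#' Default synthetic sample metadata
#'
#' Six metagenome samples (two host species, both origins and sexes,
#' digestive and non-digestive tissues) plus two host transcriptomes, with
#' ORF library sizes in the range typical of assembled gut metagenomes.
#' Entirely synthetic; used as the default sample universe of
#' [synthetic_scenario()].
#'
#' @return data.frame accepted by [validate_sample_meta()].
#' @export
default_sample_meta <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:8),
    host_species = c("A_aquaticus", "A_aquaticus", "P_pruinosus",
                     "P_pruinosus", "P_dilatatus", "P_dilatatus",
                     "A_aquaticus", "P_pruinosus"),
    origin = c("laboratory", "field", "laboratory", "field", "laboratory",
               "laboratory", "laboratory", "laboratory"),
    sex = c("male", "female", "female", "female", "male", "female",
            "male", "female"),
    tissue = c("hindgut", "non_digestive", "caeca", "hindgut", "hindgut",
               "caeca", "whole", "whole"),
    dataset_kind = c(rep("metagenome", 6L), rep("transcriptome", 2L)),
    n_orfs = c(310000L, 250000L, 280000L, 205000L, 330000L, 290000L,
               21000L, 24000L),
    stringsAsFactors = FALSE
  )
}

#' Define a synthetic holobiont scenario
#'
#' A scenario fixes every knob of the generator; [generate_holobiont()] is a
#' pure function of it.
#'
#' @param seed integer seed governing all randomness (one RNG stream).
#' @param n_filler_contigs contigs carrying only unannotated genes.
#' @param n_cazyme_orfs "probe" CAZyme ORFs whose true family each tool
#'   reports independently with probability `tool_agreement` — the set on
#'   which consensus recall is measured.
#' @param tool_agreement per-tool probability q of reporting the true
#'   family; expected consensus recall is q^3.
#' @param confusion_rate when a tool misses, probability that it emits a
#'   wrong family instead of staying silent.
#' @param multi_module_rate probability that a reported HMM hit carries a
#'   second domain module of the same family (module_count 2).
#' @param background_rate per plain gene probability of a spurious
#'   single-tool hit.
#' @param planted_puls contigs with one adjacent susC-susD pair plus a
#'   co-localized CAZyme gene.
#' @param decoy_orphans contigs with susC only, susD only, or a
#'   non-adjacent susC/susD pair (cycled), which must be tallied as orphans.
#' @param planted_cellulosomes simple cellulosome systems: each adds one
#'   scaffoldin contig (two cohesin modules), one SLH anchor contig and two
#'   dockerin-gene contigs, one of them a CAZyme-dockerin fusion.
#' @param dockerin_layout optional detailed override: list with
#'   `dockerin_contigs`, `dockerin_modules`, `cohesin_contigs`,
#'   `cohesin_modules`, `slh_contigs`, and optional `fusion_table`
#'   (data.frame with `families`, e.g. `"GH26 + CBM35"`, and optional
#'   `host_species`, `origin`, `sex`, `tissue`, `taxon` columns; fusions are
#'   planted on the first dockerin genes).
#' @param activity_rate probability that a planted CAZyme ORF receives an
#'   activity prediction.
#' @param lineage_k hits written per ORF in the lineage table.
#' @param lineage_noise probability that an ORF's secondary hits disagree at
#'   phylum level (driving its LCA up to the domain).
#' @param family_pool CAZy families sampled for probe ORFs.
#' @param taxa_pool lineage strings sampled for contigs (PUL contigs always
#'   draw Bacteroidetes lineages).
#' @param samples sample metadata data.frame (see [default_sample_meta()]).
#' @return validated list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_filler_contigs = 10L,
                               n_cazyme_orfs = 120L,
                               tool_agreement = 0.8,
                               confusion_rate = 0.05,
                               multi_module_rate = 0.1,
                               background_rate = 0.02,
                               planted_puls = 5L,
                               decoy_orphans = 10L,
                               planted_cellulosomes = 2L,
                               dockerin_layout = NULL,
                               activity_rate = 0.4,
                               lineage_k = 3L,
                               lineage_noise = 0.1,
                               family_pool = default_family_pool(),
                               taxa_pool = default_taxa_pool(),
                               samples = default_sample_meta()) {
  stopifnot(tool_agreement >= 0, tool_agreement <= 1,
            confusion_rate >= 0, confusion_rate <= 1,
            n_filler_contigs >= 0, n_cazyme_orfs >= 0, planted_puls >= 0,
            decoy_orphans >= 0, planted_cellulosomes >= 0,
            length(family_pool) >= 2L, all(is_cazy_label(family_pool)),
            length(taxa_pool) >= 1L)
  validate_sample_meta(samples)
  if (is.null(dockerin_layout)) {
    k <- planted_cellulosomes
    fusion_table <- if (k > 0L) {
      data.frame(families = rep("GH26 + CBM35", k), stringsAsFactors = FALSE)
    } else NULL
    dockerin_layout <- list(dockerin_contigs = 2L * k,
                            dockerin_modules = 2L * k,
                            cohesin_contigs = k, cohesin_modules = 2L * k,
                            slh_contigs = k, fusion_table = fusion_table)
  }
  dl <- dockerin_layout
  stopifnot(dl$dockerin_modules >= dl$dockerin_contigs,
            dl$cohesin_modules >= dl$cohesin_contigs)
  if (!is.null(dl$fusion_table) &&
      nrow(dl$fusion_table) > dl$dockerin_contigs) {
    stop("more planted fusions than dockerin genes (impossible layout)")
  }
  structure(list(seed = as.integer(seed),
                 n_filler_contigs = as.integer(n_filler_contigs),
                 n_cazyme_orfs = as.integer(n_cazyme_orfs),
                 tool_agreement = tool_agreement,
                 confusion_rate = confusion_rate,
                 multi_module_rate = multi_module_rate,
                 background_rate = background_rate,
                 planted_puls = as.integer(planted_puls),
                 decoy_orphans = as.integer(decoy_orphans),
                 dockerin_layout = dl,
                 activity_rate = activity_rate,
                 lineage_k = as.integer(lineage_k),
                 lineage_noise = lineage_noise,
                 family_pool = family_pool,
                 taxa_pool = taxa_pool,
                 samples = samples,
                 scenario_id = sprintf("scn-%d", as.integer(seed))),
            class = "synthetic_scenario")
}

# role -> controlled activity term used when the generator writes activity
# predictions for planted watchlist CAZymes
.role_activity <- c(cellulase_endo = "endoglucanase",
                    cellulase_betaglucosidase = "beta-glucosidase",
                    cellulase_phosphorylase = "cellobiose phosphorylase",
                    cellulase_lpmo = "lytic polysaccharide monooxygenase",
                    hemicellulase = "xylanase",
                    lme_laccase = "laccase",
                    lme_cdh = "cellobiose dehydrogenase")

#' Generate a synthetic holobiont dataset on disk
#'
#' Writes, into `dir`: `genes.gff3`, `hmm_hits.txt` (HMMER domtblout
#' layout), `similarity_hits.tsv` (outfmt-6), `peptide_hits.tsv`,
#' `pfam_hits.tsv`, `lineages.tsv`, `activities.tsv`, `samples.tsv`,
#' `orf_samples.tsv`, `contig_taxa.tsv` and `manifest.json` — exactly the
#' formats the readers in this package consume. Planted fusion and
#' PUL-co-localized CAZyme genes always receive full three-tool evidence
#' (they are locus ground truth, not consensus probes); only the
#' `n_cazyme_orfs` probe ORFs are subject to the `tool_agreement` draw.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the ground-truth manifest (also written as JSON):
#'   `cazymes` (with `probe` flag), `puls`, `orphan_contigs`, `fusions`,
#'   `totals`, `scenario_id`, `paths`.
#' @export
generate_holobiont <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  dl <- sc$dockerin_layout
  n_fus <- if (is.null(dl$fusion_table)) 0L else nrow(dl$fusion_table)
  caz_per_contig <- 4L
  n_caz_contigs <- ceiling(sc$n_cazyme_orfs / caz_per_contig)

  specs <- list()
  add <- function(kind, roles, families = rep(NA_character_, length(roles)),
                  taxon = NA_character_, sample = NA_character_) {
    specs[[length(specs) + 1L]] <<- list(kind = kind, roles = roles,
                                         families = families, taxon = taxon,
                                         sample = sample)
  }

  # PUL contigs: one adjacent susC/susD pair + one co-localized CAZyme gene
  bacteroidetes <- grep(";Bacteroidetes;", sc$taxa_pool, value = TRUE)
  if (!length(bacteroidetes)) bacteroidetes <- sc$taxa_pool
  pul_fams <- c("GH3", "GH16", "GH43")
  for (i in seq_len(sc$planted_puls)) {
    ng <- sample(4:7, 1L)
    p <- sample(seq_len(ng - 1L), 1L)
    roles <- rep("plain", ng)
    cfirst <- stats::runif(1) < 0.5
    roles[p] <- if (cfirst) "susC" else "susD"
    roles[p + 1L] <- if (cfirst) "susD" else "susC"
    fams <- rep(NA_character_, ng)
    free <- setdiff(seq_len(ng), c(p, p + 1L))
    cz <- if (length(free) == 1L) free else sample(free, 1L)
    roles[cz] <- "cazyme_locus"
    fams[cz] <- sample(pul_fams, 1L)
    add("pul", roles, fams, taxon = sample(bacteroidetes, 1L))
  }

  # decoy contigs: orphan susC, orphan susD, or a non-adjacent pair
  decoy_type <- rep(c("susC_only", "susD_only", "split_pair"),
                    length.out = sc$decoy_orphans)
  for (i in seq_len(sc$decoy_orphans)) {
    ng <- sample(4:6, 1L)
    roles <- rep("plain", ng)
    if (decoy_type[i] == "susC_only") {
      roles[sample(ng, 1L)] <- "susC"
    } else if (decoy_type[i] == "susD_only") {
      roles[sample(ng, 1L)] <- "susD"
    } else {
      roles[1L] <- "susC"; roles[ng] <- "susD"  # index gap >= 3
    }
    add("decoy", roles)
  }

  # cellulosome layout: dockerin contigs (first rows of the fusion table are
  # planted on the first dockerin genes), cohesin/scaffoldin contigs,
  # separate SLH anchor contigs
  fus <- dl$fusion_table
  for (i in seq_len(dl$dockerin_contigs)) {
    ng <- sample(3:5, 1L)
    roles <- rep("plain", ng)
    fams <- rep(NA_character_, ng)
    d <- sample(ng, 1L)
    roles[d] <- "dockerin"
    taxon <- NA_character_; smp <- NA_character_
    if (i <= n_fus) {
      roles[d] <- "fusion"
      fams[d] <- fus$families[i]
      if ("taxon" %in% names(fus)) taxon <- fus$taxon[i]
      if (all(c("host_species", "origin", "sex", "tissue") %in% names(fus))) {
        m <- sc$samples
        hit <- which(m$host_species == fus$host_species[i] &
                       m$origin == fus$origin[i] & m$sex == fus$sex[i] &
                       m$tissue == fus$tissue[i])
        if (!length(hit)) {
          stop("fusion_table row ", i, " matches no sample in the metadata")
        }
        smp <- m$sample_id[hit[1L]]
      }
    }
    add("dockerin", roles, fams, taxon = taxon, sample = smp)
  }
  for (i in seq_len(dl$cohesin_contigs)) {
    ng <- sample(2:4, 1L)
    roles <- rep("plain", ng)
    roles[sample(ng, 1L)] <- "cohesin"
    add("cohesin", roles)
  }
  for (i in seq_len(dl$slh_contigs)) {
    ng <- sample(2:3, 1L)
    roles <- rep("plain", ng)
    roles[sample(ng, 1L)] <- "slh"
    add("slh", roles)
  }

  # probe CAZyme contigs and plain filler
  probe_left <- sc$n_cazyme_orfs
  for (i in seq_len(n_caz_contigs)) {
    take <- min(caz_per_contig, probe_left)
    probe_left <- probe_left - take
    ng <- take + sample(1:2, 1L)
    roles <- rep("plain", ng)
    pos <- sample(ng, take)
    roles[pos] <- "cazyme_probe"
    fams <- rep(NA_character_, ng)
    fams[pos] <- sample(sc$family_pool, take, replace = TRUE)
    add("probe", roles, fams)
  }
  for (i in seq_len(sc$n_filler_contigs)) {
    add("filler", rep("plain", sample(2:6, 1L)))
  }

  # ---- flatten to a gene table with coordinates ----
  nct <- length(specs)
  contig_ids <- sprintf("ctg%06d", seq_len(nct))
  kind <- vapply(specs, `[[`, character(1L), "kind")
  ngenes <- vapply(specs, function(s) length(s$roles), integer(1L))
  taxon <- vapply(specs, `[[`, character(1L), "taxon")
  taxon[is.na(taxon)] <- sample(sc$taxa_pool, sum(is.na(taxon)),
                                replace = TRUE)
  smp <- vapply(specs, `[[`, character(1L), "sample")
  meta_samples <- sc$samples$sample_id[sc$samples$dataset_kind == "metagenome"]
  if (!length(meta_samples)) meta_samples <- sc$samples$sample_id
  smp[is.na(smp)] <- sample(meta_samples, sum(is.na(smp)), replace = TRUE)

  g <- data.frame(
    contig_id = rep(contig_ids, ngenes),
    role = unlist(lapply(specs, `[[`, "roles")),
    family = unlist(lapply(specs, `[[`, "families")),
    stringsAsFactors = FALSE
  )
  g$gene_index <- as.integer(unlist(lapply(ngenes, seq_len)))
  g$orf_id <- sprintf("%s_g%02d", g$contig_id, g$gene_index)
  len <- sample(300:2400, nrow(g), replace = TRUE)
  gap <- sample(20:200, nrow(g), replace = TRUE)
  off <- stats::ave(gap + len, g$contig_id, FUN = cumsum)
  g$start <- as.integer(off - len + 1L)
  g$end <- as.integer(off)
  g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
  g$sample_id <- rep(smp, ngenes)
  g$taxon <- rep(taxon, ngenes)

  # ---- three-tool CAZyme evidence ----
  probe <- which(g$role == "cazyme_probe")
  locus <- which(g$role %in% c("cazyme_locus", "fusion"))
  ev <- list()
  add_ev <- function(orf, fam, tool) {
    ev[[length(ev) + 1L]] <<- data.frame(orf_id = orf, family = fam,
                                         tool = tool,
                                         stringsAsFactors = FALSE)
  }
  q <- sc$tool_agreement
  mc <- rep(1L, nrow(g))
  for (tool in c("hmm", "similarity", "peptide")) {
    rep_true <- stats::runif(length(probe)) < q
    if (any(rep_true)) {
      add_ev(g$orf_id[probe][rep_true], g$family[probe][rep_true], tool)
    }
    miss <- probe[!rep_true]
    confused <- miss[stats::runif(length(miss)) < sc$confusion_rate]
    if (length(confused)) {
      wrong <- vapply(g$family[confused], function(f)
        sample(setdiff(sc$family_pool, f), 1L), character(1L))
      add_ev(g$orf_id[confused], wrong, tool)
    }
  }
  # locus CAZymes (fusions may carry several families, "GH26 + CBM35")
  for (i in locus) {
    fams_i <- strsplit(g$family[i], " + ", fixed = TRUE)[[1L]]
    for (tool in c("hmm", "similarity", "peptide")) {
      add_ev(rep(g$orf_id[i], length(fams_i)), fams_i, tool)
    }
  }
  # spurious single-tool background on plain genes
  plain <- which(g$role == "plain")
  spur <- plain[stats::runif(length(plain)) < sc$background_rate]
  if (length(spur)) {
    add_ev(g$orf_id[spur], sample(sc$family_pool, length(spur), TRUE),
           sample(c("hmm", "similarity", "peptide"), length(spur), TRUE))
  }
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(orf_id = character(), family = character(),
               tool = character(), stringsAsFactors = FALSE)

  # second HMM module for a fraction of reported probe hits
  hmm_rows <- ev[ev$tool == "hmm", , drop = FALSE]
  fam_true <- g$family[match(hmm_rows$orf_id, g$orf_id)]
  is_probe_hit <- hmm_rows$orf_id %in% g$orf_id[probe] &
    !is.na(fam_true) & hmm_rows$family == fam_true
  dup <- is_probe_hit & stats::runif(nrow(hmm_rows)) < sc$multi_module_rate
  if (any(dup)) {
    mc[match(hmm_rows$orf_id[dup], g$orf_id)] <- 2L
    hmm_rows <- rbind(hmm_rows, hmm_rows[dup, , drop = FALSE])
  }

  # ---- write evidence files ----
  n_h <- nrow(hmm_rows)
  write_domtbl(data.frame(
    label = hmm_rows$family, orf_id = hmm_rows$orf_id,
    tlen = sample(100:400, n_h, TRUE), qlen = sample(200:800, n_h, TRUE),
    evalue = 10^-stats::runif(n_h, 20, 80),
    score = round(stats::runif(n_h, 50, 300), 1L),
    dom_i = rep(1L, n_h), dom_n = rep(1L, n_h),
    start = sample(1:50, n_h, TRUE), end = sample(100:300, n_h, TRUE),
    stringsAsFactors = FALSE
  ), file.path(dir, "hmm_hits.txt"))

  sim <- ev[ev$tool == "similarity", , drop = FALSE]
  n_s <- nrow(sim)
  write_outfmt6(data.frame(
    orf_id = sim$orf_id, subject = sprintf("ref%05d", seq_len(n_s)),
    label = sim$family, pident = round(stats::runif(n_s, 60, 99), 1L),
    length = sample(100:500, n_s, TRUE), start = rep(1L, n_s),
    end = sample(100:500, n_s, TRUE),
    evalue = 10^-stats::runif(n_s, 55, 120),
    score = round(stats::runif(n_s, 200, 900), 1L),
    stringsAsFactors = FALSE
  ), file.path(dir, "similarity_hits.tsv"))

  pep <- ev[ev$tool == "peptide", , drop = FALSE]
  write_peptide_tab(data.frame(
    orf_id = pep$orf_id, label = pep$family,
    score = round(stats::runif(nrow(pep), 10, 60), 1L),
    stringsAsFactors = FALSE
  ), file.path(dir, "peptide_hits.tsv"))

  # ---- Pfam marker hits ----
  mk <- default_markers()
  role_acc <- c(susC = mk[["susC"]], susD = mk[["susD"]],
                dockerin = mk[["dockerin"]], fusion = mk[["dockerin"]],
                cohesin = mk[["cohesin"]], slh = mk[["slh"]])
  pf_idx <- which(g$role %in% names(role_acc))
  pf <- data.frame(orf_id = g$orf_id[pf_idx],
                   accession = unname(role_acc[g$role[pf_idx]]),
                   stringsAsFactors = FALSE)
  # distribute extra modules (several repeats on one gene) for dockerin and
  # cohesin so module totals can exceed gene counts
  extra_rows <- function(kind, total) {
    genes_k <- g$orf_id[g$role %in% kind]
    nk <- length(genes_k)
    if (!nk || total <= nk) return(NULL)
    per <- total %/% nk + (seq_len(nk) <= total %% nk)
    data.frame(orf_id = rep(genes_k, per - 1L),
               accession = role_acc[[kind[1L]]], stringsAsFactors = FALSE)
  }
  pf <- rbind(pf, extra_rows(c("dockerin", "fusion"), dl$dockerin_modules),
              extra_rows("cohesin", dl$cohesin_modules))
  pf$evalue <- 10^-stats::runif(nrow(pf), 6, 40)
  write_tsv(pf[order(pf$orf_id, pf$accession), ],
            file.path(dir, "pfam_hits.tsv"))

  # ---- lineages for annotated ORFs ----
  ann <- unique(c(g$orf_id[probe], g$orf_id[locus], g$orf_id[pf_idx]))
  true_lin <- g$taxon[match(ann, g$orf_id)]
  k <- sc$lineage_k
  n_ann <- length(ann)
  noisy <- stats::runif(n_ann) < sc$lineage_noise & k > 1L
  lin_rows <- data.frame(
    orf_id = rep(ann, each = k),
    hit_rank = rep(seq_len(k), n_ann),
    evalue = 10^-stats::runif(n_ann * k, 5, 60),
    lineage = rep(true_lin, each = k),
    stringsAsFactors = FALSE
  )
  if (any(noisy)) {
    alt <- vapply(true_lin[noisy], function(tl)
      sample(setdiff(sc$taxa_pool, tl), 1L), character(1L))
    lin_rows$lineage[rep(noisy, each = k) & lin_rows$hit_rank == k] <- alt
  }
  if (n_ann) {
    lin_rows <- lin_rows[order(lin_rows$orf_id, lin_rows$evalue), ]
    lin_rows$hit_rank <- as.integer(
      stats::ave(lin_rows$evalue, lin_rows$orf_id, FUN = seq_along))
  }
  write_tsv(lin_rows, file.path(dir, "lineages.tsv"))

  # ---- activity predictions ----
  map <- load_class_map()
  act_idx <- c(probe, locus)
  act_idx <- act_idx[stats::runif(length(act_idx)) < sc$activity_rate]
  fam_first <- sub(" \\+.*$", "", g$family[act_idx])
  role1 <- sub(",.*$", "",
               map$roles[match(canonical_family(fam_first, level = "family"),
                               map$family)])
  act <- unname(.role_activity[role1])
  act[is.na(act)] <- "chitinase"
  act_rows <- data.frame(orf_id = g$orf_id[act_idx], family = fam_first,
                         activity = act, stringsAsFactors = FALSE)
  write_tsv(act_rows, file.path(dir, "activities.tsv"))

  # ---- gene models, metadata, mappings ----
  write_gene_table(g[, c("contig_id", "start", "end", "strand", "orf_id")],
                   file.path(dir, "genes.gff3"))
  write_tsv(sc$samples, file.path(dir, "samples.tsv"))
  write_tsv(g[, c("orf_id", "sample_id")], file.path(dir, "orf_samples.tsv"))
  ct <- data.frame(contig_id = contig_ids, taxon = taxon,
                   stringsAsFactors = FALSE)
  write_tsv(ct, file.path(dir, "contig_taxa.tsv"))

  # ---- ground-truth manifest ----
  tidx <- c(probe, locus)
  fam_list <- strsplit(g$family[tidx], " + ", fixed = TRUE)
  nfam <- lengths(fam_list)
  caz_truth <- data.frame(
    orf_id = rep(g$orf_id[tidx], nfam),
    family = canonical_family(unlist(fam_list), level = "family"),
    module_count = rep(mc[tidx], nfam),
    sample_id = rep(g$sample_id[tidx], nfam),
    probe = rep(g$role[tidx] == "cazyme_probe", nfam),
    stringsAsFactors = FALSE
  )
  pul_truth <- do.call(rbind, lapply(which(kind == "pul"), function(ci) {
    gc <- g[g$contig_id == contig_ids[ci], , drop = FALSE]
    data.frame(contig_id = contig_ids[ci],
               susC_orf = gc$orf_id[gc$role == "susC"],
               susD_orf = gc$orf_id[gc$role == "susD"],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pul_truth)) {
    pul_truth <- data.frame(contig_id = character(), susC_orf = character(),
                            susD_orf = character())
  }
  fus_truth <- do.call(rbind, lapply(which(g$role == "fusion"), function(i) {
    data.frame(orf_id = g$orf_id[i], contig_id = g$contig_id[i],
               families = g$family[i], stringsAsFactors = FALSE)
  }))
  if (is.null(fus_truth)) {
    fus_truth <- data.frame(orf_id = character(), contig_id = character(),
                            families = character())
  }
  manifest <- list(
    scenario_id = sc$scenario_id,
    seed = sc$seed,
    cazymes = caz_truth,
    puls = pul_truth,
    orphan_contigs = contig_ids[kind == "decoy"],
    fusions = fus_truth,
    totals = list(
      dockerin_modules = dl$dockerin_modules,
      cohesin_modules = dl$cohesin_modules,
      dockerin_cohesin_contigs = dl$dockerin_contigs + dl$cohesin_contigs,
      slh_contigs = dl$slh_contigs,
      sus_marker_contigs = sc$planted_puls + sc$decoy_orphans,
      pul_pairs = sc$planted_puls
    ),
    paths = list(dir = dir)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a ground-truth manifest back from disk
#'
#' @param dir directory written by [generate_holobiont()].
#' @return the manifest list.
#' @export
read_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  for (f in c("cazymes", "puls", "fusions")) {
    m[[f]] <- as.data.frame(m[[f]], stringsAsFactors = FALSE)
  }
  m$orphan_contigs <- as.character(m$orphan_contigs)
  m
}

.pr <- function(truth, detected) {
  tp <- length(intersect(truth, detected))
  list(precision = if (length(detected)) tp / length(detected) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       exact = setequal(truth, detected))
}

#' Score pipeline outputs against a ground-truth manifest
#'
#' Computes per-stage precision and recall plus exact-match booleans:
#' consensus calls against planted (ORF, family) truths (with a separate
#' recall over the probe subset, the one governed by the tool-agreement
#' rate), PUL candidates against planted pairs, orphan tallies against decoy
#' contigs, and dockerin-CAZyme fusions against planted fusions. A detector
#' that returns nothing has recall 0 and undefined (NA) precision.
#'
#' @param results list with any of `calls` (consensus calls), `pul`
#'   (a `pul_screen`), `cellulosome` (a `cellulosome_screen`); the bundle
#'   returned by [run_pipeline()] works directly.
#' @param manifest manifest from [generate_holobiont()] / [read_manifest()].
#' @return nested list of class `"truth_score"` with elements `consensus`,
#'   `pul`, `orphans`, `fusions`.
#' @export
score_against_truth <- function(results, manifest) {
  if (!is.null(results$scenario_id) && !is.null(manifest$scenario_id) &&
      !identical(results$scenario_id, manifest$scenario_id)) {
    stop("results and manifest come from different scenarios: ",
         results$scenario_id, " vs ", manifest$scenario_id)
  }
  out <- list()
  if (!is.null(results$calls)) {
    truth_all <- paste(manifest$cazymes$orf_id, manifest$cazymes$family)
    det <- paste(results$calls$orf_id,
                 canonical_family(results$calls$family, level = "family"))
    out$consensus <- .pr(truth_all, det)
    pr <- manifest$cazymes$probe
    probe_truth <- truth_all[pr]
    out$consensus$probe_recall <- if (length(probe_truth)) {
      length(intersect(probe_truth, det)) / length(probe_truth)
    } else NA_real_
  }
  if (!is.null(results$pul)) {
    truth <- paste(manifest$puls$contig_id, manifest$puls$susC_orf,
                   manifest$puls$susD_orf)
    det <- paste(results$pul$candidates$contig_id,
                 results$pul$candidates$susC_orf,
                 results$pul$candidates$susD_orf)
    out$pul <- .pr(truth, det)
    out$orphans <- .pr(manifest$orphan_contigs, results$pul$orphans$contig_id)
  }
  if (!is.null(results$cellulosome)) {
    truth <- paste(manifest$fusions$orf_id, manifest$fusions$families)
    det <- paste(results$cellulosome$fusions$orf_id,
                 results$cellulosome$fusions$families)
    out$fusions <- .pr(truth, det)
  }
  structure(out, class = "truth_score")
}

#' @export
print.truth_score <- function(x, ...) {
  for (st in names(x)) {
    cat(sprintf("%-10s precision %.3f recall %.3f exact %s\n", st,
                x[[st]]$precision, x[[st]]$recall, x[[st]]$exact))
  }
  invisible(x)
}
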