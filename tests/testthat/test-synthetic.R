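# Synthetic-data generator: limit cases, determinism, manifest consistency.

read_evidence <- function(d) {
  rbind(read_domain_hits(file.path(d, "hmm_hits.txt"), "hmm_domtbl"),
        read_domain_hits(file.path(d, "similarity_hits.tsv"), "similarity_tab"),
        read_domain_hits(file.path(d, "peptide_hits.tsv"), "peptide_tab"))
}

test_that("full tool agreement recovers every planted CAZyme; zero agreement recovers none", {
  # no planted loci so all truths are consensus probes
  base <- list(seed = 11, planted_puls = 0L, decoy_orphans = 0L,
               planted_cellulosomes = 0L, n_cazyme_orfs = 60L,
               background_rate = 0)
  d1 <- file.path(tempdir(), "scn-q1")
  man1 <- generate_holobiont(do.call(synthetic_scenario,
                                     c(base, tool_agreement = 1)), d1)
  calls1 <- call_consensus(read_evidence(d1))
  s1 <- score_against_truth(list(calls = calls1), man1)
  expect_equal(s1$consensus$recall, 1)
  expect_equal(s1$consensus$precision, 1)

  d0 <- file.path(tempdir(), "scn-q0")
  generate_holobiont(do.call(synthetic_scenario,
                             c(base, tool_agreement = 0, confusion_rate = 0)),
                     d0)
  expect_equal(nrow(call_consensus(read_evidence(d0))), 0L)
})

test_that("generation is byte-identical for a fixed seed", {
  sc <- synthetic_scenario(seed = 77, n_cazyme_orfs = 25, planted_puls = 2,
                           decoy_orphans = 3, planted_cellulosomes = 1)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_holobiont(sc, d1)
  generate_holobiont(sc, d2)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  m1 <- read_manifest(d1); m2 <- read_manifest(d2)
  m1$paths <- m2$paths <- NULL
  expect_equal(m1, m2)
})

test_that("the manifest is re-derivable from the generated files by an independent scan", {
  sc <- synthetic_scenario(seed = 13, planted_puls = 4, decoy_orphans = 7,
                           planted_cellulosomes = 2, n_cazyme_orfs = 20)
  d <- file.path(tempdir(), "scn-manifest")
  man <- generate_holobiont(sc, d)
  mk <- default_markers()

  # independent scan: raw file reads, no screen functions
  pf <- utils::read.delim(file.path(d, "pfam_hits.tsv"))
  gff <- utils::read.delim(file.path(d, "genes.gff3"), header = FALSE,
                           comment.char = "#")
  ids <- sub(".*ID=([^;]+).*", "\\1", gff$V9)
  ord <- order(gff$V1, gff$V4)
  by_contig <- split(ids[ord], gff$V1[ord])
  has <- function(orfs, acc) orfs %in% pf$orf_id[pf$accession == acc]
  pair_contigs <- names(Filter(function(orfs) {
    c_pos <- which(has(orfs, mk[["susC"]])); d_pos <- which(has(orfs, mk[["susD"]]))
    length(c_pos) && length(d_pos) &&
      any(abs(outer(c_pos, d_pos, `-`)) == 1L)
  }, by_contig))
  expect_setequal(pair_contigs, man$puls$contig_id)

  orphan_contigs <- names(Filter(function(orfs) {
    c_pos <- which(has(orfs, mk[["susC"]])); d_pos <- which(has(orfs, mk[["susD"]]))
    (length(c_pos) || length(d_pos)) &&
      !(length(c_pos) && length(d_pos) &&
          any(abs(outer(c_pos, d_pos, `-`)) == 1L))
  }, by_contig))
  expect_setequal(orphan_contigs, man$orphan_contigs)

  # dockerin/cohesin module totals match the Pfam file
  expect_equal(sum(pf$accession == mk[["dockerin"]]),
               man$totals$dockerin_modules)
  expect_equal(sum(pf$accession == mk[["cohesin"]]),
               man$totals$cohesin_modules)
})

test_that("scoring definitions: perfect detector, empty detector, one spurious among five", {
  man <- list(scenario_id = "scn-x",
              cazymes = data.frame(orf_id = paste0("o", 1:4),
                                   family = "GH5", probe = TRUE),
              puls = data.frame(contig_id = paste0("c", 1:5),
                                susC_orf = paste0("c", 1:5, "_gC"),
                                susD_orf = paste0("c", 1:5, "_gD")),
              orphan_contigs = character(),
              fusions = data.frame(orf_id = character(),
                                   contig_id = character(),
                                   families = character()))
  perfect <- list(calls = data.frame(orf_id = paste0("o", 1:4), family = "GH5"),
                  pul = list(candidates = man$puls,
                             orphans = data.frame(contig_id = character())))
  s <- score_against_truth(perfect, man)
  expect_equal(s$consensus$precision, 1)
  expect_equal(s$consensus$recall, 1)
  expect_true(s$pul$exact)

  nothing <- list(calls = data.frame(orf_id = character(),
                                     family = character()))
  s0 <- score_against_truth(nothing, man)
  expect_equal(s0$consensus$recall, 0)
  expect_true(is.na(s0$consensus$precision))

  spurious <- list(pul = list(
    candidates = rbind(man$puls,
                       data.frame(contig_id = "c9", susC_orf = "c9_gC",
                                  susD_orf = "c9_gD")),
    orphans = data.frame(contig_id = character())))
  s6 <- score_against_truth(spurious, man)
  expect_equal(s6$pul$precision, 5 / 6)
  expect_equal(s6$pul$recall, 1)
  expect_false(s6$pul$exact)
})

test_that("mismatched scenario ids are fatal", {
  man <- list(scenario_id = "scn-1", cazymes = data.frame(
    orf_id = "o1", family = "GH5", probe = TRUE))
  res <- list(scenario_id = "scn-2",
              calls = data.frame(orf_id = "o1", family = "GH5"))
  expect_error(score_against_truth(res, man), "different scenarios")
})

test_that("impossible layouts are rejected at scenario build time", {
  expect_error(synthetic_scenario(dockerin_layout = list(
    dockerin_contigs = 1L, dockerin_modules = 1L, cohesin_contigs = 0L,
    cohesin_modules = 0L, slh_contigs = 0L,
    fusion_table = data.frame(families = c("GH5", "GH9")))),
    "impossible layout")
  expect_error(synthetic_scenario(tool_agreement = 1.2))
})
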