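# PUL and cellulosome screens on gene-ordered contigs.

mk <- default_markers()

# contig [unk, susC, susD, GH43-cazyme]
pul_contig <- function(ct = "c1") {
  rbind(gene_row(ct, 100, 400, "+", paste0(ct, "_g1")),
        gene_row(ct, 500, 1400, "+", paste0(ct, "_g2")),
        gene_row(ct, 1500, 3000, "+", paste0(ct, "_g3")),
        gene_row(ct, 3100, 4000, "-", paste0(ct, "_g4")))
}

test_that("an adjacent susC-susD pair with a CAZyme on the contig is one candidate", {
  genes <- pul_contig()
  pf <- rbind(pfam_row("c1_g2", mk[["susC"]]), pfam_row("c1_g3", mk[["susD"]]))
  calls <- calls_df("c1_g4", "GH43")
  r <- screen_pul(genes, pf, calls)
  expect_equal(nrow(r$candidates), 1L)
  expect_equal(r$candidates$susC_orf, "c1_g2")
  expect_equal(r$candidates$susD_orf, "c1_g3")
  expect_equal(r$candidates$cazyme_families, "GH43")
  expect_equal(nrow(r$orphans), 0L)
  expect_equal(r$n_marker_contigs, 1L)
  expect_equal(render_pul_map(r$candidates[1, ], genes, calls),
               "unk - susC - susD - GH43")
})

test_that("orphan markers and non-adjacent pairs are tallied, not called", {
  genes <- rbind(pul_contig("c1"), pul_contig("c2"))
  pf <- rbind(pfam_row("c1_g2", mk[["susC"]]),                  # susC only
              pfam_row("c2_g1", mk[["susD"]]),                  # separated by 2
              pfam_row("c2_g4", mk[["susC"]]))
  r <- screen_pul(genes, pf)
  expect_equal(nrow(r$candidates), 0L)
  expect_equal(nrow(r$orphans), 2L)
  expect_equal(r$orphans$n_susC[r$orphans$contig_id == "c1"], 1L)
  expect_equal(r$n_marker_contigs, 2L)
})

test_that("either pair order is accepted by default; strict mode wants susC-then-susD on one strand", {
  genes <- pul_contig()
  pf_rev <- rbind(pfam_row("c1_g2", mk[["susD"]]),
                  pfam_row("c1_g3", mk[["susC"]]))
  expect_equal(nrow(screen_pul(genes, pf_rev)$candidates), 1L)
  expect_equal(nrow(screen_pul(genes, pf_rev, strict = TRUE)$candidates), 0L)

  pf_fwd <- rbind(pfam_row("c1_g2", mk[["susC"]]),
                  pfam_row("c1_g3", mk[["susD"]]))
  expect_equal(nrow(screen_pul(genes, pf_fwd, strict = TRUE)$candidates), 1L)
})

test_that("screen_pul is invariant to shuffling of the gene rows", {
  genes <- rbind(pul_contig("c1"), pul_contig("c2"))
  pf <- rbind(pfam_row("c1_g2", mk[["susC"]]), pfam_row("c1_g3", mk[["susD"]]),
              pfam_row("c2_g3", mk[["susD"]]))
  set.seed(8)
  r1 <- screen_pul(genes, pf)
  r2 <- screen_pul(genes[sample(nrow(genes)), ], pf)
  expect_equal(r1$candidates, r2$candidates)
  expect_equal(r1$orphans, r2$orphans)
})

test_that("a bp window restricts co-localized CAZymes; the default is the whole contig", {
  genes <- pul_contig()
  pf <- rbind(pfam_row("c1_g2", mk[["susC"]]), pfam_row("c1_g3", mk[["susD"]]))
  calls <- calls_df("c1_g1", "GH3")   # 100..400, pair spans 500..3000
  whole <- screen_pul(genes, pf, calls)
  expect_equal(whole$candidates$cazyme_families, "GH3")
  narrow <- screen_pul(genes, pf, calls, window = 50)
  expect_equal(narrow$candidates$n_cazymes, 0L)
})

test_that("dockerin + CAZy families on one gene is emitted as a fusion", {
  genes <- rbind(gene_row("k1", 100, 1200, "+", "k1_g1"),
                 gene_row("k1", 1300, 2500, "+", "k1_g2"))
  pf <- pfam_row("k1_g2", mk[["dockerin"]])
  calls <- rbind(calls_df("k1_g2", "GH26"), calls_df("k1_g2", "CBM35"))
  r <- screen_cellulosome(genes, pf, calls)
  expect_equal(nrow(r$fusions), 1L)
  expect_equal(r$fusions$families, "GH26 + CBM35")  # CAZy class order
  expect_equal(unname(r$totals["fusion_genes"]), 1L)
})

test_that("SLH-only contigs are candidates with empty dockerin/cohesin lists and no fusion", {
  genes <- gene_row("k2", 100, 900, "+", "k2_g1")
  pf <- pfam_row("k2_g1", mk[["slh"]])
  r <- screen_cellulosome(genes, pf, calls_df("other", "GH5"))
  expect_equal(nrow(r$candidates), 1L)
  expect_equal(r$candidates$n_slh, 1L)
  expect_equal(r$candidates$n_dockerin + r$candidates$n_cohesin, 0L)
  expect_equal(nrow(r$fusions), 0L)
  expect_equal(unname(r$totals["slh_contigs"]), 1L)
})

test_that("no marker domains anywhere yields an empty screen", {
  genes <- gene_row("k3", 100, 900, "+", "k3_g1")
  pf <- pfam_row("k3_g1", "PF12345")
  r <- screen_cellulosome(genes, pf)
  expect_equal(nrow(r$candidates), 0L)
  expect_equal(sum(r$totals), 0L)
})

test_that("module totals count domain hits, not genes", {
  genes <- gene_row("k4", 100, 2000, "+", "k4_g1")
  pf <- rbind(pfam_row("k4_g1", mk[["dockerin"]], 1e-12),
              pfam_row("k4_g1", mk[["dockerin"]], 1e-9))
  r <- screen_cellulosome(genes, pf)
  expect_equal(unname(r$totals["dockerin_modules"]), 2L)
  expect_equal(unname(r$totals["dockerin_cohesin_contigs"]), 1L)
})

test_that("fusion count matches a brute-force recount on a generated scenario", {
  sc <- synthetic_scenario(seed = 31, tool_agreement = 1, confusion_rate = 0,
                           planted_cellulosomes = 3, planted_puls = 2,
                           decoy_orphans = 4, n_cazyme_orfs = 30)
  d <- file.path(tempdir(), "scn-fusion")
  generate_holobiont(sc, d)
  genes <- read_gene_table(file.path(d, "genes.gff3"))
  pf <- read_pfam_hits(file.path(d, "pfam_hits.tsv"))
  hits <- rbind(read_domain_hits(file.path(d, "hmm_hits.txt"), "hmm_domtbl"),
                read_domain_hits(file.path(d, "similarity_hits.tsv"),
                                 "similarity_tab"),
                read_domain_hits(file.path(d, "peptide_hits.tsv"),
                                 "peptide_tab"))
  calls <- call_consensus(hits)
  r <- screen_cellulosome(genes, pf, calls)
  # brute force: genes carrying the dockerin accession AND >= 1 called family
  dock <- unique(pf$orf_id[pf$accession == default_markers()[["dockerin"]]])
  expect_equal(sort(r$fusions$orf_id),
               sort(intersect(dock, unique(calls$orf_id))))
})
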