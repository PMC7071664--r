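# Evidence readers: dialect parsing, canonicalization, lenient/strict modes.

domtbl_line <- function(target = "GH13.hmm", query = "orf_001",
                        ievalue = "1e-60") {
  paste(target, "-", "300", query, "-", "500", "1e-55", "55.0", "0.0",
        "1", "1", "1e-58", ievalue, "55.0", "0.0", "1", "300", "5", "200",
        "5", "200", "0.90", "some target description")
}

test_that("HMM domtblout rows are parsed and labels canonicalized", {
  p <- tempfile()
  writeLines(c("# comment line", domtbl_line()), p)
  h <- read_domain_hits(p, "hmm_domtbl")
  expect_equal(nrow(h), 1L)
  expect_equal(h$orf_id, "orf_001")
  expect_equal(h$label, "GH13")   # trailing .hmm stripped
  expect_equal(h$evalue, 1e-60)   # i-Evalue column, not full-sequence
  expect_equal(h$tool, "hmm")
  expect_equal(h$start, 5L)
  expect_equal(h$end, 200L)
})

test_that("subfamily suffixes survive canonicalization; aggregation collapses them", {
  p <- tempfile()
  writeLines(domtbl_line(target = "GH5_13.hmm"), p)
  h <- read_domain_hits(p, "hmm_domtbl")
  expect_equal(h$label, "GH5_13")
  expect_equal(canonical_family(h$label, level = "family"), "GH5")
})

test_that("empty evidence files yield empty tables", {
  p <- tempfile()
  writeLines(character(), p)
  for (d in c("hmm_domtbl", "similarity_tab", "peptide_tab")) {
    h <- read_domain_hits(p, d)
    expect_equal(nrow(h), 0L)
    expect_equal(attr(h, "n_skipped"), 0L)
  }
})

test_that("rows with invalid family labels are skipped with line numbers (lenient) or fatal (strict)", {
  p <- tempfile()
  writeLines(c(domtbl_line(), domtbl_line(target = "XY99.hmm")), p)
  expect_warning(h <- read_domain_hits(p, "hmm_domtbl"), "line.* 2")
  expect_equal(nrow(h), 1L)
  expect_equal(attr(h, "n_skipped"), 1L)
  expect_equal(nrow(h) + attr(h, "n_skipped"), 2L)  # accepted + skipped = total
  expect_error(read_domain_hits(p, "hmm_domtbl", strict = TRUE), "line")
})

test_that("similarity dialect takes the family after the last pipe of the subject id", {
  p <- tempfile()
  writeLines(c("orf_9\tAAA123|x|GH43\t97.0\t120\t0\t0\t1\t120\t1\t120\t1e-70\t350",
               "orf_9\tAAA124|CBM35\t90.0\t80\t0\t0\t1\t80\t1\t80\t2e-60\t200"), p)
  h <- read_domain_hits(p, "similarity_tab")
  expect_equal(h$label, c("GH43", "CBM35"))
  expect_equal(h$evalue, c(1e-70, 2e-60))
  expect_equal(h$start, c(1L, 1L))
})

test_that("peptide dialect reads header + rows, keeping scores with NA evalue", {
  p <- tempfile()
  writeLines(c("orf_id\tfamily\tscore", "orf_1\tGH13\t31.5"), p)
  h <- read_domain_hits(p, "peptide_tab")
  expect_equal(h$score, 31.5)
  expect_true(is.na(h$evalue))
})

test_that("gene tables get per-contig gene_index by ascending start", {
  p <- tempfile()
  write_gff_text(c(gff_line("c1", 500, 900, "-", "gB"),
                   gff_line("c1", 100, 400, "+", "gA"),
                   gff_line("c2", 50, 300, "+", "gC")), p)
  g <- read_gene_table(p)
  c1 <- g[g$contig_id == "c1", ]
  expect_equal(c1$orf_id[order(c1$gene_index)], c("gA", "gB"))
  expect_equal(c1$gene_index[order(c1$start)], 1:2)
  expect_equal(g$gene_index[g$contig_id == "c2"], 1L)  # indices restart per contig
  expect_false(any(g$overlaps))
})

test_that("invalid coordinates are skipped leniently, fatal in strict mode; duplicates warn", {
  p <- tempfile()
  write_gff_text(c(gff_line("c1", 100, 400, id = "g1"),
                   gff_line("c1", 900, 500, id = "gbad")), p)
  expect_warning(g <- read_gene_table(p), "invalid gene record")
  expect_equal(g$orf_id, "g1")
  expect_error(read_gene_table(p, strict = TRUE), "invalid gene record")

  p2 <- tempfile()
  write_gff_text(c(gff_line("c1", 100, 400, id = "g1"),
                   gff_line("c1", 500, 800, id = "g1")), p2)
  expect_warning(g2 <- read_gene_table(p2), "duplicate orf_id")
  expect_equal(nrow(g2), 2L)  # both kept
})

test_that("overlapping genes are kept and flagged", {
  p <- tempfile()
  write_gff_text(c(gff_line("c1", 100, 600, id = "g1"),
                   gff_line("c1", 550, 900, id = "g2")), p)
  g <- read_gene_table(p)
  expect_equal(g$overlaps, c(FALSE, TRUE))
})

test_that("gene tables round-trip through write_gene_table", {
  p <- tempfile()
  write_gff_text(c(gff_line("c1", 100, 400, "+", "gA"),
                   gff_line("c1", 500, 900, "-", "gB"),
                   gff_line("c2", 50, 300, "+", "gC")), p)
  g1 <- read_gene_table(p)
  p2 <- tempfile(fileext = ".gff3")
  write_gene_table(g1, p2)
  g2 <- read_gene_table(p2)
  cols <- c("contig_id", "gene_index", "start", "end", "strand", "orf_id")
  expect_equal(g1[cols], g2[cols])
})

test_that("lineage reader keeps top-k best hits and applies the e-value cutoff", {
  d <- data.frame(orf_id = "o1", hit_rank = 1:7,
                  evalue = c(1e-50, 1e-40, 1e-30, 1e-20, 1e-10, 1e-8, 1e-6),
                  lineage = paste0("Bacteria;Phylum", 1:7))
  p <- write_tsv_tmp(d, "lin.tsv")
  l <- read_lineages(p)                      # default k = 5
  expect_equal(nrow(l), 5L)
  expect_equal(l$hit_rank, 1:5)
  expect_equal(l$evalue, sort(l$evalue))     # best first

  d2 <- data.frame(orf_id = c("o1", "o1"), hit_rank = 1:2,
                   evalue = c(1e-3, 1e-6),
                   lineage = c("Bacteria;A", "Bacteria;B"))
  l2 <- read_lineages(write_tsv_tmp(d2), evalue_cutoff = 1e-4)
  expect_equal(nrow(l2), 1L)                 # 1e-3 dropped by cutoff
  expect_equal(l2$lineage, "Bacteria;B")

  d3 <- data.frame(orf_id = "o2", hit_rank = 1L, evalue = 1e-9,
                   lineage = "Bacteria;Proteobacteria")
  expect_equal(nrow(read_lineages(write_tsv_tmp(d3))), 1L)
})

test_that("empty lineage strings are dropped with a warning", {
  d <- data.frame(orf_id = c("o1", "o2"), hit_rank = 1L,
                  evalue = 1e-9, lineage = c("", "Bacteria;X"))
  expect_warning(l <- read_lineages(write_tsv_tmp(d)), "empty lineage")
  expect_equal(l$orf_id, "o2")
})

test_that("Pfam reader validates accessions and applies the cutoff", {
  d <- rbind(pfam_row("o1", "PF00593"), pfam_row("o2", "NOTPF"),
             pfam_row("o3", "PF07980", evalue = 1e-2))
  p <- write_tsv_tmp(d)
  expect_warning(h <- read_pfam_hits(p), "invalid Pfam")
  expect_equal(h$orf_id, "o1")   # bad accession skipped, weak hit filtered
})
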