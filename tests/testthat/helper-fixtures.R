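# Small in-code fixture builders shared across the suite.

hit_row <- function(orf, tool, label, evalue = 1e-60, score = 50,
                    start = NA_integer_, end = NA_integer_) {
  data.frame(orf_id = orf, tool = tool, label = label, evalue = evalue,
             score = score, start = start, end = end,
             stringsAsFactors = FALSE)
}

# full three-tool evidence for one (orf, family)
three_tool <- function(orf, label, sim_evalue = 1e-80) {
  rbind(hit_row(orf, "hmm", label),
        hit_row(orf, "similarity", label, evalue = sim_evalue),
        hit_row(orf, "peptide", label, evalue = NA_real_))
}

gene_row <- function(contig, start, end, strand = "+", orf = NULL) {
  data.frame(contig_id = contig, start = start, end = end, strand = strand,
             orf_id = if (is.null(orf)) sprintf("%s_%d", contig, start) else orf,
             stringsAsFactors = FALSE)
}

# write a GFF3 file from raw fields (allows malformed records)
write_gff_text <- function(rows, path) {
  writeLines(c("##gff-version 3", rows), path)
}

gff_line <- function(contig, start, end, strand = "+", id = "g1") {
  sprintf("%s\tsrc\tgene\t%s\t%s\t.\t%s\t.\tID=%s", contig, start, end,
          strand, id)
}

pfam_row <- function(orf, acc, evalue = 1e-10) {
  data.frame(orf_id = orf, accession = acc, evalue = evalue,
             stringsAsFactors = FALSE)
}

mini_meta <- function(ids = c("m1", "t1"),
                      kinds = c("metagenome", "transcriptome"),
                      n_orfs = c(100000L, 20000L)) {
  data.frame(sample_id = ids, host_species = "A_aquaticus",
             origin = "laboratory", sex = "male", tissue = "hindgut",
             dataset_kind = kinds, n_orfs = n_orfs, stringsAsFactors = FALSE)
}

# calls table bypassing call_consensus, for downstream-stage tests
calls_df <- function(orf, family, module_count = 1L, sample_id = "m1") {
  n <- length(orf)
  data.frame(orf_id = orf, family = rep_len(family, n),
             hmm = rep(TRUE, n), similarity = rep(TRUE, n),
             peptide = rep(TRUE, n),
             module_count = rep_len(as.integer(module_count), n),
             sample_id = rep_len(sample_id, n), stringsAsFactors = FALSE)
}

write_tsv_tmp <- function(d, name = "fixture.tsv") {
  p <- file.path(tempfile("fix"), name)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}
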