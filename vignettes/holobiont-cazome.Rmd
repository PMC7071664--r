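---
title: "Reconstructing holobiont CAZomes: methods and design notes"
author: "cazomer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing holobiont CAZomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazomer)
```

# The problem

Decomposer animals such as isopods digest lignocellulose — the
cellulose/hemicellulose/lignin composite of plant cell walls — with a
repertoire of carbohydrate-active enzymes (CAZymes) contributed partly by
the host and partly by its gut microbiota. Reconstructing this joint
repertoire (the holobiont *CAZome*) from assembled metagenomes and host
transcriptomes raises a chain of small, error-prone bookkeeping problems:
CAZyme annotation tools disagree; counts must be comparable across samples
of very different sequencing depth; a CAZy family rarely maps one-to-one
onto a substrate; the taxonomic origin of each enzyme must be inferred from
ambiguous database hits; and the most interesting degradative systems —
polysaccharide utilization loci (PULs) and cellulosomes — are *gene
clusters*, visible only in the gene order of contigs.

`cazomer` implements this chain as composable, individually tested stages.
Every stage consumes plain tables in the formats the upstream tools emit,
and a synthetic-data generator with known ground truth exercises each stage
without any database download.

# Consensus CAZyme calling

Three independent evidence streams are read per ORF: HMM domain hits
against family profiles (HMMER `--domtblout` layout), sequence-similarity
hits against an annotated protein set (BLAST/DIAMOND tabular), and short
peptide-signature hits (a Hotpep-like TSV). The calling rule is
deliberately conservative: an (ORF, family) assignment is kept **only when
all three tools report it**. Assignments supported by one or two tools are
retained in a side channel for inspection (`partial_calls()`) but never
counted.

Two details matter:

* **Agreement level.** Tools differ in subfamily resolution, so agreement
  is evaluated at family level by default — `GH5_13` and `GH5_4` agree at
  `GH5`. The most specific HMM-reported label is kept in the `subfamily`
  column so reports can still print `GH5_13`. Strict subfamily agreement is
  available (`agreement = "subfamily"`).
* **Counting unit.** A "CAZyme" here is a functional module (domain), not a
  gene: the `module_count` of a call is the number of HMM domain hits of
  that family on the ORF, so a two-domain gene contributes two modules.

The similarity stream passes an e-value gate before consensus
(`similarity_evalue`, default 1e-50 — the conventional stringent gate for a
pre-annotated CAZyme database). Peptide hits are not filtered by default;
whether a score floor should apply is genuinely open, so
`peptide_min_score` exists but is `NULL` unless set.

Because consensus is a set intersection it is order-free and deterministic;
no tie-breaking is needed. If each tool independently recovers a true
family with probability $q$, expected consensus recall is $q^3$ — a
property the test suite verifies empirically against the generator at
$q \in \{0, 0.5, 0.8, 1\}$ with $n = 2000$ planted ORFs.

# Counting and normalization

`count_families()` tallies `module_count` into a family × sample matrix
(total modules are conserved by construction). Libraries differ enormously
in ORF count, so `normalize_counts()` rescales each sample by the simple
ratio rule:

$$\mathrm{norm}(f, s) = \frac{\mathrm{raw}(f, s)}{n_\mathrm{ORF}(s)}
  \times \min_{s' \in G(s)} n_\mathrm{ORF}(s')$$

i.e. relative abundance times the smallest ORF library of the sample's
normalization group, so the group's shallowest sample keeps its raw counts.
This is intentionally *not* a rarefaction or a DESeq-style size factor: the
method under study is the plain ratio, and anything cleverer would change
the quantity being reproduced. Groups default to `dataset_kind` strata
(metagenomes vs transcriptomes are never normalized onto a common
reference, and a `norm_group` metadata column can split them further, e.g.
newly sequenced metagenomes vs metagenomes from an earlier study — the
configuration used in the acceptance computations, with group minima of
202,349, 22,641 and 19,473 ORFs). Normalized values are kept unrounded;
only the report layer rounds.

Three invariants are property-tested on 200 random matrices: identity at
the group minimum, scale equivariance (scaling one non-minimal sample's
column and its ORF count together changes nothing for that sample), and
monotonicity within a sample.

# Lignocellulose classification

Membership of a CAZy family is only a prior for substrate: GH5 contains
cellulases *and* hemicellulases; GH18 is mostly chitinases. Classification
therefore works in two layers:

1. A packaged, editable **class map**
   (`inst/extdata/lignocellulose_families.tsv`) lists the watchlist
   families with their functional roles (endocellulase, β-glucosidase,
   cellobiose phosphorylase, LPMO, hemicellulase, laccase, cellobiose
   dehydrogenase), the compartment they were observed in, and whether their
   most common activity is lignocellulolytic. The microbiota watchlist
   holds 44 families (33 GH, 8 CE, 3 AA — the AA families being AA1
   laccases, AA3 cellobiose dehydrogenases and AA10 LPMOs), plus host-side
   entries (AA15 LPMO, GH38/GH47). Families named in published isopod
   CAZome results are tagged `reported`; the remaining hemicellulase GH
   families required to complete the list follow standard family-activity
   assignments and are tagged `curated`, and users can edit either. AA2
   manganese peroxidases are deliberately absent from the default
   watchlist (the published family count for the microbiota includes three
   AA families); the `lme_peroxidase` role exists so users can add AA2 with
   one TSV row.
2. An explicit per-ORF **activity prediction** always overrides the family
   default. Activity strings are matched case-insensitively against a small
   controlled vocabulary of enzyme names; an unmatched string yields
   `unresolved`, never a guess. Calls without a prediction take the
   family's most-common-activity default (`activity_source =
   "family_default"`), so the override precedence is total by construction.

`summarize_classes()` reports module totals per substrate class and the
percentage of *activity-predicted* modules that are lignocellulolytic vs
other-substrate, to one decimal. With zero predicted modules the
percentages are `NA`, not 0. `ligno_richness_ratio()` compares watchlist
family richness of one host species against the mean of the others (one
decimal), the statistic used to contrast an aquatic host's microbiota with
terrestrial ones.

# Taxonomic attribution

Each CAZyme-encoding ORF carries up to `k` database hits (default 5, after
an e-value cutoff of 1e-4), each a semicolon-delimited lineage from domain
downward. `lca()` assigns the naive lowest common ancestor: the longest
common prefix of the retained lineages, compared position-by-position
(position 1 = domain, 2 = phylum, ...). Design choices:

* **Naive on purpose.** No min-support or top-percent weighting: the
  simplest faithful LCA rule is used, and weighting hooks would add
  parameters the reproduced method does not define.
* **Missing ranks are wildcards.** An empty token matches whatever name the
  other lineages carry at that position, so patchy database lineages do not
  truncate the assignment; trailing wildcard-only positions are trimmed.
* Single hit → its full lineage; conflict at the first position → root
  ("unassigned"); empty input → unassigned with support 0.

`profile_community()` aggregates module counts per taxon at a requested
rank, per CAZy class; ORFs that do not resolve to that rank fall into an
explicit `unknown` row, so column totals conserve modules (real gut
metagenomes have large unknown fractions, and hiding them would distort
the profile). The suite checks `lca()` against an independent brute-force
longest-common-prefix recomputation on 1000 random lineage sets.

# Locus screens

Both screens run on gene-ordered contigs; gene order is always recomputed
from start coordinates, so results are invariant to row shuffling.

**PULs.** The marker pair is a susC-like TonB-dependent transporter
(Pfam PF00593) and its partner susD-like glycan-binding protein (PF07980).
A candidate is one *sequential* pair: two genes with gene-index difference
exactly 1, one bearing each marker. Either order counts and strand is
ignored by default, because fragmented metagenome contigs routinely truncate
and flip loci; a `strict` mode demands the canonical Bacteroidetes tandem
(susC immediately upstream of susD, same strand). Contigs carrying markers
without an adjacent pair are tallied as orphans — on real assemblies
orphan-bearing contigs outnumber pair-bearing ones by two orders of
magnitude, and the tally is part of the result, not noise. Co-localized
CAZymes default to the whole contig (metagenome contigs are short); a
bp-window option exists for long contigs. `render_pul_map()` prints the
gene organization (`"unk - susC - susD - GH43"`).

**Cellulosomes.** The screen lists genes bearing cohesin (PF00963),
dockerin and S-layer homology (SLH, PF00395) domains, counting *modules*
(domain hits — a scaffoldin with several cohesin repeats contributes them
all). The dockerin accession defaults to the standard Pfam dockerin repeat
(PF00404) but is an ordinary config key: published marker lists sometimes
repeat the cohesin accession for the dockerin, so the screen refuses to
hard-code it. Genes bearing both a dockerin and ≥ 1 called CAZy family are
emitted as enzyme–dockerin fusions, joined to host/origin/sex/tissue and
contig taxonomy when supplied — the table shape in which such evidence is
conventionally reported. A packaged inventory of 30 such fusion genes
observed in isopod gut metagenomes (`dockerin_fusion_inventory()`) doubles
as a realistic planting table for the generator.

# The synthetic generator

`synthetic_scenario()` + `generate_holobiont()` emulate exactly the
statistical structure the pipeline consumes: contigs with uniform gene
lengths (300–2400 bp) and intergenic gaps (20–200 bp); planted adjacent
susC–susD pairs; orphan/non-adjacent decoys (cycling susC-only, susD-only,
split-pair); dockerin/cohesin/SLH genes with configurable module-to-gene
ratios and fusion tables; probe CAZyme ORFs whose true family each tool
reports independently with probability `tool_agreement` (missed reports may
become mislabels at `confusion_rate`); second HMM modules at
`multi_module_rate`; spurious single-tool background hits; ranked lineages
with a configurable phylum-level disagreement rate; and activity
predictions drawn from the class map's role vocabulary. Locus-planted
CAZymes (PUL co-located genes and fusions) always receive full three-tool
evidence: they are locus ground truth, and entangling their recovery with
the consensus draw would make the locus tests measure two things at once.

A single integer seed drives one RNG stream, and generation is
byte-identical for a fixed seed. The manifest lists every planted truth
item and is re-derivable from the files by an independent scan (tested).
`score_against_truth()` computes per-stage precision/recall and exact-match
booleans, with `NA` precision for a detector that returns nothing.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic HMM score distributions and alignment
coordinates, correlated tool errors (real annotation tools fail on the
same hard ORFs, so real consensus recall is not exactly $q^3$), codon
content or any sequence realism, assembly chimerism, and uneven taxon
abundance. The screens and arithmetic are exercised end-to-end; biological
realism of the evidence is out of scope.

# Problem sizes and numerical choices

The test suite runs scenarios of 20–2000 planted ORFs and up to ~60
contigs; the acceptance computations use a survey-scale assembly (5,089
sus-marker contigs, 874 dockerin/cohesin contigs, 163 SLH contigs, ~29,000
genes) and 2,000 consensus probes — sizes chosen so the full suite
completes in well under a minute of compute per stage while keeping
binomial confidence intervals tight enough to distinguish $q^3$ curves.
Other numerical conventions: all coordinates 1-based inclusive (GFF);
readers are lenient by default (malformed rows skipped with line-numbered
warnings, `strict = TRUE` promotes them to errors); duplicate ORF ids are
tolerated with a warning because metagenome assemblies are messy; empty
inputs yield empty, correctly-shaped outputs everywhere; percentages and
ratios are rounded only at the report layer.

# Known limitations

* The three evidence dialects are fixed column schemas, documented in
  `read_domain_hits()`; exotic tool output variants need reshaping first.
* Lineages are compared positionally against the canonical rank ladder;
  lineages with non-canonical rank structures should be normalized upstream.
* The class map is a curated starting point, not an authority — families'
  activity spectra evolve with the CAZy literature, and the map is shipped
  as data precisely so users can revise it.
* The PUL screen detects the marker pair, not the full locus model (no
  regulator/transporter grammar, no substrate prediction); the cellulosome
  screen detects components and fusions, not cohesin–dockerin binding
  specificity.
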