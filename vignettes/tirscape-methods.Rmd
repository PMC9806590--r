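---
title: "Methods: domain architectures, shared clades, co-occurrence and immune-expression association"
author: "tirscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain architectures, shared clades, co-occurrence and immune-expression association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirscape)
```

`tirscape` implements a five-stage comparative analysis of plant
Toll/Interleukin-1 receptor (TIR) domain proteins. This vignette documents
the procedures, the tunable parameters and their defaults, the numerical
conventions, what the synthetic-data generators do and do not emulate, and
the design choices made where the design was genuinely open.

## 1. Domain assembly and architecture classification

TIR annotation in plants proceeds from HMM searches of predicted proteomes.
Several TIR and TIR-like HMMs typically hit the same region of a protein, so
raw hit tables contain redundant detections; and short, marginal envelopes
are unreliable. The assembly stage therefore applies three filters in
order:

1. **E-value cutoff at parse time** (`max_evalue = 0.01`, `evalue <=`
   cutoff). This mirrors an inclusion threshold applied during the search
   itself, for both the TIR screen and a general Pfam scan.
2. **Overlap deduplication** (`max_overlap = 20` aa). Two same-class hits
   whose 1-based inclusive envelopes overlap by strictly more than 20
   residues (`min(e1, e2) - max(s1, s2) + 1`) are redundant. Redundancy is
   closed transitively — a chain of pairwise-overlapping hits forms one
   cluster — and exactly one representative per cluster is kept: lowest
   E-value, ties broken by the longer envelope, then lexicographic HMM name.
   The tie-break is arbitrary but fixed, because deterministic output
   matters more than which of two equally good redundant hits survives.
   Hits of different domain classes never suppress each other. We apply the
   same rule to every domain class, not only TIRs, since NBARC and TPR HMM
   sets show the same redundancy.
3. **Length minima**: TIR ≥ 50 aa, NBARC ≥ 150 aa; classes without a
   configured minimum pass unfiltered.

Classification assigns the first matching rule: TIR+NBARC+TPR → **TNP**;
TIR+NBARC+LRR → **TNL**; TIR+NBARC → **TN**; a lone TIR in a protein
strictly shorter than 400 aa with no other predicted domain → **TIR-only**;
any other TIR protein → TIR_OTHER; no TIR → NON_TIR. TNP takes precedence,
so a TIR+NBARC+LRR+TPR protein is a TNP, and per-species count tables never
count TNPs in the TNL/TN/TIR-only columns.

Two open points were resolved as follows. Domain order (TIR N-terminal of
NBARC) is *not* required by default — the N-terminal position of TIRs is
descriptive, not definitional — but a `require_tir_first` flag is available.
The 400-aa TIR-only bound is applied to the full annotated protein length,
the only length the hit table carries.

## 2. Alignment column filtering and motif support

Columns whose gap fraction is strictly greater than `max_gap_frac = 0.40`
are removed; a column at exactly 40% gaps is kept. `-` and `.` both count
as gaps; letters, including the ambiguity code `X`, do not; residues are
uppercased on read. All-gap columns (possible in subsetted alignments) are
removed by the same rule at any threshold below 1 and flagged via an
attribute. The filter returns a new-to-old column index map, so per-column
residue frequencies computed on the filtered alignment can always be traced
to original coordinates; frequencies are taken over non-gap residues only
and sum to one, with the gap fraction reported separately.
`map_reference_columns()` maps alignment columns to ungapped positions of a
chosen reference sequence; motif windows (catalytic glutamate, dimerisation
interfaces, αD helix) are defined visually against a reference structure
and are therefore user-supplied configuration, not package defaults.

## 3. Taxonomically shared clades

The input is a phylogeny whose internal-node labels carry branch support in
either the single (`"95"`, ultrafast bootstrap) or dual
(`"80/95"`, SH-aLRT/ultrafast bootstrap) dialect of ML tree inference.
Unrooted trees are midpoint-rooted — deterministic and requiring no
outgroup — with support labels kept attached to the branches they describe.
A textual label on the root node (some tools write `Root` after re-rooting)
is treated as absent support rather than an error.

A clade *qualifies* when its ultrafast bootstrap is strictly above
`min_ufboot = 90`, its SH-aLRT is strictly above `min_sh_alrt = 80` when
that threshold is in force, and its leaves span at least `min_lineages = 2`
lineages from a user-supplied taxonomy table (leaf → species → lineage,
e.g. Rosids / Asterids / monocots / magnoliids — the package never infers
taxonomy). Nodes lacking a required support value fail the test rather than
erroring, since inference leaves some nodes unlabeled. By default only
*maximal* qualifying clades are reported (no reported clade is a descendant
of another); `include_nested = TRUE` exposes the full qualifying set. Note
that monotonicity in the support threshold holds for the qualifying set,
not necessarily for the maximal-group count: lowering the threshold can
merge several groups under one qualifying ancestor.

Strictness follows the ">90" convention throughout; marking branches at
"≥90%" in a figure is a display choice, not a detection rule.
`select_representatives()` subsamples each group for reduced re-analysis
(large alignments can have more sequences than alignment patterns):
lineages are cycled in random order, one random member at a time, so every
lineage in a group is represented whenever the quota allows; selection is
deterministic under the seed. This is a principled subsampling scheme, not
a reconstruction of any particular published representative set.

## 4. Presence/absence co-occurrence

Orthogroup tables (row = orthogroup, one gene-list column per species) are
binarized at the species level: presence means at least one gene, never
weighted by copy number. Pattern matching is strict by default — a row
matches only if it equals the query at every required species; unlisted
species are free — because the screen is designed to retain high-confidence
candidates only. A `max_mismatches` relaxation exists but defaults to 0.
Downstream refinement against discriminatory genomes (reciprocal BLAST) is
an external manual step; the module emits the candidate list and accepts a
keep-list to apply its outcome. Whether fragmentary hits in required-absent
species should count as presence is deliberately left to that keep-list
mechanism. Profile agreement is summarised as Jaccard over present-species
sets (defined as 1 when both sets are empty) and as the fraction of species
with equal state.

## 5. Expression association

Genes count as expressed at tpm strictly greater than
`tpm_threshold = 0`. For each gene, a 2×2 table of expressed × triggered
over samples is tested with the one-sided Fisher exact test for enrichment
in triggered samples, computed as the upper hypergeometric tail
(`stats::phyper` in log space; exact to double precision). Degenerate
margins — a gene expressed in all samples or none, or a study without both
sample groups at the gene level — return p = 1 rather than NA, keeping the
Bonferroni denominator stable. Bonferroni uses m = number of genes tested
per study (the candidate set per species); stars are strict:
`***` p < 0.001, `**` p < 0.01, `*` p < 0.05.

Samples, not studies, are the test units: data pooled from heterogeneous
public experiments are tested jointly, accepting between-study
heterogeneity. A per-study stratified alternative (exact
Cochran–Mantel–Haenszel via `stats::mantelhaen.test`) is available but off
by default, as is a two-sided test. Per-sample z-scores (sample standard
deviation, n−1 denominator; constant samples become zero with a warning)
are provided for display only, because pooled samples differ in library
preparation and depth.

## Synthetic data: what it emulates, and what it does not

The generators replace downloaded proteomes, inferred trees, orthology runs
and RNA-seq with seeded constructions that exercise every code path:

- `simulate_proteome_hits()` plants, per species, 5 TNL + 3 TN + 2 TIR-only
  + 1 TNP + 9 non-TIR proteins by default (20 proteins/species, 10
  species). Planted TIRs are ≥ 130 aa, NBARCs ≥ 250 aa, TIR-only proteins
  < 400 aa, so noise-free truth survives every filter. Injected noise is
  *filterable by design*: hits with E-value above 0.01 (removed at parse),
  sub-threshold NBARC envelopes placed where they cannot interact with the
  merge step (removed by the length filter), and redundant same-class hits
  overlapping a planted TIR by > 20 aa at a strictly worse E-value (removed
  at merge). Protein sequences are random residues — the classifiers read
  hit tables, not sequences — and FASTA is emitted for interface
  completeness.
- `simulate_tree()` builds a random-join topology with planted multi-lineage
  clades whose supports lie above the thresholds (UFboot 93–99, SH-aLRT
  85–99) and decoys that fail either taxonomically (single lineage, high
  support) or by support (multi-lineage, UFboot 30–88). Supports are
  specification, not inference: no substitution model is simulated, because
  the clade detector consumes labelled topologies. Branch lengths are
  exponential and carry no signal.
- `simulate_og_matrix()` plants exact pattern matches (default 7 rows over
  10 species, 5 required present and 5 required absent) among background
  rows drawn i.i.d. at 35% presence, rejection-sampled so no background row
  matches by accident; present cells carry 1–3 gene ids to exercise
  copy-number-blind binarization.
- `simulate_expression()` gives responsive genes zero control tpm (up to a
  leak probability, default 0) and detection probability 1 in triggered
  samples by default; positive magnitudes are lognormal(μ = 2, σ = 1) —
  display-level realism only, since the association test sees only
  exceedance of the 0 threshold.

Passing tests on these inputs show that the filters, detectors and tests
implement their definitions exactly and recover planted structure under
noise designed to be removable. They do *not* show robustness to the
hardness of real data — fragmented gene models, mis-annotated domains,
clades broken by long-branch artefacts, batch effects correlated with
trigger status — which no desk-scale simulation can certify.

## Numerical conventions and degenerate inputs

All thresholds and their strictness are centralised in
`threshold_config()`. Coordinates are 1-based inclusive throughout (the
hit-table convention). Fisher p-values are validated against exhaustive
enumeration of all tables with the observed margins to below 1e-12 for
margins up to 30. Empty inputs return empty, correctly typed results;
mixed-protein merges, ragged alignments, unknown species and out-of-range
indices raise errors naming the offending item. Every random procedure
(generators, representative selection) flows from an explicit integer seed
through an isolated RNG scope, so repeated runs are byte-identical; the
end-to-end runner records input MD5 hashes, thresholds and per-stage row
counts in a JSON manifest.

Problem sizes used by the test-suite and the acceptance script — 10 × 20
proteins, 200-leaf trees with 4 planted clades and 10 decoys, 1,000 × 10
orthogroup matrices with 7 planted rows, 2,000-gene null studies at 6 vs 6
samples — were chosen as the smallest instances that exercise every rule
and give the exact tests adequate resolution.

## Interfaces

Each stage reads and writes the standard plain-text formats of the tools it
sits between (domtblout/TSV, FASTA, Newick, orthogroup TSV, tpm/metadata
TSV). The package functions are the primary interface;
`inst/cli/tirscape.R` wraps them for shell use, and `run_pipeline()` runs
any subset of stages from one YAML configuration. Running the external
programs themselves (hmmsearch, MAFFT, IQ-TREE, Orthofinder, Salmon) is out
of scope, as are custom HMM construction, structure comparison and
orthology refinement by reciprocal BLAST.
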