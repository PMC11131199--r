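---
title: "Methods and design notes for comparative CAZyome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for comparative CAZyome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazyome)
```

## The problem

Carbohydrate-active enzymes (CAZymes) — glycoside hydrolases (GH),
polysaccharide lyases (PL), carbohydrate esterases (CE), auxiliary
activity oxidoreductases (AA) and carbohydrate-binding modules (CBM) —
determine which polysaccharides a bacterium can deconstruct. Comparative
questions about a genome collection ("which orders are lignocellulose
specialists?", "who co-localises enzymes into degradation loci?", "where
should bioprospecting look for novel enzymes?") all reduce to a common
pipeline: call CAZymes consistently per gene, locate them in their gene
neighbourhood, attach substrate semantics, summarise per genome, and
compare groups statistically. This package implements that pipeline for
the annotation formats the field's standard tools emit.

## Consensus calling

dbCAN2 annotates each gene with up to three tools. The rule implemented
here trusts HMMER for family assignment: a gene is a **classified**
CAZyme iff HMMER reports at least one family label, and every label
becomes a separate functional module (duplicated labels stay duplicated
— a xylanase with two CBM2 copies has three modules). Genes supported
only by Hotpep and/or DIAMOND are **unclassified** CAZymes: they look
CAZyme-like by peptide or homology evidence but match no recognised
family model, which makes them candidates for novel families; they carry
no modules and are excluded from family-based statistics while being
tracked as a per-genome ratio (typically a few percent of CAZyme-like
genes).

Glycosyltransferases (GT) synthesise rather than hydrolyse glycosidic
bonds, so `exclude_gt = TRUE` strips GT modules from all tools before
the status is decided. One corner case is deliberately resolved the
strict way: a gene whose HMMER evidence was GT-only gets status `none`
even if DIAMOND suggested a GH — HMMER *did* see the gene, so it can
never fall into the "unclassified" (HMMER-missed) category, and after GT
removal it has no family. The alternative (demoting it to unclassified)
would double-count genes HMMER already adjudicated; the truth-table test
pins the chosen behaviour.

## CGC detection

A CAZyme gene cluster (CGC) — the bacterial analogue of a
polysaccharide utilisation locus — is detected on each contig by greedy
chaining over gene rank (order along the contig; physical coordinates
and strand never enter the logic, so the GFF coordinate convention is
irrelevant). Signature genes are classified CAZymes and auxiliary genes
(transcription factors and transporters, matched on product text against
a configurable keyword list; CAZyme status takes precedence). Two
consecutive signature genes chain iff at most `max_gap` (default 2)
other genes lie between them, and a maximal chain is emitted iff it
contains at least one CAZyme and either an auxiliary gene or a second
CAZyme. Emitted clusters start and end on signature genes.

The gap rule is enforced pairwise between consecutive signature genes
(the CGCFinder convention), not on a cluster-wide budget. Greedy
chaining provably equals the brute-force "enumerate all valid windows,
keep maximal ones" oracle: a maximal chain that fails the composition
rule has either no CAZyme or a single CAZyme and no auxiliary, and no
sub-window of it can then satisfy composition either. The acceptance
suite re-verifies this equivalence on 1000 random contigs at
`max_gap` 0–3. Unclassified CAZymes count as ordinary genes for
clustering (they have no family and cannot anchor a locus) but are
surfaced in the cluster "unassigned" fraction, the compartment where
novel functions hide. Contigs are treated as linear; ends terminate
chains.

## Substrate categories, ratios, secretion

GH and PL families map to a biomass category (algal / plant /
algal-plant / other) and a substrate category (algal polysaccharides,
glucans, oligosaccharides, lignocellulose, NAG-based, pectin, other).
Lookup is subfamily-first with family fallback; unmapped families are
"unassigned". The map is user-supplied data, with a small documented
default covering well-characterised families; families with genuinely
polyspecific activities are still mapped to a single main-target
category, a simplification the map format makes explicit rather than
hides.

Two ratio conventions coexist on purpose. The **assigned ratio** (mapped
GH/PL modules over all GH/PL modules) counts modules, because family
assignment happens after module splitting and a bifunctional GH5+GH10
protein genuinely contributes two enzymatic activities. **Secretion
ratios** count genes, because a signal peptide belongs to the whole
protein: among genes carrying at least one GH/PL module of a category,
the fraction whose signalP type is in the requested set (default: any
type except NONE). A gene whose modules span several categories counts
once per category. Restricting the accepted signal peptide types can
only lower a secretion ratio; this monotonicity is property-tested.

## Per-genome metrics

* Family diversity is counted at both family and subfamily granularity,
  since reports in this field mix the two; both columns are emitted.
* CAZyme coding frequency is `100 * classified genes / n_proteins`, with
  `n_proteins` taken from metadata (the gene caller's count) so that
  fragmented or subsampled gene tables stay testable; disagreement with
  the gene table is a warning, not an error.
* The T1/T2 trend splits genomes at 2% GH+CBM coding frequency; exactly
  2% is assigned to T2, consistent with reading the bins as "< 2%" and
  "> 2%" with the boundary going to the lower bin. The boundary is
  pinned by a test.
* Quality filtering keeps genomes with completeness strictly above 75%,
  contamination strictly below 10%, and at least 10 classified CAZymes;
  boundary values (75.0, 10.0, 9 CAZymes) are excluded. Classes with
  fewer than 10 genomes pool into "other class".
* The GH–CBM diversity correlation uses Spearman's rank with average
  ties. For n ≥ 10 the p-value uses the t approximation; below that the
  exact permutation distribution is enumerated, because small taxon
  groups (a dozen genomes) deserve honest small-sample p-values. The
  exact path is cross-checked against `cor.test(..., exact = TRUE)` on
  tie-free data.

## Comparative statistics

The genome × family presence matrix (family granularity by default,
subfamily optional) feeds Jaccard distances
(`1 − |A∩B| / |A∪B|`; a pair of genomes with empty family sets — which
cannot survive the quality filter — is defined as distance 0 with a
warning). PCoA is classical MDS via Gower double-centering; negative
eigenvalues, the signature of non-Euclidean distances like Jaccard, are
reported rather than dropped, and for Euclidean-embeddable input the
full-rank coordinates reproduce the distances to 1e-8. PERMANOVA and
ANOSIM run with 999 label permutations by default and a mandatory seed;
p-values have resolution `1/(n_permutations + 1)`. Implementations are
delegated to vegan behind this package's interface; the test suite
checks the statistics against hand-computed rank formulas on toy
fixtures and calibrates both tests' type-I error on 500 null
simulations.

Per-family enrichment uses the tie-corrected Kruskal–Wallis test with
Benjamini–Hochberg adjustment across all testable (non-constant)
families; the BH output is verified against a literal step-up
implementation. The LDA effect size follows the LEfSe recipe: profiles
are normalised per genome and scaled to one million (so scores are
comparable with the conventional "log LDA score > 4" threshold), a
one-axis linear discriminant is fitted on the KW-passing features over
30 bootstrap rounds of 2/3 per-group subsampling, and the per-family
effect size averages the raw between-class mean difference with its
discriminant-weighted counterpart; the reported score is its log10.
LEfSe's exact bootstrap schedule is not published, so these scores are
rank-comparable, not bit-identical, with the reference implementation;
when the within-class scatter is singular the raw mean difference is
used and the family flagged as a fallback. Recovery and false-flag rates
are measured by simulation (planted occupancy 0.9 vs 0.1, 100
replicates) in the acceptance suite.

## Novelty scoring

Best hits against a reference CAZyme sequence set are reduced per query
by maximal bitscore, ties broken by higher identity then lexicographic
subject id — deterministic and order-independent. Genes with best-hit
identity below 30% are flagged as putatively novel; summaries report
median, IQR and the low-identity fraction per family or taxon. No
coverage or e-value filter is applied by default, since the input table
is already a tool's filtered output.

## What the generator emulates — and what it does not

`generate_dataset()` produces the statistical structure of an annotated
genome collection: per-group family occurrence probabilities (optionally
with planted enriched families), planted CGCs with known spans,
multi-modular proteins (default 10% of CAZymes), DIAMOND-only
unclassified CAZymes (default 3%, matching the few-percent range seen in
real genomes), GT-only genes, category-dependent signal peptide
probabilities (high for lignocellulose/pectin targets, low for glucans),
and quality metadata drawn inside the filter-passing region
(completeness 76–100, contamination 0–9.9). Defaults of 800–1200 genes
per genome put a GH-diverse genome at a realistic few-percent CAZyme
coding frequency. Two layout guarantees make cluster tests exact:
planted clusters are flanked by at least `flank_gap > max_gap`
non-signature genes, and background CAZymes are placed pairwise more
than `max_gap` apart with no auxiliary-product neighbours, so the
planted spans are provably the only valid clusters.

The generator does **not** emulate: nucleotide or protein sequences,
assembly fragmentation beyond a fixed contig count, correlated family
co-occurrence within genomes (families are independent Bernoulli given
the group), shared phylogenetic signal between groups, or annotation
errors (tools disagree only through the configured miss probabilities).
A green simulation test therefore establishes algorithmic correctness
and statistical calibration under this stated world — not fidelity to
any particular real dataset, whose headline values depend on external
databases and genome sets.

`simulate_profile_matrix()` exposes the same occurrence model without
gene-level construction; the large calibration loops (500 null
simulations, 100 enrichment replicates) use it so the acceptance suite
stays inside its runtime budget while testing the identical statistical
model.

## Numerical and design choices

* All thresholds live in `pipeline_config()` with the defaults above;
  the config is echoed as YAML into every output directory.
* Permutation schedules, bootstraps and the generator are seeded;
  reruns with one seed are byte-identical, which the determinism test
  enforces file-by-file.
* A genome whose inputs fail to parse is quarantined with a logged
  reason; the run aborts only if more than 10% of genomes fail —
  draft-genome collections are heterogeneous and robustness is part of
  the job.
* A missing signal-peptide input skips only the secretion columns, with
  an explicit "missing input" log status; all other outputs are
  unchanged.
* Ratios with empty denominators (no CAZymes, no genes in a category)
  are `NA`, never 0: absence of evidence is not a zero rate.
* `detect_cgcs()` rejects unsorted input and negative gaps instead of
  silently reordering.

## Known limitations

The default substrate map is intentionally small; real analyses should
supply a comprehensive family-to-substrate table. LDA scores are
approximations of LEfSe's, suitable for ranking and thresholding, not
for cross-study numerical comparison. Habitat-style multi-factor designs
are supported only through the single grouping column; no nested or
stratified permutation schemes are exposed. Circular contigs are not
modelled.
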