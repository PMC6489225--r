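---
title: "Methods: classifying plant U-box E3 ligases and profiling their stress response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying plant U-box E3 ligases and profiling their stress response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubclassr)
```

Plant U-box (PUB) proteins are E3 ubiquitin ligases defined by a ~70-residue
U-box domain, a modified-RING fold that confers ligase activity. Family
surveys in Arabidopsis, rice, barley and other species group PUB proteins
into classes by the additional domains flanking the U-box, because those
domains (ARM/HEAT solenoids, kinase domains, WD40 propellers, TPR repeats,
cyclophilin, UFD2, MIF4G, DJ-1) predict interaction partners and function.
`pubclassr` makes that grouping an explicit, auditable rule system and adds
the downstream analyses that normally accompany such a survey: tandem
duplication detection from genome loci, neighbor-joining phylogenetics with
bootstrap support, and delta-delta-Ct stress-expression calling. A
synthetic-data module generates inputs with known ground truth so that every
stage is testable end to end.

## The classification rules

A protein is represented as its length plus an ordered set of located domain
hits on a controlled vocabulary (`U_BOX`, `UFD2`, `ARM`, `HEAT`, `ARM_LIKE`,
`CYCLOPHILIN`, `PKC`, `STK_N`, `WD40`, `TPR`, `MIF4G`, `DJ1`, `OTHER`).
Annotations from InterProScan TSV, `hmmscan --domtblout`, or a simple
five-column table are normalized onto this vocabulary; overlapping hits with
the same label are merged into their union, and for hmmscan input the
alignment coordinates are used rather than the envelope, which keeps domain
bounds tight for the positional rule below.

The class decision is a precedence list. A protein with no U-box hit is
`UNCLASSIFIED`. Otherwise:

| precedence | evidence | class |
|---|---|---|
| 1 | UFD2 | I |
| 2 | cyclophilin | III |
| 3 | TPR and a kinase domain | VIII |
| 4 | kinase domain (PKc and/or STK-N) | IV |
| 5 | TPR | VII |
| 6 | WD40 | VI |
| 7 | MIF4G | IX |
| 8 | DJ-1 | X |
| 9 | ARM and/or HEAT repeats | II |
| 10 | none of the above | V |

The ordering is a design choice: published class definitions never state how
a multi-domain conflict should resolve, so we put rarer and more specific
domains first (a TPR+kinase protein is the TPR-kinase class, not a generic
kinase class). Every rule consulted is appended to a machine-readable
rationale trace on the assignment, so users can audit any individual call.

Two refinements need their own rules:

* **ARM-like regions.** Degenerate ARM-homologous regions (historically
  called GKL boxes) share sequence similarity with ARM repeats but lack
  conserved residues; they do not qualify a protein for Class II, so such
  proteins fall through to Class V. This is the default
  (`arm_like_counts_as_arm = FALSE`); the superseded grouping, in which
  ARM-like evidence builds a separate class, can be reproduced by flipping
  the flag, which is useful for comparing classifications across studies.
* **Class II sub-grouping.** Class II-a proteins carry a U-box near the
  centre with a U-box N-terminal domain (UND) before it; II-b proteins carry
  the U-box close to the N-terminus. The rule compares a reference point of
  the most N-terminal U-box hit against one fourth of the protein length:
  at or below the boundary is II-b. We use the hit midpoint by default
  because domain start coordinates are annotation-tool sensitive (start vs
  midpoint can differ by half a domain width); the start-based variant is
  available via `ubox_point = "start"`. The boundary itself (midpoint
  exactly at 0.25 L) is II-b — an arbitrary but documented tie rule. No
  attempt is made to detect the UND itself: it is defined only negatively,
  as the region N-terminal of the U-box.

Class IV splits by kinase-domain content: `IV_1` has both the catalytic PKc
domain and the N-terminal STK-N domain, `IV_2` only PKc, `IV_3` only STK-N;
the three cases are exhaustive once a protein has gated into Class IV.

One documented discrepancy: the barley family's Class II-b is described in
places as having 7 members, but the gene catalog lists 8 II-b rows, and
19 + 8 = 27 matches the stated Class II total. The packaged catalog and the
generator preset follow the catalog (8).

## The gene catalog and tandem duplication

The catalog dialect mirrors the published family table: gene name, genome
locus as `chr5H:102370756-102,375,777` (both hyphen and en-dash, with or
without digit-grouping commas), optional class label, and four EST-library
counts (abiotic stress, biotic stress, generative tissue, vegetative
tissue), with blank cells meaning zero. Coordinates are 1-based inclusive
throughout.

Tandem/duplication clusters are maximal chains of same-chromosome genes in
which consecutive genes are separated by at most `tandem_max_gap_bp`
(default 100 kb). The default is a deliberate calibration: at 100 kb the
barley catalog yields exactly the two gene pairs known to be recent tandem
duplicates (HvPUB11/12, gap 62,584 bp; HvPUB58/59, gap 53,809 bp), while the
looser groupings that are "clustered" but not tandem (members megabases
apart) are excluded. The packaged 67-gene barley catalog ships in
`inst/extdata/`; its class labels and loci are exact transcriptions, while
the EST cell boundaries in a few rows are a best-effort reading of the
printed table.

## Neighbor joining and bootstrap

Distances come from aligned amino-acid sequences as uncorrected p-distances
(proportion of mismatching residues over compared columns), with
`pairwise_deletion` (default) or `complete_deletion` gap handling, and an
optional Poisson correction `-log(1 - p)`. The source survey names no
distance model, so the simplest one is the default; p-distances are not
additive or ultrametric in general, and triangle-inequality violations are
possible — NJ does not require them to be absent.

Tree construction is the Saitou–Nei neighbor-joining algorithm implemented
in the package: join the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, with branch
lengths from the rate-corrected split formula. Ties in $Q$ break toward the
lowest (row, column) position in input order, making the algorithm fully
deterministic. Negative branch lengths — a known NJ artefact — are clamped
to zero with the deficit moved to the sister edge so their sum is preserved.
On additive input the tree's path-length matrix reproduces the input to
within 1e-9, which the test suite verifies against trees with known
topologies (and cross-checks against an independent NJ implementation).

Bootstrap support resamples alignment columns with replacement, rebuilds the
NJ tree per replicate, and annotates each internal edge of the full-data
tree with the percentage of replicates containing the same leaf bipartition
(the presentation used when bootstrap values are drawn on a reference NJ
topology rather than a majority-rule consensus). The default is 1000
replicates, the conventional setting for gene-family trees of this size. A
replicate in which some pair has no comparable columns is skipped with a
warning and the denominator shrinks accordingly. All resampling is driven by
an explicit seed; the same seed gives bit-identical output.

## Delta-delta-Ct expression calling

Quantification cycles (Cq) are modelled hierarchically: technical replicates
of each (gene, condition, biological replicate) cell are averaged first, and
biological replicates are the unit of inference. Then

$$\Delta Ct = Cq_\text{gene} - Cq_\text{reference}, \qquad
\Delta\Delta Ct_b = \Delta Ct_{\text{treated},b} -
\overline{\Delta Ct_\text{control}}, \qquad
\text{fold}_b = 2^{-\Delta\Delta Ct_b}.$$

The reported fold is the mean over treated biological replicates; the
efficiency-free form assumes near-100% amplification efficiency for gene and
reference alike. Significance is a two-sided two-sample t-test on the
$\Delta Ct$ values — the approximately normal scale — with pooled variance
(classic Student) by default and Welch via a flag, starred at 0.05/0.01. No
multiple-testing correction is applied by default, matching per-gene
starring conventions; Benjamini–Hochberg adjustment can be reported
alongside. Both error-bar summaries are emitted: the per-condition standard
deviation of technical-replicate Cq values and the spread of per-biological-
replicate folds.

Stress calls use an inclusive two-fold induction threshold (fold ≥ 2, and
significance when `require_significance = TRUE`) and a strong-suppression
threshold at fold ≤ 1/3 ("more than 3-fold suppressed"), the latter as a
pure fold criterion.

## What the generators emulate — and what they do not

`generate_architectures()` inverts the classification rules: for each
requested (class, subclass) count it emits a protein whose domain set
satisfies exactly that rule and no higher-precedence rule, with lengths
uniform in 350–1100 aa, II-a U-box midpoints in (0.35 L, 0.6 L) with ≥ 2
C-terminal ARM repeats, II-b midpoints in the N-terminal fifth, and Class V
proteins carrying a decoy ARM-like hit with probability 0.5. The built-in
`"barley-table1"` preset encodes the barley family composition
(I 1, II-a 19, II-b 8, III 1, IV 11 split 6 PKc-only / 5 STK-N-only, V 21,
VI 3, VII 2, X 1; 67 genes). The round-trip property — classification
recovers any requested composition exactly, for any seed — is what the
generator is for; it does not emulate real domain-coordinate distributions,
and no per-gene domain coordinates are published for this family, so
passing round-trip tests demonstrates rule consistency, not annotation-tool
accuracy on real proteomes.

`simulate_alignment()` evolves sequences down a tree under a
Jukes–Cantor-style model on 20 states with uniform equilibrium frequencies:
on each edge a site substitutes with probability $1 - e^{-r\,t}$ to a
uniformly chosen different residue. That is adequate ground truth for NJ
recovery testing and deliberately not a realistic protein model (no rate
heterogeneity, no exchangeability structure, no indels).

`simulate_cq_table()` plants a log2 fold change per gene: each gene gets a
true control $\Delta Ct$ drawn once from 1–6 cycles above the reference, the
treated $\Delta Ct$ is shifted by minus the planted fold, and Gaussian noise
(default sd 0.2 cycles) is added independently to every Cq measurement —
gene and reference, each technical replicate. Defaults are 3 biological × 3
technical replicates, the technical-triplicate convention (figure legends in
this literature sometimes say four technical replicates; the count is a
parameter). With zero noise the planted folds are recovered exactly; the
reference gene always yields fold 1 exactly because its $\Delta Ct$ is
identically zero.

One calibration consequence worth knowing: with the up-call cutoff at fold
2, a gene planted at exactly fold 2 sits on the threshold, and an unbiased
estimate clears it only about half the time. Reliable up-calls start above
the cutoff — at a planted log2 fold of 1.5 (fold 2.8) and noise sd 0.2 the
up-call rate exceeds 90%, and the direction (sign of the estimated log2
fold) is recovered in ≥ 95% of simulations whenever the planted |log2 fold|
is at least 1.5. Under the planted null, the t-test's empirical type-I error
at α = 0.05 stays within [0.03, 0.07] over 1000 simulations.

## Problem sizes and numerical choices

The test suite uses problem sizes chosen to make the statistical assertions
stable while keeping a full run interactive: 100 random 5–12-taxon trees for
the NJ additivity/recovery property (tolerance 1e-9), 100-replicate
bootstraps on 4-taxon diagnostic alignments, 1000 null simulations for the
type-I check, and 120 planted-fold simulations for direction recovery. The
barley-scale demonstration pipeline (67 taxa) runs with a reduced bootstrap
in tests; the function default remains 1000.

Degenerate inputs are handled explicitly rather than left to underflow: a
zero-variance t-test gives p = 1 for equal means and p = 0 flagged
`degenerate` otherwise; a pair with no comparable alignment columns is an
error naming the pair; a bootstrap replicate hitting that error is skipped
and counted out of the denominator; Poisson correction refuses p = 1.

## Interfaces and limitations

The package's functions are its interface: `run_pipeline()` orchestrates
classification → catalog structure → phylogeny → expression into a joined
per-gene report (TSV outputs with the seed and a config hash in every
header; reruns are byte-identical), and `synth_demo_bundle()` builds a
complete synthetic input set around the packaged barley catalog. The
pipeline is configured by a plain YAML file or in code via
`pub_run_config()`, with all thresholds (UND fraction 0.25, tandem gap
100 kb, fold cutoffs 2 and 3, bootstrap 1000) surfaced.

Out of scope by design: de novo U-box detection from raw sequence (profile
search is upstream), multiple sequence alignment computation (pre-aligned
FASTA is consumed), maximum-likelihood or Bayesian tree inference, ortholog
calling across species, amplification-efficiency-corrected qPCR models, and
EST database querying. The published phylogenies and qPCR bar values for
the barley family cannot be reproduced here because the underlying
sequences and raw Cq tables are not public; the package instead verifies
every stage against synthetic ground truth and the catalog-derived numbers
that are recomputable.
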