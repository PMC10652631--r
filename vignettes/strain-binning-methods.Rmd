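---
title: "Strain-resolved read binning and downstream statistics: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-resolved read binning and downstream statistics: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainscope)
```

## The problem

A long-read metagenome of a bacterial population often contains several
within-species variants ("strains") at ANI above 99%. Assembling all reads
together collapses the strains into a chimeric consensus. strainscope
implements the alternative: separate the long reads into per-strain
subdatasets *before* assembly, then quantify how the resulting strain
genomes differ. The package covers the read-binning stage and the
comparative statistics; assembly, annotation, orthology inference and
variant calling are external and their outputs are consumed as plain
tables.

## The binning model

### Features

Each long read is summarised by three features:

* **Recruitment depth** — short reads are aligned to the long reads under a
  strict regime (fewer than 3 mismatches, primary hits only, top score per
  query, at most one hit per query) and the read's depth is its recruited
  aligned-base mass divided by its length, i.e. its mean per-base coverage.
  Aligned-base mass rather than hit counts makes depth exactly linear in
  the alignment set and robust to partial overlaps at read ends.
* **GC content** — computed over non-N bases.
* **Canonical tetranucleotide composition** — 4-mers counted with windows
  containing N skipped, collapsed into the 136 strand-symmetric classes and
  normalised to frequencies. k = 4 is the community standard for
  composition-based binning.

The clustering matrix has one depth column, `log10(depth + 0.1)`, and 136
centred log-ratio (CLR) columns from the 4-mer counts (+1 pseudocount).
Both pseudocounts are exposed; the depth pseudocount keeps depth-0 reads
finite, and the CLR makes the compositional part scale-free (every CLR row
sums to 0).

### Why the depth axis leads

The depth of a long read under the primary-hit regime is (short-read mass
of its strain) / (long-read redundancy of its strain): reads from one
strain share a depth, and strains separate whenever the short-read
composition of the sample differs from the long-read composition — which is
the general situation when the two libraries come from different specimens.
Composition, by contrast, is almost identical between within-species
strains, but is *not* identical between overlapping reads from different
parts of one genome: at validation scale (a 100-kb chromosome tiled by
10-kb reads) the CLR vectors trace a thin curve parameterised by genome
position, shared by all strains. Any composition axis that reaches the
mixture model invites the likelihood to split reads by position rather than
by strain, and the gain from such splits is invariant to rescaling.

`cluster_reads()` therefore multiplies the CLR block by
`composition_weight` (default 0.05) before PCA. With the default, the
retained principal components are dominated by depth unless compositional
structure is large on the scale of the depth spread — the regime of
cross-species contamination, where composition genuinely discriminates.
The weight is a tunable: set it to 1 to give composition full variance
share, or 0 to cluster on depth alone.

### Dimension reduction and the mixture

The (weighted) matrix is centred and projected onto the leading principal
components that explain at least `pca_var = 0.90` of the variance, capped
at `max_pc = 10` components. The cap matters: with n of order 10^3 reads a
full-covariance Gaussian mixture in tens of near-noise dimensions is
over-parameterised and BIC degenerates.

For each k in `k_min:k_max` (default 1–8) a full-covariance Gaussian
mixture is fitted by EM with `n_init = 10` seeded restarts (k-means
initialisation), ridge `reg = 1e-6` added to covariance diagonals
(escalated tenfold on Cholesky failure, so point-mass clusters never
crash), relative log-likelihood tolerance `tol = 1e-4` and at most 500
iterations. Collapsed components are re-seeded on a random observation. k
is chosen by minimum BIC; ties break toward smaller k. All randomness
derives from one seed and identical invocations are bit-reproducible.

### Depth consolidation

Local coverage fluctuates along a genome; at a long-read depth of 10x its
coefficient of variation is about 1/sqrt(10), roughly 30%. With precise
recruitment depth the BIC-optimal mixture resolves this within-strain
structure into several components per strain. Since reads of one strain
share a depth *up to that fluctuation*, components whose mean depths are
closer than `merge_depth_ratio = 2` are consolidated into one strain bin by
average-linkage clustering of component mean log10-depths (cut at
`log10(merge_depth_ratio)`). Average linkage was chosen deliberately:
single linkage chains across between-strain gaps via tail components, and
complete linkage splits heavy-tailed low-coverage strains. The consequence
is a stated resolution limit: strains are depth-resolvable only when their
abundances differ by more than the merge ratio. `raw_k` records the BIC
minimiser, `chosen_k` the post-consolidation strain count; bins are
numbered by decreasing mean depth. Setting `merge_depth_ratio = 1` disables
the step.

### Scoring

`score_bins()` reports the adjusted Rand index on the (bin, strain)
contingency table, per-bin precision (majority-strain fraction), per-strain
recall (fraction of a strain's reads in its majority bin) and the recovery
rate (assigned reads / input reads; below 1 only when a posterior threshold
diverts low-confidence reads).

## What the mock generator emulates — and what it does not

`make_mock_community()` derives strains from one ancestor by independent
per-site substitutions, so pairwise ANI follows analytically from the
mutation logs. Defaults encode the validation design: a 100-kb circular
chromosome, three strains at divergences 0.0025/0.001/0.0005 from the
ancestor (pairwise ANI 99.5–99.9%), long-read depths 80x/30x/10x, and
uniform 100x short-read depth. Values chosen where no external constraint
existed, with rationale:

* **Genome length 100 kb** keeps the full pipeline (five replicate
  communities) to a few minutes on one CPU; it is ~35x smaller than a real
  methanotroph genome and read-to-genome ratios are correspondingly larger.
* **Circularity** matches bacterial chromosomes and keeps coverage
  stationary; with linear ends, edge reads suffer depressed long-read
  redundancy and their depth feature inflates ~2x.
* **Short-read depth uniform at 100x** (not proportional to long-read
  depths): the depth feature is short-read mass over long-read redundancy,
  so proportional depths would erase the signal. Uniform short coverage
  emulates an Illumina library from a different specimen; 100x reflects a
  realistic Illumina run over a small genome, and depth precision scales as
  1/sqrt(recruited reads).
* **HiFi reads** are simulated directly with substitution-only errors at
  0.002 and truncated-normal lengths (10 kb ± 1.5 kb, minimum 500 bp)
  rather than via a CLR multi-pass error model — the binning method
  consumes only sequences and depths. Short reads are proper innie pairs,
  100 bp with a 150-bp insert and 0.01 substitution errors; qualities are a
  constant Q30 placeholder because nothing consumes them.
* **Indels are not simulated**, which keeps truth ANI analytic and
  alignment accounting exact.
* **`align_by_truth()`** stands in for the short-to-long aligner, which the
  package deliberately does not run: each mate is assigned to one uniformly
  chosen same-strain long read that fully contains it, and mismatch counts
  are drawn Binomial(aligned bases, short + long error). It reproduces the
  primary-hit mass-splitting that makes per-read depth equal short-mass /
  long-redundancy, but it never misassigns a mate across strains. Real
  aligners do, at a rate governed by strain divergence versus the mismatch
  threshold; passing the mock therefore demonstrates the clustering
  machinery, not aligner robustness.

Passing tests on this generator show that the method recovers strains whose
signal matches its model (depth-separable, composition-identical). They do
not show robustness to real-data features the generator omits: structural
variation, chimeric reads, GC-dependent coverage bias, repeat-induced
mismapping, or strains at equal abundance (which are invisible to any
depth-based splitter).

## Downstream statistics

* **Core genes**: present in strictly more than 90% of genomes
  (`call_core`, threshold exposed). **Clade-specific genes**: one-sided
  Fisher exact test for presence enrichment per (ortholog, clade),
  Benjamini–Hochberg adjusted within each clade across orthologs, adjusted
  p < 0.05, *and* present in at least one clade genome and absent outside —
  significance alone never suffices.
* **pN/pS**: Nei–Gojobori potential sites (each codon position contributes
  the synonymous fraction of its three substitutions; stop-gaining changes
  are nonsynonymous; bacterial code 11 by default), observed variants
  classified by codon translation, and
  `pnps = (N_obs/N_pot) / ((S_obs + 1)/S_pot)` — the +1 on observed
  synonymous counts keeps the ratio defined. Variants count by presence by
  default; `weight_by_frequency = TRUE` weights by pooled allele frequency.
  Which of the two the original analyses used is not determinable from the
  methods text; presence-counting is the default here, and no claim of
  script-level equivalence is made.
* **dN/dS handling**: externally fitted values are filtered to
  `0.0001 < v <= 4` (both bounds as stated, boundary 4 kept), and
  `sample_concatenations()` draws 1000 sets of 25 distinct orthologs
  (uniform, without replacement within a set) for concatenated estimates.
* **FST**: Hudson's estimator in ratio-of-averages form per gene, with the
  standard finite-sample corrections and den = 0 sites skipped; a gene with
  no usable site raises an error rather than returning 0. The estimator
  choice follows current population-genomics practice for two-population
  allele-frequency data; it is the only estimator implemented.
* **ANI**: genome A is cut into non-overlapping 1-kb windows; each window
  is anchored in B by the first exact 31-mer among up to ten offsets and
  aligned globally to the anchored region (+/-100 bp pad); fragments with
  identity >= 0.90 and coverage >= 0.70 contribute; ANI is 100x their mean
  identity. This is a transparent fragment mapper, validated against
  mutation-log truth on substitution-only mocks — not a FastANI/dRep
  replacement for arbitrary real genomes.
* **Rank-sum test**: `wilcox.test` wrapper; exact enumeration when both
  samples are <= 8 without ties, otherwise the tie-corrected normal
  approximation with continuity correction.
* **IS flank density**: the window around a focal gene is
  `[start - 3000, start) U [end, end + 3000)` clipped to the contig; a
  feature counts at >= 1 bp overlap (exposed); densities divide by the
  flank actually available, so edge genes are not biased; the focal gene
  never counts itself. Transposases are recognised from annotation products
  (case-insensitive "transposase" / "insertion sequence") — upstream IS
  predictors are consumed, not reimplemented. Each element counts
  individually ("frequency of occurrence" read as per-element counts).
* **Plasmid filtering**: keep a contig iff target genes > 3, target-gene
  proportion > 0.30, length >= 5000 bp, coverage >= genome coverage / 3,
  plasmid-positive and phage-negative predictions (both consumed as boolean
  columns). Rejections carry the first failed rule; the outcome is
  order-independent because the rules are conjunctive.
* **Abundance**: `rpkg = reads / (kb of genome) / (Gb of metagenome)`; the
  same normalisation per gene for `gene_frequency`.

## Numerical choices and degenerate inputs

Internal coordinates are uniformly 0-based half-open; GFF3's 1-based
inclusive convention applies only at serialization. "Mismatch" always means
substitutions; indel bases are carried separately so mismatch thresholds
act on substitutions alone. Ties among equal-score recruitment hits break
by input order. Covariance ridges, EM tolerances and restarts are listed
above; empty alignment sets, reads without recruits (depth 0), genes
without variants (pN/pS 0 via the +1 correction) and monomorphic FST sites
are all defined, non-crashing cases, while contradictory inputs (alt ==
ref, end <= start, unknown ids) raise errors naming the offender.

## Validation problem sizes

The shipped validation runs five replicate three-strain communities
(100-kb ancestor; roughly 1200 long reads and 150k short-read pairs each),
a 12-point exhaustive bipartition oracle, 100 random CDSs against a
nine-mutation enumeration, 20 replicate 200-site two-population FST
simulations at planted 0.3, a 50-kb ANI mock, and fixture-based checks of
the classification and MGE rules. These sizes were chosen so the full suite
completes in minutes on a single CPU while leaving each statistical check
adequately powered.

## Known limitations

Strains at abundance ratios below `merge_depth_ratio` are reported as one
bin; composition contributes nothing for within-species strains by design;
the ANI mapper assumes mostly collinear genomes; the mock generator's
idealizations are listed above. The per-module command-line interface
(`inst/scripts/strainscope`) is a thin wrapper — the R functions are the
primary surface.
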