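---
title: "Methods: gene age, cold-stress response, and how the pipeline is verified"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene age, cold-stress response, and how the pipeline is verified}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthostress)
```

# The scientific question

Comparative cold-stress transcriptomics asks two linked questions. First,
which transcriptional responses to low temperature are shared across
species and which are lineage-specific — answered at the level of
orthogroups, since gene identifiers do not transfer across genomes. Second,
does a gene's evolutionary age predict its transcriptional plasticity —
are recently emerged, lineage-specific genes more likely to be
differentially expressed under stress than ancient, conserved ones? This
package implements both analyses over standard inputs (an OrthoFinder-style
orthogroup table, a rooted species tree with named internal nodes,
per-species count matrices with a sample sheet) and ships a synthetic-data
generator so that every stage can be verified against planted truth.

# Phylostratigraphic age assignment

A gene's age class (phylostratum) is defined through its orthogroup: the
presence set $P$ is the set of species contributing at least one gene, and
the orthogroup is assigned to the *smallest named clade containing
$\mathrm{MRCA}(P)$*, where the named clades form an ordered ladder of
internal nodes along the path from the root to the focal species (for
decapod work, a ladder like Metazoa > Bilateria > Protostomia > Ecdysozoa >
Arthropoda > Crustacea > Decapoda > family). Genes inherit their
orthogroup's stratum.

Assumptions and choices:

* **Presence means ≥ 1 gene.** Copy number, fragments and isoforms are not
  distinguished; the analysis is at gene level.
* **The ladder is explicit configuration**, an ordered list of node labels,
  not something inferred from a taxonomy service. It must be strictly
  nested along the root-to-focal path; `stratified_tree()` rejects anything
  else, which also makes ties impossible by construction.
* A named clade contains $\mathrm{MRCA}(P)$ exactly when it contains all of
  $P$. This equivalence is what the exhaustive test oracle uses — it checks
  clade containment directly for every presence subset of a 7-leaf tree and
  must agree with the implementation on all $2^7-1$ subsets containing the
  focal leaf.
* Orthogroups with no focal-species gene keep stratum `NA` rather than
  being dropped, so cross-species presence/absence summaries still see
  them.

The companion filter `select_tree_orthologs()` reproduces the usual
phylogenomic marker criteria: taxon occupancy ≥ 100% and ≥ 50% of species
single-copy, both configurable.

# The differential-expression caller

The caller is deliberately minimal and fully specified, so that its
behaviour is provable on synthetic data:

1. **Size factors** by median-of-ratios against the geometric-mean
   reference over genes with no zero counts, rescaled to geometric mean 1.
   If no such gene exists the caller falls back to total-count scaling with
   a warning.
2. **Fold change** on normalized condition means with pseudocount ½:
   $\mathrm{LFC} = \log_2\frac{m_{cold}+0.5}{m_{ctrl}+0.5}$. The
   pseudocount gives zero-safety with minimal bias at the expression levels
   where calls are made.
3. **Dispersion** per gene by method of moments,
   $\alpha_c = (v_c - m_c)/m_c^2$ within each condition, pooled with
   degrees-of-freedom weights and floored at $10^{-8}$. No shrinkage across
   genes — empirical-Bayes moderation is out of scope and the acceptance
   properties are calibration and power, not equality with any specific
   published caller.
4. **Wald statistic** LFC/SE with the delta-method standard error
   $\mathrm{SE}^2 = \frac{1}{\ln^2 2}\left(\frac{(m_1+\alpha m_1^2)/n_1}{(m_1+0.5)^2}
   + \frac{(m_2+\alpha m_2^2)/n_2}{(m_2+0.5)^2}\right)$,
   referred to a **t distribution with $n_1+n_2-2$ df**. The t reference is
   a deliberate design choice: with five replicates per condition a normal
   reference ignores the variance-estimation noise and inflates the null
   $p<0.05$ fraction to roughly 0.08; with the t reference the same
   simulation is calibrated (measured ≈ 0.046–0.051 at 2000 genes, 5+5).
5. **Expressed genes** (EGs) are those with normalized mean ≥ 1.0
   (configurable). Only EGs are tested and enter the BH adjustment; others
   report NA p-values and class NS. The EG set is also the denominator for
   all plasticity proportions and the default enrichment universe.
6. **Classes**: DEG at FDR < 0.05 and |LFC| > 1.5; HDEG at FDR < 0.01 and
   |LFC| > 2. Both cuts are strict inequalities; HDEG ⊆ DEG by
   construction.

Measured operating characteristics (from `scripts/acceptance.R`, also
asserted in the test suite): null $p<0.05$ fraction 0.042–0.057 across
seeds; with 10% of genes planted at |LFC| = 3, dispersion 0.1, 6+6
replicates: sensitivity ≈ 0.99, observed FDR ≤ 0.001, over 10 seeds.

# Cross-species sharing

A species' status in an orthogroup is lifted from its member genes: `up` if
at least one member is significantly up and none down, `down` symmetric,
`mixed` if both (counted as responsive — directional flows must not lose
these), `tested_NS` if members exist but none is significant, `absent`
otherwise. Because published Venn counts are ambiguous between "responsive
in exactly this species set" and "in at least this set", `sharing_counts()`
emits both readings for every non-empty subset, plus cumulative counts by
k. The Sankey export is the long (orthogroup, species, direction) table.

Representatives are the longest transcript per orthogroup × species with
ties broken lexicographically (deterministic); transcript lengths come from
a plain `gene_id, length` table rather than FASTA parsing. The conserved-
orthogroup PCA stacks all samples over conserved orthogroups, using
log2(x+1) expression and per-orthogroup z-scoring, so that species and
condition structure rather than expression scale drives the components;
component signs follow the largest-|loading|-positive convention.

# Co-expression modules

The network recipe is the classic weighted one: unsigned adjacency
$|\mathrm{cor}|^\beta$ (signed variant behind a flag), topological overlap
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$,
average-linkage clustering of $1-\mathrm{TOM}$, a **static cut** at height
0.99, minimum module size 30, and iterative merging of modules whose
eigengenes correlate above 0.75 (merge threshold 0.25). A static cut plus
eigengene merging replaces dynamic tree cutting: it is simpler, exactly
reproducible, and sufficient for planted-structure recovery; the cut height
default moved from the conventional 0.95 to 0.99 because TOM dissimilarity
concentrates near 1 at moderate powers and a lower static cut fragments
genuine modules. Soft-power selection sweeps β = 1..20 and returns the
smallest with scale-free fit R² ≥ 0.8 (equal-width connectivity bins —
quantile bins would make the bin occupancy constant by construction and the
fit meaningless); when no power qualifies, the best-fitting power is
returned with a warning, which is common and expected on strongly
module-structured data whose degree distribution is bimodal rather than
scale-free.

Module enrichment is an upper-tail hypergeometric test with the **network
genes as universe** (the actual sampling frame), BH across modules, and a
per-direction significance flag at FDR < 0.05 — the directional criterion is
unstated in common practice, so it is an explicit, documented default here.
Hub genes are ranked by intramodular connectivity (within-module TOM row
sums, self excluded, ties on gene ID), optionally restricted to annotated
genes, top 40 by default.

# Term enrichment

Flat hypergeometric enrichment (no ontology-graph propagation): terms are
gene sets, the universe defaults to the run's expressed genes (avoiding
detection bias toward highly expressed genes), terms with fewer than 3
universe genes are skipped, BH across tested terms. The cross-species
summary keeps terms significant (FDR < 0.05) in at least 3 species and
marks per-species direction (up/down/both) when enrichment was run per
direction.

# The age × plasticity trend

For each stratum: EG, DEG and HDEG counts over expressed genes, the
proportions DEG/EG and HDEG/EG, and each stratum's fold versus the pooled
proportion. "Progressively increasing toward younger strata" is made
assertable with a Cochran–Armitage trend test on (responsive,
non-responsive) counts with integer scores 1..S from oldest to youngest —
integer scores because the ladder is ordinal, not a branch-length scale.
The signed statistic is positive for increasing trends; the p-value is
two-sided normal; a separate strict-monotonicity flag reports the
descriptive pattern. The statistic squares to the classical chi-square
trend test and agrees with a permutation null (both asserted in the
suite). Measured calibration: 5.4% ± 0.6% rejection at nominal 5% over
5000 age-independent tables.

# What the synthetic generator emulates — and what it does not

`sim_config()` defaults mirror a multi-species cold-stress study at desk
scale: 6 species on a pectinate tree (5 nested strata), 2000 orthogroups
born mostly on the oldest stratum (1000/200/150/150/500), per-cell gene
counts 1 + Poisson(0.3), 5 control + 5 cold replicates, log-normal baseline
means (meanlog 4, sdlog 1.5), NB dispersion 0.1, size factors log-uniform
in [0.7, 1.4], response probability rising with youth
(0.05/0.08/0.10/0.15/0.20), planted |LFC| = 3, four 50-gene modules with
within-module correlation 0.6, and 40 annotation terms of which 4 are
enriched among responsive genes (70% of their members drawn from the
responsive set).

Module structure uses a per-module latent sample factor with per-gene
loadings calibrated so the within-module correlation of log2(x+1)
expression hits the configured value; the calibration uses the exact NB pmf
variance of log2(X+1) (a first-order delta approximation undershoots badly
at small means). Two generator-design consequences deserve emphasis:

* Module genes are drawn only from well-expressed (baseline mean ≥ 50),
  non-responsive genes. At low means, count noise hides the factor; for
  responsive genes the planted condition effect adds variance orthogonal to
  it. Both would silently attenuate the planted correlation — and both are
  faithful to reality, which is exactly why the planted benchmark excludes
  them.
* Median-of-ratios normalization partially absorbs the latent factors when
  module genes dominate the matrix (a compositional effect). Benchmarks
  therefore embed modules in a realistic background (10% of genes in
  modules).

What the generator does **not** emulate: GC/length biases, batch effects,
outlier samples, dispersion-mean trends, isoform switching, presence noise
in orthogroups beyond a simple loss-rate flag, and correlated evolution of
expression along the tree. Passing the planted-truth tests therefore shows
the pipeline's operations are correct and calibrated under clean
assumptions — not that real-data inference is free of the biases above.

# Benchmark problem sizes

The test suite and `scripts/acceptance.R` use: the full $2^7-1$ presence
enumeration on a 7-leaf tree; 2000 planted orthogroup births; 2000-gene
null and power DE simulations (5+5 and 6+6 replicates, 10 seeds for
power); exhaustive hypergeometric enumeration for all $N \le 20$ plus spot
checks at $N = 50$; 300 orthogroups × 5 species for sharing-count
enumeration; module recovery with two planted 50-gene modules among 1000
genes at 15+15 replicates, soft power 7, five seeds (correlation-network
recovery is information-limited: with 10 samples the sampling error of a
correlation estimate, about $1/\sqrt{n-3}$, is half the planted correlation
itself, so the benchmark uses a sample size at which the method can
possibly succeed — consistent with standard guidance that co-expression
networks want 15+ samples); 200 + 2000 null tables and 20 gradient
replicates for the trend test; and a 350-orthogroup end-to-end run executed
twice for byte-level determinism. These sizes keep the whole verification
under a few minutes on one CPU while preserving the structure of the
full-scale analysis.

# Known limitations

* Gene-level DE calls are not guaranteed to match shrinkage-based callers
  on real data; the contract is calibration and power on NB data, not
  caller equality.
* The orthogroup table is held in memory with R lists; the design targets
  10²–10⁵ orthogroups, not millions.
* One focal species (one stratum ladder) per pipeline run; multi-focal
  studies run the pipeline once per focal species with its own ladder.
* The trend test treats genes as independent; co-regulation inflates its
  effective sample size on real data, so its p-values are cleanest on the
  per-gene-independent synthetic regime it is verified under.
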