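# orthostress

Comparative cold-stress transcriptomics across species: how does a gene's
evolutionary age relate to how strongly it responds to low temperature?

Ectothermic aquaculture species (shrimp, crabs, crayfish) suffer real
production losses under cold stress, and single-species RNA-seq studies
cannot separate lineage-specific responses from conserved ones. This package
implements the comparative pipeline such studies need, end to end:

1. **Phylostratigraphy** — assign every orthogroup (and every focal-species
   gene) an evolutionary age. For an orthogroup with species-presence set
   *P* on a rooted species tree, the age is the smallest named clade
   containing MRCA(*P*), taken from an ordered ladder of named internal
   nodes (e.g. Metazoa > Bilateria > … > Decapoda) along the root-to-focal
   path.
2. **Differential expression** — a self-contained negative-binomial caller:
   median-of-ratios size factors, per-gene method-of-moments dispersion
   pooled within condition, a Wald statistic on
   log2((m_cold + ½)/(m_ctrl + ½)) with a delta-method standard error and a
   t reference (df = n₁+n₂−2), BH FDR. Genes are classed **DEG**
   (FDR < 0.05 and |log2FC| > 1.5) or **HDEG** (FDR < 0.01 and |log2FC| > 2,
   a strict subset), with direction.
3. **Cross-species sharing** — lift gene-level calls to orthogroup level
   (up / down / mixed / tested_NS / absent per species), count k-way
   sharing for Venn/upset and Sankey views, select longest-transcript
   representatives, and run a PCA of all samples over conserved
   orthogroups.
4. **Co-expression modules** — soft-threshold adjacency |cor|^β, topological
   overlap, average-linkage clustering with a static cut and eigengene
   merging, hypergeometric module-DEG enrichment, and hub ranking by
   intramodular connectivity.
5. **Term enrichment** — flat hypergeometric enrichment against an
   annotation table, plus a summary of terms shared across species.
6. **Age × plasticity** — per-stratum EG/DEG/HDEG counts and proportions and
   a Cochran–Armitage trend test (integer scores, oldest → youngest) that
   makes "younger genes are more transcriptionally plastic" a testable
   statement.
7. **Synthetic data** — a generator that plants gene ages on tree branches,
   NB counts with age-dependent condition effects, latent-factor
   co-expression modules and enriched annotation terms, with truth tables
   for every planted quantity.

## Worked example

```r
library(orthostress)

cfg <- list(
  seed = 7, out_dir = "run", simulate = TRUE,
  focal_species = "sp1", strata = paste0("stratum_", 1:5),
  sim = list(strata_births = c(stratum_1 = 200L, stratum_2 = 60L,
                               stratum_3 = 50L, stratum_4 = 40L,
                               stratum_5 = 100L)))
run_stage("all", cfg)

read.delim("run/plasticity.tsv", comment.char = "#")
#>     stratum n_eg n_deg n_hdeg   prop_deg  prop_hdeg
#> 1 stratum_1  263    13     12 0.04942966 0.04562738
#> 2 stratum_2   84     7      6 0.08333333 0.07142857
#> 3 stratum_3   65     4      4 0.06153846 0.06153846
#> 4 stratum_4   50     7      5 0.14000000 0.10000000
#> 5 stratum_5  130    24     23 0.18461538 0.17692308

read.delim("run/trend.tsv", comment.char = "#")
#>   metric statistic       pvalue  direction monotone
#> 1    deg  4.357977 1.312699e-05 increasing    FALSE
#> 2   hdeg  4.227183 2.366347e-05 increasing    FALSE
```

The generator planted response probabilities rising from 0.05 (oldest
stratum) to 0.20 (youngest); the recovered DEG proportions climb from ~0.05
to ~0.18 and the trend test calls the increase (z ≈ 4.4, p ≈ 1e-5). The
`monotone` flag is strict non-decrease of the observed proportions — here a
single sampling dip between strata 2 and 3 turns it off while the tested
trend is still firmly increasing.

The same run writes per-species DE tables (`de_sp*.tsv`), orthogroup
sharing and Venn/Sankey tables, PCA coordinates, co-expression modules with
enrichment and hubs for the focal species, term enrichment, and a
`manifest.json` of MD5 checksums; rerunning the same config reproduces every
file byte for byte.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/orthostress.R all --config run.yaml
```

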