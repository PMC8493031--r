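# mangroveGBM

Tools for studying the evolution of **gene body methylation (gbM)** — CG-context
cytosine methylation inside coding regions, without CHG/CHH enrichment — across
a paired phylogenetic design of three mangrove species and three terrestrial
relatives with a grass outgroup, and for relating evolved and salt-induced gbM
gains to the stability of gene expression under stress. It is aimed at plant
epigenomics researchers who have per-cytosine bisulfite counts, gene models,
ortholog clusters and expression matrices, and want the full chain from site
calls to convergence and robustness statistics in one tested pipeline.

## What it computes

Per sample, a cytosine with $m$ methylated of $n$ reads is methylated when
$P(X \ge m \mid X \sim \mathrm{Bin}(n, 1-c))$ survives Benjamini–Hochberg
control at FDR 0.05, with $c$ the bisulfite conversion rate; replicate calls
are filtered at ≥ 3 reads and kept when ≥ 2 replicates agree. A gene is
**BM** (body-methylated) when its CDS methylated-site count is binomially
enriched over the species' genome-wide basal level in CG but not CHG/CHH
(classes mCHH > mCHG > BM > UM by precedence, ≥ 20 sites per consulted
context). Ancestral BM/UM states on the fixed seven-taxon tree come from
hierarchical Fitch parsimony with the outgroup breaking root ties; per-branch
gain and loss rates are changes divided by the parent node's UM or BM count.
A cluster is **convBMM** (convergently body-methylated in mangroves) when the
root is UM and ≥ 2 of the 3 mangrove leaves are BM. Salt-stress analysis
adds per-cytosine binomial GLMs (`methylated, unmethylated ~ treatment +
individual`) for DMPs, condition-wise reclassification for DMGs (UM↔BM
transitions), the stratified convBMM-vs-others contingency analysis with its
`100 · changed / unchanged` percentage, and the expression-robustness
statistic $|e_1 - e_2|$ on z-normalised log10 mean RPKM. Simulators generate
every input with planted ground truth.

## Worked example

Ancestral reconstruction and convergence for one ortholog cluster in which
all three mangroves are body-methylated and nobody else is:

```r
library(mangroveGBM)
lv <- c(Ama = "BM", Rap = "BM", Sal = "BM",
        Mgu = "UM", Ptr = "UM", Egr = "UM", Osa = "UM")
a <- inferAncestralStates(lv)
a
#> AncestralAssignment for 1 cluster(s); 1 root tie(s) resolved by the outgroup
classifyConvergence(a)
#>   cluster_id root_state   label n_bm_mangrove n_bm_nonmangrove conservation_group
#> 1   cluster1         UM convBMM             3                0                  3
```

The pair ancestors are all ambiguous under Fitch, so the root tie falls to
the rice state (UM) and the three mangrove BM states are three independent
terminal gains — the cluster is convergently body-methylated in mangroves.

A full simulated salt experiment, from cytosine counts to the stratified
contingency analysis (1,000 genes, convBMM genes gaining gbM under salt at
probability 0.12 vs 0.01 for the rest):

```r
sim <- simulateSaltExperiment(nGenes = 1000, seed = 42)
dmg <- callDMGs(sim$control, sim$treated, sim$genes)
table(dmg$status)
#>   excluded gained_gbM   lost_gbM  unchanged
#>          1         26          4        969
dmgContingency(dmg, data.frame(gene_id = sim$truth$gene_id,
                               label = sim$truth$label))
#>   stratum   group unchanged changed pct_dmg chi2_statistic       chi2_p
#> 1      BM convBMM        19       1     5.3      0.4247005 5.146009e-01
#> 2      BM  others       121       3     2.5      0.4247005 5.146009e-01
#> 3      UM convBMM        78      19    24.4    101.6004012 6.793153e-24
#> 4      UM  others       751       7     0.9    101.6004012 6.793153e-24
```

Among baseline-unmethylated genes, 24.4% of convBMM genes gained gbM under
salt against 0.9% of the others (χ² p ≈ 7 × 10⁻²⁴) — the planted enrichment
of stress-induced gains in convergently methylated genes, recovered from raw
counts by the full pipeline. The BM stratum, where nothing was planted,
stays non-significant.

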