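---
title: "Methods: gene body methylation evolution and stress response"
author: "mangroveGBM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene body methylation evolution and stress response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangroveGBM)
```

## The problem

Gene body methylation (gbM) is CG-context cytosine methylation concentrated in
the coding regions of a gene, without accompanying CHG or CHH methylation.
Across a paired design of three mangrove species and three terrestrial
relatives (plus a grass outgroup), the package asks three questions: where on
the phylogeny was gbM gained or lost; whether those gains are convergent in
the mangrove lineages; and whether gbM — induced by salt stress or acquired
during evolution — correlates with buffered (less variable) gene expression
under stress. Every analysis stage is reproduced here from per-cytosine read
counts upward, with simulators that generate all inputs with known truth.

## Site-level methylation model

A bisulfite library reports, per cytosine, methylated and unmethylated read
counts. Failed bisulfite conversion makes an unmethylated cytosine look
methylated with probability $1 - c$, where $c$ is the conversion rate
estimated from a known-unmethylated control genome (chloroplast or spiked
lambda): `estimateConversionRate()` pools control counts, so the estimate is
invariant to how reads distribute over control sites. `callSites()` tests
each site one-sidedly, $P(X \ge m \mid \mathrm{Bin}(n, 1-c))$ — "methylated"
only ever means an excess over conversion noise — and applies
Benjamini–Hochberg (BH) control at `alphaFdr` (default 0.05) across **all**
cytosines of a sample jointly. Contexts (CG, CHG, CHH; H = A, C or T) are
separated afterwards, when levels are computed, not in the BH pool.

Replicate handling is *filter, then vote* (`consensusReplicates()`): within
each replicate only cytosines covered by at least `minSiteReads` (default 3)
reads are eligible, and a site is kept when at least two eligible replicates
agree on its status, taking the majority when they disagree. A 2–2 tie (an
even replicate count) drops the site. Applying the coverage filter per
library before the consistency vote makes the two rules composable and is the
natural reading of discarding low-coverage observations per library. Pooled
counts over eligible replicates are carried forward; pooling (rather than
averaging per-replicate levels) is a configurable-by-construction choice —
all downstream code consumes the consensus table, so an alternative pooling
can be swapped in at that interface.

## Gene classification

`aggregateGeneCounts()` counts, per gene and context, methylated ($m$) and
total ($n$) consensus cytosines falling inside the merged CDS intervals of
the gene's primary transcript. Intervals are 1-based and closed (the cytosine
report convention; BED input is converted on read), boundary positions
included. Cytosines on either DNA strand count: the underlying protocols do
not restrict gbM to the coding strand, and the choice is isolated in this one
function.

Each species provides its own basal levels — the genome-wide proportion of
methylated cytosines per context (`computeBackground()`). `classifyGenes()`
tests $P(X \ge m \mid \mathrm{Bin}(n, \mathrm{basal}))$ per context, adjusts
BH across genes within each context, and assigns one of four classes with a
CHH > CHG > CG precedence:

* **mCHH** — CHH q-value < `alphaFdr`;
* **mCHG** — CHH not significant, CHG significant;
* **BM** — CHH and CHG not significant, CG significant;
* **UM** — nothing significant.

The precedence is what makes the four definitions (each phrased as
"significant here, not significant below") mutually exclusive. A context is
only trusted when the gene carries at least `minGeneSites` (default 20)
cytosines of it; the rule applies to every context the decision actually
consults, so a gene with ample CG sites but five CHH sites is
*unclassifiable* (its CHH test is unreliable and CHH is always consulted
first), while an under-covered CHG context is irrelevant for a gene whose
CHH test already fires. This per-consulted-context reading is the
conservative interpretation of the sufficient-cytosine rule.

## Ancestral states, gains/losses, convergence

The seven-taxon tree `(Osa,((Ama,Mgu)P1,((Rap,Ptr)P2,(Sal,Egr)P3)Ninner)Root)`
is packaged as the default (`defaultSpeciesTree()`); topology and roles are
ordinary inputs. `inferAncestralStates()` performs hierarchical parsimony on
the six ingroup leaves: Fitch candidate sets built bottom-up (intersection
when non-empty, otherwise union) over P1, P2, P3, Ninner and Root. When the
root's candidate set remains ambiguous, the outgroup (rice) leaf state is
adopted as the ancestral state — the outgroup acts purely as a tie-breaker
and its branch never enters the change counts. A top-down pass then gives
every internal node its parent's state when that state is among its
candidates, otherwise its sole candidate; propagating the parent state into
ambiguous children minimises changes on the entering branch and makes the
gain/loss bookkeeping deterministic. The test suite checks, for all $2^7$
leaf patterns against exhaustive enumeration of the $2^5$ internal
labelings, that the resolved assignment attains the minimum change count
(restricted to the rice-state root in tie cases).

`countGainLoss()` tallies per-branch UM→BM gains and BM→UM losses over
clusters, plus the UM/BM counts at each parent node; `gainLossRates()`
divides by those parent counts, which is the maximum-likelihood estimate of
a per-branch change probability. Rates are undefined (NA) on a zero
denominator.

`classifyConvergence()` labels a cluster **convBMM** when the reconstructed
root state is UM and at least two of the three mangrove leaves carry the
derived BM state; **convBMN** is the mirror for the non-mangrove species;
clusters BM in at least two species without either condition are
**non-convBM**. "Ancestral state" is read as the ingroup root (the
group-specific ancestor is the obvious alternative; the root reading is the
one consistent with a single shared ancestral UM state for both groups).
One leaf pattern out of 128 — both of two full pairs BM, third pair and
outgroup UM, root tie resolved to UM — satisfies the convBMM and convBMN
conditions simultaneously; the classifier then prefers the mangrove label,
a documented deterministic precedence. The conservation group is simply the
number of BM species among all seven leaves. `siteConvergence()` applies the
identical machinery to the methylation status of CG sites conserved across
all species; clusters containing mCHG/mCHH genes are expected to be
excluded upstream (a pre-pass on the classification tables), mirroring the
restriction of the evolutionary analysis to the BM/UM axis.

## Salt-stress response

**DMPs.** `callDMPs()` fits, per cytosine covered by at least `minDmpReads`
(default 5) reads in *every* one of the six libraries (the strictest reading
that keeps the design balanced), a binomial-logit GLM of methylated vs
unmethylated counts on treatment plus replicate index. The replicate index
1..3 is shared across conditions — a six-level sample identity would be
confounded with treatment, so the 3-level coding is the only one that leaves
the treatment effect estimable. The Wald p-value of the treatment
coefficient is BH-adjusted across sites; a likelihood-ratio test replaces
Wald when the fit flags quasi-separation (non-convergence or an absurd
coefficient), and sites that are entirely unmethylated or entirely
methylated across all six libraries are reported degenerate with p = 1.
The per-site fits use `stats::glm.fit` with a single precomputed design
matrix — the same IRLS as `glm()`, minus the per-site formula machinery.

**DMGs.** `callDMGs()` runs the full site-calling → consensus →
classification chain per condition, each condition with its own genome
background, and compares classes: UM→BM is a gained-gbM gene, BM→UM a lost
one; genes mCHG, mCHH or unclassifiable in either condition are excluded.

**Contingency analysis.** `dmgContingency()` stratifies genes by their
control-condition class (BM or UM), crosses convBMM membership with
changed/unchanged status, reports `100 * changed / unchanged` (one decimal)
as the percentage of DMGs, and attaches an uncorrected Pearson χ² p-value.
The changed/unchanged ratio is the only formula consistent with all eight
published stratum percentages, so reporting follows that arithmetic; χ²
without continuity correction is the common default for large contingency
tables and the correction would be immaterial at these counts.

## Expression robustness

`computeRPKM()` is the standard $10^9 \cdot \mathrm{count} / (\mathrm{length}
\cdot \mathrm{librarysize})$, discarding genes with no reads in any library.
`expressionDifference()` fixes the order of operations as: average replicate
RPKM within condition → $\log_{10}$ → drop genes with $\log_{10}$ RPKM ≤ 0.01
in either condition → z-normalise each condition across genes (sample SD) →
$|e_1 - e_2|$. The source phrasing is ambiguous about where the log and the
filter sit; log-of-mean is chosen because the filter itself is phrased on
$\log_{10}$ RPKM, and the z-normalisation makes the statistic invariant to
positive affine maps of either condition's log-mean vector (so the SD
convention cancels in group comparisons). `compareExpressionGroups()` runs
pairwise two-sided Mann–Whitney U tests with medians and interquartile
ranges per category. Differential-expression calling is consumed, never
fitted: `filterDEGs()` applies FDR < 0.05 and ≥ 2-fold change to an external
table.

## The simulators

`simulateMethylome()` emulates the statistical structure the callers see,
not reads: genes laid head to tail on one chromosome with Poisson numbers of
cytosines per context (mean 40, comfortably above the 20-site floor), plus
free-standing intergenic cytosines; a planted fraction (default 0.15,
matching the observed abundance of body-methylated genes in mangroves) of
genes whose CG sites are truly methylated with probability 0.8; background
site-methylation probabilities CG 0.15, CHG 0.10, CHH 0.05; coverage
Poisson(20) per replicate (the experiments averaged ~25×); conversion rate
0.995; methylated sites yield methylated reads at rate
$0.8 + 0.2(1 - c)$, unmethylated ones at $1 - c$. Site truth is drawn once
and shared across replicates, as a plant's methylome is.

`simulateTreeStates()` evolves BM/UM down the tree from a root that is BM
with probability 743/7343 (the ancestrally body-methylated fraction of the
cluster set), flipping with per-branch gain/loss probabilities, and forces
convergent BM into two (probability 0.68, the observed two-vs-three split)
or three mangrove leaves in a fraction of root-UM clusters.

`simulateSaltExperiment()` adds the treatment axis: baseline-UM genes gain
gbM under salt with probability 0.12 when labelled convBMM and 0.01
otherwise (the planted contrast behind the enrichment analysis), and
expression counts are Poisson-gamma with a per-gene $\log_{10}$ treatment
response whose SD is 0.05 for genes body-methylated under treatment
("buffered") and 0.3 otherwise — roughly two-fold swings for unbuffered
genes and a near-flat response for buffered ones, consistent with the
overall transcriptional robustness of these species; a genome-wide ten-fold
response regime would not be. Because each condition is z-normalised
separately, unequal response variances leak a little baseline expression
into $|e_1 - e_2|$; the chosen SDs keep that leakage realistic rather than
eliminating it.

What the simulators deliberately omit: read-level bisulfite errors beyond
the conversion rate, chromosome-scale genome structure, transposable-element
evolution, linkage between neighbouring cytosines, and any coupling between
methylation and expression *level*. Passing recovery tests therefore shows
the inference machinery is correct under the stated generative model, not
that real methylomes satisfy that model.

## Numerical and testing choices

* Exact Mann–Whitney null for pooled samples ≤ 12 without ties, tie-corrected
  normal approximation otherwise: exactness where it is cheap.
* Binomial tails via `pbinom`, BH via `p.adjust`, χ²/Fisher/hypergeometric
  via their base R implementations — the package wraps, never re-derives,
  standard distributions; tests check the wrappers against independent
  enumeration and summation oracles.
* Degenerate inputs are explicit: zero-margin 2×2 tables give statistic 0 and
  p = 1 with a warning; empty contexts and zero denominators are errors or
  NA, never silent coercions.
* Problem sizes in the test-suite and acceptance-script simulations — 2,000
  genes for classifier recovery, 2,000 sites × 50 replicates for the null
  false-positive checks, 800 genes × 100 replicates for the
  induction-enrichment recovery, 600 genes × 50 replicates for expression
  buffering — are the package's chosen desk-scale study conditions: large
  enough that the planted effects dominate Monte-Carlo noise, small enough
  to re-run routinely.

## Known limitations

Genome-scale published counts (absolute numbers of gains, DMPs, DEGs)
depend on the deposited sequencing data and are not reproducible from
simulations; the suite covers the corresponding *properties* (FDR control,
recovery, enrichment detection) instead. The parsimony reconstruction is the
uniform-cost Fitch minimum with a fixed tie policy — no probabilistic
(rate-matrix) reconstruction is attempted. Conserved-CG-site homology is an
input; no alignment is performed. DMR (region-level) calling, promoter/TE
methylation classes and negative-binomial differential expression are out of
scope.
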