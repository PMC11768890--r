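---
title: "Methods: dissecting compound interactions in a botanical extract with multi-omics networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting compound interactions in a botanical extract with multi-omics networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytointeract)
```

## The scientific problem

Botanical extracts are mixtures. When a water extract of *Centella
asiatica* (CAW) shows neuroprotective bioactivity, the effect may come
from single constituents, from a compound class, or from interactions
between classes. The experimental design this package analyses compares
five arms in cultured neurons: a vehicle control, the extract's four
pentacyclic triterpenes combined (TT), its eight mono- and
di-caffeoylquinic acids combined (CQA), the twelve compounds together
(TTCQA), and the full extract (CAW), each compound dosed at the
concentration it reaches in a 50 µg/mL extract solution. Two untargeted
molecular readouts are collected on separate culture batches: bulk
RNA-seq (n = 8 per arm) and a targeted metabolome of 192 annotated
metabolites (n = 10 per arm).

The analysis asks four questions, each implemented as a pipeline stage:

1. Which genes and metabolites does each arm change (differential
   analysis)?
2. For each responsive gene, is the combination effect the *sum* of the
   two class effects (additive), *more* (positive/synergistic), or
   *less* (negative/antagonistic)?
3. Which co-expression and co-abundance modules respond, and how do
   their eigenfeatures behave across arms?
4. Do the responsive genes and metabolites of an arm sit close together
   in a knowledge network (composite metabolite–protein network,
   community detection, PPI shortest-path permutation test)?

No raw data from the motivating experiment is publicly deposited, so the
package ships a synthetic-data generator with planted, exported ground
truth; every stage is validated by recovering what was planted.

## Differential analysis

Counts are filtered (a gene must have ≥ 10 counts in *every* sample),
normalized by trimmed-mean-of-M-values (TMM: 30 % trim on M-values, 5 %
on A-values, inverse-asymptotic-variance weights, reference sample
chosen by the upper-quartile rule), and transformed to
`log2((count + 0.5) / (effective library + 1) * 1e6)`. A lowess trend of
the square-root residual standard deviation against mean log-count
yields per-observation precision weights (inverse fourth power of the
fitted trend), which feed a weighted least-squares model per gene with
the control as reference. Residual variances are moderated by an
empirical-Bayes inverse-chi-square prior whose hyperparameters (prior df
$d_0$, prior scale $s_0^2$) come from method-of-moments estimation on
the log variances; the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and moderated t statistics
use $d + d_0$ degrees of freedom. When the observed variances show no
excess spread beyond chi-square sampling noise the prior df is infinite
and every variance is pooled to the mean. All per-arm tables are
Benjamini–Hochberg adjusted at FDR 0.05. The test suite cross-checks the
TMM factors against edgeR and the moderation hyperparameters against
limma on shared input; these packages are oracles there, not
dependencies of the implementation.

Metabolite abundances are median-normalized per sample (divide by the
sample median, multiply by the grand median), log2 transformed, and
Pareto scaled (centred, divided by the square root of the standard
deviation — the divisor that MetaboAnalyst-style workflows use to keep
large fold changes influential without letting them dominate). Each arm
is compared to control by a pooled-variance t-test per metabolite with
BH adjustment across the 192 metabolites within each arm. A metabolite
that is constant after normalization is set to a zero row with a
warning rather than erroring, so a single degenerate feature cannot
abort a run.

## Interaction classification

For every gene differentially expressed in at least one of TT, CQA, or
TTCQA, the interaction contrast is

$$c = \beta_{TTCQA} - (\beta_{TT} + \beta_{CQA}),$$

whose reference-coding identity on balanced data is
$\bar y_{TTCQA} - \bar y_{TT} - \bar y_{CQA} + \bar y_{Ctrl}$ (verified
against that brute-force form in the tests). The contrast's standard
error comes from the fitted coefficient covariance; its p-values are
BH-adjusted *over the eligible genes only*, and a gene is classed
positive (synergistic) when $c > 0$ at q ≤ 0.05, negative
(antagonistic) when $c < 0$ at q ≤ 0.05, and none (additive) otherwise.
Restricting to eligible genes and requiring contrast significance were
design choices: significance (not mere sign) avoids classifying noise on
genes whose three coefficients are all near zero, and 0.05 FDR matches
the convention used everywhere else in the pipeline. Each record also
receives a descriptive category from its status transitions (a parent
effect *neutralized* — parent significant, combination not; *diminished*
— same sign, smaller, still significant; *new* effects absent from both
parents), mirroring how combination effects are usually narrated.

The DEG-overlap accounting reports the fraction of parent-arm DEGs
retained in the combination, combination-novel DEGs and their retention
in the full extract, parent DEGs lost in the combination but restored in
the extract, and the four-way common set.

## Co-expression and co-abundance modules

Both layers use the same machinery. Counts enter through a
log-CPM variance-stabilizing transform whose per-sample scale is
estimated by median-of-ratios size factors — with strong planted
co-expression, total-count normalization leaks module signal into every
gene's profile, while the median of per-gene ratios anchors on the
unperturbed majority. Metabolites enter through the normalization above.

The adjacency is $a_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta}$ with
$\beta = 12$ for both layers (a signed variant is available;
unsigned is the default because only the correlation magnitude, not its
sign, should decide module co-membership here). `pick_soft_threshold()`
reports the scale-free fit $R^2$ (log–log regression of the
connectivity distribution over equal-width bins) and mean connectivity
per candidate power, for checking that choice. The topological overlap

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj}$$

is computed by matrix multiplication and checked against a triple-loop
oracle to 1e-10. Modules come from average-linkage clustering of
$1 - \mathrm{TOM}$ cut at 99 % of the merge-height *range* (soft
thresholding at power 12 compresses dissimilarities toward 1, so a
fraction of the maximum would cut inside module branches), with two
refinements when the data matrix is available: a candidate module must
be *coherent* — its first principal component has to explain at least
1.5 times the Marchenko–Pastur expectation
$(1 + \sqrt{m/n})^2 / m$ for a random cluster of its size, which
removes chance aggregations of unstructured features at any module
size — and unassigned features are rescued into the module whose
eigenfeature they correlate with at $|r| \ge 0.5$. Minimum module sizes
are 30 genes and 5 metabolites; label 0 is unassigned.

Eigenfeatures are the first right singular vectors of the row-
standardized module submatrix (unit norm, sign-aligned to the module
mean profile), kME is the feature–eigenfeature correlation, kWithin the
within-module adjacency degree. Treatment effects on a module are tested
by a one-way fit of its eigenfeature on the five arms with Tukey HSD
across all pairs, keeping the four versus-control comparisons and
BH-adjusting across modules × comparisons. With two groups this reduces
exactly to the pooled t-test (asserted in the suite). Unassigned
(label 0) features are excluded from eigenfeature testing. Under this
Tukey-plus-FDR procedure the analytic power to detect a 2-standard-
deviation eigenfeature shift at n = 8 is about 0.72, reaching ~0.95 at
3 standard deviations; the tests assert those derived rates rather than
an optimistic round number.

## Enrichment

Over-representation is the upper-tail hypergeometric probability
$P[X \ge k]$ of drawing $k$ annotated features in a query of size $n$
from a universe of $N$ with $K$ annotated, BH-adjusted across the tested
sets. The universe is every feature that survived the count filter (or
all 192 metabolites); sets overlapping the query in fewer than 2
features are reported but not tested. The implementation is checked
against exhaustive enumeration of all $\binom{N}{n}$ draws for small
universes and against the closed form 76/15504 on a worked example.

## Knowledge-network integration

Per arm, seed genes are its DEGs and seed metabolites its DAMs plus all
members of metabolite modules with a significant eigenmetabolite shift
for that arm (metabolite seeds are deliberately generous because
individual-metabolite tests are few and underpowered). The scored PPI
edge list is thresholded at 400 on the 0–1000 confidence scale;
duplicate undirected edges keep the maximum score. The primary PPI
subnetwork is induced on the seed genes; where it is disconnected, a
minimum-network heuristic repeatedly joins the two largest
seed-containing components through the shortest connecting path in the
full graph (ties: fewer added nodes, then lexicographic path names) as
long as a path of at most 3 edges exists. This is a Steiner-tree-style
approximation — the exhaustive optimum is exponential — and the suite
bounds its connector count by twice the brute-force optimum on small
graphs. The metabolite–gene bipartite layer and a secondary PPI over the
partner genes are built the same way, and the three layers compose on
shared gene nodes, with per-edge layer tags and per-node roles.

Communities come from the Walktrap algorithm (4-step random walks,
agglomeration cut at maximum modularity) via igraph; random-walk
distances are computed exactly from the transition matrix, so the
partition is deterministic. Only communities containing at least one
seed gene *and* one seed metabolite are analysed further — they are the
places where the two omics layers meet — and each is enriched over all
its gene nodes, seeds and connectors alike. Arms are then compared by
shared mixed-community seed genes and shared enriched pathways.

## Network proximity

For each arm, the mean unweighted shortest path among its DEGs in the
thresholded PPI is compared with 1000 uniform random node sets of the
same size (unmatched for degree, following the literal "randomly
distributing the same number of genes"; a degree-matched null is a
possible extension, not a default). Unreachable pairs are excluded from
the mean and counted. The one-sided empirical p-value uses the add-one
correction $p = (1 + \#\{\bar d_{perm} \le \bar d_{obs}\})/(B + 1)$,
which keeps it super-uniform under the null; calibration is verified by
simulation (type-I error within 0.05 ± 0.02 over 400 replicates).

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the tests and the acceptance script.

**Expression.** 2,000 genes × 5 arms × 8 samples. Counts are negative
binomial with $\mathrm{Var} = \mu + \phi\mu^2$; gene dispersions are
gamma-distributed around `nb_dispersion = 0.05` (shape 10 — a typical
bulk-RNA-seq spread), baselines uniform on log2 means 4–10, and
per-sample library factors uniform on 0.7–1.4. Half the genes belong to
five equal planted modules driven by per-module, per-sample standard
normal latent factors; loadings are calibrated against the expected
NB log-scale noise so within-module correlations land near
`module_cor = 0.7`.

**Planted effects.** Interaction classes (10 % additive, 6 %
synergistic, 4 % antagonistic, 80 % null) are assigned to *background*
genes only: a module loading at correlation 0.7 inflates a member
gene's residual variance about threefold, which would entangle the
per-gene interaction-recovery task with the module-recovery task, so
the two planted structures are kept disjoint and modules get treatment
behaviour through their latents instead. Effect magnitude is 1 log2
unit; the combination coefficient is the parent sum plus 0, +1, or −1
by class; the extract coefficient equals the combination's, with an
extra ±1 effect on 5 % of genes to emulate compounds absent from the
defined panels. Module-level shift patterns are additive in the
contrast sense (the combination shift always equals the sum of the
parent shifts) so module membership never changes a gene's planted
class; they act on the latent factor, giving members graded effects of
roughly loading × shift — which reproduces the realistic situation
where only part of a responsive module crosses the DE threshold.

**Metabolome.** 192 log-normal metabolites × 5 arms × 10 samples,
residual sd 0.35 on the log2 scale, three planted modules covering 65 %
of features (the first amino-acid-enriched), planted shifts on 15 % of
background metabolites with the same class machinery.

**Knowledge graph.** A preferential-attachment backbone (m = 2) over
the gene universe with uniform scores 150–999, densified inside planted
modules and inside co-regulated groups — genes sharing a planted effect
signature, and arm-level responsive sets — with scores 400–999, so
functional relatedness survives the confidence filter and responsive
gene sets are network-proximal, as co-regulated pathway members are in
a real PPI. Each planted module spawns one pathway set with 60–80 %
overlap plus random decoys; each planted metabolite module links to the
genes of one expression module.

**What passing tests do and do not show.** The generator plants linear,
homogeneous-magnitude effects, Gaussian latents, and exact class
arithmetic. Recovery under these conditions demonstrates the pipeline's
correctness and calibration, not its power on real data, where effect
sizes are heterogeneous, modules overlap, dispersion is
expression-dependent in more complex ways, and the knowledge graph is
incomplete and biased. The headline counts of the motivating experiment
are not reproduction targets for the same reason: its raw data are not
public, and absolute DEG counts depend on the realized data.

## Numerical and operational choices

- Problem sizes in the tests and acceptance script: 20 generator seeds
  for the interaction-recovery and null-pipeline studies, 500-gene
  module-recovery matrices, 20-node oracle adjacencies, 400-replicate
  proximity calibration at 1000 permutations each. These sizes give
  stable rates while keeping a full run in minutes on one core.
- The module-recovery benchmark uses an effect-free configuration
  (`effect_size = 0`): with treatment effects on, genes sharing a
  planted effect signature form genuine treatment-driven co-expression
  clusters, which the detector correctly finds but which the planted
  module labels would score as errors. The pipeline summary therefore
  reports both the global adjusted Rand index and the index restricted
  to planted-module features.
- Zero residual variances are floored at machine epsilon with a
  warning before moderation; a zero-overlap enrichment reports p = 1;
  graphs with fewer than 3 nodes form a single community; an all-`ns`
  eligibility set yields an empty, well-typed record table.
- One global seed derives all per-stage seeds, so the whole pipeline is
  reproducible from a single integer and stages can be re-run
  independently from their predecessors' files.

## Known limitations

- The minimum-network heuristic is an approximation; on adversarial
  graphs it can add up to twice the optimal connector count.
- The static-plus-coherence module cut emulates, but is not, the
  dynamic hybrid tree cut; very close or nested modules may merge.
- Transcriptome and metabolome come from different culture batches by
  design, so integration is knowledge-based only; no data-driven
  cross-omics correlation is attempted, and conclusions inherit the
  incompleteness of the pathway and interaction annotations.
- Compound molar masses in the shipped panel are reference constants
  supplied with the package; two printed molarities in the motivating
  panel (madecassic acid, 3,4-diCQA) differ from the mass/molar-mass
  arithmetic by one unit in the last digit, and the panel validator
  reports rather than hides such discrepancies.
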