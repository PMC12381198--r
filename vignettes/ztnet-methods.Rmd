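---
title: "Models and methods behind ztnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ztnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ztnet` analyses diel time-course RNA-seq from a genotype x temperature
experiment: which co-expressed gene programs exist across the day, and
where (in which genotype, at which temperature and time of day) a mutant's
program departs from the wild type. This vignette documents the models,
the tunable parameters, the synthetic-data generator, and the numerical
and design choices, in enough detail to audit every stage.

## Count model and differential expression

Counts for gene $g$ in sample $j$ are modelled as negative binomial,

$$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g), \qquad
  \log \mu_{gj} = \eta_{g,\mathrm{group}(j)} + \log(N_j f_j),$$

with $N_j$ the library size, $f_j$ the TMM normalization factor, and
$\phi_g$ the gene dispersion ($\mathrm{Var} = \mu + \phi\mu^2$; $\phi = 0$
recovers Poisson). Group means are fitted by Fisher scoring on $\eta$.

**Dispersion.** The common dispersion maximizes the Cox-Reid adjusted
profile likelihood (APL) averaged over genes; for the one-way cell-means
layout the CR adjustment is $\tfrac12 \sum_{\text{groups}} \log
\sum_j \mu/(1+\phi\mu)$. The maximizer is located on a 25-point log-spaced
grid on $[10^{-6}, 4]$ and refined by golden-section search. Gene-wise
values are shrunk by maximizing the weighted likelihood
$\mathrm{APL}_g(\phi) + (d_0/d)\,\overline{\mathrm{APL}}(\phi)$ with prior
degrees of freedom $d_0 = 10$ (configurable) and residual df $d$ — the
usual empirical-Bayes compromise between a noisy per-gene profile and the
stable common profile, with quadratic interpolation of the grid maximum.

**Testing.** Each contrast (one mutant vs the reference within one
temperature and ZT timepoint) is a likelihood-ratio test of equal group
means against $\chi^2_1$. The reported `log2fc` uses moderated group-mean
CPM with a prior count of 0.5, so an all-zero group yields a large but
finite estimate. The LRT was chosen over a conditioned exact test because
it handles the unbalanced cells created by the dropped sample natively
(no pseudo-count quantile adjustment); it is validated by calibration
properties (null $p$ uniform within [0.04, 0.06] at $p<0.05$; observed FDR
$\le$ 0.075 in a 10%-non-null simulation) and by rank agreement with an
independent reference implementation on shared fixtures, not by
bit-for-bit output matching.

**DEG rule.** `q < 0.05` (strict; the inclusive variant is a switch) and
`|log2FC| >= 0.25`. The fold-change bound is read on the log2 scale: a
raw fold change of 0.25 would be a 4-fold down-only rule, inconsistent
with symmetric up/down calling.

**Expression filter.** Genes are kept when at least one sample has
CPM > 1 (strict) and cumulative CPM > 1, computed on raw library sizes.
By default the filter is evaluated on the reference genotype's samples
(matching the original reference-only filter convention), with a switch
for all samples.

## Co-expression network and communities

CPM values are centered per gene (mean 0 across all samples; a
unit-variance option exists but centering only is the default, since the
correlation and the ANOVA are location-invariant, and correlation is also
scale-invariant). Pearson correlations are computed across *all* samples
— both temperatures, all genotypes, replicates as separate points — and
an edge connects two genes when $r > 0.9$, signed and strict: strongly
anti-correlated genes are *not* connected (an absolute-value mode is a
switch). Genes without any edge are excluded from the network, as they can
never reach the minimum community size.

Girvan-Newman community detection is implemented from scratch: edge
betweenness by Brandes' BFS accumulation over unweighted shortest paths
(correlation weights are kept as annotation only; a reciprocal-weight
distance mode is a possible extension we deliberately did not default to),
iterative removal of the highest-betweenness edge with recomputation after
every removal, restricted to the affected component. Ties are broken
toward the lexicographically smallest `(gene_a, gene_b)` edge, making runs
deterministic across platforms. A partition is recorded at every component
split; modularity is always evaluated against the *original* graph; the
returned partition maximizes modularity with ties broken toward fewer
communities. Communities with fewer than four genes are dropped from
downstream analysis but retained in the saved full partition.

## Misregulation heatmaps

The observational unit is the per-sample community score: the mean of the
member genes' centered values in that sample. Member genes are correlated
by construction, so treating genes as independent observations would
inflate the degrees of freedom and understate $p$; a gene-level mode is
available behind a switch for comparison. For each community, temperature
and mutant, a two-way ANOVA (genotype $\in$ {reference, mutant} $\times$
timepoint) is fitted on the scores with Type-II sums of squares (well
defined under the unbalance from the dropped sample), and Tukey HSD is
applied over all genotype-by-time cell means using the full-model residual
mean square and the Tukey-Kramer standard error. The heatmap cell is the
adjusted $p$ of mutant vs reference within that timepoint. Pairwise
(reference vs one mutant) models are fitted rather than one four-genotype
model, producing one independent heatmap row per mutant. No additional
correction is applied across communities (the conventional display shows
raw Tukey-adjusted $p$); BH across cells is a switch. The studentized
range distribution is evaluated with R's `ptukey`, whose absolute error is
far below the $10^{-6}$ contract.

## Enrichment

All overlap tests use the hypergeometric upper tail including the observed
count, $P(X \ge k)$, evaluated in log space via `phyper` — the enrichment
convention. Binding enrichment tests a DEG list against each TF of a
panel, BH-adjusts across TFs, and reports the specificity rank of a named
TF (rank 1 = most enriched). Promoter motif counting is literal string
matching in the window adjacent to the TSS (promoter records are written
5'->3' on the gene strand with the TSS at the right end). Overlapping
occurrences are counted (CGCGCG contains CGCG twice), since multiple
instances of a core motif are biologically meaningful; this is toggleable.
Both strands are scanned by default — TF binding is strand-agnostic — as
the union of match positions of the motif and its reverse complement, so
the palindromic CGCG is not double-counted while CGTG additionally picks
up CACG sites. The window is upstream-only (1 kb) by default. Gene-set
over-representation is a one-sided Fisher/hypergeometric test per term
with fold enrichment $(k/|list|)/(|term|/N)$ and BH across terms; the
universe is always the expression-filtered gene set, never the whole
genome.

## Phenotype indices

Flowering is scored as total leaf number (TLN) at bud appearance. Group
comparisons use one-way ANOVA + Tukey HSD within each temperature (or
genotype x light two-way ANOVA), summarized as compact letter displays via
the insert-and-absorb algorithm with deterministic ordering. Leaves per
day is TLN divided by days post-germination. The leaf number ratio (LNR)
— the temperature sensitivity of flowering — is an index between two
*populations*, not single plants; since the exact pairing scheme of the
original index is not restated here, two defensible constructions are
implemented: the default all-pairs ratio multiset
$\{TLN_{cool}(i)/TLN_{warm}(j)\}$ (exactly $|cool|\cdot|warm|$ values,
order-invariant) and a seeded bootstrap of mean ratios; the choice is
recorded in the output attributes. ddCq relative expression is
$2^{-\Delta\Delta C_q}$ with $\Delta C_q$ the target-minus-control
difference referenced to the calibrator-condition mean; it is invariant to
adding a constant to every $C_q$.

## The synthetic-data generator

The generator's defaults are the study conditions: 4 genotypes (wild-type
reference, two single mutants, the double) x 2 temperatures (20, 15 C) x
7 ZT timepoints (0, 4, ..., 24 h) x 3 replicates; ~19,000 expressed genes;
one sample (wild type, 15 C, ZT12, replicate 1) dropped by default so all
statistics are exercised under unbalance. Background gene abundances are
log-normal on the CPM scale (median 5, log-SD 1.8), deliberately spanning
the CPM > 1 filter boundary so the expression filter is exercised.
Library sizes are log-normal with mean $10^7$ reads.

Five planted communities of 20 genes carry sinusoidal diel log2 profiles
with a shared phase within each community and phases spread evenly across
communities: the shared profile keeps within-community correlation above
the 0.9 edge threshold while distinct phases keep between-community
correlation far below it, making recovery tests sharp. Community baselines
span 60-350 CPM. Two communities are shifted by +1 log2 unit at ZT8-16 in
all mutants at 15 C; the other three carry shifts (±1) in other
temperature/ZT windows so that every community enters the DEG universe.
Shift windows are centered on each community's expression peak (the
sinusoid peaks at phase + 6 h): a planted effect at the diel trough would
be tested where the gene is barely expressed, which probes sequencing
depth rather than the pipeline.

The default dispersion is $\phi = 0.025$ (biological CV $\approx 0.16$).
The emulated samples are pools of six seedlings of an isogenic inbred
line grown in controlled chambers; the conventional guidance for
genetically identical model organisms is a biological CV near 0.1, with
0.2 as the generic figure, and the default sits between them. The
dispersion and library-size distribution of the real data are not known
to this package; these defaults are conventional, not fitted.

Promoter backgrounds are generated CG-dinucleotide-free (a Markov draw
that never emits G after C), which guarantees none of the scanned motifs
(CGCG, CGTG and their reverse complements) can occur by chance; planned
motifs are planted with 2-bp spacers and any occurrence accidentally
created at a junction is repaired by mutating a background base, with a
final verification that scans return exactly the planted counts. The CG
depletion makes the background compositionally unlike real promoters —
which is the point: motif counts have a single, exact ground truth.

Randomness uses a single root seed with deterministic per-artifact child
seeds, so counts, promoters, binding tables and phenotypes can be
regenerated independently; identical spec + seed gives bit-identical
output.

**What passing tests do and do not show.** The generator has independent
NB noise per gene and sample (no batch structure, no gene-gene
correlation beyond the planted communities, no GC or length bias, no
outlier samples beyond the one dropped), sinusoidal rather than
arbitrarily shaped diel profiles, and motif-free promoter backgrounds.
Recovery of planted structure under these conditions demonstrates the
pipeline's correctness, not its robustness to the full messiness of real
RNA-seq.

## Numerical choices and degenerate inputs

* NB fitting floors $\phi$ at $10^{-8}$ (Poisson limit) and caps Newton
  steps at ±5 on the log scale; all-zero genes fit at the $e^{-30}$ floor.
* Likelihood-ratio statistics are clipped at 0 before the $\chi^2$ tail.
* Betweenness ties are resolved lexicographically; floating-point ties
  within $10^{-9}$ (relative) are treated as equal.
* Constant genes have undefined correlation: NA, warned, never an edge.
* Constant ANOVA responses report $p = 1$ with a warning; a two-level
  single-timepoint design degrades the two-way heatmap model to one-way.
* `tmm_factors` excludes genes with a zero in either sample, trims 30% on
  M and 5% on A with inverse-asymptotic-variance weights, normalizes to
  geometric mean 1, and auto-picks the reference by upper-quartile
  closeness to the mean.
* The all-singleton and all-in-one partitions bracket the dendrogram; the
  all-in-one partition has modularity exactly 0, a property used in tests.

## Problem sizes used by the test-suite and acceptance runs

Unit tests run on reduced designs (hundreds to a few thousand genes).
The deeper property checks use: 200 random graphs of up to 12 nodes
against brute-force path enumeration; 20 stochastic block graphs (4 blocks
x 10 nodes); 20,000-gene null and mixture simulations for DE calibration
(3 seeds); and one full default synthetic experiment (~19,000 genes, 167
samples, 42 contrasts) for end-to-end recovery. These sizes were chosen to
make Monte-Carlo error small relative to every asserted margin while
keeping a complete run comfortably on a laptop.

## Known limitations

* The DE module covers two-group contrasts only — no multi-group GLMs,
  quasi-likelihood F-tests, or spline time-course models.
* Girvan-Newman is cubic-ish in practice and intended for networks of
  hundreds to a few thousand edges, as produced by a stringent PCC
  threshold; it is not a Louvain/Leiden replacement for large graphs.
* The misregulation ANOVA treats replicate scores as exchangeable; no
  mixed-effects structure or circadian curve fitting.
* Motif scanning is literal (with Ns never matching); no position-weight
  matrices.
* At the stated study conditions (three replicates, dispersion 0.1,
  twofold changes), single-cell contrast power at a BH threshold is
  intrinsically modest (~0.3); the pipeline compensates by testing each
  gene at several timepoints and mutants, which is exactly how the
  experimental design gains its sensitivity.
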