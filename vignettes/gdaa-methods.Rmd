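---
title: "Differential association analysis with permutation N-statistics"
author: "gdaa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential association analysis with permutation N-statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdaa)
```

## The question the test answers

Differential *expression* analysis asks whether a gene's mean level changes
between two phenotypes. Differential *association* analysis asks a different
question: has the gene changed its relationship with the rest of the
transcriptome?  A gene can keep its mean perfectly constant while its
correlations with other genes reorganise completely — for example when a
regulatory interaction is gained or lost — and such genes are invisible to
mean-based tests.

Formally, with `m` genes measured on `n` subjects under each of two
conditions A and B, gene *i* is summarised by its **correlation vector**:
the (m−1)-vector of Fisher-transformed Pearson correlations between gene
*i* and every other gene,

$$ w_{ik} = \tfrac{1}{2}\log\frac{1+r_{ik}}{1-r_{ik}},
   \qquad k \ne i, $$

with \(r_{ik}\) the Pearson correlation computed from the raw-moment
(cross-product) formula.  The null hypothesis for gene *i* is that the joint
distribution of its correlation vector is the same under both conditions,
\(H_i : F_{w_i(A)} = F_{w_i(B)}\).  Rejected genes are **differentially
associated (DA)**.

## From one vector to a testable sample

A single dataset yields only one correlation vector per gene per condition,
so each condition's `n` subjects are split into `G` disjoint **subgroups**
(each of size at least two, sizes differing by at most one), and the
correlation vector is estimated once per subgroup.  That gives `G`
vector-valued observations per condition, enough for a two-sample test.
`G` trades variance for sample size: more subgroups mean more (but noisier)
correlation estimates.  It is a required user parameter, with
\(1 \le G \le \lfloor n/2\rfloor\); the balanced split maximises the
information in each subgroup.

Subgroup membership is assigned contiguously over the current sample order.
For the observed statistic this is a fixed, reproducible choice (a different
partition would give a numerically different observed statistic — users who
suspect order structure in their columns should randomise column order
first); under permutations the order is freshly shuffled, so contiguous
assignment is equivalent to a random partition there.

The two samples of `G` vectors are compared with the energy-distance
**N-statistic** built on the Euclidean kernel
\(L(x, y) = \lVert x - y\rVert_2\):

$$ N_i = \frac{2}{G^2}\sum_{k,l} L(w_i(A,k), w_i(B,l))
       - \frac{1}{G^2}\sum_{k,l} L(w_i(A,k), w_i(A,l))
       - \frac{1}{G^2}\sum_{k,l} L(w_i(B,k), w_i(B,l)), $$

all three sums running over all \(G^2\) ordered pairs (the within-group
self-pairs contribute zero; no \(\binom{G}{2}\) shortcut is taken, which
would change the normalisation).  \(N_i\) is nonnegative up to roundoff and
grows with the distributional difference between the two samples.

## Permutation null and error control

Significance comes from a permutation null: the `2n` subjects are pooled,
shuffled, split into two equal pseudo-conditions, and the whole
subgroup/correlation/N-statistic computation is repeated.  `K` shuffles give
a null sample \(N_{ik}\) per gene and

$$ p_i = \frac{\#(N_{ik} \ge N_i^*)}{K}, $$

ties counting as exceedances.  No +1 smoothing is applied — the formula is
used verbatim, so \(p = 0\) is possible and means "never reached in K
permutations", not "impossible".  `K` bounds the resolution: p-values live
exactly on the grid \(\{0, 1/K, \dots, 1\}\), and multiplicity-adjusted
inference needs `K` much larger than `m` divided by the target threshold.

Multiplicity is handled with the extended Bonferroni adjustment
\(\tilde p_i = p_i \times m\), which controls the **per-family error rate**
(PFER) — the expected *count* of false positives.  Because an expected count
can exceed 1, \(\tilde p\) is deliberately **not** capped at 1; thresholding
consumers are unaffected.  No FDR-style alternative is offered: the
procedure is defined by this adjustment.

## Numerical conventions

* **Zero variance.** A gene constant within a subgroup has no defined
  correlation; the package substitutes \(r = 0\) with a warning rather than
  abort a long permutation run (a strict mode turns this into an error).
  This situation also arises systematically when a condition is an exact
  copy of the other and a permuted size-2 subgroup pairs a column with its
  duplicate.
* **Fisher clamp.** \(r\) is clamped to \(|r| \le 1 - 10^{-12}\) before the
  transform, so perfectly correlated pairs map to a finite ~14.16 instead of
  infinity, which would otherwise propagate through every Euclidean kernel.
  The clamp value is irrelevant to rankings.
* **Zero diagonal.** The full m×m transformed-correlation matrix is kept
  with its diagonal fixed at 0.  Both rows in any row-to-row distance then
  contribute an exact 0 at position *i*, so full-row distances equal the
  entry-*i*-excluded distances of the definition while allowing one
  vectorised `rowSums` per subgroup pair.  The brute-force oracle
  (`nStatisticBruteForce`) excludes entry *i* explicitly, which doubles as a
  continuous check of this convention.
* **Fixed accumulation.** Kernel sums are accumulated in a fixed
  deterministic order, grouped by unordered subgroup pair with the two
  distances of a pair added together first.  Since IEEE addition is
  commutative, this makes `nStatisticAll(A, B)` bitwise symmetric in its
  arguments and exactly zero for identical samples, while keeping results
  bit-identical across all parallel configurations.

## Two-tier execution model

Permutations are embarrassingly parallel but each one is expensive, and the
per-permutation working set (expression matrix plus two m×G moment arrays)
is worth sharing.  The executor therefore has two tiers:

* **Workers** (coarse grain): processes that pull one not-yet-assigned
  permutation at a time from the centrally generated plan — dynamic
  balancing at single-permutation granularity.  Results are keyed by
  permutation index, never arrival order.
* **Lanes** (fine grain): within a worker, the genes are split into
  contiguous blocks with sizes differing by at most one; each lane computes
  and writes only its own block of the statistic vector while reading the
  single shared copy of the permuted data and moment arrays.

Randomness is confined to the plan (`makePermutationPlan`, one seeded
Mersenne-Twister stream); workers never draw random numbers.  Together with
the fixed accumulation order this yields the core contract, asserted in the
tests: *any* configuration (workers × lanes) serialises to byte-identical
results.  Worker failure aborts the run with the failing permutation index;
an optional in-flight cap bounds concurrent dispatch.  The implementation
uses forked R processes for workers (sequential fallback where fork is
unavailable) and an in-process loop over lanes; the contract, not the
mechanism, is the interface, so a cluster transport could replace it without
touching results.  CPU pinning is an OS-level tuning concern and is not part
of the package.

## The synthetic-data generator

`generateDaPair` builds the only kind of dataset for which the ground truth
of \(H_i\) is known exactly: `daGenes` genes form an equicorrelated block
via the single-factor Gaussian construction
\(x = \sqrt{\rho}\, f + \sqrt{1-\rho}\,\sigma\,\varepsilon\) (one latent
factor per sample), with within-block correlation \(\rho_A\) in condition A
and \(\rho_B\) in B; all other genes are independent standard normals.  The
construction leaves marginal means and variances untouched (for
\(\sigma = 1\)), so the planted signal lives purely in the correlation
structure — exactly the quantity the test targets, unlike a mean-shift
model.  The factor construction requires \(\rho \in [0, 1)\); negative
equicorrelation, though valid for small blocks, is rejected as infeasible
for this generator.  `generateNullPair` draws both conditions i.i.d. for
type-I-error checks.

What the generator does **not** emulate: heavy-tailed intensity noise,
probe/batch effects, normalisation residue, mean differences between
conditions, or realistic gene-gene correlation beyond one block.  Passing
tests on these data demonstrate the statistical machinery (calibration under
the null, power against correlation changes, determinism); they do not
certify behaviour under microarray-specific artifacts.

## Problem sizes used in the checks

The package's own verification uses desk-scale instances chosen to make the
relevant property measurable: oracle equivalence on ~100 random instances
with m ≤ 25 and G ≤ 5; null calibration pooled over 10 replicates of
m = 40 genes, n = 40, G = 4, K = 200 (the pooled rejection rate at
α = 0.05 is expected in a wide band around 0.055, since the shared
permutations correlate genes and the empirical p-value carries a +1/2K
offset relative to exact uniformity); signal recovery at m = 200, n = 60,
daGenes = 20, ρ_A = 0.8, ρ_B = 0, G = 6, K = 200.  Production runs scale
far beyond this (tens of thousands of genes, K in the thousands); the
executor exists for exactly that regime.

## A worked example

```{r example}
sim <- generateDaPair(simulationConfig(m = 60, n = 30, daGenes = 10,
                                       rhoA = 0.9, rhoB = 0, seed = 11))
res <- runGDAA(sim$A, sim$B, G = 5, K = 100, seed = 11)
res
head(as.data.frame(res)[rankGenes(res)[1:10], ])
```

Genes `g01`–`g10` carry the planted correlation change; with K = 100 the
smallest attainable p-value is 0, i.e. no permutation reached the observed
statistic, and the adjusted values are on the expected-false-positive scale
(compare against the PFER budget you are willing to spend, e.g. 1).

## Known limitations

* Equal sample counts per condition are required; the equal-split
  permutation scheme presupposes them.
* Pearson correlation only — the statistic is defined on linear association;
  no rank-based or information-theoretic variant is provided.
* The observed statistic depends on the (fixed, contiguous) subgroup
  assignment; different partitions give different \(N^*\).
* p-value resolution is 1/K; adjusted inference at small thresholds needs
  large K.
* The permutation test assumes exchangeability of subjects across
  conditions under the null.
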