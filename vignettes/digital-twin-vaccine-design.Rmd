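---
title: "Digital-twin simulation and optimal neoantigen vaccine composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-twin simulation and optimal neoantigen vaccine composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A personal neoantigen vaccine can carry only a handful of elements —
tumor-specific mutations, each represented by a long peptide construct —
while the tumor it targets is a heterogeneous population of cells. Cells
differ in which mutations they carry (subclonal variants are present in
only a fraction of cells), in how strongly the mutated genes are
expressed, and in which of the resulting minimal epitopes actually reach
the cell surface on MHC class I molecules. Ranking candidates by a single
prediction score (binding percentile, affinity) ignores all of this
population structure, and tends to select redundant, high-scoring elements
that cover the same cells.

`vaxtwin` takes the alternative route of simulating the tumor explicitly:
it builds an in-silico population of cancer cells — a *digital twin* of
the patient's tumor — propagates each candidate mutation through a
probabilistic model of the antigen presentation pathway, and then selects
the vaccine composition that maximizes the likelihood of immune response
across the simulated population, under a budget on the number (or total
length) of elements.

## The cell model

Each simulated cell $c_j$, $j = 1..M$, is generated by five sampling
stages. All quantities below are per patient and derived from standard
upstream outputs (variant calls with read counts, expression estimates,
epitope prediction tables); the predictors themselves are upstream of this
package.

1. **Mutation presence.** Variant $v_i$ is present in the cell with
   probability equal to its DNA variant allele frequency,
   $V_i \sim \mathrm{Bernoulli}\!\left(d^{ALT}_i / (d^{REF}_i +
   d^{ALT}_i)\right)$, using whole-exome read counts. Absent variants
   contribute nothing further.
2. **Abundance.** The transcript count of the variant's gene is drawn from
   a gamma-Poisson distribution matched to the empirical mean and variance
   of the gene's expression. The mutated-protein copy number is the
   transcript count times the RNA VAF, rounded half-to-even to an integer.
3. **Cleavage.** The variant's minimal epitopes (8–11-mers containing the
   altered residue) receive copy numbers from a multinomial with the
   protein copy number as trial count and the normalized cleavage scores
   as event probabilities. Pooling over present variants gives the cell's
   peptide multiset $P^*$.
4. **Binding.** Each HLA allele $a$ has a gamma-Poisson number of MHC
   molecules (from the allele gene's expression; a unitary VAF is assumed
   for HLA genes). The number of binding events is
   $n^*_a = \min(n^{MHC}_a, |P^*|)$, allocated over the distinct pooled
   peptides by a multinomial on binding propensities — this models the
   *competition* of peptides for a limited supply of MHC molecules, which
   single-score rankings cannot capture.
5. **Presentation.** Each distinct bound complex is presented
   (multiplicity 1) independently with probability equal to its predicted
   stability divided by the summed stability of the cell's bound
   complexes.

The cell is reduced to its multiset $S^*$ of presented peptide–MHC
complexes. Populations of $M$ cells are simulated $K$ times to expose the
Monte-Carlo variability of everything downstream.

## From populations to coefficients

A vaccine element $e_i$ responds through its epitopes: an epitope
presented $N$ times in cell $j$ fails to trigger recognition with
probability $\max(0, 1 - \lambda N)^{\mathrm{DFS}(p)}$, and the element
fails only if all of its epitopes fail. Summing logs over epitopes gives
the coefficient $p_{ij} \le 0$, the log-probability that element $i$
elicits no response in cell $j$. Two global knobs:

* $\lambda$ is set to the reciprocal of the **largest** presentation count
  observed anywhere in the population, so that exactly one peptide–cell
  pair reaches response probability 1 and the scale never saturates.
  `build_response_matrix()` computes $\lambda$ per population by default
  (the right choice when replicate populations are optimized separately,
  as in the consensus analysis below) or jointly across populations via
  `lambda_scope = "joint"`.
* $\mathrm{DFS}$ ("distance from self") is a pluggable `[0, 1]` peptide
  weight approximating T-cell recognition relative to self peptides. No
  trained implementation is bundled; the default is the constant 1, and
  the sole contract is that a DFS of 0 silences an epitope entirely.

A log of exactly zero (an epitope at the maximum count) is floored at a
finite constant (default $-50$ per log term, and the summed coefficient is
floored at the same value). This preserves the "this element certainly
kills this cell" dominance — $e^{-50} \approx 2\cdot10^{-22}$ — while
keeping the integer programs bounded.

## Selection objectives

With costs $k_i > 0$ and budget $b$, the selector $x \in \{0,1\}^N$
solves either

$$\textbf{MinSum:}\quad \min_x \sum_j \sum_i p_{ij} x_i
\qquad\text{or}\qquad
\textbf{MinMax:}\quad \min_x \max_j \sum_i p_{ij} x_i,$$

subject to $\sum_i k_i x_i \le b$. MinSum maximizes the expected kill
across the whole population; MinMax protects against the single most
resistant cell, linearized in the standard way with a surrogate variable
$z \ge \sum_i p_{ij} x_i$ for every cell. Both are solved **exactly** by a
branch-and-bound written for this package: MinSum is separable and reduces
to a 0/1 knapsack over per-element aggregate coefficients (fractional
relaxation bound); MinMax uses depth-first search with an optimistic
all-remaining-elements column bound. Instances here are small — tens of
elements, with the cell dimension collapsing into the aggregates or
entering only bound evaluations — so exact search is fast and keeps the
package free of solver dependencies. An exhaustive enumeration oracle
(`brute_force_optimum()`, up to 20 elements) cross-checks both solvers in
the test suite.

Two behaviors worth knowing:

* **Ties** between equal-objective optima are broken deterministically in
  favor of the lexicographically smallest sorted element-id tuple (a
  proper prefix wins over its extensions, so elements contributing nothing
  are left out). Reproducible selections are a prerequisite for the
  replicate-consensus analysis.
* **MinMax and uncovered cells.** If any simulated cell presents no
  epitope of any candidate (common at small $M$, or whenever per-cell
  presentation is sparse), then every selection leaves that cell's sum at
  0, the optimum is 0, and the tie-break returns the empty design: under
  the worst-cell criterion, nothing helps. This is a property of the
  objective, not a solver artifact; MinSum is the practical default and is
  the objective used in the package's own analyses.

## Evaluation

`cell_response_probabilities()` turns a design into per-cell response
probabilities $1 - \exp(\sum_{i \in E} p_{ij})$; `coverage_curve()`
reports the fraction of cells responding above a threshold grid;
`design_iou()` measures consensus of selections across replicate
populations (strict all-sets intersection-over-union by default, mean
pairwise IoU as the smoother alternative); `baseline_select()` implements
the conventional comparison selector — filter score rows at the standard
cutoffs (500 nM affinity, 2.0 percentile), rank ascending, lift to
variants by each variant's best row, take the top $n$ — and
`recall_report()` scores selections against validated mutations. When
validated mutations exist but none is selected, recall is reported as 0
(it is well-defined); recall is *undefined* only when there are no
validated mutations to recover.

## The synthetic-patient generator

Real inputs require exome/RNA sequencing plus external predictor runs, so
the package ships a generator whose output is structurally
indistinguishable from the real tables. Defaults describe a mid-sized
tumor: 40 variants on distinct genes, 6 HLA alleles, sequencing depths of
200 (DNA) and 100 (RNA), expression means of 5–50 (FPKM-like) with
variance = 4 x mean (the overdispersed, negative-binomial regime; a
dispersion factor at or below 1 exercises the Poisson fallback), HLA
expression 200–600, and 2–6 minimal epitopes per variant. Five *planted*
immunogenic variants are clonal (VAF 0.5), drawn from the top 30% of the
expression range, and given strong prediction profiles (percentile
0.05–0.5, cleavage and stability 0.5–1). Decoys are the hard negatives a
ranking method faces: a quarter of them carry equally strong prediction
scores but subclonal VAF (0.05–0.2) — these fool single-score rankings and
should be down-weighted by the simulation — and the rest carry weak
profiles (percentile 2–30) with mixed clonality. Read counts are derived
deterministically from the configured VAF and depth, so the empirical VAF
equals the configured one up to rounding.

What the generator does **not** emulate: correlated score biases of real
predictors, linkage between mutations (clonal co-occurrence structure),
allele-specific HLA expression, and RNA VAFs decoupled from DNA VAFs.
Passing tests on synthetic patients therefore demonstrate correctness of
the sampling, coefficient and optimization machinery under the stated
model — not predictive performance on any real tumor.

## Numerical choices and degenerate inputs

* Multinomial draws across cells use the exact chain-rule decomposition
  into sequential binomials with bottom-up tail sums, so category counts
  conserve the trial count exactly (the last positive-weight category gets
  probability exactly 1).
* Binding scores are turned into propensities by $w = 1/\max(v,
  10^{-3})$, for both percentile and affinity conventions (both are
  "lower is stronger"); the transform is pluggable
  (`transform` argument of the simulation functions).
* Per-allele binding draws sample independently from the same pooled
  multiset, so the total bound copies of a peptide across alleles may
  exceed its pooled copy number; allele competition for shared copies is
  intentionally not modeled.
* Zero RNA coverage for a variant is accepted with a warning and treated
  as "no mutated protein". An all-zero cleavage vector is an error, not a
  uniform fallback — a silent uniform would change the model. A population
  in which nothing is presented anywhere raises a degenerate-model error
  at $\lambda$ computation, since optimization would be vacuous.
* Fractional protein copy numbers are rounded half-to-even, avoiding
  systematic inflation of multinomial trial counts.
* Randomness: one root seed; each replicate population runs on a
  deterministic sub-seed, and within a population every stage draws
  vectorized across cells in a fixed order. The same (seed, replicate,
  patient) is bit-reproducible regardless of how many replicates are
  evaluated, and replicate populations pass independence checks on
  variant-presence co-occurrence.

## Problem sizes used in the package's own analyses

The bundled tests and the acceptance script use: 20,000 cells for
marginal-recovery and conservation checks; 50,000 draws for gamma-Poisson
moment recovery; 100+ randomized instances (up to 12 elements, 6 cells)
for solver/oracle agreement; populations of {10, 100, 1000, 5000} cells
with 10 replicates each for the consensus (IoU) trend; and 10 synthetic
patients at 2,000 cells, budget 5, for the recall comparison against the
percentile baseline. These sizes give the statistical oracles comfortable
power while keeping a full run in minutes on a single core.

## Known limitations

MHC class II presentation (CD4+ help) is not modeled; neither are tumor
clonality structure, TAP transport or ER trimming, the tumor
microenvironment, or TCR-repertoire effects. The method inherits the
quality of its upstream predictions — cleavage, binding and stability
scores enter the sampling distributions directly — and of the variant
calls and expression estimates behind the patient tables. Construct
assembly (ordering elements into a vector while avoiding junctional
epitopes) is downstream of this package.

## A minimal session

```{r, eval = FALSE}
library(vaxtwin)

sp <- generate_patient(synthetic_patient_config(seed = 7))
pops <- simulate_replicates(sp$patient,
                            simulation_params(2000, num_replicates = 10,
                                              seed = 11))
mats <- build_response_matrix(sp$patient, pops)
designs <- lapply(mats, function(m) {
  solve_min_sum(optimization_problem(m, budget = 5))
})
design_iou(designs, mode = "pairwise_mean")
recall_report(designs[[1]]$selected, sp$ground_truth$planted)
```
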