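# vaxtwin

Selection of personal neoantigen vaccine compositions by **digital-twin
simulation** of a patient's tumor cell population.

## What problem this solves, and for whom

Personalized cancer vaccines carry a limited number of elements —
tumor-specific mutations, each contributing a set of 8–11-mer minimal
epitopes — while the tumor is a heterogeneous population of cells:
subclonal mutations exist in only a fraction of cells, expression varies,
and epitopes compete for a limited supply of MHC class I molecules.
Conventional pipelines rank candidates by a single prediction score and
take the top N, which ignores all of that structure and happily selects
redundant elements covering the same cells.

`vaxtwin` is for computational immunologists building vaccine-design
pipelines downstream of standard variant-calling / expression /
epitope-prediction tools (e.g. pVACtools-family output). It works in two
steps:

1. **Simulate** a population of $M$ cancer cells. Each cell draws
   mutation presence $V_i \sim \mathrm{Bernoulli}(\mathrm{VAF}^{DNA}_i)$,
   transcript and MHC-molecule counts from gamma-Poisson models of
   expression, epitope copy numbers from a multinomial on cleavage
   scores, binding events from a multinomial on binding propensities
   capped at $\min(n^{MHC}_a, |P^*|)$ per allele (competition), and
   surface presentation from stability-weighted Bernoulli draws. The cell
   is reduced to its multiset $S^*$ of presented peptide–MHC complexes.
2. **Optimize** the composition. Each element–cell pair gets the log
   no-response coefficient
   $p_{ij} = \sum_k \mathrm{DFS}(p_k)\,\log \max(0, 1 - \lambda N_{jk})$
   over the element's epitopes, with $\lambda = 1/\max N$. A
   budget-constrained binary program then selects the elements, under
   either the **MinSum** objective $\min \sum_j \sum_i p_{ij} x_i$ (kill
   the most cells overall) or **MinMax**
   $\min \max_j \sum_i p_{ij} x_i$ (best-protect against the most
   resistant cell), both solved exactly by a built-in branch-and-bound
   with deterministic tie-breaking.

Evaluation utilities provide per-cell response probabilities
($1 - e^{\sum_{i\in E} p_{ij}}$), coverage curves, consensus
(intersection-over-union) across replicate simulations, threshold/top-N
baseline selectors and recall against validated mutations. A
synthetic-patient generator with planted immunogenic variants makes the
whole pipeline testable without any sequencing data.

## Worked example

```r
library(vaxtwin)

# a synthetic patient: 40 variants, 5 of them planted immunogenic
sp <- generate_patient(synthetic_patient_config(seed = 7))
sp$patient
#> <patient_input> 40 variants, 6 HLA alleles, 906 score rows (percentile)

# 10 replicate digital twins of 1000 cells each
pops <- simulate_replicates(sp$patient,
                            simulation_params(1000, num_replicates = 10,
                                              seed = 11))
pops[[1]]
#> <cell_population> 1000 cells (replicate 1), 906 candidate complexes,
#>   1041 presented complex occurrences

mats <- build_response_matrix(sp$patient, pops)
mats[[1]]
#> <response_matrix> 40 elements x 1000 cells, lambda = 0.5, floor = -50

designs <- lapply(mats, function(m)
  solve_min_sum(optimization_problem(m, budget = 5)))
designs[[1]]
#> <vaccine_design> min_sum: 5 element(s), objective -1700.45,
#>   cost 5 / budget 5 [optimal]
#>   v001, v002, v003, v004, v005

design_iou(designs, mode = "pairwise_mean")
#> [1] 0.8740741

probs <- cell_response_probabilities(mats[[1]], designs[[1]])
mean(probs)
#> [1] 0.326

recall_report(designs[[1]]$selected, sp$ground_truth$planted)$recall
#> [1] 1
recall_report(baseline_select(sp$patient$scores, "percentile", top_n = 5),
              sp$ground_truth$planted)$recall
#> [1] 0.2
```

Reading the numbers: the simulated population presents about one complex
per cell (presentation is sparse — stability normalization spreads mass
over every bound complex). The MinSum design at budget 5 recovers all
five planted clonal immunogenic variants (recall 1.0), while the
percentile top-5 baseline spends most of its budget on subclonal decoys
with excellent binding scores (recall 0.2). The selection is stable
across replicate simulations (mean pairwise IoU 0.87 at 1000 cells); a
mean response probability of 0.33 says a third of the simulated cells is
expected to be covered by at least one vaccine element.

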