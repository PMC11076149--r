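# Stochastic simulation of the MHC class I presentation pathway.
#
# Each simulated cancer cell passes through five sampling stages:
#   1. mutation presence     ~ Bernoulli(DNA VAF)
#   2. transcript abundance  ~ Gamma-Poisson(mean, variance); mutated protein
#      copies = transcripts x RNA VAF (rounded half-to-even)
#   3. proteasomal cleavage  ~ Multinomial(protein copies, cleavage scores)
#   4. peptide-MHC binding   ~ Multinomial(min(#MHC, pool size), binding
#      propensities) per allele, modelling competition for MHC molecules
#   5. surface presentation  ~ Bernoulli(stability / total stability) per
#      distinct bound complex
# The cell is reduced to its multiset of presented peptide-MHC complexes.

#' Simulation parameters
#'
#' @param population_size number of cells per population (M).
#' @param num_replicates number of replicate populations (K).
#' @param seed root seed; each replicate runs on a deterministic sub-seed.
#' @param binding_mode optional override of the patient's binding mode.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(population_size, num_replicates = 1L,
                              seed = 1L, binding_mode = NULL) {
  stopifnot(is_count(population_size), population_size >= 1,
            is_count(num_replicates), num_replicates >= 1,
            is_count(abs(seed)))
  structure(list(population_size = as.integer(population_size),
                 num_replicates = as.integer(num_replicates),
                 seed = as.integer(seed), binding_mode = binding_mode),
            class = "simulation_params")
}

#' Sample per-cell presence of a mutation
#'
#' Presence follows a Bernoulli distribution with success probability equal
#' to the DNA variant allele frequency, ALT / (ALT + REF) exome reads.
#'
#' @param variant one-row data frame (or list) with `dna_alt_reads` and
#'   `dna_ref_reads`.
#' @param n number of independent draws.
#' @return logical vector of length `n`.
#' @export
sample_variant_presence <- function(variant, n = 1L) {
  tot <- variant$dna_alt_reads + variant$dna_ref_reads
  if (any(tot <= 0)) {
    stop_vaxtwin("DNA VAF undefined: zero total DNA reads",
                 class = "vaxtwin_domain_error")
  }
  rbinom(n, 1L, variant$dna_alt_reads / tot) == 1L
}

#' Draw integer expression counts from a gamma-Poisson model
#'
#' Moment-matched negative binomial when `variance > mean` (the gamma-Poisson
#' mixture with `size = mean^2 / (variance - mean)`), plain Poisson when the
#' mixture is degenerate (`variance <= mean`), and the constant 0 when
#' `mean == 0`.
#'
#' @param mean,variance empirical mean and variance of the gene's
#'   expression (non-negative, arbitrary expression units such as FPKM).
#' @param n number of draws.
#' @return integer vector of length `n`.
#' @export
sample_gamma_poisson <- function(mean, variance, n = 1L) {
  if (!is.numeric(mean) || !is.numeric(variance) || is.na(mean) ||
      is.na(variance) || mean < 0 || variance < 0) {
    stop_vaxtwin("mean and variance must be non-negative numbers",
                 class = "vaxtwin_domain_error")
  }
  if (mean == 0) return(integer(n))
  if (variance > mean) {
    size <- mean^2 / (variance - mean)
    as.integer(rnbinom(n, size = size, mu = mean))
  } else {
    as.integer(rpois(n, mean))
  }
}

#' Mutated protein copies from transcript count and RNA VAF
#'
#' The transcript count is scaled by the RNA variant allele frequency and
#' rounded half-to-even to obtain an integer trial count for the cleavage
#' draw. Zero RNA coverage yields zero mutated protein.
#'
#' @param transcript_count non-negative integer vector.
#' @param variant one-row data frame with `rna_alt_reads`, `rna_ref_reads`.
#' @return integer vector.
#' @export
compute_variant_protein_count <- function(transcript_count, variant) {
  tot <- variant$rna_alt_reads + variant$rna_ref_reads
  vaf <- if (tot > 0) variant$rna_alt_reads / tot else 0
  as.integer(round(transcript_count * vaf))
}

#' Cleave protein copies into minimal epitopes
#'
#' Peptide multiplicities follow a multinomial with the protein copy number
#' as trial count and the normalized cleavage scores as event probabilities.
#'
#' @param protein_count non-negative integer (number of trials).
#' @param peptides character vector of the variant's minimal epitopes.
#' @param cleavage_scores non-negative scores, same length; must not be
#'   all zero when `protein_count > 0`.
#' @return named integer vector of multiplicities summing to
#'   `protein_count`.
#' @export
sample_cleavage <- function(protein_count, peptides, cleavage_scores) {
  stopifnot(length(peptides) == length(cleavage_scores),
            length(peptides) >= 1L, is_count(protein_count))
  if (sum(cleavage_scores) <= 0 && protein_count > 0) {
    stop_vaxtwin("all-zero cleavage score vector: the cleavage distribution is degenerate",
                 class = "vaxtwin_degenerate_distribution")
  }
  if (protein_count == 0) {
    return(setNames(integer(length(peptides)), peptides))
  }
  draw <- rmultinom(1L, protein_count, cleavage_scores / sum(cleavage_scores))
  setNames(as.integer(draw), peptides)
}

#' Binding propensity from a predicted binding value
#'
#' Both supported score conventions are "lower is stronger" (percentile
#' ranks and IC50 affinities in nM); the reciprocal `1 / max(value, eps)`
#' maps them to a propensity where stronger binders receive proportionally
#' more binding events.
#'
#' @param values positive binding values.
#' @param binding_mode `"percentile"` or `"affinity_nm"` (same transform;
#'   the argument is kept so a custom transform can dispatch on it).
#' @param eps lower clamp avoiding division blow-up at values near 0.
#' @return positive propensities.
#' @export
binding_propensity <- function(values, binding_mode = "percentile",
                               eps = 1e-3) {
  1 / pmax(values, eps)
}

#' Draw the peptides binding one HLA allele
#'
#' Competition for a limited number of MHC molecules: the number of binding
#' events is `min(n_mhc, pool size)` (pool size counted with multiplicity)
#' and events are allocated over the distinct pooled peptides by a
#' multinomial on their binding propensities.
#'
#' @param pool named integer vector: cleaved peptide multiset of the cell.
#' @param allele allele name (labelling only).
#' @param n_mhc number of MHC molecules of this allele in the cell.
#' @param scores named numeric vector mapping peptide to binding value.
#' @param binding_mode,transform propensity transform; `transform` defaults
#'   to [binding_propensity()].
#' @return named integer vector over the distinct pooled peptides.
#' @export
sample_binding <- function(pool, allele, n_mhc, scores,
                           binding_mode = "percentile", transform = NULL) {
  stopifnot(is_count(n_mhc))
  transform <- transform %||% binding_propensity
  pool <- pool[pool > 0]
  if (length(pool) == 0L || n_mhc == 0) {
    return(setNames(integer(length(pool)), names(pool)))
  }
  missing <- setdiff(names(pool), names(scores))
  if (length(missing)) {
    stop_vaxtwin("no binding value for pooled peptide(s): %s",
                 paste(missing, collapse = ", "),
                 class = "vaxtwin_referential_error")
  }
  n_star <- min(n_mhc, sum(pool))
  w <- transform(scores[names(pool)], binding_mode)
  draw <- rmultinom(1L, n_star, w / sum(w))
  setNames(as.integer(draw), names(pool))
}

#' Draw surface presentation of bound complexes
#'
#' Each distinct bound complex is presented (multiplicity 1) independently
#' with probability equal to its stability score divided by the summed
#' stability of all distinct complexes bound in the cell.
#'
#' @param bound data frame with columns `peptide`, `allele_name`,
#'   `multiplicity` (the bound multiset).
#' @param stability named numeric vector keyed `"<peptide>/<allele>"` (see
#'   [complex_stability_map()]), or a data frame with `peptide`,
#'   `allele_name`, `stability_score`.
#' @return data frame of presented complexes (`peptide`, `allele_name`,
#'   `multiplicity` = 1).
#' @export
sample_presentation <- function(bound, stability) {
  bound <- bound[bound$multiplicity > 0, , drop = FALSE]
  if (is.data.frame(stability)) stability <- complex_stability_map(stability)
  if (nrow(bound) == 0L) {
    return(data.frame(peptide = character(), allele_name = character(),
                      multiplicity = integer()))
  }
  key <- complex_key(bound$peptide, bound$allele_name)
  missing <- setdiff(key, names(stability))
  if (length(missing)) {
    stop_vaxtwin("no stability score for complex(es): %s",
                 paste(missing, collapse = ", "),
                 class = "vaxtwin_referential_error")
  }
  st <- stability[key]
  denom <- sum(st)
  p <- if (denom > 0) st / denom else rep(0, length(st))
  keep <- rbinom(length(p), 1L, p) == 1L
  out <- bound[keep, c("peptide", "allele_name"), drop = FALSE]
  out$multiplicity <- rep(1L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the stability lookup used by [sample_presentation()]
#'
#' @param scores data frame with `peptide`, `allele_name`,
#'   `stability_score`.
#' @return named numeric vector keyed `"<peptide>/<allele>"`.
#' @export
complex_stability_map <- function(scores) {
  setNames(scores$stability_score,
           complex_key(scores$peptide, scores$allele_name))
}

# ---------------------------------------------------------------------------
# Vectorized population core

sim_index <- function(patient) {
  sc <- patient$scores
  vp <- paste(sc$variant_id, sc$peptide, sep = "\r")
  first <- !duplicated(vp)
  pep_tab <- data.frame(variant_id = sc$variant_id[first],
                        peptide = sc$peptide[first],
                        cleavage_score = sc$cleavage_score[first],
                        stringsAsFactors = FALSE)
  pep_tab$v_index <- match(pep_tab$variant_id, patient$variants$variant_id)
  cx_tab <- sc[c("variant_id", "peptide", "allele_name", "binding_value",
                 "stability_score")]
  cx_tab$d_index <- match(vp, vp[first])
  cx_tab$a_index <- match(cx_tab$allele_name, patient$alleles$allele_name)
  cx_tab$v_index <- match(cx_tab$variant_id, patient$variants$variant_id)
  list(pep_tab = pep_tab, cx_tab = cx_tab)
}

# Runs the full cascade for M cells using the current RNG state.
simulate_cells_core <- function(patient, M, binding_mode = NULL,
                                keep_intermediate = FALSE,
                                transform = NULL) {
  stopifnot(inherits(patient, "patient_input"))
  binding_mode <- binding_mode %||% patient$binding_mode
  transform <- transform %||% binding_propensity
  idx <- sim_index(patient)
  pep <- idx$pep_tab
  cx <- idx$cx_tab
  vr <- patient$variants
  N <- nrow(vr); A <- nrow(patient$alleles)
  D <- nrow(pep); P <- nrow(cx)

  expr <- patient$expression
  gmatch <- match(vr$gene_id, expr$gene_id)

  # stage 1: mutation presence
  vaf_dna <- vr$dna_alt_reads / (vr$dna_alt_reads + vr$dna_ref_reads)
  presence <- matrix(0L, N, M)
  for (i in seq_len(N)) presence[i, ] <- rbinom(M, 1L, vaf_dna[i])

  # stage 2: transcripts -> mutated protein copies
  rna_tot <- vr$rna_alt_reads + vr$rna_ref_reads
  vaf_rna <- ifelse(rna_tot > 0, vr$rna_alt_reads / pmax(rna_tot, 1L), 0)
  protein <- matrix(0L, N, M)
  for (i in seq_len(N)) {
    tr <- sample_gamma_poisson(expr$mean[gmatch[i]],
                               expr$variance[gmatch[i]], M)
    protein[i, ] <- as.integer(round(tr * vaf_rna[i])) * presence[i, ]
  }

  # stage 3: cleavage into the pooled peptide multiset
  cleaved <- matrix(0L, D, M)
  for (i in seq_len(N)) {
    rows <- which(pep$v_index == i)
    if (length(rows) == 0L) next
    cs <- pep$cleavage_score[rows]
    if (sum(cs) <= 0 && any(protein[i, ] > 0)) {
      stop_vaxtwin(
        "all-zero cleavage score vector for variant '%s': degenerate cleavage distribution",
        vr$variant_id[i], class = "vaxtwin_degenerate_distribution")
    }
    cleaved[rows, ] <- rmultinom_chain(protein[i, ],
                                       matrix(cs, length(rows), M))
  }
  pool_total <- colSums(cleaved)

  # stage 4: MHC counts and competitive binding, per allele
  n_mhc <- matrix(0L, A, M)
  for (a in seq_len(A)) {
    n_mhc[a, ] <- sample_gamma_poisson(patient$alleles$mean[a],
                                       patient$alleles$variance[a], M)
  }
  bound <- matrix(0L, P, M)
  prop <- transform(cx$binding_value, binding_mode)
  for (a in seq_len(A)) {
    rows <- which(cx$a_index == a)
    if (length(rows) == 0L) next
    n_star <- pmin(n_mhc[a, ], pool_total)
    W <- prop[rows] * (cleaved[cx$d_index[rows], , drop = FALSE] > 0)
    bound[rows, ] <- rmultinom_chain(n_star, W)
  }

  # stage 5: presentation of distinct bound complexes
  support <- bound > 0
  denom <- colSums(support * cx$stability_score)
  pm <- (support * cx$stability_score) /
    matrix(pmax(denom, .Machine$double.xmin), P, M, byrow = TRUE)
  pm[!support] <- 0
  presented <- matrix(rbinom(P * M, as.integer(support), pm), P, M)

  structure(list(
    M = as.integer(M),
    replicate_index = NA_integer_,
    seed_used = NA_integer_,
    variants = vr$variant_id,
    alleles = patient$alleles$allele_name,
    peptides = pep,
    complexes = cx,
    presence = presence,
    presented = presented,
    intermediate = if (keep_intermediate) {
      list(protein = protein, cleaved = cleaved, n_mhc = n_mhc,
           bound = bound, pool_total = pool_total)
    }), class = "cell_population")
}

#' Simulate one population of cancer cells
#'
#' Runs the five-stage presentation cascade for `population_size` cells.
#' Each replicate uses a deterministic sub-seed of `params$seed`, so the
#' same `(seed, replicate_index, patient)` always yields a bit-identical
#' population, independent of evaluation order.
#'
#' @param patient a [patient_input()].
#' @param params a [simulation_params()].
#' @param replicate_index which of the `num_replicates` replicates to run.
#' @param keep_intermediate keep per-stage count matrices (protein copies,
#'   cleaved pool, MHC counts, bound multiset) for auditing; off by default
#'   to save memory.
#' @param transform optional custom binding-propensity transform,
#'   `function(values, binding_mode)`.
#' @return object of class `cell_population` with fields `presence`
#'   (variants x cells 0/1), `presented` (complexes x cells 0/1),
#'   `complexes`, `peptides`, and `intermediate` when requested.
#' @export
simulate_population <- function(patient, params, replicate_index = 1L,
                                keep_intermediate = FALSE,
                                transform = NULL) {
  stopifnot(inherits(params, "simulation_params"),
            replicate_index >= 1, replicate_index <= params$num_replicates)
  sub <- derive_seeds(params$seed, params$num_replicates)[replicate_index]
  set.seed(sub)
  pop <- simulate_cells_core(patient, params$population_size,
                             binding_mode = params$binding_mode,
                             keep_intermediate = keep_intermediate,
                             transform = transform)
  pop$replicate_index <- as.integer(replicate_index)
  pop$seed_used <- as.integer(sub)
  pop
}

#' Simulate all replicate populations
#'
#' @inheritParams simulate_population
#' @return list of `num_replicates` `cell_population` objects.
#' @export
simulate_replicates <- function(patient, params, keep_intermediate = FALSE,
                                transform = NULL) {
  lapply(seq_len(params$num_replicates), function(r) {
    simulate_population(patient, params, r,
                        keep_intermediate = keep_intermediate,
                        transform = transform)
  })
}

#' Simulate a single cell with the current RNG state
#'
#' Convenience wrapper over the same cascade used by
#' [simulate_population()], for inspection and testing.
#'
#' @inheritParams simulate_population
#' @param cell_index label for the returned cell.
#' @return object of class `simulated_cell`: `cell_index`,
#'   `present_variants` (character), `presented` (data frame `peptide`,
#'   `allele_name`, `multiplicity`).
#' @export
simulate_cell <- function(patient, cell_index = 1L, transform = NULL) {
  pop <- simulate_cells_core(patient, 1L, keep_intermediate = FALSE,
                             transform = transform)
  population_cell(pop, 1L, cell_index = cell_index)
}

#' Extract one cell from a simulated population
#'
#' @param population a `cell_population`.
#' @param j cell column index.
#' @param cell_index label for the returned cell (defaults to `j`).
#' @return a `simulated_cell`.
#' @export
population_cell <- function(population, j, cell_index = j) {
  hit <- which(population$presented[, j] > 0)
  structure(list(
    cell_index = as.integer(cell_index),
    present_variants = population$variants[population$presence[, j] == 1L],
    presented = data.frame(
      peptide = population$complexes$peptide[hit],
      allele_name = population$complexes$allele_name[hit],
      multiplicity = population$presented[hit, j],
      stringsAsFactors = FALSE)), class = "simulated_cell")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf(
    "<cell_population> %d cells (replicate %s), %d candidate complexes, %d presented complex occurrences\n",
    x$M, x$replicate_index, nrow(x$complexes), sum(x$presented)))
  invisible(x)
}

#' Per-peptide presented counts, summed over alleles
#'
#' Returns the matrix of presentation counts per distinct (variant,
#' peptide) and cell; the count of a peptide in a cell is its presented
#' multiplicity summed over all alleles presenting it.
#'
#' @param population a `cell_population`.
#' @return integer matrix, `nrow(population$peptides)` x `M`.
#' @export
presented_peptide_counts <- function(population) {
  D <- nrow(population$peptides)
  if (D == 0L) return(matrix(0L, 0L, population$M))
  out <- rowsum(population$presented, group = population$complexes$d_index)
  full <- matrix(0L, D, population$M)
  full[as.integer(rownames(out)), ] <- out
  full
}
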