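# Shared fixtures, built in code.

tiny_tables <- function() {
  list(
    variants = data.frame(
      variant_id = c("v1", "v2"),
      gene_id = c("gA", "gB"),
      dna_alt_reads = c(30L, 40L), dna_ref_reads = c(10L, 0L),
      rna_alt_reads = c(25L, 1L), rna_ref_reads = c(75L, 1L),
      stringsAsFactors = FALSE),
    expression = data.frame(
      gene_id = c("gA", "gB"), mean = c(50, 10), variance = c(200, 5),
      stringsAsFactors = FALSE),
    alleles = data.frame(
      allele_name = c("HLA-X*01:01", "HLA-X*02:01"),
      mean = c(100, 80), variance = c(400, 80),
      stringsAsFactors = FALSE),
    scores = expand.grid(
      peptide = c("ACDEFGHI", "ACDEFGHIK", "KLMNPQRS"),
      allele_name = c("HLA-X*01:01", "HLA-X*02:01"),
      stringsAsFactors = FALSE) |>
      transform(variant_id = ifelse(peptide == "KLMNPQRS", "v2", "v1"),
                cleavage_score = ifelse(peptide == "ACDEFGHI", 1, 0.5),
                binding_value = c(0.2, 1.5, 0.7, 2.5, 0.4, 1.1),
                stability_score = c(0.9, 0.3, 0.6, 0.2, 0.8, 0.5)))
}

tiny_patient <- function() {
  tb <- tiny_tables()
  patient_input(tb$variants, tb$expression, tb$alleles, tb$scores,
                binding_mode = "percentile")
}

# A single-variant, single-allele patient where the variant is always
# present and highly transcribed: S* support is fully determined.
deterministic_patient <- function(peptides = "ACDEFGHI",
                                  binding = rep(1, length(peptides)),
                                  cleavage = rep(1, length(peptides)),
                                  stability = rep(1, length(peptides)),
                                  gene_mean = 50, gene_var = 50,
                                  allele_mean = 1000, allele_var = 1000) {
  patient_input(
    variants = data.frame(variant_id = "v1", gene_id = "gA",
                          dna_alt_reads = 50L, dna_ref_reads = 0L,
                          rna_alt_reads = 50L, rna_ref_reads = 0L),
    expression = data.frame(gene_id = "gA", mean = gene_mean,
                            variance = gene_var),
    alleles = data.frame(allele_name = "AL1", mean = allele_mean,
                         variance = allele_var),
    scores = data.frame(variant_id = "v1", peptide = peptides,
                        allele_name = "AL1", cleavage_score = cleavage,
                        binding_value = binding,
                        stability_score = stability),
    binding_mode = "percentile")
}

# Hand-built population: complexes is a data.frame(variant_id, peptide,
# allele_name); presented is a 0/1 (or count) matrix complexes x cells.
fake_population <- function(complexes, presented, variants = NULL) {
  vp <- paste(complexes$variant_id, complexes$peptide, sep = "\r")
  first <- !duplicated(vp)
  variants <- variants %||% sort(unique(complexes$variant_id))
  pep <- data.frame(variant_id = complexes$variant_id[first],
                    peptide = complexes$peptide[first],
                    stringsAsFactors = FALSE)
  pep$v_index <- match(pep$variant_id, variants)
  complexes$d_index <- match(vp, vp[first])
  structure(list(M = ncol(presented), replicate_index = 1L,
                 seed_used = NA_integer_, variants = variants,
                 alleles = unique(complexes$allele_name), peptides = pep,
                 complexes = complexes,
                 presence = matrix(1L, length(variants), ncol(presented)),
                 presented = presented, intermediate = NULL),
            class = "cell_population")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Response matrix straight from a coefficient matrix (testing the solvers).
matrix_fixture <- function(coef, elements = sprintf("e%02d", seq_len(nrow(coef))),
                           lambda = 1, floor = -50) {
  vaxtwin:::new_response_matrix(elements, coef, lambda, floor)
}

fake_cell <- function(peptide = character(), allele = character(),
                      multiplicity = integer(), present = character()) {
  structure(list(cell_index = 1L, present_variants = present,
                 presented = data.frame(peptide = peptide,
                                        allele_name = allele,
                                        multiplicity = multiplicity,
                                        stringsAsFactors = FALSE)),
            class = "simulated_cell")
}

random_problem <- function(n = NULL, m = NULL, budget = NULL,
                           objective = "min_sum") {
  n <- n %||% sample(4:12, 1)
  m <- m %||% sample(1:6, 1)
  coef <- -matrix(stats::rexp(n * m), n, m)
  coef[stats::runif(n * m) < 0.3] <- 0
  optimization_problem(matrix_fixture(coef),
                       budget = budget %||% sample(seq_len(n), 1),
                       costs = sample(c(1, 1, 2, 3), n, replace = TRUE),
                       objective = objective)
}
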