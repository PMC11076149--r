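# Sampling-stage distributions are checked against their analytic moments
# (binomial / multinomial / negative-binomial oracles) under a fixed seed.

test_that("mutation presence follows the DNA VAF Bernoulli", {
  set.seed(101)
  v0 <- list(dna_alt_reads = 0L, dna_ref_reads = 50L)
  expect_false(any(sample_variant_presence(v0, n = 200)))
  v1 <- list(dna_alt_reads = 40L, dna_ref_reads = 0L)
  expect_true(all(sample_variant_presence(v1, n = 200)))
  v <- list(dna_alt_reads = 30L, dna_ref_reads = 10L)
  freq <- mean(sample_variant_presence(v, n = 10000))
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(freq - 0.75), 3 * se)
  expect_error(sample_variant_presence(
    list(dna_alt_reads = 0L, dna_ref_reads = 0L)),
    class = "vaxtwin_domain_error")
})

test_that("gamma-Poisson draws recover the requested moments", {
  set.seed(202)
  expect_identical(sample_gamma_poisson(0, 10, n = 100), integer(100))
  # overdispersed: negative-binomial regime
  x <- sample_gamma_poisson(50, 200, n = 50000)
  expect_lt(abs(mean(x) - 50), 3 * sqrt(200 / 50000))
  expect_lt(abs(var(x) - 200) / 200, 0.10)
  # variance <= mean: Poisson fallback with variance = mean
  y <- sample_gamma_poisson(10, 5, n = 50000)
  expect_lt(abs(mean(y) - 10), 3 * sqrt(10 / 50000))
  expect_lt(abs(var(y) - 10) / 10, 0.10)
  expect_error(sample_gamma_poisson(-1, 1), class = "vaxtwin_domain_error")
})

test_that("protein copies scale transcripts by RNA VAF with banker's rounding", {
  v <- list(rna_alt_reads = 25L, rna_ref_reads = 75L)
  expect_identical(compute_variant_protein_count(100L, v), 25L)
  expect_identical(compute_variant_protein_count(0L, v), 0L)
  half <- list(rna_alt_reads = 1L, rna_ref_reads = 1L)
  expect_identical(compute_variant_protein_count(7L, half), 4L) # 3.5 -> even
  none <- list(rna_alt_reads = 0L, rna_ref_reads = 0L)
  expect_identical(compute_variant_protein_count(100L, none), 0L)
})

test_that("cleavage is multinomial on normalized scores and conserves copies", {
  set.seed(303)
  expect_identical(sample_cleavage(0L, c("AAAA", "BBBB"), c(1, 1)),
                   c(AAAA = 0L, BBBB = 0L))
  expect_identical(sample_cleavage(17L, "ACDEFGHI", 0.3),
                   c(ACDEFGHI = 17L))
  m <- sample_cleavage(100000L, c("p1", "p2"), c(1, 3))
  expect_identical(sum(m), 100000L)
  expect_lt(abs(m[["p2"]] / 100000 - 0.75),
            3 * sqrt(0.75 * 0.25 / 100000))
  expect_error(sample_cleavage(5L, c("p1", "p2"), c(0, 0)),
               class = "vaxtwin_degenerate_distribution")
})

test_that("binding competition caps events at available MHC and splits by propensity", {
  set.seed(404)
  scores <- c(p1 = 1, p2 = 1)
  expect_identical(sample_binding(c(p1 = 0L, p2 = 0L), "A", 100L, scores),
                   setNames(integer(0), character(0)))
  expect_identical(sample_binding(c(p1 = 5L), "A", 0L, scores["p1"]),
                   c(p1 = 0L))
  # n* = min(n_mhc, pool size)
  b <- sample_binding(c(p1 = 3L, p2 = 4L), "A", 100L, scores)
  expect_identical(sum(b), 7L)
  # symmetric propensities: 10,000 events split evenly within 3 SE
  big <- sample_binding(c(p1 = 6000L, p2 = 6000L), "A", 10000L, scores)
  expect_identical(sum(big), 10000L)
  expect_lt(abs(big[["p1"]] - 5000), 3 * sqrt(10000 * 0.25))
  expect_error(sample_binding(c(p1 = 1L, px = 1L), "A", 10L, scores),
               class = "vaxtwin_referential_error")
})

test_that("presentation retains distinct complexes by normalized stability", {
  set.seed(505)
  one <- data.frame(peptide = "p1", allele_name = "A", multiplicity = 4L)
  st <- c("p1/A" = 0.37)
  out <- sample_presentation(one, st)
  expect_identical(out$multiplicity, 1L) # single complex: p = st/st = 1
  zero <- data.frame(peptide = c("p1", "p2"), allele_name = "A",
                     multiplicity = c(2L, 3L))
  st0 <- c("p1/A" = 0, "p2/A" = 1)
  for (i in 1:25) expect_false("p1" %in% sample_presentation(zero, st0)$peptide)
  # stabilities (1, 3): retention frequencies -> (0.25, 0.75)
  st13 <- c("p1/A" = 1, "p2/A" = 3)
  hits <- replicate(20000, sample_presentation(zero, st13)$peptide,
                    simplify = FALSE)
  f1 <- mean(vapply(hits, function(h) "p1" %in% h, logical(1)))
  f2 <- mean(vapply(hits, function(h) "p2" %in% h, logical(1)))
  expect_lt(abs(f1 - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
  expect_lt(abs(f2 - 0.75), 3 * sqrt(0.25 * 0.75 / 20000))
  expect_error(sample_presentation(zero, st13["p1/A"]),
               class = "vaxtwin_referential_error")
})

test_that("degenerate patients yield empty cell surfaces", {
  tb <- tiny_tables()
  # VAF 0 everywhere: nothing presented
  tb$variants$dna_alt_reads <- c(0L, 0L)
  tb$variants$dna_ref_reads <- c(50L, 50L)
  p <- patient_input(tb$variants, tb$expression, tb$alleles, tb$scores)
  set.seed(1)
  cell <- simulate_cell(p)
  expect_length(cell$present_variants, 0)
  expect_equal(nrow(cell$presented), 0)
  # expression 0 everywhere: present but never transcribed
  tb <- tiny_tables()
  tb$expression$mean <- 0
  tb$expression$variance <- 0
  p <- patient_input(tb$variants, tb$expression, tb$alleles, tb$scores)
  pop <- simulate_population(p, simulation_params(200, seed = 5))
  expect_equal(sum(pop$presented), 0)
})

test_that("a one-variant one-allele patient presents only its own complex", {
  p <- deterministic_patient()
  set.seed(9)
  cell <- simulate_cell(p)
  expect_identical(cell$present_variants, "v1")
  expect_true(all(cell$presented$peptide == "ACDEFGHI"))
  expect_true(all(cell$presented$allele_name == "AL1"))
})

test_that("populations conserve counts through every stage", {
  pop <- simulate_population(tiny_patient(),
                             simulation_params(500, seed = 77),
                             keep_intermediate = TRUE)
  im <- pop$intermediate
  # cleavage conserves protein copies per variant and cell, exactly
  cl_by_v <- rowsum(im$cleaved, group = pop$peptides$v_index)
  expect_identical(unname(cl_by_v), unname(im$protein))
  # binding events equal min(n_mhc, pool size) per allele and cell, exactly
  for (a in seq_along(pop$alleles)) {
    rows <- pop$complexes$a_index == a
    expect_identical(unname(colSums(im$bound[rows, , drop = FALSE])),
                     unname(pmin(im$n_mhc[a, ], im$pool_total)))
  }
  # support: presented within bound support, peptides only from present variants
  expect_true(all(pop$presented[im$bound == 0] == 0))
  v_of_cx <- pop$complexes$v_index
  for (j in seq_len(50)) {
    hit <- unique(v_of_cx[pop$presented[, j] > 0])
    expect_true(all(pop$presence[hit, j] == 1L))
  }
})

test_that("populations are bit-reproducible and replicates independent", {
  p <- tiny_patient()
  params <- simulation_params(300, num_replicates = 2, seed = 123)
  a1 <- simulate_population(p, params, 1)
  a2 <- simulate_population(p, params, 1)
  expect_identical(a1$presented, a2$presented)
  expect_identical(a1$presence, a2$presence)
  b <- simulate_population(p, params, 2)
  expect_false(identical(a1$presented, b$presented))
  # presence of v1 across replicates is independent (chi-square)
  tab <- table(factor(a1$presence[1, ], levels = 0:1),
               factor(b$presence[1, ], levels = 0:1))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
})

test_that("stronger binders end up presented more often", {
  # equal cleavage and stability, binding propensity ratio 1:9
  # (percentiles 9 and 1); scarce protein makes competition bite
  p <- deterministic_patient(peptides = c("WEAKWEAK", "STRNGSTR"),
                             binding = c(9, 1), cleavage = c(1, 1),
                             stability = c(0.5, 0.5),
                             gene_mean = 3, gene_var = 1)
  pop <- simulate_population(p, simulation_params(5000, seed = 31))
  strong <- pop$presented[pop$complexes$peptide == "STRNGSTR", ]
  weak <- pop$presented[pop$complexes$peptide == "WEAKWEAK", ]
  expect_gt(mean(strong), mean(weak))
  n_s <- sum(strong == 1 & weak == 0)
  n_w <- sum(weak == 1 & strong == 0)
  expect_lt(stats::binom.test(n_s, n_s + n_w, 0.5,
                              alternative = "greater")$p.value, 0.01)
})

test_that("single-cell and population paths agree on structure", {
  p <- tiny_patient()
  pop <- simulate_population(p, simulation_params(20, seed = 3))
  cell <- population_cell(pop, 7)
  expect_s3_class(cell, "simulated_cell")
  expect_identical(cell$cell_index, 7L)
  expect_true(all(cell$presented$multiplicity == 1L))
})
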