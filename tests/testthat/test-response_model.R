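cx2 <- data.frame(variant_id = c("v1", "v1", "v2"),
                  peptide = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC"),
                  allele_name = c("A1", "A2", "A1"),
                  stringsAsFactors = FALSE)

test_that("lambda is the reciprocal of the maximum presentation count", {
  # peptide AAAAAAAA presented on both alleles in cell 2: count 2 + 2 = 4
  pres <- matrix(c(1L, 0L, 0L,
                   2L, 2L, 1L), nrow = 3)
  pop <- fake_population(cx2, pres)
  expect_equal(compute_lambda(pop), 1 / 4)
  one <- fake_population(cx2, matrix(c(1L, 0L, 0L), 3, 1))
  expect_equal(compute_lambda(one), 1)
  empty <- fake_population(cx2, matrix(0L, 3, 4))
  expect_error(compute_lambda(empty), class = "vaxtwin_degenerate_model")
})

test_that("per-epitope no-response probability follows the saturation model", {
  expect_equal(epitope_no_response_prob(4, lambda = 1 / 4), 0)
  expect_equal(epitope_no_response_prob(0, lambda = 0.1), 1)
  expect_equal(epitope_no_response_prob(2, lambda = 0.25), 0.5)
  # the DFS exponent tempers the response
  expect_equal(epitope_no_response_prob(2, 0.25, dfs_value = 0.5),
               sqrt(0.5))
  expect_equal(epitope_no_response_prob(2, 0.25, dfs_value = 0), 1)
})

test_that("element coefficients multiply epitope probabilities in log space", {
  cell <- fake_cell(peptide = c("p1", "p2"), allele = c("A", "A"),
                    multiplicity = c(2L, 2L), present = "v1")
  # both epitopes at no-response prob 0.5 -> log 0.25
  expect_equal(element_cell_log_no_response(c("p1", "p2"), cell,
                                            lambda = 0.25), log(0.25))
  # epitope absent from the cell contributes log 1 = 0
  expect_equal(element_cell_log_no_response("p9", cell, lambda = 0.25), 0)
  empty <- fake_cell()
  expect_equal(element_cell_log_no_response(c("p1", "p2"), empty, 0.25), 0)
  # a log-zero event is capped at the floor
  expect_equal(element_cell_log_no_response("p1", cell, lambda = 0.5,
                                            floor = -50), -50)
})

test_that("matrix construction matches the per-cell operation and its identities", {
  sp <- generate_patient(synthetic_patient_config(
    num_variants = 8, num_alleles = 2, planted_immunogenic = 1:2,
    peptides_per_variant = c(2L, 3L), seed = 5))
  pop <- simulate_population(sp$patient, simulation_params(80, seed = 8))
  mat <- build_response_matrix(sp$patient, pop)[[1]]
  expect_equal(dim(mat$coefficients), c(8, 80))
  expect_true(all(mat$coefficients <= 0))
  expect_true(all(mat$coefficients >= mat$floor_used))
  # agreement with the scalar per-cell path
  lam <- compute_lambda(pop)
  for (j in c(1, 17, 50)) {
    cell <- population_cell(pop, j)
    for (i in c(1, 4, 8)) {
      eps <- sp$patient$elements[[mat$elements[i]]]
      expect_equal(mat$coefficients[i, j],
                   element_cell_log_no_response(eps, cell, lam),
                   tolerance = 1e-12)
    }
  }
  # probability-space equivalence away from the floor
  counts <- presented_peptide_counts(pop)
  away <- mat$coefficients > mat$floor_used / 2
  direct <- vapply(seq_len(ncol(counts)), function(j) {
    prod(epitope_no_response_prob(counts[, j], lam))
  }, numeric(1))
  whole <- colSums(matrix(pmax(log(pmax(1 - lam * counts, 0)),
                               mat$floor_used),
                          nrow(counts)))
  expect_lt(max(abs(exp(whole[whole > -25]) -
                    direct[whole > -25])), 1e-12)
  # a cell presenting nothing has an all-zero column
  empty_cols <- colSums(pop$presented) == 0
  if (any(empty_cols)) {
    expect_true(all(mat$coefficients[, empty_cols] == 0))
  }
})

test_that("coefficients are invariant to joint doubling of counts and halving of lambda", {
  pres <- matrix(c(1L, 0L, 1L,
                   2L, 1L, 0L,
                   0L, 2L, 1L), nrow = 3)
  pop1 <- fake_population(cx2, pres)
  pop2 <- fake_population(cx2, 2L * pres)
  sp_el <- list(v1 = "AAAAAAAA", v2 = "CCCCCCCC")
  fake_patient <- structure(list(elements = sp_el), class = "patient_input")
  m1 <- build_response_matrix(fake_patient, pop1)[[1]]
  m2 <- build_response_matrix(fake_patient, pop2)[[1]]
  expect_equal(m2$lambda_used, m1$lambda_used / 2)
  expect_equal(m1$coefficients, m2$coefficients)
})

test_that("the DFS exponent behaves as a recognition weight", {
  pres <- matrix(c(1L, 1L, 2L), 3, 1)
  pop <- fake_population(cx2, pres)
  fake_patient <- structure(list(elements = list(v1 = "AAAAAAAA",
                                                 v2 = "CCCCCCCC")),
                            class = "patient_input")
  m0 <- build_response_matrix(fake_patient, pop, dfs = constant_dfs(0))[[1]]
  expect_true(all(m0$coefficients == 0))
  m1 <- build_response_matrix(fake_patient, pop, dfs = constant_dfs(1))[[1]]
  mh <- build_response_matrix(fake_patient, pop, dfs = constant_dfs(0.5))[[1]]
  expect_equal(mh$coefficients, m1$coefficients / 2)
  expect_error(
    build_response_matrix(fake_patient, pop,
                          dfs = function(p) rep(2, length(p))),
    class = "vaxtwin_domain_error")
})

test_that("more presentation never raises a coefficient (monotonicity)", {
  base <- matrix(c(1L, 0L, 1L), 3, 1)
  fake_patient <- structure(list(elements = list(v1 = "AAAAAAAA",
                                                 v2 = "CCCCCCCC")),
                            class = "patient_input")
  # raise one count at fixed lambda via the scalar path
  lam <- 0.2
  cell_lo <- fake_cell("AAAAAAAA", "A1", 1L)
  cell_hi <- fake_cell("AAAAAAAA", "A1", 3L)
  expect_lte(element_cell_log_no_response("AAAAAAAA", cell_hi, lam),
             element_cell_log_no_response("AAAAAAAA", cell_lo, lam))
})

test_that("lambda scope spans populations only when requested", {
  pres_small <- matrix(c(1L, 0L, 0L), 3, 1)
  pres_big <- matrix(c(0L, 0L, 5L), 3, 1)
  p1 <- fake_population(cx2, pres_small)
  p2 <- fake_population(cx2, pres_big)
  fake_patient <- structure(list(elements = list(v1 = "AAAAAAAA",
                                                 v2 = "CCCCCCCC")),
                            class = "patient_input")
  per <- build_response_matrix(fake_patient, list(p1, p2))
  expect_equal(per[[1]]$lambda_used, 1)
  expect_equal(per[[2]]$lambda_used, 1 / 5)
  joint <- build_response_matrix(fake_patient, list(p1, p2),
                                 lambda_scope = "joint")
  expect_equal(joint[[1]]$lambda_used, 1 / 5)
  expect_equal(joint[[2]]$lambda_used, 1 / 5)
})
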