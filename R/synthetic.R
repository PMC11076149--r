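# Synthetic patients with planted ground truth.
#
# The generator emulates the per-patient input structure of upstream
# variant-calling / expression / epitope-prediction pipelines: a variant
# table with DNA and RNA read counts, a gene-expression table, an HLA
# allele expression table, and per-(variant, peptide, allele) prediction
# scores. "Planted" immunogenic variants are clonal (VAF ~ 0.5), highly
# expressed and carry strong prediction profiles; decoys are either
# subclonal variants with strong scores (traps for single-score ranking)
# or variants with weak prediction profiles.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for a synthetic patient
#'
#' Defaults describe a mid-sized tumor exome: 40 somatic variants on
#' distinct genes, 6 HLA class I alleles, 5 planted immunogenic variants.
#' Read counts are chosen so the empirical VAF matches the configured VAF;
#' expression variance is tied to the mean by `dispersion_factor`
#' (`variance = dispersion_factor * mean`), exercising the
#' negative-binomial regime when `> 1` and the Poisson fallback when
#' `<= 1`.
#'
#' @param num_variants number of somatic variants.
#' @param num_alleles number of HLA alleles.
#' @param planted_immunogenic indices of the planted (truly immunogenic)
#'   variants.
#' @param clonal_vaf VAF of clonal variants.
#' @param subclonal_vaf_range VAF interval for subclonal variants.
#' @param decoy_strong_fraction fraction of decoys given strong prediction
#'   scores but subclonal VAF (hard negatives for ranking baselines).
#' @param decoy_clonal_fraction fraction of the remaining (weak-score)
#'   decoys that are clonal.
#' @param expression_mean_range mean expression interval (FPKM-like
#'   units); planted variants draw from the upper 30% of the interval.
#' @param allele_expression_mean_range expression interval for HLA genes
#'   (highly expressed).
#' @param dispersion_factor variance/mean ratio of expression (> 0).
#' @param peptides_per_variant inclusive integer range (within 1..24) of
#'   minimal epitopes per variant.
#' @param dna_depth,rna_depth sequencing depths used to derive read
#'   counts.
#' @param score_profiles two lists, `strong` and `decoy`, each holding
#'   `percentile`, `cleavage` and `stability` sampling intervals.
#' @param seed generator seed.
#' @return object of class `synthetic_patient_config`.
#' @export
synthetic_patient_config <- function(
    num_variants = 40L,
    num_alleles = 6L,
    planted_immunogenic = 1:5,
    clonal_vaf = 0.5,
    subclonal_vaf_range = c(0.05, 0.2),
    decoy_strong_fraction = 0.25,
    decoy_clonal_fraction = 0.5,
    expression_mean_range = c(5, 50),
    allele_expression_mean_range = c(200, 600),
    dispersion_factor = 4,
    peptides_per_variant = c(2L, 6L),
    dna_depth = 200L,
    rna_depth = 100L,
    score_profiles = list(
      strong = list(percentile = c(0.05, 0.5), cleavage = c(0.5, 1),
                    stability = c(0.5, 1)),
      decoy = list(percentile = c(2, 30), cleavage = c(0.02, 0.5),
                   stability = c(0.02, 0.5))),
    seed = 1L) {
  cfg <- list(num_variants = as.integer(num_variants),
              num_alleles = as.integer(num_alleles),
              planted_immunogenic = as.integer(planted_immunogenic),
              clonal_vaf = clonal_vaf,
              subclonal_vaf_range = subclonal_vaf_range,
              decoy_strong_fraction = decoy_strong_fraction,
              decoy_clonal_fraction = decoy_clonal_fraction,
              expression_mean_range = expression_mean_range,
              allele_expression_mean_range = allele_expression_mean_range,
              dispersion_factor = dispersion_factor,
              peptides_per_variant = as.integer(peptides_per_variant),
              dna_depth = as.integer(dna_depth),
              rna_depth = as.integer(rna_depth),
              score_profiles = score_profiles,
              seed = as.integer(seed))
  problems <- character(0)
  if (cfg$num_variants < 1) problems <- c(problems, "num_variants")
  if (cfg$num_alleles < 1) problems <- c(problems, "num_alleles")
  if (length(cfg$planted_immunogenic) &&
      (any(cfg$planted_immunogenic < 1) ||
       any(cfg$planted_immunogenic > cfg$num_variants))) {
    problems <- c(problems, "planted_immunogenic")
  }
  if (cfg$clonal_vaf <= 0 || cfg$clonal_vaf > 1) {
    problems <- c(problems, "clonal_vaf")
  }
  if (diff(cfg$subclonal_vaf_range) < 0 || cfg$subclonal_vaf_range[1] <= 0) {
    problems <- c(problems, "subclonal_vaf_range")
  }
  if (cfg$dispersion_factor <= 0) problems <- c(problems, "dispersion_factor")
  if (cfg$peptides_per_variant[1] < 1 || cfg$peptides_per_variant[2] > 24 ||
      diff(cfg$peptides_per_variant) < 0) {
    problems <- c(problems, "peptides_per_variant")
  }
  if (cfg$decoy_strong_fraction < 0 || cfg$decoy_strong_fraction > 1 ||
      cfg$decoy_clonal_fraction < 0 || cfg$decoy_clonal_fraction > 1) {
    problems <- c(problems, "decoy fractions")
  }
  if (length(problems)) {
    stop_vaxtwin("invalid synthetic patient configuration: %s",
                 paste(problems, collapse = ", "),
                 class = "vaxtwin_config_error")
  }
  structure(cfg, class = "synthetic_patient_config")
}

random_peptides <- function(n, lengths = 8:11) {
  out <- character(0)
  while (length(out) < n) {
    len <- sample(lengths, 1L)
    pep <- paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
    if (!pep %in% out) out <- c(out, pep)
  }
  out
}

runif_range <- function(n, range) runif(n, range[1], range[2])

#' Generate a synthetic patient with planted ground truth
#'
#' Deterministic given `config$seed`: repeated calls produce identical
#' patients and, when `out_dir` is given, byte-identical files (the four
#' canonical TSV tables, a peptide FASTA, and `ground_truth.json`).
#'
#' @param config a [synthetic_patient_config()].
#' @param out_dir optional directory to write the canonical tables to.
#' @return list of class `synthetic_patient` with `patient` (a validated
#'   [patient_input()]), `ground_truth` (planted ids, per-variant VAF and
#'   profile role), and `paths` (when files were written).
#' @export
generate_patient <- function(config = synthetic_patient_config(),
                             out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_patient_config"))
  set.seed(config$seed)
  nv <- config$num_variants
  na <- config$num_alleles
  variant_id <- sprintf("v%03d", seq_len(nv))
  gene_id <- sprintf("ENSG_SYN%04d", seq_len(nv))

  planted <- logical(nv)
  planted[config$planted_immunogenic] <- TRUE
  decoys <- which(!planted)
  n_strong <- round(config$decoy_strong_fraction * length(decoys))
  decoy_strong <- if (n_strong > 0) sample(decoys, n_strong) else integer(0)
  role <- ifelse(planted, "planted",
                 ifelse(seq_len(nv) %in% decoy_strong, "decoy_strong",
                        "decoy_weak"))

  vaf <- numeric(nv)
  vaf[planted] <- config$clonal_vaf
  vaf[role == "decoy_strong"] <- runif_range(sum(role == "decoy_strong"),
                                             config$subclonal_vaf_range)
  weak <- which(role == "decoy_weak")
  weak_clonal <- runif(length(weak)) < config$decoy_clonal_fraction
  vaf[weak[weak_clonal]] <- config$clonal_vaf
  vaf[weak[!weak_clonal]] <- runif_range(sum(!weak_clonal),
                                         config$subclonal_vaf_range)

  dna_alt <- pmax(1L, as.integer(round(config$dna_depth * vaf)))
  rna_alt <- pmax(1L, as.integer(round(config$rna_depth * vaf)))
  variants <- data.frame(
    variant_id = variant_id, gene_id = gene_id,
    dna_alt_reads = dna_alt, dna_ref_reads = config$dna_depth - dna_alt,
    rna_alt_reads = rna_alt, rna_ref_reads = config$rna_depth - rna_alt,
    stringsAsFactors = FALSE)

  rng <- config$expression_mean_range
  emean <- runif_range(nv, rng)
  emean[planted] <- runif_range(sum(planted),
                                c(rng[1] + 0.7 * diff(rng), rng[2]))
  expression <- data.frame(gene_id = gene_id, mean = emean,
                           variance = config$dispersion_factor * emean,
                           stringsAsFactors = FALSE)

  amean <- runif_range(na, config$allele_expression_mean_range)
  alleles <- data.frame(
    allele_name = sprintf("HLA-SYN*%02d:01", seq_len(na)),
    mean = amean, variance = config$dispersion_factor * amean,
    stringsAsFactors = FALSE)

  pr <- config$peptides_per_variant
  n_pep <- sample(seq(pr[1], pr[2]), nv, replace = TRUE)
  score_rows <- vector("list", nv)
  for (i in seq_len(nv)) {
    prof <- config$score_profiles[[
      if (role[i] %in% c("planted", "decoy_strong")) "strong" else "decoy"]]
    peps <- random_peptides(n_pep[i])
    cleav <- runif_range(n_pep[i], prof$cleavage)
    grid <- expand.grid(peptide = peps,
                        allele_name = alleles$allele_name,
                        stringsAsFactors = FALSE)
    score_rows[[i]] <- data.frame(
      variant_id = variant_id[i],
      peptide = grid$peptide,
      allele_name = grid$allele_name,
      cleavage_score = cleav[match(grid$peptide, peps)],
      binding_value = runif_range(nrow(grid), prof$percentile),
      stability_score = runif_range(nrow(grid), prof$stability),
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, score_rows)

  patient <- patient_input(variants, expression, alleles, scores,
                           binding_mode = "percentile")
  ground_truth <- list(
    planted = variant_id[planted],
    seed = config$seed,
    variants = data.frame(variant_id = variant_id, role = role, vaf = vaf,
                          expression_mean = emean,
                          stringsAsFactors = FALSE))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      variants = file.path(out_dir, "variants.tsv"),
      expression = file.path(out_dir, "expression.tsv"),
      alleles = file.path(out_dir, "alleles.tsv"),
      scores = file.path(out_dir, "scores.tsv"),
      peptides = file.path(out_dir, "peptides.fasta"),
      ground_truth = file.path(out_dir, "ground_truth.json"))
    wt <- function(df, path) {
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wt(variants, paths$variants)
    wt(expression, paths$expression)
    wt(alleles, paths$alleles)
    wt(patient$scores, paths$scores)
    pep_tab <- unique(patient$scores[c("variant_id", "peptide")])
    writeLines(as.vector(rbind(
      sprintf(">%s|%s", pep_tab$variant_id, pep_tab$peptide),
      pep_tab$peptide)), paths$peptides)
    jsonlite::write_json(ground_truth, paths$ground_truth,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(list(patient = patient, ground_truth = ground_truth,
                 paths = paths, config = config),
            class = "synthetic_patient")
}

#' Generate a suite of synthetic patients
#'
#' One patient per seed (the remaining configuration is shared), with a
#' manifest aggregating the planted ground truth — the multi-patient
#' benchmark layout used for recall comparisons and replicate-consensus
#' analyses.
#'
#' @param seeds integer vector, one patient per seed.
#' @param config base [synthetic_patient_config()]; its `seed` field is
#'   replaced per patient.
#' @param out_dir optional directory; patient `i` is written to
#'   `<out_dir>/patient_<seed>`.
#' @return list with `patients` (list of `synthetic_patient`) and
#'   `manifest` (data frame: seed, variant_id, role, vaf).
#' @export
generate_benchmark_suite <- function(seeds, config =
                                       synthetic_patient_config(),
                                     out_dir = NULL) {
  stopifnot(length(seeds) >= 1L)
  patients <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    generate_patient(cfg, out_dir = if (!is.null(out_dir))
      file.path(out_dir, sprintf("patient_%d", s)))
  })
  manifest <- do.call(rbind, lapply(patients, function(p) {
    cbind(seed = p$ground_truth$seed, p$ground_truth$variants)
  }))
  list(patients = patients, manifest = manifest)
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(
    "<synthetic_patient> seed %d: %d variants (%d planted), %d alleles\n",
    x$config$seed, x$config$num_variants,
    length(x$ground_truth$planted), x$config$num_alleles))
  invisible(x)
}
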