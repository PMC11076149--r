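# Reading, validating and writing patient-level tables.
#
# Canonical dialect: tab-separated UTF-8 with a header row. Four tables make
# up one patient:
#   variants:    variant_id  gene_id  dna_alt_reads dna_ref_reads
#                rna_alt_reads rna_ref_reads
#   expression:  gene_id  mean  variance
#   alleles:     allele_name  mean  variance         (per-allele expression)
#   scores:      variant_id  peptide  allele_name  cleavage_score
#                binding_value  stability_score
# `binding_value` is either an affinity in nM or a predictor percentile;
# which one is recorded as `binding_mode` and applied during simulation.

VARIANT_COLS <- c("variant_id", "gene_id", "dna_alt_reads", "dna_ref_reads",
                  "rna_alt_reads", "rna_ref_reads")
EXPRESSION_COLS <- c("gene_id", "mean", "variance")
ALLELE_COLS <- c("allele_name", "mean", "variance")
SCORE_COLS <- c("variant_id", "peptide", "allele_name", "cleavage_score",
                "binding_value", "stability_score")

read_table_checked <- function(path, required, rename = NULL, what) {
  if (!file.exists(path)) {
    stop_vaxtwin("%s table not found: '%s'", what, path,
                 class = "vaxtwin_io_error")
  }
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(rename)) {
    hit <- match(names(rename), names(df))
    names(df)[hit[!is.na(hit)]] <- unname(rename)[!is.na(hit)]
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_vaxtwin("%s table '%s' lacks column(s): %s", what, path,
                 paste(missing, collapse = ", "),
                 class = "vaxtwin_schema_error")
  }
  df[required]
}

#' Column-name mapping from pVACbind-style epitope tables
#'
#' Upstream pipelines in the pVACtools family emit an `all_epitopes.tsv`
#' whose column names differ from this package's canonical schema. The map
#' returned here can be passed to [load_patient_input()] as `score_rename`
#' to translate on the fly; entries are `c(upstream_name = canonical_name)`.
#' Adjust the `binding_value` source to whichever predictor column you want
#' to feed the binding-competition step (percentiles by default).
#'
#' @param binding_column upstream column holding the binding value.
#' @return named character vector mapping upstream to canonical names.
#' @export
#' @examples
#' pvacbind_column_map()
pvacbind_column_map <- function(binding_column = "Best MT Percentile") {
  c("Mutation" = "variant_id",
    "Epitope Seq" = "peptide",
    "HLA Allele" = "allele_name",
    "Cleavage Score" = "cleavage_score",
    "Stability Score" = "stability_score",
    setNames("binding_value", binding_column))
}

#' Assemble and validate a patient input object
#'
#' Constructor from in-memory data frames; [load_patient_input()] is the
#' file-based front end. All referential-integrity checks are performed
#' here so that downstream operations never meet a dangling key.
#'
#' @param variants data frame with columns `variant_id`, `gene_id`,
#'   `dna_alt_reads`, `dna_ref_reads`, `rna_alt_reads`, `rna_ref_reads`.
#' @param expression data frame with `gene_id`, `mean`, `variance`.
#' @param alleles data frame with `allele_name`, `mean`, `variance`.
#' @param scores data frame with `variant_id`, `peptide`, `allele_name`,
#'   `cleavage_score`, `binding_value`, `stability_score`.
#' @param binding_mode `"percentile"` (lower is stronger; the rank output
#'   of NetMHCpan-style predictors) or `"affinity_nm"` (IC50 in nM, lower
#'   is stronger). Stored here, applied during simulation.
#' @return object of class `patient_input` with fields `variants`,
#'   `expression`, `alleles`, `scores`, `elements` (named list mapping each
#'   variant to its distinct minimal epitopes) and `binding_mode`.
#' @export
patient_input <- function(variants, expression, alleles, scores,
                          binding_mode = c("percentile", "affinity_nm")) {
  binding_mode <- match.arg(binding_mode)
  variants <- as.data.frame(variants)[VARIANT_COLS]
  expression <- as.data.frame(expression)[EXPRESSION_COLS]
  alleles <- as.data.frame(alleles)[ALLELE_COLS]
  scores <- as.data.frame(scores)[SCORE_COLS]

  for (col in c("dna_alt_reads", "dna_ref_reads", "rna_alt_reads",
                "rna_ref_reads")) {
    x <- variants[[col]]
    if (any(is.na(x) | x < 0 | x != trunc(x))) {
      stop_vaxtwin("column '%s' must hold non-negative integers", col,
                   class = "vaxtwin_schema_error")
    }
  }
  if (anyDuplicated(variants$variant_id)) {
    stop_vaxtwin("duplicated variant_id: %s",
                 paste(unique(variants$variant_id[
                   duplicated(variants$variant_id)]), collapse = ", "),
                 class = "vaxtwin_schema_error")
  }
  zero_dna <- variants$dna_alt_reads + variants$dna_ref_reads == 0
  if (any(zero_dna)) {
    stop_vaxtwin("DNA VAF undefined (0 ALT + 0 REF reads) for: %s",
                 paste(variants$variant_id[zero_dna], collapse = ", "),
                 class = "vaxtwin_schema_error")
  }
  zero_rna <- variants$rna_alt_reads + variants$rna_ref_reads == 0
  if (any(zero_rna)) {
    warning(sprintf(
      "no RNA reads for variant(s) %s; RNA VAF treated as 0 (no mutated protein)",
      paste(variants$variant_id[zero_rna], collapse = ", ")),
      call. = FALSE)
  }
  if (anyDuplicated(expression$gene_id)) {
    stop_vaxtwin("duplicated gene_id in expression table",
                 class = "vaxtwin_schema_error")
  }
  if (any(expression$mean < 0) || any(expression$variance < 0) ||
      any(alleles$mean < 0) || any(alleles$variance < 0)) {
    stop_vaxtwin("expression means and variances must be non-negative",
                 class = "vaxtwin_schema_error")
  }
  if (anyDuplicated(alleles$allele_name) || any(!nzchar(alleles$allele_name))) {
    stop_vaxtwin("allele names must be unique and non-empty",
                 class = "vaxtwin_schema_error")
  }

  missing_genes <- setdiff(variants$gene_id, expression$gene_id)
  if (length(missing_genes)) {
    stop_vaxtwin("gene_id not in expression table: %s",
                 paste(missing_genes, collapse = ", "),
                 class = "vaxtwin_referential_error")
  }
  bad_var <- setdiff(scores$variant_id, variants$variant_id)
  if (length(bad_var)) {
    stop_vaxtwin("score rows reference unknown variant(s): %s",
                 paste(bad_var, collapse = ", "),
                 class = "vaxtwin_referential_error")
  }
  bad_allele <- setdiff(scores$allele_name, alleles$allele_name)
  if (length(bad_allele)) {
    stop_vaxtwin("score rows reference unknown allele(s): %s",
                 paste(bad_allele, collapse = ", "),
                 class = "vaxtwin_referential_error")
  }

  plen <- nchar(scores$peptide)
  if (nrow(scores) && any(plen < 8 | plen > 11)) {
    stop_vaxtwin("minimal epitopes must be 8- to 11-mers; offending: %s",
                 paste(unique(scores$peptide[plen < 8 | plen > 11]),
                       collapse = ", "),
                 class = "vaxtwin_schema_error")
  }
  if (any(scores$binding_value <= 0)) {
    stop_vaxtwin("binding_value must be positive",
                 class = "vaxtwin_schema_error")
  }
  if (any(scores$cleavage_score < 0) || any(scores$stability_score < 0)) {
    stop_vaxtwin("cleavage and stability scores must be non-negative",
                 class = "vaxtwin_schema_error")
  }
  key <- paste(scores$variant_id, scores$peptide, scores$allele_name,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_vaxtwin("duplicated (variant, peptide, allele) score row: %s",
                 gsub("\r", " / ", dup),
                 class = "vaxtwin_schema_error")
  }
  # cleavage is a property of (variant, peptide); must agree across alleles
  vp <- paste(scores$variant_id, scores$peptide, sep = "\r")
  cleav_range <- tapply(scores$cleavage_score, vp,
                        function(x) diff(range(x)))
  if (length(cleav_range) && any(cleav_range > 0)) {
    stop_vaxtwin("cleavage_score differs across alleles for: %s",
                 gsub("\r", " / ", names(cleav_range)[cleav_range > 0][1L]),
                 class = "vaxtwin_schema_error")
  }
  # binding competition needs a binding value for every pooled peptide on
  # every allele: require complete (variant, peptide) x allele coverage
  if (nrow(scores)) {
    cover <- table(vp) # rows per (variant, peptide)
    incomplete <- names(cover)[cover != nrow(alleles)]
    if (length(incomplete)) {
      stop_vaxtwin(
        "score table must cover every allele for each (variant, peptide); incomplete: %s",
        gsub("\r", " / ", incomplete[1L]),
        class = "vaxtwin_referential_error")
    }
  }

  # canonical order: C-locale sort, so every derived index is reproducible
  variants <- variants[order_c(variants$variant_id), , drop = FALSE]
  expression <- expression[order_c(expression$gene_id), , drop = FALSE]
  alleles <- alleles[order_c(alleles$allele_name), , drop = FALSE]
  scores <- scores[order_c(scores$variant_id, scores$peptide,
                           scores$allele_name), , drop = FALSE]
  rownames(variants) <- rownames(expression) <- rownames(alleles) <-
    rownames(scores) <- NULL

  elements <- lapply(
    setNames(variants$variant_id, variants$variant_id),
    function(v) unique(scores$peptide[scores$variant_id == v]))

  structure(list(variants = variants, expression = expression,
                 alleles = alleles, scores = scores, elements = elements,
                 binding_mode = binding_mode),
            class = "patient_input")
}

#' Load a patient's tables from TSV files
#'
#' @param variant_path,expression_path,allele_path,score_path paths to the
#'   four canonical TSV tables (tab-separated, header row, `#` comments).
#' @param binding_mode see [patient_input()].
#' @param score_rename optional named character vector translating upstream
#'   column names to canonical ones, e.g. [pvacbind_column_map()].
#' @return a validated [patient_input()] object.
#' @export
load_patient_input <- function(variant_path, expression_path, allele_path,
                               score_path,
                               binding_mode = c("percentile", "affinity_nm"),
                               score_rename = NULL) {
  binding_mode <- match.arg(binding_mode)
  patient_input(
    variants = read_table_checked(variant_path, VARIANT_COLS,
                                  what = "variant"),
    expression = read_table_checked(expression_path, EXPRESSION_COLS,
                                    what = "expression"),
    alleles = read_table_checked(allele_path, ALLELE_COLS, what = "allele"),
    scores = read_table_checked(score_path, SCORE_COLS,
                                rename = score_rename, what = "score"),
    binding_mode = binding_mode)
}

#' @export
print.patient_input <- function(x, ...) {
  cat(sprintf(
    "<patient_input> %d variants, %d HLA alleles, %d score rows (%s)\n",
    nrow(x$variants), nrow(x$alleles), nrow(x$scores), x$binding_mode))
  invisible(x)
}

#' Write a vaccine design to TSV
#'
#' One data row per selected element (`variant_id`, `cost`, `aggregate_p`
#' = the element's summed log no-response coefficient over all cells),
#' preceded by `#`-comment metadata (objective, objective value, budget,
#' solver status). The file is re-loadable losslessly with
#' [read_vaccine_design()].
#'
#' @param design a `vaccine_design` as returned by the solvers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vaccine_design <- function(design, path) {
  stopifnot(inherits(design, "vaccine_design"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_vaxtwin("cannot open '%s' for writing: %s", path,
                 conditionMessage(e), class = "vaxtwin_io_error")
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("# objective: %s", design$objective),
    sprintf("# objective_value: %.17g", design$objective_value),
    sprintf("# budget: %.17g", design$budget),
    sprintf("# total_cost: %.17g", design$total_cost),
    sprintf("# solver_status: %s", design$solver_status),
    "variant_id\tcost\taggregate_p"), con)
  for (v in design$selected) {
    writeLines(sprintf("%s\t%.17g\t%.17g", v,
                       design$element_costs[[v]],
                       design$element_aggregates[[v]]), con)
  }
  invisible(path)
}

#' Read a vaccine design written by [write_vaccine_design()]
#'
#' @param path TSV path.
#' @return a `vaccine_design` object.
#' @export
read_vaccine_design <- function(path) {
  if (!file.exists(path)) {
    stop_vaxtwin("design file not found: '%s'", path,
                 class = "vaxtwin_io_error")
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    k <- sub(":.*$", "", kv)
    v <- sub("^[^:]*:\\s*", "", kv)
    meta[[k]] <- v
  }
  df <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                   stringsAsFactors = FALSE)
  new_vaccine_design(
    selected = df$variant_id,
    objective = meta$objective,
    objective_value = as.numeric(meta$objective_value),
    total_cost = as.numeric(meta$total_cost),
    budget = as.numeric(meta$budget),
    solver_status = meta$solver_status,
    element_costs = setNames(df$cost, df$variant_id),
    element_aggregates = setNames(df$aggregate_p, df$variant_id))
}

#' Write a simulated cell population to TSV (+ JSON sidecar)
#'
#' Rows are the presented complexes `(cell_index, peptide, allele_name,
#' multiplicity)`; cells presenting nothing contribute no rows. The sidecar
#' records seed, population size and replicate index.
#'
#' @param population a `cell_population`.
#' @param path output TSV path.
#' @param sidecar JSON sidecar path (default `<path>.json`); `NULL` skips it.
#' @return `path`, invisibly.
#' @export
write_cell_population <- function(population, path,
                                  sidecar = paste0(path, ".json")) {
  stopifnot(inherits(population, "cell_population"))
  hit <- which(population$presented > 0, arr.ind = TRUE)
  df <- data.frame(
    cell_index = hit[, 2L],
    peptide = population$complexes$peptide[hit[, 1L]],
    allele_name = population$complexes$allele_name[hit[, 1L]],
    multiplicity = population$presented[hit])
  df <- df[order_c(df$cell_index, df$peptide, df$allele_name), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sidecar)) {
    jsonlite::write_json(
      list(population_size = population$M,
           replicate_index = population$replicate_index,
           seed_used = population$seed_used),
      sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write / read a response matrix as TSV with a JSON sidecar
#'
#' The TSV holds one row per element (first column `variant_id`, then one
#' column per cell); the sidecar records lambda, the flooring constant and
#' the distance-from-self identifier.
#'
#' @param matrix a `response_matrix` from [build_response_matrix()].
#' @param path output TSV path.
#' @param sidecar JSON sidecar path (default `<path>.json`).
#' @return `path` (write) / a `response_matrix` (read), invisibly for write.
#' @export
write_response_matrix <- function(matrix, path,
                                  sidecar = paste0(path, ".json")) {
  stopifnot(inherits(matrix, "response_matrix"))
  df <- data.frame(variant_id = matrix$elements,
                   matrix$coefficients, check.names = FALSE)
  names(df)[-1L] <- paste0("cell_", seq_len(matrix$num_cells))
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(lambda = matrix$lambda_used, floor = matrix$floor_used,
         dfs = matrix$dfs_id, num_cells = matrix$num_cells),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path, sidecar = paste0(path, ".json")) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  coef <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(coef) <- NULL
  new_response_matrix(elements = df$variant_id, coefficients = coef,
                      lambda_used = meta$lambda, floor_used = meta$floor,
                      dfs_id = meta$dfs)
}

#' Read a YAML run configuration
#'
#' Convenience loader for the file format used by the command-line
#' interface: a YAML map naming the four input tables (`variants`,
#' `expression`, `alleles`, `scores`), `binding_mode`, and the simulation /
#' optimization parameter blocks.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_vaxtwin("config not found: '%s'", path, class = "vaxtwin_io_error")
  }
  yaml::read_yaml(path)
}
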