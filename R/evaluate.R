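# Post-optimization analytics: per-cell response probabilities, coverage
# curves, replicate-consensus IoU, ranking baselines and recall scoring.

#' Per-cell response probabilities of a vaccine design
#'
#' For each simulated cell j, the probability that at least one selected
#' element elicits a response: `1 - exp(sum of p_ij over selected i)`.
#'
#' @param matrix a `response_matrix`.
#' @param design a `vaccine_design` (or character vector of element ids).
#' @return numeric vector in `[0, 1]`, one entry per cell.
#' @export
cell_response_probabilities <- function(matrix, design) {
  stopifnot(inherits(matrix, "response_matrix"))
  selected <- if (inherits(design, "vaccine_design")) design$selected
              else as.character(design)
  sel <- match(selected, matrix$elements)
  if (anyNA(sel)) {
    stop_vaxtwin("design references element(s) absent from the matrix: %s",
                 paste(selected[is.na(sel)], collapse = ", "),
                 class = "vaxtwin_referential_error")
  }
  if (length(sel) == 0L) return(rep(0, matrix$num_cells))
  1 - exp(colSums(matrix$coefficients[sel, , drop = FALSE]))
}

#' Coverage ratio at a response-probability threshold
#'
#' The proportion of cells whose response probability is at least the
#' threshold.
#'
#' @param probs response probabilities (see
#'   [cell_response_probabilities()]).
#' @param threshold value in `[0, 1]`.
#' @return fraction in `[0, 1]`.
#' @export
coverage_ratio <- function(probs, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (length(probs) == 0L) return(NA_real_)
  mean(probs >= threshold)
}

#' Coverage curve over a threshold grid
#'
#' @inheritParams coverage_ratio
#' @param thresholds grid of thresholds; default 0 to 1 in steps of 0.05.
#' @return data frame with columns `threshold` and `ratio`
#'   (non-increasing in `threshold`, 1 at threshold 0).
#' @export
coverage_curve <- function(probs, thresholds = seq(0, 1, by = 0.05)) {
  data.frame(threshold = thresholds,
             ratio = vapply(thresholds, coverage_ratio, numeric(1),
                            probs = probs))
}

#' Intersection-over-union consensus of replicate designs
#'
#' Measures agreement among element sets selected on replicate simulated
#' populations: `"all_sets"` is `|intersection| / |union|` over all
#' designs; `"pairwise_mean"` averages the IoU of every design pair.
#' Identical selections give 1.
#'
#' @param designs list of `vaccine_design` objects (or character vectors).
#' @param mode `"all_sets"` (default) or `"pairwise_mean"`.
#' @return value in `[0, 1]`, or `NA` when every design is empty (the
#'   union is empty and the ratio is undefined).
#' @export
design_iou <- function(designs, mode = c("all_sets", "pairwise_mean")) {
  mode <- match.arg(mode)
  stopifnot(length(designs) >= 2L)
  sets <- lapply(designs, function(d) {
    if (inherits(d, "vaccine_design")) d$selected else as.character(d)
  })
  pair_iou <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) NA_real_ else length(intersect(a, b)) / u
  }
  if (mode == "all_sets") {
    u <- length(Reduce(union, sets))
    if (u == 0L) return(NA_real_)
    length(Reduce(intersect, sets)) / u
  } else {
    n <- length(sets)
    vals <- unlist(lapply(seq_len(n - 1L), function(i) {
      vapply((i + 1L):n, function(j) pair_iou(sets[[i]], sets[[j]]),
             numeric(1))
    }))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
}

#' Threshold-and-rank baseline selection
#'
#' The conventional single-score selection this package is compared
#' against: rank all (variant, peptide, allele) score rows ascending by
#' binding value (lower is stronger for both affinities and percentiles),
#' keep rows passing the standard cutoff (500 nM for affinities, 2.0 for
#' percentiles), lift to variants via each variant's best row, and return
#' the top `top_n` variants.
#'
#' @param scores data frame of score rows (e.g. `patient$scores`).
#' @param value_kind `"percentile"` or `"score_nm"`, describing what
#'   `binding_value` holds.
#' @param top_n maximum number of variants returned.
#' @param affinity_cutoff keep rows with affinity `<=` this (nM).
#' @param percentile_cutoff keep rows with percentile `<=` this.
#' @return character vector of selected variant ids (possibly fewer than
#'   `top_n`).
#' @export
baseline_select <- function(scores, value_kind = c("percentile", "score_nm"),
                            top_n = 10L, affinity_cutoff = 500,
                            percentile_cutoff = 2.0) {
  value_kind <- match.arg(value_kind)
  stopifnot(is_count(top_n), top_n >= 1)
  cutoff <- if (value_kind == "percentile") percentile_cutoff
            else affinity_cutoff
  keep <- scores[scores$binding_value <= cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) return(character(0))
  keep <- keep[order_c(keep$binding_value, keep$variant_id, keep$peptide,
                       keep$allele_name), , drop = FALSE]
  variants <- unique(keep$variant_id)
  head(variants, top_n)
}

#' Recall of validated mutations
#'
#' @param selected set of selected variant ids.
#' @param validated set of experimentally validated immunogenic variant
#'   ids.
#' @return list with `tp`, `fn` and `recall`; `recall` is `NA` when no
#'   validated mutations exist (undefined), and 0 when validated mutations
#'   exist but none was selected.
#' @export
recall_report <- function(selected, validated) {
  selected <- unique(as.character(selected))
  validated <- unique(as.character(validated))
  tp <- length(intersect(selected, validated))
  fn <- length(setdiff(validated, selected))
  list(tp = tp, fn = fn,
       recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
}

#' Full evaluation report for a design
#'
#' Bundles per-cell response probabilities, the coverage curve, the
#' replicate-consensus IoU (when replicate designs are supplied) and the
#' recall against validated mutations (when ground truth is supplied).
#'
#' @param matrix a `response_matrix`.
#' @param design a `vaccine_design`.
#' @param thresholds coverage-curve grid.
#' @param replicate_designs optional list of designs from replicate
#'   populations for the IoU.
#' @param validated optional validated variant ids.
#' @param iou_mode see [design_iou()].
#' @return object of class `evaluation_report`.
#' @export
evaluate_design <- function(matrix, design,
                            thresholds = seq(0, 1, by = 0.05),
                            replicate_designs = NULL, validated = NULL,
                            iou_mode = "all_sets") {
  probs <- cell_response_probabilities(matrix, design)
  structure(list(
    response_probs = probs,
    coverage_curve = coverage_curve(probs, thresholds),
    iou = if (length(replicate_designs) >= 2L)
      design_iou(replicate_designs, iou_mode),
    recall = if (!is.null(validated))
      recall_report(if (inherits(design, "vaccine_design")) design$selected
                    else design, validated)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d cells, mean response %.3f\n",
              length(x$response_probs), mean(x$response_probs)))
  if (!is.null(x$iou)) cat(sprintf("  replicate IoU: %.3f\n", x$iou))
  if (!is.null(x$recall)) {
    cat(sprintf("  recall: TP %d / FN %d -> %s\n", x$recall$tp,
                x$recall$fn,
                if (is.na(x$recall$recall)) "undefined"
                else sprintf("%.2f", x$recall$recall)))
  }
  invisible(x)
}
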