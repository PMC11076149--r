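# Log no-response coefficients linking vaccine elements to simulated cells.
#
# A vaccine element (mutation) e_i is a set of minimal epitopes. An epitope
# presented N times in a cell fails to trigger a response with probability
# max(0, 1 - lambda * N)^DFS(peptide); an element fails only if all its
# epitopes fail, so its log no-response coefficient for a cell is the sum
# of the per-epitope log terms. lambda is set to 1 / (maximum presentation
# count observed anywhere) so that only the most-presented peptide reaches
# response probability 1, avoiding saturation. Log-zero events are floored
# at a finite constant so the downstream integer programs stay bounded.

new_response_matrix <- function(elements, coefficients, lambda_used,
                                floor_used, dfs_id = "constant_1") {
  structure(list(elements = elements, num_cells = ncol(coefficients),
                 coefficients = coefficients, lambda_used = lambda_used,
                 floor_used = floor_used, dfs_id = dfs_id),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response_matrix> %d elements x %d cells, lambda = %.6g, floor = %g\n",
    length(x$elements), x$num_cells, x$lambda_used, x$floor_used))
  invisible(x)
}

#' A constant distance-from-self function
#'
#' Distance-from-self (DFS) maps a peptide to `[0, 1]` and discounts
#' epitopes resembling self peptides, approximating T-cell recognition.
#' No specific implementation is bundled; the default is the constant 1
#' (no self-discount), and any `function(peptides) -> [0, 1]` can be
#' supplied in its place.
#'
#' @param value constant in `[0, 1]`.
#' @return a DFS function with an `id` attribute used in persisted
#'   metadata.
#' @export
constant_dfs <- function(value = 1) {
  stopifnot(value >= 0, value <= 1)
  f <- function(peptides) rep(value, length(peptides))
  attr(f, "id") <- sprintf("constant_%g", value)
  f
}

eval_dfs <- function(dfs, peptides) {
  out <- as.numeric(dfs(peptides))
  if (length(out) != length(peptides) || any(is.na(out)) ||
      any(out < 0 | out > 1)) {
    stop_vaxtwin("DFS function must return values in [0, 1], one per peptide",
                 class = "vaxtwin_domain_error")
  }
  out
}

#' Saturation-avoiding lambda from simulated populations
#'
#' `lambda = 1 / max N`, the reciprocal of the largest per-peptide
#' presentation count (summed over alleles) observed across all cells of
#' the supplied populations.
#'
#' @param populations a `cell_population` or list of them.
#' @return positive scalar.
#' @export
compute_lambda <- function(populations) {
  if (inherits(populations, "cell_population")) populations <- list(populations)
  mx <- 0L
  for (pop in populations) {
    counts <- presented_peptide_counts(pop)
    if (length(counts)) mx <- max(mx, max(counts))
  }
  if (mx == 0L) {
    stop_vaxtwin("no complex is presented in any cell: the response model is degenerate",
                 class = "vaxtwin_degenerate_model")
  }
  1 / mx
}

#' Per-epitope no-response probability
#'
#' `max(0, 1 - lambda * count) ^ dfs_value`: an epitope never presented in
#' a cell cannot elicit a response there (probability 1 of no response),
#' while the globally most-presented peptide (count = 1 / lambda) elicits a
#' response with certainty.
#'
#' @param count presentation count of the epitope in the cell.
#' @param lambda positive saturation parameter, see [compute_lambda()].
#' @param dfs_value distance-from-self in `[0, 1]`.
#' @return probability in `[0, 1]`.
#' @export
epitope_no_response_prob <- function(count, lambda, dfs_value = 1) {
  stopifnot(lambda > 0, all(count >= 0), all(dfs_value >= 0 & dfs_value <= 1))
  pmax(0, 1 - lambda * count)^dfs_value
}

#' Log no-response coefficient of one element for one cell
#'
#' Sum over the element's epitopes of `dfs(peptide) * log(max(0, 1 -
#' lambda * N))`, where `N` is the epitope's presentation count in the cell
#' summed over alleles. Each log term, and the final sum, is floored at
#' `floor` to keep the coefficient finite.
#'
#' @param element_epitopes character vector of the element's minimal
#'   epitopes.
#' @param cell a `simulated_cell` (see [simulate_cell()],
#'   [population_cell()]).
#' @param lambda positive, from [compute_lambda()] on the same populations.
#' @param dfs distance-from-self function; default [constant_dfs()].
#' @param floor negative flooring constant for log-zero events.
#' @return non-positive scalar in `[floor, 0]`.
#' @export
element_cell_log_no_response <- function(element_epitopes, cell,
                                         lambda, dfs = NULL, floor = -50) {
  stopifnot(inherits(cell, "simulated_cell"), lambda > 0, floor < 0)
  dfs <- dfs %||% constant_dfs(1)
  if (length(element_epitopes) == 0L) return(0)
  counts <- vapply(element_epitopes, function(p) {
    sum(cell$presented$multiplicity[cell$presented$peptide == p])
  }, numeric(1))
  w <- eval_dfs(dfs, element_epitopes)
  terms <- w * pmax(log(pmax(0, 1 - lambda * counts)), floor)
  max(sum(terms), floor)
}

#' Build response matrices from simulated populations
#'
#' One `elements x cells` matrix of log no-response coefficients per
#' population. With `lambda_scope = "per_population"` (default) lambda is
#' derived from each population separately — the natural choice when
#' replicate populations are optimized independently, e.g. for consensus
#' analysis. With `"joint"` a single lambda is computed across all supplied
#' populations, for joint optimization over concatenated cells.
#'
#' @param patient the [patient_input()] the populations were simulated
#'   from.
#' @param populations a `cell_population` or list of them.
#' @param dfs distance-from-self function; default [constant_dfs()].
#' @param floor negative flooring constant applied to each log term and to
#'   each coefficient.
#' @param lambda_scope `"per_population"` or `"joint"`.
#' @return list of `response_matrix` objects, one per population.
#' @export
build_response_matrix <- function(patient, populations, dfs = NULL,
                                  floor = -50,
                                  lambda_scope = c("per_population",
                                                   "joint")) {
  lambda_scope <- match.arg(lambda_scope)
  stopifnot(inherits(patient, "patient_input"), floor < 0)
  dfs <- dfs %||% constant_dfs(1)
  if (inherits(populations, "cell_population")) populations <- list(populations)
  joint_lambda <- if (lambda_scope == "joint") compute_lambda(populations)
  lapply(populations, function(pop) {
    lam <- joint_lambda %||% compute_lambda(pop)
    counts <- presented_peptide_counts(pop)
    w <- eval_dfs(dfs, pop$peptides$peptide)
    logterm <- pmax(log(pmax(1 - lam * counts, 0)), floor) * w
    coef <- matrix(0, length(pop$variants), pop$M)
    if (nrow(logterm)) {
      agg <- rowsum(logterm, group = pop$peptides$v_index)
      coef[as.integer(rownames(agg)), ] <- agg
    }
    coef <- pmax(coef, floor)
    new_response_matrix(elements = pop$variants, coefficients = coef,
                        lambda_used = lam, floor_used = floor,
                        dfs_id = attr(dfs, "id") %||% "custom")
  })
}
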