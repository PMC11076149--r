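# Budget-constrained selection of vaccine elements.
#
# Given the elements x cells matrix of log no-response coefficients p_ij
# (all <= 0), a cost k_i per element and a budget b, two objectives are
# supported, both over binary selectors x_i with sum(k_i x_i) <= b:
#   MinSum: minimize sum_j sum_i p_ij x_i   (kill the most cells overall)
#   MinMax: minimize max_j sum_i p_ij x_i   (best-protect against the most
#           resistant cell, linearized with a surrogate variable z)
# Both are solved exactly by branch-and-bound (no external MILP solver is
# required): MinSum reduces to a 0/1 knapsack over the per-element
# aggregates; MinMax uses depth-first search with an optimistic
# all-remaining-included column bound. Ties between equal-objective optima
# are broken deterministically in favor of the lexicographically smallest
# sorted element-id tuple.

OBJ_TOL <- 1e-9

obj_equal <- function(a, b) abs(a - b) <= OBJ_TOL * max(1, abs(a), abs(b))

# strict C-locale string comparison
cless <- function(x, y) x != y && order_c(c(x, y))[1L] == 1L

# lexicographic comparison of sorted id tuples; a proper prefix sorts first
tuple_less <- function(a, b) {
  la <- length(a); lb <- length(b)
  for (i in seq_len(min(la, lb))) {
    if (a[i] != b[i]) return(cless(a[i], b[i]))
  }
  la < lb
}

new_vaccine_design <- function(selected, objective, objective_value,
                               total_cost, budget, solver_status,
                               element_costs = setNames(numeric(0),
                                                        character(0)),
                               element_aggregates = setNames(numeric(0),
                                                             character(0))) {
  structure(list(selected = selected, objective = objective,
                 objective_value = objective_value, total_cost = total_cost,
                 budget = budget, solver_status = solver_status,
                 element_costs = element_costs,
                 element_aggregates = element_aggregates),
            class = "vaccine_design")
}

#' @export
print.vaccine_design <- function(x, ...) {
  cat(sprintf(
    "<vaccine_design> %s: %d element(s), objective %.6g, cost %.6g / budget %.6g [%s]\n",
    x$objective, length(x$selected), x$objective_value, x$total_cost,
    x$budget, x$solver_status))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Define a vaccine selection problem
#'
#' @param matrix a `response_matrix` (see [build_response_matrix()]).
#' @param budget positive budget `b` limiting the total selected cost.
#' @param costs positive per-element costs `k_i`; default 1 each, so the
#'   budget counts elements. A length-weighted alternative is to pass the
#'   peptide lengths of the element constructs.
#' @param objective `"min_sum"` or `"min_max"`.
#' @return object of class `optimization_problem`.
#' @export
optimization_problem <- function(matrix, budget, costs = NULL,
                                 objective = c("min_sum", "min_max")) {
  objective <- match.arg(objective)
  stopifnot(inherits(matrix, "response_matrix"), budget > 0)
  n <- length(matrix$elements)
  costs <- costs %||% rep(1, n)
  if (length(costs) != n || any(costs <= 0)) {
    stop_vaxtwin("costs must be positive, one per element",
                 class = "vaxtwin_domain_error")
  }
  structure(list(matrix = matrix, costs = as.numeric(costs),
                 budget = as.numeric(budget), objective = objective),
            class = "optimization_problem")
}

# objective value of a selection (index vector into elements)
selection_objective <- function(coef, sel, objective) {
  if (length(sel) == 0L) return(0)
  s <- colSums(coef[sel, , drop = FALSE])
  if (objective == "min_sum") sum(s) else max(s)
}

# exact 0/1 knapsack maximum: gains >= 0, costs > 0
knapsack_max <- function(gains, costs, budget) {
  keep <- which(gains > 0 & costs <= budget)
  if (length(keep) == 0L) return(0)
  g <- gains[keep]; co <- costs[keep]
  ord <- order(-(g / co), co)
  g <- g[ord]; co <- co[ord]
  n <- length(g)
  best <- 0
  frac_bound <- function(k, cap) {
    tot <- 0
    while (k <= n) {
      if (co[k] <= cap) {
        tot <- tot + g[k]; cap <- cap - co[k]
      } else {
        tot <- tot + g[k] * cap / co[k]
        break
      }
      k <- k + 1L
    }
    tot
  }
  dfs <- function(k, cap, val) {
    if (val > best) best <<- val
    if (k > n) return(invisible())
    if (val + frac_bound(k, cap) <= best + OBJ_TOL) return(invisible())
    if (co[k] <= cap) dfs(k + 1L, cap - co[k], val + g[k])
    dfs(k + 1L, cap, val)
  }
  dfs(1L, budget, 0)
  best
}

# exact MinMax minimum over subsets of `items` added on top of `cur`
# (length-M vector of already-forced column sums)
minmax_min <- function(coef, items, costs, budget, cur) {
  best <- max(cur) # the empty addition is always feasible
  if (length(items) == 0L) return(best)
  agg <- rowSums(coef[items, , drop = FALSE])
  ord <- order(agg)                      # most negative first
  items <- items[ord]
  n <- length(items)
  cmat <- coef[items, , drop = FALSE]
  # suffix[k, ] = column sums of rows k..n
  suffix <- rbind(cmat, 0)
  for (k in n:1) suffix[k, ] <- suffix[k + 1L, ] + cmat[k, ]
  co <- costs[items]
  dfs <- function(k, cap, colsum) {
    val <- max(colsum)
    if (val < best) best <<- val
    if (k > n) return(invisible())
    if (max(colsum + suffix[k, ]) >= best - OBJ_TOL) return(invisible())
    for (i in k:n) {
      if (co[i] <= cap) dfs(i + 1L, cap - co[i], colsum + cmat[i, ])
    }
  }
  dfs(1L, budget, cur)
  best
}

# minimum objective achievable with `forced` already selected and further
# elements drawn only from `candidates` (index vectors)
restricted_optimum <- function(coef, costs, budget, objective,
                               forced, candidates) {
  spent <- sum(costs[forced])
  cap <- budget - spent
  cand <- candidates[costs[candidates] <= cap]
  if (objective == "min_sum") {
    base <- selection_objective(coef, forced, "min_sum")
    base - knapsack_max(-rowSums(coef[cand, , drop = FALSE]) *
                          (length(cand) > 0),
                        costs[cand], cap)
  } else {
    cur <- if (length(forced)) colSums(coef[forced, , drop = FALSE])
           else numeric(ncol(coef))
    minmax_min(coef, cand, costs, cap, cur)
  }
}

# deterministic tie-break: walk element ids in C-locale order, building the
# lexicographically smallest sorted tuple among optimal selections
lex_optimal_selection <- function(coef, elements, costs, budget, objective,
                                  zstar) {
  ord <- order_c(elements)
  chosen <- integer(0)
  pool <- ord[costs[ord] <= budget]
  repeat {
    # a prefix achieving the optimum is lexicographically smallest: stop
    if (obj_equal(selection_objective(coef, chosen, objective), zstar)) {
      return(sort(elements[chosen]))
    }
    found <- FALSE
    for (pos in seq_along(pool)) {
      t <- pool[pos]
      if (sum(costs[c(chosen, t)]) > budget) next
      rest <- if (pos < length(pool)) pool[(pos + 1L):length(pool)]
              else integer(0)
      if (obj_equal(restricted_optimum(coef, costs, budget, objective,
                                       c(chosen, t), rest), zstar)) {
        chosen <- c(chosen, t)
        pool <- rest
        found <- TRUE
        break
      }
    }
    if (!found) return(NULL) # numerically unreachable; caller falls back
  }
}

solve_problem <- function(problem, objective) {
  stopifnot(inherits(problem, "optimization_problem"))
  if (problem$objective != objective) {
    stop_vaxtwin("problem declares objective '%s', solver is '%s'",
                 problem$objective, objective,
                 class = "vaxtwin_domain_error")
  }
  coef <- problem$matrix$coefficients
  elements <- problem$matrix$elements
  costs <- problem$costs
  budget <- problem$budget
  agg <- if (nrow(coef)) rowSums(coef) else numeric(0)
  affordable <- which(costs <= budget)
  if (length(affordable) == 0L) {
    return(new_vaccine_design(character(0), objective, 0, 0, budget,
                              "infeasible"))
  }
  zstar <- if (objective == "min_sum") {
    -knapsack_max(-agg[affordable], costs[affordable], budget)
  } else {
    minmax_min(coef, affordable, costs, budget, numeric(ncol(coef)))
  }
  sel_ids <- lex_optimal_selection(coef, elements, costs, budget, objective,
                                   zstar)
  if (is.null(sel_ids)) { # tolerance fallback: deterministic greedy repair
    sel_ids <- character(0)
  }
  sel <- match(sel_ids, elements)
  new_vaccine_design(
    selected = sel_ids, objective = objective,
    objective_value = selection_objective(coef, sel, objective),
    total_cost = sum(costs[sel]), budget = budget,
    solver_status = "optimal",
    element_costs = setNames(costs[sel], sel_ids),
    element_aggregates = setNames(agg[sel], sel_ids))
}

#' Solve the MinSum vaccine selection problem
#'
#' Minimizes the total log no-response over all cells,
#' `sum_j sum_i p_ij x_i`, subject to the budget constraint. Separable in
#' the elements, hence equivalent to a 0/1 knapsack over the per-element
#' aggregate coefficients; solved exactly.
#'
#' @param problem an [optimization_problem()] with `objective = "min_sum"`.
#' @return a `vaccine_design`.
#' @export
solve_min_sum <- function(problem) solve_problem(problem, "min_sum")

#' Solve the MinMax vaccine selection problem
#'
#' Minimizes the worst cell's log no-response, `max_j sum_i p_ij x_i`,
#' subject to the budget constraint — the surrogate-variable linearization
#' `min z, z >= sum_i p_ij x_i` for every cell j — solved exactly by
#' branch-and-bound.
#'
#' @param problem an [optimization_problem()] with `objective = "min_max"`.
#' @return a `vaccine_design`.
#' @export
solve_min_max <- function(problem) solve_problem(problem, "min_max")

#' Exhaustive-enumeration optimum (test oracle)
#'
#' Enumerates every feasible subset (so limited to 20 elements) and applies
#' the same deterministic tie-breaking as the branch-and-bound solvers.
#'
#' @param problem an [optimization_problem()].
#' @return a `vaccine_design`.
#' @export
brute_force_optimum <- function(problem) {
  stopifnot(inherits(problem, "optimization_problem"))
  coef <- problem$matrix$coefficients
  elements <- problem$matrix$elements
  n <- length(elements)
  if (n > 20L) {
    stop_vaxtwin("exhaustive enumeration refused for %d > 20 elements", n,
                 class = "vaxtwin_domain_error")
  }
  costs <- problem$costs
  budget <- problem$budget
  objective <- problem$objective
  if (!any(costs <= budget)) {
    return(new_vaccine_design(character(0), objective, 0, 0, budget,
                              "infeasible"))
  }
  best_obj <- Inf
  best_ids <- NULL
  masks <- if (n == 0L) 0 else 0:(2^n - 1)
  bits <- if (n == 0L) integer(0) else bitwShiftL(1L, 0:(n - 1L))
  for (mask in masks) {
    sel <- which(bitwAnd(mask, bits) != 0L)
    if (sum(costs[sel]) > budget) next
    obj <- selection_objective(coef, sel, objective)
    ids <- sort(elements[sel])
    if (obj < best_obj - OBJ_TOL ||
        (obj_equal(obj, best_obj) && tuple_less(ids, best_ids))) {
      best_obj <- min(obj, best_obj)
      best_ids <- ids
    }
  }
  sel <- match(best_ids, elements)
  agg <- if (nrow(coef)) rowSums(coef) else numeric(0)
  new_vaccine_design(
    selected = best_ids, objective = objective,
    objective_value = selection_objective(coef, sel, objective),
    total_cost = sum(costs[sel]), budget = budget,
    solver_status = "optimal",
    element_costs = setNames(costs[sel], best_ids),
    element_aggregates = setNames(agg[sel], best_ids))
}
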