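#' Maximum-weight, minimum-length path segmentation
#'
#' Solves the unpenalized multiple-segmentation problem on the DAG: among
#' all source-target paths (equivalently, all segmentations into at least
#' two segments of length `>= l_min`), find the one of maximum total weight
#' `F` (sum of distances between networks of consecutive segments); among
#' those, the one with the fewest segments; among those, the one with the
#' lexicographically smallest breakpoint sequence. Runs in one pass per
#' segment-count layer over the nodes in topological order.
#'
#' @param dag A `seg_dag` from [build_dag()].
#' @return A `segmentation_result`.
#' @export
max_weight_min_length_path <- function(dag) {
  stopifnot(inherits(dag, "seg_dag"))
  d <- dag$nodes$d
  tab <- dp_best_by_count(dag, node_w = d, first_w = d)
  best <- tab$best
  opt <- max(best)
  if (!is.finite(opt)) stop("no source-target path: l_min is too large for T")
  k_star <- as.integer(names(best)[which(best >= opt - dp_tolerance(opt))[1L]])
  bp <- dp_extract_path(dag, k_star, node_w = d, first_w = d)
  new_segmentation_result(bp, dag$n_time,
                          objective = best[[as.character(k_star)]],
                          penalty = 0, score = best[[as.character(k_star)]])
}

path_penalty <- function(breakpoints, n_time, criterion, lambda, k_max) {
  k <- length(breakpoints) + 1L
  if (criterion == "none" || lambda == 0 || k < 3L) return(0)
  seg <- segments_table(breakpoints, n_time)
  if (criterion == "count") {
    sum(vapply(3L:k, bp_penalty_count, numeric(1L), k_max = k_max, lambda = lambda))
  } else {
    sum(vapply(seg$length[3L:k], bp_penalty_length, numeric(1L), lambda = lambda))
  }
}

default_k_max <- function(n_time, l_min) max(1L, n_time %/% l_min - 1L)

#' Breakpoint-penalized optimal segmentation
#'
#' Maximizes the path weight minus the accumulated breakpoint penalty (see
#' [bp_penalty_count()]). The first pair node on a path is exempt: entering
#' the DAG necessarily creates two segments at once, so no penalty is
#' charged on the source edge. At `lambda = 0` this reduces exactly to
#' [max_weight_min_length_path()]. Ties are broken as in the unpenalized
#' solver (fewest segments, then lexicographically smallest breakpoints).
#'
#' @param dag A `seg_dag`.
#' @param criterion `"count"` (penalty grows with the number of segments)
#'   or `"length"` (penalty reciprocal in the new segment's length).
#' @param lambda Tuning parameter, `>= 0`.
#' @param k_max Maximum possible number of breakpoints; defaults to
#'   `floor(T / l_min) - 1`.
#' @return A `segmentation_result`.
#' @export
penalized_path <- function(dag, criterion = c("count", "length"), lambda,
                           k_max = NULL) {
  stopifnot(inherits(dag, "seg_dag"), lambda >= 0)
  criterion <- match.arg(criterion)
  k_max <- k_max %||% default_k_max(dag$n_time, dag$l_min)
  if (criterion == "count") {
    tab <- dp_best_by_count(dag, node_w = dag$nodes$d, first_w = dag$nodes$d)
    sol <- select_count_solution(dag, tab, lambda, k_max)
  } else {
    len_right <- dag$nodes$b - dag$nodes$i
    node_w <- dag$nodes$d - bp_penalty_length(len_right, lambda = lambda)
    tab <- dp_best_by_count(dag, node_w = node_w, first_w = dag$nodes$d)
    best <- tab$best
    opt <- max(best)
    if (!is.finite(opt)) stop("no source-target path: l_min is too large for T")
    k_star <- as.integer(names(best)[which(best >= opt - dp_tolerance(opt))[1L]])
    bp <- dp_extract_path(dag, k_star, node_w = node_w, first_w = dag$nodes$d)
    sol <- list(breakpoints = bp, score = best[[as.character(k_star)]])
  }
  f <- recompute_objective(dag$nodes, sol$breakpoints, dag$n_time)
  pen <- path_penalty(sol$breakpoints, dag$n_time, criterion, lambda, k_max)
  new_segmentation_result(sol$breakpoints, dag$n_time, objective = f,
                          penalty = pen, score = f - pen, k_max = k_max,
                          lambda = lambda, criterion = criterion)
}

# Count criterion: the cumulative penalty depends on the segment count k
# alone, so the penalized optimum is a maximum-weight k-segment path for
# the k maximizing bestF(k) - lambda * C(k).
select_count_solution <- function(dag, tab, lambda, k_max) {
  ks <- as.integer(names(tab$best))
  c_of_k <- vapply(ks, function(k) {
    if (k < 3L) 0 else
      sum(vapply(3L:k, bp_penalty_count, numeric(1L), k_max = k_max, lambda = 1))
  }, numeric(1L))
  scores <- tab$best - lambda * c_of_k
  opt <- max(scores)
  if (!is.finite(opt)) stop("no source-target path: l_min is too large for T")
  k_star <- ks[which(scores >= opt - dp_tolerance(opt))[1L]]
  bp <- dp_extract_path(dag, k_star, node_w = dag$nodes$d, first_w = dag$nodes$d)
  list(breakpoints = bp, score = scores[[which(ks == k_star)]])
}

#' Sweep the penalty tuning parameter
#'
#' Runs [penalized_path()] at `n_grid` equidistant values of the tuning
#' parameter between the bounds (inclusive) and summarizes the sweep by a
#' consensus: the modal breakpoint set across the grid, ties broken toward
#' fewer segments, then lexicographically. For the count criterion the
#' layered DP tables are shared across the whole grid.
#'
#' @inheritParams penalized_path
#' @param bounds Numeric `c(lambda_low, lambda_high)`; defaults to
#'   [lambda_bounds()] of the DAG's pair table.
#' @param n_grid Number of grid points (default 20); `n_grid = 1` runs at
#'   the lower bound only.
#' @return A `segmentation_result` for the consensus, with the per-lambda
#'   table in `$sweep` (columns `lambda`, `k`, `breakpoints`, `F`,
#'   `penalty`, `score`).
#' @export
sweep_lambda <- function(dag, criterion = c("count", "length"), bounds = NULL,
                         n_grid = 20, k_max = NULL) {
  stopifnot(inherits(dag, "seg_dag"), n_grid >= 1)
  criterion <- match.arg(criterion)
  k_max <- k_max %||% default_k_max(dag$n_time, dag$l_min)
  bounds <- bounds %||% lambda_bounds(structure(dag$nodes,
                                               class = c("pair_table", "data.frame")))
  stopifnot(bounds[1L] <= bounds[2L])
  grid <- if (n_grid == 1L) bounds[1L] else
    seq(bounds[1L], bounds[2L], length.out = n_grid)
  sols <- lapply(grid, function(lam)
    penalized_path(dag, criterion = criterion, lambda = lam, k_max = k_max))
  sweep <- data.frame(
    lambda = grid,
    k = vapply(sols, `[[`, integer(1L), "k"),
    breakpoints = vapply(sols, function(s)
      paste(s$breakpoints, collapse = ","), character(1L)),
    F = vapply(sols, `[[`, numeric(1L), "objective"),
    penalty = vapply(sols, `[[`, numeric(1L), "penalty"),
    score = vapply(sols, `[[`, numeric(1L), "score"))
  counts <- table(sweep$breakpoints)
  top <- names(counts)[counts == max(counts)]
  ord <- order(vapply(top, function(s) length(strsplit(s, ",")[[1L]]), integer(1L)),
               top)
  winner <- top[ord[1L]]
  pick <- sols[[which(sweep$breakpoints == winner)[1L]]]
  new_segmentation_result(pick$breakpoints, dag$n_time,
                          objective = pick$objective, penalty = pick$penalty,
                          score = pick$score, k_max = k_max,
                          lambda = pick$lambda, criterion = criterion,
                          sweep = sweep,
                          consensus = list(breakpoints = pick$breakpoints,
                                           support = as.integer(max(counts)),
                                           n_grid = as.integer(n_grid)))
}
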