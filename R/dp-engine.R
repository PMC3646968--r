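# Layered dynamic program over the segmentation DAG.
#
# States are (pair node, number of segments L). The forward table gives the
# best achievable score among paths reaching a node with exactly L segments;
# maximizing over nodes ending at T yields the best score per segment count,
# from which the solvers pick the optimum under their tie-breaking rule
# (maximum score, then fewest segments, then lexicographically smallest
# breakpoint sequence). Scores are additive per node, so penalties that
# depend only on the node being added (or only on L) fold into the node
# weights or into a per-count offset, respectively.

dp_tolerance <- function(x) 1e-9 * (1 + abs(x))

# Best score per segment count k = 2..k_cap.
# node_w: score contribution of a node added as a non-first node;
# first_w: contribution when the node is the first on the path (the
# source edge is exempt from penalties).
dp_best_by_count <- function(dag, node_w, first_w) {
  nodes <- dag$nodes
  n_time <- dag$n_time
  k_cap <- max(2L, n_time %/% dag$l_min)
  pred_key <- paste(nodes$a - 1L, nodes$i, sep = ":")  # preds share (i, b)
  group_key <- paste(nodes$i, nodes$b, sep = ":")
  ends_at_T <- nodes$b == n_time
  W <- matrix(-Inf, nrow(nodes), k_cap)
  W[nodes$a == 1L, 2L] <- first_w[nodes$a == 1L]
  if (k_cap >= 3L) {
    for (L in 3L:k_cap) {
      gm <- tapply(W[, L - 1L], group_key, max)
      prev <- gm[pred_key]
      prev[is.na(prev)] <- -Inf
      W[, L] <- node_w + as.numeric(prev)
    }
  }
  best <- vapply(2L:k_cap, function(L) {
    v <- W[ends_at_T, L]
    if (length(v)) max(v) else -Inf
  }, numeric(1L))
  list(best = stats::setNames(best, 2L:k_cap), W = W, k_cap = k_cap)
}

# Lexicographically smallest breakpoint sequence among the maximum-score
# paths with exactly k segments. Returns integer breakpoints.
dp_extract_path <- function(dag, k, node_w, first_w) {
  nodes <- dag$nodes
  n_time <- dag$n_time
  m <- k - 1L  # pair nodes on the path
  P <- nrow(nodes)
  succ_src_key <- paste(nodes$a, nodes$i, sep = ":")   # succs share (a, i)
  succ_of_key <- paste(nodes$i + 1L, nodes$b, sep = ":")
  R <- matrix(-Inf, P, m)  # R[v, j]: best score after v when v is j-th node
  R[nodes$b == n_time, m] <- 0
  if (m >= 2L) {
    for (j in (m - 1L):1L) {
      S <- node_w + R[, j + 1L]
      gm <- tapply(S, succ_src_key, max)
      nxt <- gm[succ_of_key]
      nxt[is.na(nxt)] <- -Inf
      R[, j] <- as.numeric(nxt)
    }
  }
  total <- first_w + R[, 1L]
  total[nodes$a != 1L] <- -Inf
  opt <- max(total)
  if (!is.finite(opt)) stop("no admissible path with ", k, " segments")
  cand <- which(total >= opt - dp_tolerance(opt))
  cand <- cand[order(nodes$i[cand], nodes$b[cand])]
  v <- cand[1L]
  cuts <- nodes$i[v]
  for (j in seq_len(m - 1L)) {
    cuts <- c(cuts, nodes$b[v])
    target <- R[v, j]
    succs <- which(succ_src_key == succ_of_key[v])
    vals <- node_w[succs] + R[succs, j + 1L]
    ok <- succs[vals >= target - dp_tolerance(target)]
    ok <- ok[order(nodes$b[ok])]
    v <- ok[1L]
  }
  as.integer(cuts)
}

# Sum of pair distances along a segmentation (the unpenalized objective F),
# recomputed directly from the pair table.
recompute_objective <- function(pt, breakpoints, n_time = attr(pt, "n_time")) {
  seg <- segments_table(breakpoints, n_time)
  key <- paste(pt$a, pt$i, pt$b, sep = ":")
  d_of <- stats::setNames(pt$d, key)
  sum(vapply(seq_len(nrow(seg) - 1L), function(j) {
    k <- paste(seg$start[j], seg$end[j], seg$end[j + 1L], sep = ":")
    v <- d_of[[k]]
    if (is.null(v)) stop("pair table lacks triple ", k)
    v
  }, numeric(1L)))
}

new_segmentation_result <- function(breakpoints, n_time, objective, penalty,
                                    score, k_max = NULL, lambda = NULL,
                                    criterion = "none", meta = list(),
                                    sweep = NULL, consensus = NULL) {
  structure(c(list(
    breakpoints = as.integer(breakpoints),
    k = length(breakpoints) + 1L,
    n_time = as.integer(n_time),
    objective = objective,
    penalty = penalty,
    score = score,
    lambda = lambda,
    criterion = criterion,
    k_max = k_max,
    sweep = sweep,
    consensus = consensus), meta),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: T = %d, k = %d segments\n", x$n_time, x$k))
  cat("  breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  cat(sprintf("  objective F = %.6g", x$objective))
  if (!is.null(x$lambda) && x$criterion != "none")
    cat(sprintf("; penalty = %.6g (criterion '%s', lambda = %.6g)",
                x$penalty, x$criterion, x$lambda))
  cat("\n")
  if (!is.null(x$sweep))
    cat(sprintf("  sweep over %d lambda values; consensus k = %d\n",
                nrow(x$sweep), x$k))
  invisible(x)
}
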