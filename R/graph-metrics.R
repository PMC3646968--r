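#' Network properties of segment graphs
#'
#' Per-node (local and local-global) properties used to compare the
#' networks of consecutive time segments, plus the global relative
#' density. Conventions are fixed so results are exactly reproducible:
#' betweenness is unnormalized (each unordered node pair contributes the
#' fraction of its shortest paths through the node), and closeness uses the
#' reachability-scaled form
#' `(r_v / (n - 1)) * (r_v / sum of distances to reachable nodes)` with
#' `r_v` the number of nodes reachable from `v`, so isolated nodes score 0
#' and a node of a complete graph scores 1. Shortest paths are unweighted.
#'
#' @param g A `segment_graph` (or logical/0-1 adjacency matrix).
#' @return For the vector properties, a named numeric vector aligned to the
#'   node order; for [relative_density()], a scalar.
#' @name graph-properties
NULL

as_adjacency <- function(g) {
  if (inherits(g, "segment_graph")) return(g$adjacency)
  if (is.matrix(g)) {
    adj <- (g != 0)
    diag(adj) <- FALSE
    return(adj | t(adj))
  }
  stop("expected a segment_graph or an adjacency matrix")
}

node_names <- function(g) {
  if (inherits(g, "segment_graph")) g$nodes else
    rownames(g) %||% paste0("v", seq_len(nrow(g)))
}

#' @rdname graph-properties
#' @export
degree_vector <- function(g) {
  adj <- as_adjacency(g)
  stats::setNames(rowSums(adj), node_names(g))
}

# BFS distances from one source over a logical adjacency matrix;
# unreachable nodes get Inf.
bfs_distances <- function(adj, src) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- which(matrixStats_any(adj[frontier, , drop = FALSE]) & is.infinite(dist))
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

matrixStats_any <- function(m) colSums(m) > 0

#' @rdname graph-properties
#' @export
closeness_vector <- function(g) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  out <- vapply(seq_len(n), function(v) {
    dist <- bfs_distances(adj, v)
    reach <- is.finite(dist) & seq_len(n) != v
    r <- sum(reach)
    if (r == 0L) return(0)
    (r / (n - 1)) * (r / sum(dist[reach]))
  }, numeric(1L))
  stats::setNames(out, node_names(g))
}

#' @rdname graph-properties
#' @export
betweenness_vector <- function(g) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  nbrs <- apply(adj, 1L, which, simplify = FALSE)
  bc <- numeric(n)
  # Brandes (2001) accumulation for unweighted graphs.
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, node_names(g))
}

#' @rdname graph-properties
#' @export
relative_density <- function(g) {
  adj <- as_adjacency(g)
  (sum(adj) / 2) / nrow(adj)
}

#' Lp distance between per-node property vectors
#'
#' Distance between two networks on the same node set described by the
#' vectors of a per-node property: the Lp norm of the difference vector.
#' `p = 2` (default elsewhere in the package) is the Euclidean distance.
#'
#' @param a,b Numeric vectors of equal length, same property and node order.
#' @param p Norm order, `p >= 1` (may be `Inf`).
#' @return Non-negative scalar.
#' @export
lp_property_distance <- function(a, b, p = 2) {
  if (length(a) != length(b))
    stop("property vectors have different lengths")
  stopifnot(p >= 1)
  d <- abs(a - b)
  if (is.infinite(p)) return(max(d))
  sum(d^p)^(1 / p)
}

#' Global-property distance via symmetric difference and union
#'
#' Distance between two networks on the same node set in terms of a global
#' property `P`: the ratio `P(G delta G') / P(G union G')`, where
#' `G delta G'` contains the edges present in exactly one of the graphs and
#' `G union G'` the edges present in either. With relative density as `P`
#' the node counts cancel and the distance is `|E(delta)| / |E(union)|`,
#' which lies in `[0, 1]`, is 0 exactly when the edge sets coincide, and
#' grows as the intersection of the two networks becomes sparser relative
#' to their union. Two identical graphs (including two empty graphs) are at
#' distance 0.
#'
#' @param g1,g2 `segment_graph`s (or adjacency matrices) on identical node
#'   sets.
#' @param property Global property; `"density"` (relative density) is
#'   implemented.
#' @return Non-negative scalar, symmetric in its arguments.
#' @export
global_sd_distance <- function(g1, g2, property = "density") {
  property <- match.arg(property, "density")
  a1 <- as_adjacency(g1)
  a2 <- as_adjacency(g2)
  if (!identical(dim(a1), dim(a2)) ||
      !identical(node_names(g1), node_names(g2)))
    stop("graphs must share an identical node set")
  sym_diff <- xor(a1, a2)
  uni <- a1 | a2
  p_union <- relative_density(segment_graph_from_adjacency(uni, node_names(g1)))
  if (p_union == 0) return(0)
  p_sd <- relative_density(segment_graph_from_adjacency(sym_diff, node_names(g1)))
  p_sd / p_union
}
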