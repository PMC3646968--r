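#' Enumerate admissible consecutive segment pairs
#'
#' Every candidate breakpoint position `i` splits the time axis into a left
#' segment `[a..i]` and right segment `[i+1..b]`. This enumerates all
#' triples `(a, i, b)` with `1 <= a <= i < b <= T` and both segment lengths
#' at least `l_min`, in lexicographic order. With `l_min = 1` the count has
#' the closed form `T (T^2 - 1) / 6` (2600 pairs at `T = 25`).
#'
#' @param n_time Number of time points `T`.
#' @param l_min Minimum segment length.
#' @return Data frame with integer columns `a`, `i`, `b`.
#' @export
enumerate_pairs <- function(n_time, l_min = 1) {
  n_time <- as.integer(n_time)
  l_min <- as.integer(l_min)
  stopifnot(l_min >= 1)
  if (n_time < 2L * l_min)
    stop(sprintf("no admissible pair: T = %d < 2 * l_min = %d", n_time, 2L * l_min))
  out <- do.call(rbind, lapply(seq_len(n_time - 1L), function(i) {
    if (i < l_min || i + l_min > n_time) return(NULL)
    a <- seq_len(i - l_min + 1L)
    b <- seq.int(i + l_min, n_time)
    if (!length(a)) return(NULL)
    cbind(a = rep(a, each = length(b)), i = i, b = rep(b, length(a)))
  }))
  out <- as.data.frame(out)
  out[order(out$a, out$i, out$b), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Distances for all admissible consecutive segment pairs
#'
#' The weight source of the segmentation DAG: for every admissible triple
#' `(a, i, b)` the networks of `[a..i]` and `[i+1..b]` are reconstructed at
#' the threshold for their respective lengths and their distance is
#' computed. Each segment's network (and property vector) is computed once
#' and reused across all pairs it participates in.
#'
#' @param m Filtered expression matrix.
#' @param l_min Minimum segment length (`>= 2`; correlation is undefined on
#'   a single time point).
#' @param property Network property: `"density"` (global), `"degree"`,
#'   `"betweenness"` or `"closeness"` (per-node).
#' @param distance `"auto"` picks the global symmetric-difference/union
#'   distance for `"density"` and the Lp distance otherwise.
#' @param p Norm order for the Lp distance.
#' @param thresholds Threshold table from [threshold_table()], covering all
#'   lengths in `[l_min, T]`.
#' @param absolute Passed to [build_segment_network()].
#' @return A `pair_table`: data frame `(a, i, b, d)` with attributes
#'   `n_time`, `l_min`, `property`, `distance`, `p`.
#' @export
pair_weight_table <- function(m, l_min, property = c("density", "degree",
                                                     "betweenness", "closeness"),
                              distance = c("auto", "lp", "global"), p = 2,
                              thresholds, absolute = TRUE) {
  property <- match.arg(property)
  distance <- match.arg(distance)
  if (distance == "auto")
    distance <- if (property == "density") "global" else "lp"
  if (distance == "global" && property != "density")
    stop("the global symmetric-difference distance is defined for global properties (density)")
  if (distance == "lp" && property == "density")
    stop("use distance = 'global' with the density property")
  validate_expression_matrix(m)
  n_time <- ncol(m)
  l_min <- as.integer(l_min)
  if (l_min < 2L)
    stop("network reconstruction needs l_min >= 2 (correlation is undefined on 1 point)")
  pairs <- enumerate_pairs(n_time, l_min)
  segs <- unique(rbind(
    data.frame(start = pairs$a, end = pairs$i),
    data.frame(start = pairs$i + 1L, end = pairs$b)))
  lens <- segs$end - segs$start + 1L
  tau_of <- stats::setNames(thresholds$tau, thresholds$length)
  missing_len <- setdiff(unique(lens), thresholds$length)
  if (length(missing_len))
    stop("threshold table lacks segment lengths: ",
         paste(sort(missing_len), collapse = ", "))
  key <- function(s, e) paste(s, e, sep = ":")
  nets <- vector("list", nrow(segs))
  names(nets) <- key(segs$start, segs$end)
  for (j in seq_len(nrow(segs))) {
    g <- build_segment_network(m, c(segs$start[j], segs$end[j]),
                               tau = tau_of[[as.character(lens[j])]],
                               absolute = absolute)
    nets[[j]] <- if (distance == "global") {
      g$adjacency[upper.tri(g$adjacency)]
    } else {
      switch(property,
             degree = degree_vector(g),
             betweenness = betweenness_vector(g),
             closeness = closeness_vector(g))
    }
  }
  n_nodes <- nrow(m)
  d <- vapply(seq_len(nrow(pairs)), function(r) {
    left <- nets[[key(pairs$a[r], pairs$i[r])]]
    right <- nets[[key(pairs$i[r] + 1L, pairs$b[r])]]
    if (distance == "global") {
      m_union <- sum(left | right)
      if (m_union == 0) 0 else sum(xor(left, right)) / m_union
    } else {
      lp_property_distance(left, right, p)
    }
  }, numeric(1L))
  pt <- cbind(pairs, d = d)
  attr(pt, "n_time") <- n_time
  attr(pt, "l_min") <- l_min
  attr(pt, "property") <- property
  attr(pt, "distance") <- distance
  attr(pt, "p") <- p
  class(pt) <- c("pair_table", "data.frame")
  pt
}

#' Assemble a pair table from precomputed weights
#'
#' Mainly for testing, caching and for decoupling the expensive network
#' reconstruction from segmentation experiments: wraps a complete
#' `(a, i, b, d)` table (as produced by [pair_weight_table()] or read back
#' from TSV) into a validated `pair_table`.
#'
#' @param df Data frame with columns `a`, `i`, `b`, `d`.
#' @param n_time Number of time points `T`.
#' @param l_min Minimum segment length.
#' @return A `pair_table`.
#' @export
as_pair_table <- function(df, n_time, l_min = 1) {
  expected <- enumerate_pairs(n_time, l_min)
  df <- df[order(df$a, df$i, df$b), c("a", "i", "b", "d"), drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) != nrow(expected) ||
      !identical(as.integer(df$a), expected$a) ||
      !identical(as.integer(df$i), expected$i) ||
      !identical(as.integer(df$b), expected$b))
    stop("table does not cover exactly the admissible (a, i, b) triples")
  if (any(!is.finite(df$d)) || any(df$d < 0))
    stop("pair distances must be finite and non-negative")
  attr(df, "n_time") <- as.integer(n_time)
  attr(df, "l_min") <- as.integer(l_min)
  class(df) <- c("pair_table", "data.frame")
  df
}

#' Write / read a pair table as TSV
#'
#' @param pt A `pair_table`.
#' @param path File path.
#' @export
write_pair_table <- function(pt, path) {
  out <- as.data.frame(pt)
  out$d <- formatC(out$d, format = "g", digits = 17)  # bit-exact round trip
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @param n_time,l_min Dimensions used to validate the table read back.
#' @export
read_pair_table <- function(path, n_time, l_min = 1) {
  as_pair_table(utils::read.delim(path), n_time, l_min)
}

#' Build the segmentation DAG
#'
#' Transforms a pair table into the edge-weighted directed acyclic graph
#' whose source-to-target paths are exactly the segmentations of `[1..T]`
#' into at least two segments of length `>= l_min`: one node per admissible
#' segment pair `(a, i, b)`; a zero-weight edge from the source to every
#' node with `a = 1`; an edge `u -> v` (weight `d(u)`) whenever `v`'s left
#' segment equals `u`'s right segment; and an edge of weight `d(v)` from
#' each node whose right segment ends at `T` to the target. Edge weights
#' are placed so that the weight of any source-target path equals the sum
#' of `d` over its pair nodes.
#'
#' @param pt A `pair_table`.
#' @return A `seg_dag` (nodes, edge list, `n_time`, `l_min`).
#' @export
build_dag <- function(pt) {
  stopifnot(inherits(pt, "pair_table"), nrow(pt) > 0)
  n_time <- attr(pt, "n_time")
  nodes <- as.data.frame(pt)
  nodes$id <- seq_len(nrow(nodes))
  # u -> v iff (u$i + 1, u$b) == (v$a, v$i): join on the shared segment.
  left_key <- paste(nodes$a, nodes$i, sep = ":")
  right_key <- paste(nodes$i + 1L, nodes$b, sep = ":")
  idx_by_left <- split(nodes$id, left_key)
  succ <- idx_by_left[right_key]
  from <- rep(nodes$id, lengths(succ))
  to <- unlist(succ, use.names = FALSE)
  edges <- rbind(
    data.frame(from = 0L, to = nodes$id[nodes$a == 1L], weight = 0),
    if (length(to)) data.frame(from = from, to = to, weight = nodes$d[from]),
    data.frame(from = nodes$id[nodes$b == n_time], to = -1L,
               weight = nodes$d[nodes$b == n_time]))
  structure(list(nodes = nodes, edges = edges,
                 n_time = n_time, l_min = attr(pt, "l_min"),
                 source = 0L, target = -1L),
            class = "seg_dag")
}

#' @export
print.seg_dag <- function(x, ...) {
  cat(sprintf("seg_dag: T = %d, l_min = %d, %d pair nodes (+ source/target), %d edges\n",
              x$n_time, x$l_min, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Breakpoint penalties
#'
#' The penalty charged when a path through the segmentation DAG acquires a
#' new segment, scaled by the tuning parameter `lambda`. Two criteria:
#'
#' * **count** — `lambda * depth / k_max`, where `depth` is the number of
#'   segments in the path after adding the node and `k_max` the maximum
#'   possible number of breakpoints; the penalty grows with the number of
#'   segments, so the cumulative path penalty is convex in the segment
#'   count.
#' * **length** — `lambda / seg_len`, reciprocal in the number of time
#'   points of the new segment, so short segments are penalized hardest.
#'
#' Both vanish at `lambda = 0`. No penalty is charged on the edge from the
#' source to the first pair node, where two segments are necessarily
#' acquired at once; consequently an extra split of the first segment is
#' penalty-free and the optimizer tends to refine the first segment.
#'
#' @param depth Number of segments in the path after adding the node.
#' @param k_max Maximum possible number of breakpoints.
#' @param lambda Tuning parameter, `lambda >= 0`.
#' @return Non-negative scalar penalty.
#' @export
bp_penalty_count <- function(depth, k_max, lambda) {
  stopifnot(lambda >= 0, k_max >= 1, depth >= 1)
  lambda * depth / k_max
}

#' @rdname bp_penalty_count
#' @param seg_len Length (time points) of the newly added segment.
#' @export
bp_penalty_length <- function(seg_len, lambda) {
  stopifnot(lambda >= 0, seg_len >= 1)
  lambda / seg_len
}

#' Bounds for the penalty tuning parameter
#'
#' The tuning parameter is swept over a range tied to the scale of the path
#' weights: the lower bound is the smallest positive pair distance and the
#' upper bound the largest. An optional floor raises the lower bound.
#'
#' @param pt A `pair_table`.
#' @param floor Optional lower floor for `lambda_low`.
#' @return Numeric `c(lambda_low, lambda_high)`.
#' @export
lambda_bounds <- function(pt, floor = NULL) {
  d <- pt$d[pt$d > 0]
  if (!length(d))
    stop("degenerate instance: all pair distances are zero")
  lo <- min(d)
  if (!is.null(floor)) lo <- max(lo, floor)
  c(lambda_low = lo, lambda_high = max(pt$d))
}
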