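#' Similarity matrix over a time segment
#'
#' Computes the pairwise similarity of all entity profiles restricted to a
#' contiguous time segment. Pearson correlation is the shipped measure;
#' entries involving a profile with zero variance inside the segment are
#' undefined and returned as `NA` (such entities end up isolated in the
#' reconstructed network).
#'
#' @param m Expression matrix (entities x time points), no missing values.
#' @param segment Integer vector `c(start, end)`, 1-based inclusive.
#' @param measure Similarity measure; only `"pearson"` is implemented.
#' @return Symmetric `n x n` matrix with unit diagonal.
#' @export
similarity_matrix <- function(m, segment, measure = "pearson") {
  measure <- match.arg(measure, "pearson")
  validate_expression_matrix(m)
  seg <- as_segment(segment, ncol(m))
  if (seg[2L] - seg[1L] + 1L < 2L)
    stop("similarity needs a segment of length >= 2")
  s <- suppressWarnings(stats::cor(t(m[, seg[1L]:seg[2L], drop = FALSE])))
  diag(s) <- 1
  s
}

as_segment <- function(segment, n_time) {
  seg <- as.integer(segment)
  if (length(seg) != 2L || anyNA(seg))
    stop("a segment is an integer pair c(start, end)")
  if (seg[1L] < 1L || seg[2L] > n_time || seg[1L] > seg[2L])
    stop(sprintf("invalid segment [%d..%d] for T = %d", seg[1L], seg[2L], n_time))
  seg
}

# Circular windows of length len for every row of m, each standardized to
# zero mean and unit Euclidean norm, so window dot products are Pearson
# correlations. Returns a list (one n x len matrix per offset 0..T-1);
# zero-variance windows become NA rows.
standardized_windows <- function(m, len) {
  n_time <- ncol(m)
  lapply(0L:(n_time - 1L), function(off) {
    idx <- ((off + 0L:(len - 1L)) %% n_time) + 1L
    w <- m[, idx, drop = FALSE]
    w <- w - rowMeans(w)
    nrm <- sqrt(rowSums(w^2))
    bad <- nrm < .Machine$double.eps
    nrm[bad] <- 1
    w <- w / nrm
    w[bad, ] <- NA_real_
    w
  })
}

#' Permutation-test threshold for segment networks
#'
#' Estimates the correlation threshold that ensures significance at level
#' `alpha` for the absolute Pearson correlation between two profiles over a
#' segment of length `len`. The null distribution is built by randomizing
#' profiles and pooling the absolute correlations of all entity pairs. The
#' default `"rotation"` scheme circularly rotates each profile by an
#' independent random offset, which retains the dependence of adjacent time
#' points and therefore yields a heavier-tailed null (and a higher
#' threshold) than naive `"shuffle"` randomization on autocorrelated data.
#'
#' The threshold is the empirical `(1 - alpha)` order-statistic quantile of
#' the pooled null sample, so `alpha = 1` returns its minimum.
#'
#' @param m Expression matrix, no missing values.
#' @param len Segment length the threshold is for (`2 <= len <= T`).
#' @param alpha Significance level in `(0, 1]`.
#' @param n_perm Number of permutation rounds (ignored when `exhaustive`).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param scheme `"rotation"` (dependence-preserving, default) or
#'   `"shuffle"` (independent permutation of each profile).
#' @param exhaustive If `TRUE`, enumerate all `T^n` rotation-offset
#'   combinations instead of sampling (rotation scheme only; feasible for
#'   tiny inputs, used to make the null exact).
#' @return Threshold in `[0, 1]`.
#' @export
permutation_threshold <- function(m, len, alpha = 0.05, n_perm = 1000,
                                  seed = NULL,
                                  scheme = c("rotation", "shuffle"),
                                  exhaustive = FALSE) {
  scheme <- match.arg(scheme)
  validate_expression_matrix(m)
  n_time <- ncol(m)
  n <- nrow(m)
  if (len > n_time) stop("len exceeds the number of time points")
  if (len < 2L) stop("len must be at least 2")
  stopifnot(alpha > 0, alpha <= 1, n_perm >= 1)
  pool <- if (exhaustive) {
    if (scheme != "rotation") stop("exhaustive enumeration applies to the rotation scheme")
    wins <- standardized_windows(m, len)
    combos <- as.matrix(expand.grid(rep(list(seq_len(n_time)), n)))
    unlist(lapply(seq_len(nrow(combos)), function(k) {
      z <- do.call(rbind, lapply(seq_len(n), function(r) wins[[combos[k, r]]][r, ]))
      r <- tcrossprod(z)
      abs(r[upper.tri(r)])
    }))
  } else if (scheme == "rotation") {
    wins <- standardized_windows(m, len)
    with_seed(seed, {
      unlist(lapply(seq_len(n_perm), function(p) {
        off <- sample.int(n_time, n, replace = TRUE)
        z <- do.call(rbind, lapply(seq_len(n), function(r) wins[[off[r]]][r, ]))
        r <- tcrossprod(z)
        abs(r[upper.tri(r)])
      }))
    })
  } else {
    with_seed(seed, {
      unlist(lapply(seq_len(n_perm), function(p) {
        z <- t(apply(m, 1L, sample))[, seq_len(len), drop = FALSE]
        r <- suppressWarnings(stats::cor(t(z)))
        abs(r[upper.tri(r)])
      }))
    })
  }
  pool <- pool[!is.na(pool)]
  if (!length(pool)) stop("null distribution is empty (all profiles constant?)")
  unname(stats::quantile(pool, probs = 1 - alpha, type = 1))
}

#' Threshold table over all admissible segment lengths
#'
#' Computes [permutation_threshold()] once per segment length in
#' `[max(2, l_min), T]` and returns them as a lookup table, so that the
#' expensive permutation test is not repeated for every candidate segment.
#'
#' @inheritParams permutation_threshold
#' @param l_min Minimum segment length of the planned segmentation.
#' @return Data frame with columns `length` and `tau`; `alpha`, `n_perm`,
#'   `scheme` and `seed` are recorded as attributes.
#' @export
threshold_table <- function(m, l_min = 4, alpha = 0.05, n_perm = 1000,
                            seed = NULL, scheme = c("rotation", "shuffle")) {
  scheme <- match.arg(scheme)
  lengths <- max(2L, as.integer(l_min)):ncol(m)
  seeds <- derive_seeds(seed, length(lengths))
  tau <- vapply(seq_along(lengths), function(i) {
    permutation_threshold(m, lengths[i], alpha = alpha, n_perm = n_perm,
                          seed = seeds[[i]], scheme = scheme)
  }, numeric(1L))
  out <- data.frame(length = lengths, tau = tau)
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "scheme") <- scheme
  attr(out, "seed") <- seed
  out
}

#' Write / read a threshold table as TSV
#'
#' @param tt Threshold table from [threshold_table()].
#' @param path File path.
#' @export
write_threshold_table <- function(tt, path) {
  utils::write.table(tt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  utils::read.delim(path)
}

#' Reconstruct the network of one time segment
#'
#' Builds an undirected simple graph on the full entity set: two entities
#' are connected when the magnitude of their similarity over the segment
#' reaches the threshold `tau`. With `absolute = FALSE` only positive
#' correlations at or above `tau` create edges. Undefined similarities
#' (zero-variance profiles) never create edges, so such entities are
#' isolated nodes.
#'
#' @inheritParams similarity_matrix
#' @param tau Similarity threshold, `tau >= 0`.
#' @param absolute Threshold `|r|` (default) rather than signed `r`.
#' @return A `segment_graph`: list with the logical adjacency matrix
#'   (`adjacency`), node names, `segment` and `tau`.
#' @export
build_segment_network <- function(m, segment, tau, absolute = TRUE,
                                  measure = "pearson") {
  stopifnot(tau >= 0)
  s <- similarity_matrix(m, segment, measure)
  val <- if (absolute) abs(s) else s
  adj <- !is.na(val) & val >= tau
  diag(adj) <- FALSE
  structure(list(adjacency = adj, nodes = rownames(m),
                 segment = as_segment(segment, ncol(m)), tau = tau),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat(sprintf("segment_graph: [%d..%d], %d nodes, %d edges, tau = %.4g\n",
              x$segment[1L], x$segment[2L], length(x$nodes),
              sum(x$adjacency) / 2L, x$tau))
  invisible(x)
}

segment_graph_from_adjacency <- function(adj, nodes = NULL) {
  nodes <- nodes %||% rownames(adj) %||% paste0("v", seq_len(nrow(adj)))
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  dimnames(adj) <- list(nodes, nodes)
  structure(list(adjacency = adj, nodes = nodes, segment = NULL, tau = NULL),
            class = "segment_graph")
}

#' Convert a segment network to an igraph object
#'
#' @param g A `segment_graph`.
#' @return An [igraph::graph] (undirected, simple).
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "segment_graph"))
  igraph::graph_from_adjacency_matrix(g$adjacency * 1, mode = "undirected")
}

#' Export a segment network for inspection
#'
#' Writes either a two-column edge-list TSV or GraphML.
#'
#' @param g A `segment_graph`.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @export
write_segment_network <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
  } else {
    idx <- which(g$adjacency & upper.tri(g$adjacency), arr.ind = TRUE)
    utils::write.table(
      data.frame(from = g$nodes[idx[, 1L]], to = g$nodes[idx[, 2L]]),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
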