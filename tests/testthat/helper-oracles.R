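# Independent brute-force oracles used across the suite. They enumerate or
# hand-evaluate, never call the code paths they check.

# All segmentations of [1..n_time] into >= 2 segments of length >= l_min,
# as lists of segment lengths.
enumerate_segmentations <- function(n_time, l_min = 1) {
  out <- list()
  rec <- function(prefix, rem) {
    if (rem == 0L) {
      if (length(prefix) >= 2L) out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    if (rem < l_min) return(invisible())
    for (l in l_min:rem) rec(c(prefix, l), rem - l)
  }
  rec(integer(0), as.integer(n_time))
  out
}

lengths_to_breakpoints <- function(lens) {
  e <- cumsum(lens)
  e[-length(e)]
}

# Objective F of a segmentation, looked up from a (a, i, b, d) data frame.
oracle_objective <- function(pe, lens) {
  e <- cumsum(lens)
  s <- c(1L, utils::head(e, -1L) + 1L)
  d_of <- stats::setNames(pe$d, paste(pe$a, pe$i, pe$b, sep = ":"))
  sum(vapply(seq_len(length(lens) - 1L), function(j) {
    d_of[[paste(s[j], e[j], e[j + 1L], sep = ":")]]
  }, numeric(1L)))
}

# Penalized objective with the package's penalty forms, summed by direct
# enumeration over the segments of the path (first two segments exempt).
oracle_penalty <- function(lens, criterion, lambda, k_max) {
  k <- length(lens)
  if (k < 3L || lambda == 0) return(0)
  if (criterion == "count") {
    sum(lambda * (3:k) / k_max)
  } else {
    sum(lambda / lens[3:k])
  }
}

# Exhaustive optimum under the package's tie-breaking: max score, then
# fewest segments, then lexicographically smallest breakpoints.
oracle_best <- function(pe, n_time, l_min = 1, criterion = "none",
                        lambda = 0, k_max = NULL) {
  k_max <- if (is.null(k_max)) max(1L, n_time %/% l_min - 1L) else k_max
  segs <- enumerate_segmentations(n_time, l_min)
  scores <- vapply(segs, function(lens) {
    oracle_objective(pe, lens) -
      if (criterion == "none") 0 else
        oracle_penalty(lens, criterion, lambda, k_max)
  }, numeric(1L))
  opt <- max(scores)
  cand <- which(scores >= opt - 1e-9 * (1 + abs(opt)))
  ks <- lengths(segs[cand])
  cand <- cand[ks == min(ks)]
  bps <- lapply(segs[cand], lengths_to_breakpoints)
  ord <- order(vapply(bps, paste, character(1L), collapse = ","))
  list(score = opt, k = min(ks), breakpoints = bps[[ord[1L]]])
}

random_pair_table <- function(n_time, l_min = 1) {
  pe <- enumerate_pairs(n_time, l_min)
  pe$d <- stats::runif(nrow(pe))
  as_pair_table(pe, n_time, l_min)
}

# Adjacency matrix constructors for hand-checked graphs.
adj_from_edges <- function(n, edges, nodes = paste0("v", seq_len(n))) {
  a <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (e in edges) {
    a[e[1L], e[2L]] <- TRUE
    a[e[2L], e[1L]] <- TRUE
  }
  a
}

path_graph <- function(n) adj_from_edges(n, lapply(seq_len(n - 1L), function(i) c(i, i + 1L)))
complete_graph <- function(n) {
  a <- matrix(TRUE, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  diag(a) <- FALSE
  a
}
star_graph <- function(n_leaves) adj_from_edges(n_leaves + 1L, lapply(seq_len(n_leaves) + 1L, function(i) c(1L, i)))

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(stats::runif(n * n) < p, n, n)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  a <- a | t(a)
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}
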