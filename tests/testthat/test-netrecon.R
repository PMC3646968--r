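toy_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))), paste0("t", seq_len(ncol(m))))
  m
}

test_that("segment similarity is Pearson correlation with NA for flat profiles", {
  m <- toy_matrix(list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(2, 4, 6, 8),
                       c(4, 3, 2, 1), c(5, 5, 5, 5)))
  s <- similarity_matrix(m, c(1, 4))
  expect_equal(s["g1", "g2"], 0.8)          # hand: cov 4/3, var 5/3 each
  expect_equal(s["g1", "g3"], 1)            # identical shape
  expect_equal(s["g1", "g4"], -1)           # negation
  expect_true(is.na(s["g1", "g5"]))         # zero variance -> undefined
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 5))
  expect_error(similarity_matrix(m, c(2, 2)), "length >= 2")
  # restriction to a sub-segment uses only those columns
  s23 <- similarity_matrix(m, c(2, 3))
  expect_equal(s23["g1", "g2"], -1)         # (2,3) vs (3,2)
})

test_that("rotation threshold matches the exhaustively enumerated null", {
  m <- toy_matrix(list(c(1, 2, 4, 3), c(2, 1, 3, 5)))
  # independent oracle: all 4 x 4 circular offset combinations
  rot <- function(x, o) x[((seq_along(x) - 1 + o) %% length(x)) + 1]
  pool <- c()
  for (o1 in 0:3) for (o2 in 0:3)
    pool <- c(pool, abs(stats::cor(rot(m[1, ], o1), rot(m[2, ], o2))))
  for (alpha in c(0.05, 0.25, 0.5, 1)) {
    expected <- unname(stats::quantile(pool, 1 - alpha, type = 1))
    expect_equal(permutation_threshold(m, 4, alpha = alpha, exhaustive = TRUE),
                 expected, info = paste("alpha =", alpha))
  }
  # alpha = 1 is the minimum of the null sample
  expect_equal(permutation_threshold(m, 4, alpha = 1, exhaustive = TRUE),
               min(pool))
})

test_that("threshold is monotone in alpha and deterministic under a seed", {
  withr::local_seed(99)
  m <- toy_matrix(lapply(1:6, function(i) as.numeric(arima.sim(list(ar = 0.5), 12))))
  t1 <- permutation_threshold(m, 6, alpha = 0.01, n_perm = 200, seed = 5)
  t2 <- permutation_threshold(m, 6, alpha = 0.2, n_perm = 200, seed = 5)
  expect_gte(t1, t2)
  expect_identical(t1, permutation_threshold(m, 6, alpha = 0.01, n_perm = 200, seed = 5))
  expect_gte(t2, 0)
  expect_lte(t1, 1)
  expect_error(permutation_threshold(m, 13, seed = 1), "exceeds")
})

test_that("dependence-preserving null has a heavier upper tail than shuffling on AR(1) data", {
  withr::local_seed(42)
  m <- toy_matrix(lapply(1:15, function(i)
    as.numeric(arima.sim(list(ar = 0.8), 30))))
  tau_rot <- permutation_threshold(m, 8, alpha = 0.05, n_perm = 300, seed = 1,
                                   scheme = "rotation")
  tau_shuf <- permutation_threshold(m, 8, alpha = 0.05, n_perm = 300, seed = 1,
                                    scheme = "shuffle")
  expect_gt(tau_rot, tau_shuf)
})

test_that("edges follow the |r| >= tau rule on hand-computed correlations", {
  # three profiles with pairwise r: (g1,g2) = 0.8, (g1,g3) = -1, (g2,g3) = -0.8
  m <- toy_matrix(list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(4, 3, 2, 1)))
  g <- build_segment_network(m, c(1, 4), tau = 0.5)
  expect_equal(sum(g$adjacency) / 2, 3)          # all |r| >= 0.5
  g2 <- build_segment_network(m, c(1, 4), tau = 0.9)
  expect_equal(sum(g2$adjacency) / 2, 1)         # only |r| = 1 survives
  expect_true(g2$adjacency["g1", "g3"])
  # signed rule drops anti-correlations
  g3 <- build_segment_network(m, c(1, 4), tau = 0.5, absolute = FALSE)
  expect_equal(sum(g3$adjacency) / 2, 1)
  expect_true(g3$adjacency["g1", "g2"])
  # tau > 1 -> empty graph; tau = 0 -> all defined pairs connected
  expect_equal(sum(build_segment_network(m, c(1, 4), tau = 1.01)$adjacency), 0)
  expect_equal(sum(build_segment_network(m, c(1, 4), tau = 0)$adjacency) / 2, 3)
})

test_that("zero-variance profiles end up isolated", {
  m <- toy_matrix(list(c(1, 2, 3, 4), c(2, 4, 6, 8), c(7, 7, 7, 7)))
  g <- build_segment_network(m, c(1, 4), tau = 0)
  expect_equal(unname(degree_vector(g)), c(1, 1, 0))
})

test_that("network reconstruction is deterministic and exportable", {
  withr::local_seed(3)
  m <- toy_matrix(lapply(1:5, function(i) rnorm(8)))
  g1 <- build_segment_network(m, c(2, 7), tau = 0.4)
  g2 <- build_segment_network(m, c(2, 7), tau = 0.4)
  expect_identical(g1$adjacency, g2$adjacency)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_segment_network(g1, f)
  el <- utils::read.delim(f)
  expect_equal(nrow(el), sum(g1$adjacency) / 2)
  ig <- as_igraph(g1)
  expect_equal(igraph::gsize(ig), sum(g1$adjacency) / 2)
})

test_that("threshold tables cover all admissible lengths and serialize", {
  withr::local_seed(8)
  m <- toy_matrix(lapply(1:6, function(i) rnorm(10)))
  tt <- threshold_table(m, l_min = 4, alpha = 0.1, n_perm = 50, seed = 2)
  expect_equal(tt$length, 4:10)
  expect_true(all(tt$tau >= 0 & tt$tau <= 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_threshold_table(tt, f)
  back <- read_threshold_table(f)
  expect_equal(back$tau, tt$tau)
})
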