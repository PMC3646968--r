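test_that("pair enumeration matches the closed form and brute force", {
  expect_equal(nrow(enumerate_pairs(25, 1)), 2600)
  expect_identical(enumerate_pairs(2, 1),
                   data.frame(a = 1L, i = 1L, b = 2L))
  expect_equal(nrow(enumerate_pairs(6, 2)), 10)
  expect_error(enumerate_pairs(5, 3), "no admissible pair")

  for (n_time in 2:12) {
    pe <- enumerate_pairs(n_time, 1)
    # closed form T(T^2 - 1)/6
    expect_equal(nrow(pe), n_time * (n_time^2 - 1) / 6)
    # brute-force oracle: count triples directly
    brute <- 0L
    for (a in 1:n_time) for (i in a:n_time) for (b in i:n_time)
      if (a <= i && i < b) brute <- brute + 1L
    expect_equal(nrow(pe), brute)
    # each triple appears once, lexicographically sorted
    expect_false(anyDuplicated(pe) > 0)
    expect_identical(pe, pe[order(pe$a, pe$i, pe$b), ])
  }

  # l_min respected on both sides of every cut
  pe <- enumerate_pairs(10, 3)
  expect_true(all(pe$i - pe$a + 1 >= 3 & pe$b - pe$i >= 3))
})

test_that("DAG structure encodes segmentations bijectively", {
  pe <- enumerate_pairs(25, 1); pe$d <- 1
  dag <- build_dag(as_pair_table(pe, 25, 1))
  expect_equal(nrow(dag$nodes), 2600)

  # node -> node edges only between chained pairs, start strictly increases
  inner <- dag$edges[dag$edges$from > 0 & dag$edges$to > 0, ]
  expect_true(all(dag$nodes$a[inner$to] > dag$nodes$a[inner$from]))

  # s-t path count equals segmentation count for small T
  for (n_time in 3:7) {
    pe <- enumerate_pairs(n_time, 1); pe$d <- 1
    dag <- build_dag(as_pair_table(pe, n_time, 1))
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(dag$edges$from),
                 to = as.character(dag$edges$to)))
    n_paths <- length(igraph::all_simple_paths(g, from = "0", to = "-1"))
    expect_equal(n_paths, length(enumerate_segmentations(n_time, 1)),
                 info = paste("T =", n_time))
  }
})

test_that("every DAG path weight equals the sum of its pair-node distances", {
  withr::local_seed(17)
  pt <- random_pair_table(6, 1)
  dag <- build_dag(pt)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(dag$edges$from),
               to = as.character(dag$edges$to),
               weight = dag$edges$weight))
  paths <- igraph::all_simple_paths(g, from = "0", to = "-1")
  for (p in paths) {
    ids <- as.integer(names(p))
    nodes <- ids[ids > 0]
    w <- sum(vapply(seq_len(length(ids) - 1), function(j) {
      e <- dag$edges$from == ids[j] & dag$edges$to == ids[j + 1]
      dag$edges$weight[which(e)[1]]
    }, numeric(1)))
    expect_equal(w, sum(dag$nodes$d[nodes]))
  }
})

test_that("unpenalized DP equals exhaustive search with identical tie-breaking", {
  withr::local_seed(101)
  for (rep in 1:40) {
    n_time <- sample(4:7, 1)
    l_min <- sample(1:2, 1)
    if (n_time < 2 * l_min) l_min <- 1
    pt <- random_pair_table(n_time, l_min)
    dag <- build_dag(pt)
    res <- max_weight_min_length_path(dag)
    ref <- oracle_best(pt, n_time, l_min)
    expect_equal(res$objective, ref$score, tolerance = 1e-12)
    expect_equal(res$k, ref$k)
    expect_equal(res$breakpoints, as.integer(ref$breakpoints))
    # objective identity: F recomputable from breakpoints
    seg <- segments_table(res$breakpoints, n_time)
    f <- sum(vapply(seq_len(res$k - 1), function(j) {
      pt$d[pt$a == seg$start[j] & pt$i == seg$end[j] & pt$b == seg$end[j + 1]]
    }, numeric(1)))
    expect_equal(res$objective, f)
  }
})

test_that("equal positive weights select the finest segmentation", {
  pe <- enumerate_pairs(4, 1); pe$d <- 1
  res <- max_weight_min_length_path(build_dag(as_pair_table(pe, 4, 1)))
  expect_equal(res$k, 4)
  expect_equal(res$breakpoints, c(1L, 2L, 3L))
  expect_equal(res$objective, 3)

  pe2 <- enumerate_pairs(2, 1); pe2$d <- 0.37
  res2 <- max_weight_min_length_path(build_dag(as_pair_table(pe2, 2, 1)))
  expect_equal(res2$k, 2)
  expect_equal(res2$objective, 0.37)
})

test_that("penalty functions obey their monotonicity contracts", {
  expect_equal(bp_penalty_count(3, k_max = 35, lambda = 0), 0)
  expect_equal(bp_penalty_length(5, lambda = 0), 0)
  expect_equal(bp_penalty_count(1, k_max = 35, lambda = 1), 1 / 35)
  expect_equal(bp_penalty_length(4, lambda = 1), 1 / 4)
  for (lambda in c(0.3, 1, 4)) {
    pens <- vapply(1:10, bp_penalty_count, numeric(1), k_max = 10, lambda = lambda)
    expect_true(all(diff(pens) > 0))
    penl <- vapply(1:10, bp_penalty_length, numeric(1), lambda = lambda)
    expect_true(all(diff(penl) < 0))
  }
})

test_that("penalized DP equals exhaustive penalized search for both criteria", {
  withr::local_seed(202)
  for (rep in 1:60) {
    n_time <- sample(4:7, 1)
    pt <- random_pair_table(n_time, 1)
    dag <- build_dag(pt)
    lambda <- stats::runif(1, 0, 2)
    for (criterion in c("count", "length")) {
      res <- penalized_path(dag, criterion = criterion, lambda = lambda)
      ref <- oracle_best(pt, n_time, 1, criterion = criterion,
                         lambda = lambda, k_max = res$k_max)
      expect_equal(res$score, ref$score, tolerance = 1e-9,
                   info = paste(criterion, "rep", rep))
      expect_equal(res$k, ref$k)
      expect_equal(res$breakpoints, as.integer(ref$breakpoints))
    }
  }
})

test_that("lambda = 0 reduces the penalized DP to the unpenalized solver", {
  withr::local_seed(303)
  for (rep in 1:10) {
    pt <- random_pair_table(6, 1)
    dag <- build_dag(pt)
    base <- max_weight_min_length_path(dag)
    for (criterion in c("count", "length")) {
      res <- penalized_path(dag, criterion = criterion, lambda = 0)
      expect_equal(res$breakpoints, base$breakpoints)
      expect_equal(res$score, base$objective)
    }
  }
})

test_that("segment count is non-increasing along a count-criterion sweep", {
  withr::local_seed(404)
  for (rep in 1:20) {
    pt <- random_pair_table(sample(5:8, 1), 1)
    dag <- build_dag(pt)
    sw <- sweep_lambda(dag, criterion = "count", n_grid = 15)$sweep
    expect_true(all(diff(sw$k) <= 0), info = paste("rep", rep))
  }
})

test_that("lambda bounds track the distance range and scale linearly", {
  pe <- enumerate_pairs(5, 1)
  pe$d <- rep(c(0.2, 0.9, 3.1), length.out = nrow(pe))
  pt <- as_pair_table(pe, 5, 1)
  expect_equal(unname(lambda_bounds(pt)), c(0.2, 3.1))
  pe$d <- rep(0.7, nrow(pe))
  expect_equal(unname(lambda_bounds(as_pair_table(pe, 5, 1))), c(0.7, 0.7))
  # scaling all distances scales both bounds
  pe$d <- rep(c(0.2, 0.9, 3.1), length.out = nrow(pe))
  b1 <- lambda_bounds(as_pair_table(pe, 5, 1))
  pe$d <- pe$d * 2.5
  expect_equal(unname(lambda_bounds(as_pair_table(pe, 5, 1))), unname(b1 * 2.5))
  # floor flag raises the lower bound only
  pe$d <- rep(c(0.2, 0.9, 3.1), length.out = nrow(pe))
  expect_equal(unname(lambda_bounds(as_pair_table(pe, 5, 1), floor = 0.5)),
               c(0.5, 3.1))
  pe$d <- rep(0, nrow(pe))
  expect_error(lambda_bounds(as_pair_table(pe, 5, 1)), "degenerate")
})

test_that("sweeps report one row per grid point and a modal consensus", {
  withr::local_seed(505)
  pt <- random_pair_table(7, 1)
  dag <- build_dag(pt)
  sw <- sweep_lambda(dag, "count", n_grid = 20)
  expect_equal(nrow(sw$sweep), 20)
  counts <- table(sw$sweep$breakpoints)
  expect_equal(sw$consensus$support, max(counts))
  expect_equal(paste(sw$breakpoints, collapse = ","),
               names(counts)[which(counts == max(counts))][1])

  # n_grid = 1 runs at the lower bound
  one <- sweep_lambda(dag, "count", n_grid = 1)
  lo <- lambda_bounds(pt)[[1]]
  direct <- penalized_path(dag, "count", lambda = lo)
  expect_equal(one$breakpoints, direct$breakpoints)

  # constant solution across the grid is its own consensus
  pe <- enumerate_pairs(6, 1); pe$d <- 0.01
  pe$d[pe$a == 1 & pe$i == 3 & pe$b == 6] <- 5
  cdag <- build_dag(as_pair_table(pe, 6, 1))
  csw <- sweep_lambda(cdag, "count", n_grid = 10)
  expect_equal(length(unique(csw$sweep$breakpoints)), 1)
  expect_equal(csw$breakpoints, 3L)
})

test_that("pair tables round trip through TSV and validate coverage", {
  withr::local_seed(606)
  pt <- random_pair_table(7, 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(pt, f)
  back <- read_pair_table(f, 7, 2)
  expect_equal(back$d, pt$d)
  # truncated table rejected
  broken <- as.data.frame(pt)[-3, ]
  expect_error(as_pair_table(broken, 7, 2), "triples")
})
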