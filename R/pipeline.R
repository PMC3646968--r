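#' End-to-end network-based segmentation of a multivariate time series
#'
#' Full pipeline on a filtered expression matrix: estimate permutation
#' thresholds for every admissible segment length, reconstruct all
#' candidate segment networks and their pairwise distances, build the
#' segmentation DAG, and solve it — unpenalized, at a single tuning value,
#' or over a tuning-parameter sweep with consensus.
#'
#' @param m Numeric expression matrix (entities x time points), already
#'   filtered (no missing values); see [filter_expression_matrix()].
#' @param property Network property for the distances (see
#'   [pair_weight_table()]).
#' @param distance Distance family (`"auto"`, `"lp"`, `"global"`).
#' @param p Lp norm order.
#' @param l_min Minimum segment length (default 4, the smallest length for
#'   which the correlation threshold is statistically meaningful on real
#'   data; use 3 for short synthetic series).
#' @param alpha Significance level of the permutation threshold.
#' @param n_perm Permutation rounds per segment length.
#' @param penalty `"count"`, `"length"` or `"none"`.
#' @param lambda Single tuning value; ignored when `sweep = TRUE`.
#' @param sweep If `TRUE` (default for penalized runs), sweep `n_grid`
#'   equidistant tuning values between [lambda_bounds()] of the instance.
#' @param n_grid Sweep grid size.
#' @param scheme Randomization scheme of the permutation test.
#' @param absolute Use `|r|` when thresholding correlations.
#' @param seed Integer seed controlling all randomness of the run.
#' @param thresholds Optional precomputed [threshold_table()].
#' @param pair_table Optional precomputed [pair_weight_table()]; when
#'   supplied, network reconstruction is skipped entirely.
#' @return A `segmentation_result`; the pair table and thresholds used are
#'   attached as attributes `pair_table` and `thresholds`.
#' @export
segment_time_series <- function(m, property = "density", distance = "auto",
                                p = 2, l_min = 4, alpha = 0.05,
                                n_perm = 1000,
                                penalty = c("count", "length", "none"),
                                lambda = NULL, sweep = TRUE, n_grid = 20,
                                scheme = "rotation", absolute = TRUE,
                                seed = NULL, thresholds = NULL,
                                pair_table = NULL) {
  penalty <- match.arg(penalty)
  if (is.null(pair_table)) {
    validate_expression_matrix(m)
    if (ncol(m) < 2L * l_min)
      stop(sprintf("l_min = %d admits no segment pair for T = %d columns",
                   l_min, ncol(m)))
    thresholds <- thresholds %||%
      threshold_table(m, l_min = l_min, alpha = alpha, n_perm = n_perm,
                      seed = seed, scheme = scheme)
    pair_table <- pair_weight_table(m, l_min = l_min, property = property,
                                    distance = distance, p = p,
                                    thresholds = thresholds,
                                    absolute = absolute)
  }
  dag <- build_dag(pair_table)
  res <- if (penalty == "none") {
    max_weight_min_length_path(dag)
  } else if (sweep && is.null(lambda)) {
    sweep_lambda(dag, criterion = penalty, n_grid = n_grid)
  } else {
    lambda <- lambda %||% lambda_bounds(pair_table)[[1L]]
    penalized_path(dag, criterion = penalty, lambda = lambda)
  }
  res$property <- attr(pair_table, "property")
  res$distance <- attr(pair_table, "distance")
  res$l_min <- attr(pair_table, "l_min")
  attr(res, "pair_table") <- pair_table
  attr(res, "thresholds") <- thresholds
  res
}

#' Replicated benchmark segmentation experiment
#'
#' Generates the synthetic benchmark under `n_seeds` independent seeds,
#' segments each replicate with the penalized sweep pipeline, and reports
#' the per-replicate consensus segmentations together with the majority
#' segment count across replicates and the recovery of the planted
#' breakpoints (a planted cut counts as recovered when some consensus cut
#' lies within `tolerance` of it).
#'
#' @param n_seeds Number of replicate benchmarks.
#' @param seed Master seed from which the replicate seeds are derived.
#' @param config_args Named list of [benchmark_config()] overrides.
#' @param l_min Minimum segment length used in the segmentation runs
#'   (default 3; see the methods vignette).
#' @inheritParams segment_time_series
#' @return A list: `runs` (data frame with seed, k, breakpoints), `k_majority`,
#'   `recovered` (logical matrix replicates x planted cuts),
#'   `majority_recovered` (logical per planted cut), `results` (the
#'   per-replicate `segmentation_result`s).
#' @export
benchmark_experiment <- function(n_seeds = 20, seed = 1,
                                 config_args = list(), property = "density",
                                 l_min = 3, alpha = 0.05, n_perm = 1000,
                                 penalty = "count", n_grid = 20,
                                 tolerance = 1) {
  seeds <- unlist(derive_seeds(seed, n_seeds))
  results <- vector("list", n_seeds)
  truth <- NULL
  for (r in seq_len(n_seeds)) {
    cfg <- do.call(benchmark_config, c(list(seed = seeds[r]), config_args))
    bench <- assemble_benchmark(cfg)
    truth <- bench$breakpoints
    results[[r]] <- segment_time_series(
      bench$matrix, property = property, l_min = l_min, alpha = alpha,
      n_perm = n_perm, penalty = penalty, sweep = TRUE, n_grid = n_grid,
      seed = seeds[r])
  }
  ks <- vapply(results, `[[`, integer(1L), "k")
  bps <- lapply(results, `[[`, "breakpoints")
  tab <- table(ks)
  k_majority <- as.integer(names(tab)[which.max(tab)])
  recovered <- t(vapply(bps, function(bp)
    vapply(truth, function(tr) any(abs(bp - tr) <= tolerance), logical(1L)),
    logical(length(truth))))
  list(runs = data.frame(seed = seeds, k = ks,
                         breakpoints = vapply(bps, paste, character(1L),
                                              collapse = ",")),
       k_majority = k_majority,
       k_majority_share = max(tab) / n_seeds,
       recovered = recovered,
       majority_recovered = colMeans(recovered) > 0.5,
       truth = truth,
       results = results)
}
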