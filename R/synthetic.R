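#' Configuration of the synthetic segmentation benchmark
#'
#' Describes a multivariate time series with planted breakpoints: per time
#' segment, a small set of characteristic profiles is drawn from a
#' zero-mean ARMA process; every variable copies one randomly chosen
#' characteristic profile per segment, observation noise is added, and the
#' segment boundaries are smoothed with a discrete 3-tap approximation of a
#' Gaussian kernel to mimic temporal dependence across breakpoints.
#'
#' Defaults reproduce the benchmark the method was designed on: 70
#' variables over 36 time points, segments ending at time points 7, 12, 21
#' (and 36), with 2, 6, 3 and 7 characteristic profiles respectively.
#' The ARMA innovation scale is chosen so the stationary process variance
#' is 1; the observation noise standard deviation is therefore relative to
#' unit signal variance.
#'
#' @param n_vars Number of variables (rows).
#' @param n_time Number of time points.
#' @param breakpoints Segment-final time points of the planted segments
#'   (excluding `n_time`), strictly increasing inside `(1, n_time)`.
#' @param profiles_per_segment Number of characteristic profiles per
#'   segment; length must equal `length(breakpoints) + 1`.
#' @param ar,ma ARMA coefficient vectors (defaults ARMA(1,1) with
#'   `ar = 0.6`, `ma = 0.3`); the AR part must be stationary.
#' @param noise_sd Standard deviation of the additive Gaussian
#'   observation noise (default 0.3).
#' @param kernel Symmetric, non-negative, normalized 3-tap smoothing
#'   weights (default `c(0.25, 0.5, 0.25)`).
#' @param seed Optional integer seed making the benchmark reproducible.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_vars = 70, n_time = 36,
                             breakpoints = c(7, 12, 21),
                             profiles_per_segment = c(2, 6, 3, 7),
                             ar = 0.6, ma = 0.3, noise_sd = 0.3,
                             kernel = c(0.25, 0.5, 0.25), seed = NULL) {
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints) == 0L ||
      is.unsorted(breakpoints, strictly = TRUE) ||
      any(breakpoints <= 1L) || any(breakpoints >= n_time))
    stop("breakpoints must be strictly increasing inside (1, n_time)")
  if (length(profiles_per_segment) != length(breakpoints) + 1L)
    stop("profiles_per_segment must have one entry per segment")
  stopifnot(all(profiles_per_segment >= 1), noise_sd >= 0)
  if (length(kernel) != 3L || any(kernel < 0) ||
      abs(sum(kernel) - 1) > 1e-12 || abs(kernel[1L] - kernel[3L]) > 1e-12)
    stop("kernel must be 3 symmetric non-negative weights summing to 1")
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1))
    stop("AR coefficients define a non-stationary process")
  structure(list(n_vars = as.integer(n_vars), n_time = as.integer(n_time),
                 breakpoints = breakpoints,
                 profiles_per_segment = as.integer(profiles_per_segment),
                 ar = ar, ma = ma, noise_sd = noise_sd, kernel = kernel,
                 seed = seed),
            class = "benchmark_config")
}

# Innovation sd giving unit stationary variance for an ARMA(1,1); for
# other orders fall back to a moment estimate of the ACF at lag 0.
arma_innovation_sd <- function(ar, ma) {
  if (length(ar) == 0L && length(ma) == 0L) return(1)
  if (length(ar) <= 1L && length(ma) <= 1L) {
    phi <- if (length(ar)) ar else 0
    theta <- if (length(ma)) ma else 0
    gamma0 <- (1 + 2 * phi * theta + theta^2) / (1 - phi^2)
    return(1 / sqrt(gamma0))
  }
  acf0 <- stats::ARMAacf(ar = ar, ma = ma, lag.max = 0)
  psi <- stats::ARMAtoMA(ar = ar, ma = ma, lag.max = 500)
  1 / sqrt(1 + sum(psi^2))
}

#' Characteristic profiles for one benchmark segment
#'
#' Simulates the segment's set of characteristic profiles as independent
#' draws from the configured zero-mean ARMA process (via
#' [stats::arima.sim()]), each of the segment's length.
#'
#' @param config A `benchmark_config`.
#' @param segment_index Which segment (1-based).
#' @return Matrix with one row per characteristic profile.
#' @export
simulate_segment_profiles <- function(config, segment_index) {
  stopifnot(inherits(config, "benchmark_config"))
  seg <- segments_table(config$breakpoints, config$n_time)
  j <- as.integer(segment_index)
  if (j < 1L || j > nrow(seg)) stop("segment_index out of range")
  len <- seg$length[j]
  n_prof <- config$profiles_per_segment[j]
  sd_innov <- arma_innovation_sd(config$ar, config$ma)
  model <- list()
  if (length(config$ar)) model$ar <- config$ar
  if (length(config$ma)) model$ma <- config$ma
  t(vapply(seq_len(n_prof), function(p) {
    as.numeric(stats::arima.sim(model = model, n = len, sd = sd_innov))
  }, numeric(len)))
}

#' Smooth segment boundaries with a discrete Gaussian kernel
#'
#' For every variable and every segment's left boundary `b > 1`, replaces
#' the value at `b` by the kernel-weighted combination of the values at
#' `b - 1`, `b`, `b + 1` (pre-smoothing values; all other entries are
#' untouched). This emulates temporal dependence between adjacent
#' segments.
#'
#' @param m Numeric matrix (variables x time points).
#' @param breakpoints Segment-final time points; the smoothed columns are
#'   `breakpoints + 1`.
#' @param kernel Symmetric normalized 3-tap weights.
#' @return The smoothed matrix.
#' @export
smooth_boundaries <- function(m, breakpoints, kernel = c(0.25, 0.5, 0.25)) {
  stopifnot(is.matrix(m))
  b <- as.integer(breakpoints) + 1L
  if (any(b < 2L) || any(b + 1L > ncol(m)))
    stop("a boundary lacks a neighbor on one side; cannot smooth")
  out <- m
  out[, b] <- kernel[1L] * m[, b - 1L] + kernel[2L] * m[, b] +
    kernel[3L] * m[, b + 1L]
  out
}

#' Generate the synthetic benchmark
#'
#' Assembles the full benchmark matrix: per segment, characteristic ARMA
#' profiles are simulated and each variable copies one uniformly sampled
#' profile; i.i.d. Gaussian observation noise is added everywhere; segment
#' boundaries are then kernel-smoothed. The same seed yields a
#' bit-identical benchmark.
#'
#' @param config A `benchmark_config`.
#' @return A list with `matrix` (named `n_vars x n_time`), `breakpoints`
#'   (planted truth), `assignments` (variables x segments profile index)
#'   and `config`.
#' @export
assemble_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  with_seed(config$seed, {
    seg <- segments_table(config$breakpoints, config$n_time)
    n_seg <- nrow(seg)
    m <- matrix(0, config$n_vars, config$n_time,
                dimnames = list(paste0("v", seq_len(config$n_vars)),
                                paste0("t", seq_len(config$n_time))))
    assignments <- matrix(NA_integer_, config$n_vars, n_seg)
    for (j in seq_len(n_seg)) {
      prof <- simulate_segment_profiles(config, j)
      pick <- sample.int(nrow(prof), config$n_vars, replace = TRUE)
      assignments[, j] <- pick
      m[, seg$start[j]:seg$end[j]] <- prof[pick, , drop = FALSE]
    }
    if (config$noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = config$noise_sd),
                      nrow(m), ncol(m))
    m <- smooth_boundaries(m, config$breakpoints, config$kernel)
    list(matrix = m, breakpoints = config$breakpoints,
         assignments = assignments, config = config)
  })
}
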