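#' Read an expression-like matrix from a delimited text file
#'
#' Reads a numeric matrix of `n` biological entities (rows) by `T` ordered
#' time points (columns). The first row must hold the time-point labels and
#' the first column the entity identifiers. Empty fields and the tokens
#' `NA`, `NaN` and `null` (case-insensitive) are parsed as missing values;
#' missing values are allowed here but must be removed (see
#' [filter_expression_matrix()]) before any network reconstruction.
#'
#' @param path Path to the input file.
#' @param sep Field delimiter, tab by default.
#' @return A numeric matrix with entity ids as row names and time labels as
#'   column names, ordered as in the file.
#' @seealso [filter_expression_matrix()], [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop("matrix file must contain a header and at least 2 entity rows")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  # Header may or may not carry a leading cell above the id column.
  body_len <- length(fields[[2L]])
  time_labels <- if (length(header) == body_len) header[-1L] else header
  n_time <- length(time_labels)
  if (n_time < 2L) stop("need at least 2 time points")
  rows <- fields[-1L]
  bad <- which(lengths(rows) != n_time + 1L)
  if (length(bad))
    stop(sprintf("line %d has %d fields, expected %d",
                 bad[1L] + 1L, lengths(rows)[bad[1L]], n_time + 1L))
  ids <- vapply(rows, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate entity ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing_tokens <- c("", "na", "nan", "null")
  cells <- vapply(rows, function(r) {
    x <- trimws(r[-1L])
    x[tolower(x) %in% missing_tokens] <- NA_character_
    x
  }, character(n_time))
  num <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(is.na(num) & !is.na(cells))
  if (length(bad_cell)) {
    line <- ((bad_cell[1L] - 1L) %/% n_time) + 2L
    stop(sprintf("non-numeric value '%s' at line %d",
                 cells[bad_cell[1L]], line))
  }
  m <- matrix(num, nrow = length(rows), ncol = n_time, byrow = TRUE,
              dimnames = list(ids, time_labels))
  validate_expression_matrix(m, allow_missing = TRUE)
  m
}

#' Write an expression matrix to tab-delimited text
#'
#' Inverse of [read_expression_matrix()]: values survive a write/read
#' round trip bit-identically (full double precision is printed).
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_expression_matrix <- function(m, path, sep = "\t") {
  validate_expression_matrix(m, allow_missing = TRUE)
  header <- paste(c("entity_id", colnames(m)), collapse = sep)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i],
            formatC(m[i, ], format = "g", digits = 17)), collapse = sep)
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

validate_expression_matrix <- function(m, allow_missing = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be numeric")
  if (ncol(m) < 2L) stop("need at least 2 time points")
  if (nrow(m) < 2L) stop("need at least 2 entities")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("rows must carry unique entity ids")
  if (!allow_missing && anyNA(m))
    stop("matrix contains missing values; filter first")
  invisible(m)
}

#' Read an annotation map
#'
#' Two-column tab-delimited file: entity id and a 0/1 flag saying whether the
#' entity carries at least one functional annotation. Entities absent from
#' the file are treated as unannotated.
#'
#' @param path Path to the annotation file.
#' @return Named logical vector keyed by entity id.
#' @export
read_annotation_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("annotation file needs 2 columns (id, 0/1)")
  flags <- as.integer(tab[[2L]])
  if (anyNA(flags) || any(!flags %in% c(0L, 1L)))
    stop("annotation flags must be 0 or 1")
  stats::setNames(flags == 1L, tab[[1L]])
}

#' Filter entity profiles before network reconstruction
#'
#' Applies the standard pre-processing for time-resolved expression data:
#' removes profiles that (a) contain missing values, (b) lack any functional
#' annotation when an annotation map is supplied, and (c) show a coefficient
#' of variation (CV) below `cv_min`, i.e. profiles that barely vary over
#' time. CV is the sample standard deviation divided by the absolute mean;
#' a profile whose mean is numerically zero is kept (its CV is effectively
#' infinite, not low).
#'
#' @param m Numeric expression matrix (entities x time points).
#' @param annotations Optional named logical vector as returned by
#'   [read_annotation_map()]; entities missing from it count as unannotated.
#' @param cv_min Minimum coefficient of variation required to keep a
#'   profile; default 1.
#' @param cv_scale Scale on which the CV is computed: `"raw"` (default) or
#'   `"log"` (base-2 logarithm; requires strictly positive values).
#' @return The filtered matrix, rows in their original order.
#' @export
filter_expression_matrix <- function(m, annotations = NULL, cv_min = 1,
                                     cv_scale = c("raw", "log")) {
  validate_expression_matrix(m, allow_missing = TRUE)
  cv_scale <- match.arg(cv_scale)
  stopifnot(cv_min >= 0)
  keep <- !apply(m, 1L, anyNA)
  if (!is.null(annotations)) {
    ann <- annotations[rownames(m)]
    ann[is.na(ann)] <- FALSE
    keep <- keep & ann
  }
  cv <- rep(NA_real_, nrow(m))
  for (i in which(keep)) {
    x <- m[i, ]
    if (cv_scale == "log") {
      if (any(x <= 0)) stop("log-scale CV needs strictly positive values (row ",
                            rownames(m)[i], ")")
      x <- log2(x)
    }
    mu <- mean(x)
    cv[i] <- if (abs(mu) < .Machine$double.eps) Inf else stats::sd(x) / abs(mu)
  }
  keep <- keep & (is.infinite(cv) | cv >= cv_min)
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("all profiles removed by filtering; relax cv_min or drop the annotation filter")
  if (sum(keep) < 2L)
    stop("fewer than 2 profiles survive filtering; relax the filter parameters")
  m[keep, , drop = FALSE]
}

#' Tabulate segments from breakpoints
#'
#' Breakpoints are the 1-based time points at which segments end (the last
#' segment ends at `T` implicitly), following the convention that a
#' segmentation of `[1..T]` into `k` segments has `k - 1` internal
#' breakpoints.
#'
#' @param breakpoints Strictly increasing integer vector of internal cut
#'   positions, each in `[1, T-1]`. Must be non-empty: the method always
#'   reports at least two segments.
#' @param n_time Total number of time points `T`.
#' @return Data frame with columns `segment`, `start`, `end`, `length`.
#' @export
segments_table <- function(breakpoints, n_time) {
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints) == 0L)
    stop("empty breakpoint set: a segmentation has at least 2 segments")
  if (is.unsorted(breakpoints, strictly = TRUE) ||
      any(breakpoints < 1L) || any(breakpoints >= n_time))
    stop("breakpoints must be strictly increasing and inside [1, T-1]")
  start <- c(1L, breakpoints + 1L)
  end <- c(breakpoints, as.integer(n_time))
  data.frame(segment = seq_along(start), start = start, end = end,
             length = end - start + 1L)
}

#' Write a segmentation result to disk
#'
#' Emits two files: `<prefix>.json`, a machine-readable record of the
#' result (breakpoints, objective, penalty bookkeeping, sweep table when
#' present), and `<prefix>.segments.tsv`, a per-segment table with 1-based
#' inclusive start/end positions.
#'
#' @param res A `segmentation_result` as returned by the solvers.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_segmentation <- function(res, prefix) {
  stopifnot(inherits(res, "segmentation_result"))
  seg <- segments_table(res$breakpoints, res$n_time)
  json_path <- paste0(prefix, ".json")
  tsv_path <- paste0(prefix, ".segments.tsv")
  payload <- res[!vapply(res, is.null, logical(1L))]
  class(payload) <- NULL
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.table(seg, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, segments = tsv_path))
}
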