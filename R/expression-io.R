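#' Time-course expression matrix
#'
#' Constructs a `tc_matrix`, the container used throughout the package for
#' gene expression time courses: a genes x time-points matrix of log-ratio
#' values together with an ordered vector of sampling times (minutes) and a
#' logical mask of missing cells.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param time_points strictly increasing numeric vector of sampling times in
#'   minutes (defaults to the column names of `values`).
#' @param missing_mask logical matrix of the same shape flagging missing
#'   cells; missing cells of `values` are stored as `NA`.
#'
#' @return an object of class `tc_matrix` with elements `values`,
#'   `time_points` and `missing_mask`.
#' @export
tc_matrix <- function(values, gene_ids = rownames(values),
                      time_points = as.numeric(colnames(values)),
                      missing_mask = is.na(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) stop("gene_ids are required")
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match the number of rows")
  time_points <- as.numeric(time_points)
  if (anyNA(time_points))
    stop("time points must be numeric (malformed header?)")
  if (length(time_points) != ncol(values))
    stop("time_points length does not match the number of columns")
  if (ncol(values) >= 2 && any(diff(time_points) <= 0))
    stop("time_points must be strictly increasing")
  missing_mask <- missing_mask | is.na(values)
  values[missing_mask] <- NA_real_
  dimnames(values) <- list(gene_ids, time_points)
  dimnames(missing_mask) <- dimnames(values)
  structure(list(values = values, time_points = time_points,
                 missing_mask = missing_mask),
            class = "tc_matrix")
}

#' @export
print.tc_matrix <- function(x, ...) {
  cat(sprintf("tc_matrix: %d genes x %d time points (%g-%g min), %d missing cells\n",
              nrow(x$values), ncol(x$values), min(x$time_points),
              max(x$time_points), sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.tc_matrix <- function(x) dim(x$values)

#' Gene identifiers of a time-course matrix
#' @param x a `tc_matrix`.
#' @return character vector of gene ids in row order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Read a delimited expression matrix
#'
#' Reads a tab- or comma-delimited file whose header row holds the sampling
#' times (minutes) and whose first column holds gene identifiers.  Cells equal
#' to one of `missing_tokens` (or empty) are flagged as missing; any other
#' non-numeric cell is an error.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma from
#'   the header line.
#' @param missing_tokens character vector of tokens marking a missing value.
#' @return a [tc_matrix()].
#' @export
read_expression <- function(path, sep = NULL, missing_tokens = c("NA", "")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("expression file needs a header and >= 1 gene row")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1L])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  ## header may or may not carry a leading label for the gene-id column
  n_fields <- length(fields[[2L]])
  tp_str <- if (length(header) == n_fields) header[-1L] else header
  if (length(tp_str) != n_fields - 1L) stop("malformed header")
  time_points <- suppressWarnings(as.numeric(tp_str))
  if (anyNA(time_points)) stop("malformed header: non-numeric time point")
  rows <- fields[-1L]
  bad <- which(lengths(rows) != n_fields)
  if (length(bad)) stop("row ", bad[1L] + 1L, " has a wrong field count")
  ids <- vapply(rows, `[[`, character(1), 1L)
  cells <- t(vapply(rows, function(r) r[-1L], character(n_fields - 1L)))
  miss <- matrix(trimws(cells) %in% missing_tokens, nrow = nrow(cells))
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (any(is.na(vals) & !miss)) {
    ij <- which(is.na(vals) & !miss, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene row %d, time point %d: '%s'",
                 ij[1L], ij[2L], cells[ij[1L], ij[2L]]))
  }
  vals[miss] <- NA_real_
  tc_matrix(vals, gene_ids = ids, time_points = time_points,
            missing_mask = miss)
}

#' Write an expression matrix as TSV
#'
#' @param x a `tc_matrix`.
#' @param path output file path.
#' @param missing_token token written for missing cells.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, missing_token = "NA") {
  vals <- x$values
  out <- cbind(gene = rownames(vals),
               matrix(ifelse(x$missing_mask, missing_token,
                             format(vals, trim = TRUE, digits = 15)),
                      nrow = nrow(vals)))
  colnames(out) <- c("gene", format(x$time_points, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Preprocess a time-course matrix
#'
#' Applies the pipeline's standard transforms in order: (1) genes missing more
#' than `max_missing_frac` of their time points (or everything) are dropped
#' with a warning; (2) remaining gaps are filled by linear interpolation along
#' the time axis, with leading/trailing gaps taking the nearest observed
#' value; (3) each profile is shifted so its first value is zero, putting all
#' genes on a common log-ratio baseline; (4) spikes are damped by a centred
#' moving average of width `smooth_window`, truncated at the series edges so
#' the series length is preserved.
#'
#' @param x a [tc_matrix()].
#' @param smooth_window odd positive integer; `1` disables smoothing.
#' @param max_missing_frac genes missing more than this fraction of points are
#'   dropped.
#' @return a `tc_matrix` with no missing values and a zero first column.
#' @export
preprocess <- function(x, smooth_window = 3, max_missing_frac = 0.3) {
  stopifnot(inherits(x, "tc_matrix"))
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be an odd positive integer")
  n_tp <- ncol(x$values)
  frac_missing <- rowMeans(x$missing_mask)
  drop <- frac_missing > max_missing_frac | frac_missing == 1
  if (any(drop)) {
    warning(sum(drop), " gene(s) dropped for missingness: ",
            paste(utils::head(rownames(x$values)[drop], 5L), collapse = ", "))
    x <- tc_matrix(x$values[!drop, , drop = FALSE],
                   missing_mask = x$missing_mask[!drop, , drop = FALSE])
  }
  vals <- x$values
  tp <- x$time_points
  for (i in which(rowSums(x$missing_mask) > 0L)) {
    obs <- !x$missing_mask[i, ]
    vals[i, ] <- stats::approx(tp[obs], vals[i, obs], xout = tp,
                               rule = 2)$y
  }
  vals <- vals - vals[, 1L]                     # zero baseline at t[1]
  vals <- t(apply(vals, 1L, moving_average, w = smooth_window))
  if (n_tp == 1L) vals <- matrix(vals, ncol = 1L)
  tc_matrix(vals, gene_ids = rownames(x$values), time_points = tp,
            missing_mask = matrix(FALSE, nrow(vals), ncol(vals)))
}

## centred moving average with truncated edges (window shrinks near the ends)
moving_average <- function(v, w) {
  if (w == 1L) return(v)
  h <- (w - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(j) {
    mean(v[max(1L, j - h):min(n, j + h)])
  }, numeric(1))
}

#' Extract the expression submatrix for a set of genes
#' @param x a `tc_matrix`.
#' @param genes character vector of gene ids (must exist in `x`).
#' @return numeric matrix genes x time points.
#' @export
profiles <- function(x, genes) {
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing))
    stop("genes absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  x$values[genes, , drop = FALSE]
}
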