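# Construction of weighted, undirected functional brain networks from ROI
# time series or precomputed connectivity matrices.

#' Pearson connectivity matrix from ROI time series
#'
#' Computes the full N x N matrix of Pearson correlation coefficients between
#' all pairs of ROI time series. This is the standard construction of a
#' functional connectivity matrix: entry (i, j) is the correlation of the mean
#' BOLD signal of region i with that of region j across timepoints.
#'
#' @param ts Numeric matrix with T rows (timepoints) and N columns (regions).
#'   T must be at least 2 and no column may be constant.
#' @param subject_id Optional subject identifier attached as an attribute.
#' @param session Optional session label (e.g. `"pre"` or `"post"`) attached
#'   as an attribute.
#' @return A symmetric N x N numeric matrix with unit diagonal and entries in
#'   \[-1, 1\], with attributes `subject_id` and `session` when supplied.
#' @examples
#' ts <- matrix(rnorm(40), nrow = 10)
#' C <- pearson_connectivity(ts)
#' all(diag(C) == 1)
#' @export
pearson_connectivity <- function(ts, subject_id = NULL, session = NULL) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("`ts` must be a numeric matrix", call. = FALSE)
  if (nrow(ts) < 2L) stop("`ts` must have at least 2 timepoints (rows)", call. = FALSE)
  if (anyNA(ts)) stop("`ts` contains missing values", call. = FALSE)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop(sprintf("zero-variance time series for ROI column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  C <- stats::cor(ts)
  # guard against tiny floating-point excursions outside [-1, 1]
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  C <- (C + t(C)) / 2
  dimnames(C) <- NULL
  if (!is.null(subject_id)) attr(C, "subject_id") <- as.character(subject_id)
  if (!is.null(session)) attr(C, "session") <- as.character(session)
  C
}

#' Threshold a connectivity matrix into a weighted adjacency matrix
#'
#' Zeroes the diagonal (a region is never its own neighbour), then sets every
#' entry strictly below the threshold `t` to zero. Negative correlations are
#' therefore removed whenever `t >= 0`; surviving entries keep their
#' correlation value as edge weight, so the result is a weighted (not binary)
#' adjacency matrix.
#'
#' @param c Symmetric numeric connectivity matrix.
#' @param t Threshold (default 0.1); entries `< t` become 0.
#' @return Symmetric non-negative matrix with zero diagonal and attribute
#'   `threshold_used`.
#' @examples
#' C <- matrix(c(1, .05, .2, .05, 1, -.3, .2, -.3, 1), 3)
#' threshold_adjacency(C, 0.1)
#' @export
threshold_adjacency <- function(c, t = 0.1) {
  assert_scalar_number(t, "t", lower = 0)
  a <- symmetrize_checked(c, "c")
  diag(a) <- 0
  a[a < t] <- 0
  if (all(a == 0)) {
    stop(sprintf("thresholding at t = %g leaves a graph with zero edges", t),
         call. = FALSE)
  }
  attrs <- attributes(c)
  attr(a, "subject_id") <- attrs$subject_id
  attr(a, "session") <- attrs$session
  attr(a, "threshold_used") <- t
  a
}

#' Build a multi-graph attribute set from connectivity matrices
#'
#' Thresholds each of P connectivity matrices into a weighted adjacency
#' matrix and packages them as a joint input for the shared Gaussian encoder.
#' Node i of graph p carries as attribute vector the i-th row of that graph's
#' thresholded adjacency matrix (its connectivity profile), so the attribute
#' dimension D equals the number of nodes N.
#'
#' @param matrices List of symmetric N x N connectivity matrices (or a single
#'   matrix), all sharing the same N.
#' @param t Threshold passed to [threshold_adjacency()].
#' @param index Optional data frame with one row per matrix and columns
#'   `subject_id` and `session`; when omitted it is taken from matrix
#'   attributes or filled with placeholders.
#' @return An object of class `multigraph`: a list with elements `graphs`
#'   (list of P weighted adjacency matrices, doubling as node attribute
#'   matrices), `index`, `N`, `D`, `P` and `threshold`.
#' @export
build_multigraph <- function(matrices, t = 0.1, index = NULL) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("`matrices` must be a non-empty list of square matrices", call. = FALSE)
  }
  ns <- vapply(matrices, function(m) nrow(as.matrix(m)), integer(1))
  if (length(unique(ns)) != 1L) {
    stop(sprintf("all matrices must share the same N; got sizes: %s",
                 paste(unique(ns), collapse = ", ")), call. = FALSE)
  }
  P <- length(matrices)
  if (is.null(index)) {
    index <- data.frame(
      subject_id = vapply(seq_len(P), function(p) {
        attr(matrices[[p]], "subject_id") %||% sprintf("graph%02d", p)
      }, character(1)),
      session = vapply(seq_len(P), function(p) {
        attr(matrices[[p]], "session") %||% NA_character_
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(index) != P) stop("`index` must have one row per matrix", call. = FALSE)
  graphs <- lapply(matrices, threshold_adjacency, t = t)
  structure(
    list(graphs = graphs, index = index,
         N = ns[1L], D = ns[1L], P = P, threshold = t),
    class = "multigraph"
  )
}

#' @export
print.multigraph <- function(x, ...) {
  cat(sprintf("<multigraph> P = %d graphs, N = %d nodes, D = %d attributes, threshold = %g\n",
              x$P, x$N, x$D, x$threshold))
  invisible(x)
}

#' Read a delimited numeric matrix (time series or connectivity)
#'
#' Reads a comma- or tab-delimited text file holding one numeric matrix,
#' auto-detecting the delimiter and an optional header row.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  probe <- utils::read.table(path, sep = sep, header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE)
  header <- !all(vapply(probe, is.numeric, logical(1)))
  m <- as.matrix(utils::read.table(path, sep = sep, header = header))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Write a numeric matrix as tab-delimited text
#'
#' @param m Numeric matrix.
#' @param path Destination file path.
#' @export
write_matrix_file <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an atlas table mapping ROI index to name and functional system
#'
#' The atlas file is tab-delimited with columns `roi_index` (0-based,
#' contiguous), `roi_name` and `system_name`, mirroring the structure of the
#' 264-region functional atlas with 14 neural systems commonly used for
#' resting-state connectivity.
#'
#' @param path File path.
#' @return Data frame with columns `roi_index`, `roi_name`, `system_name`,
#'   ordered by `roi_index`.
#' @export
read_atlas <- function(path) {
  at <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_atlas(at)
}

#' Write an atlas table
#' @param atlas Data frame as returned by [read_atlas()] or [synthetic_atlas()].
#' @param path Destination file path.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_atlas <- function(at) {
  need <- c("roi_index", "roi_name", "system_name")
  if (!all(need %in% names(at))) {
    stop(sprintf("atlas must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  at <- at[order(at$roi_index), need, drop = FALSE]
  n <- nrow(at)
  if (n == 0L || !identical(as.integer(at$roi_index), 0:(n - 1L))) {
    stop("atlas `roi_index` must be unique, contiguous and 0-based", call. = FALSE)
  }
  if (anyNA(at$system_name) || any(!nzchar(at$system_name))) {
    stop("every ROI must carry exactly one non-empty system name", call. = FALSE)
  }
  rownames(at) <- NULL
  at
}
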