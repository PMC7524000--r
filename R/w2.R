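# Downstream quantification: Wasserstein-2 distances between node Gaussians,
# within-subject pre/post change profiles, the cross-subject reorganization
# index with one-sample t-tests and FDR correction, and uncertainty-based
# effective latent dimensionality.

#' Wasserstein-2 distance between diagonal Gaussians
#'
#' Closed form for Gaussians: `W2^2 = ||mu_i - mu_j||^2 +
#' ||Sigma_i^(1/2) - Sigma_j^(1/2)||_F^2`; with diagonal covariances the
#' Frobenius term reduces to `sum_d (sigma_i,d - sigma_j,d)^2` on the
#' standard deviations. Unlike the KL energy this is a true metric, which is
#' what makes it suitable for quantifying how far a node's embedding moved.
#' Inputs may be single vectors or row-wise matrices.
#'
#' @param mu_i,sigma2_i Mean(s) and variance(s) of the first Gaussian(s).
#' @param mu_j,sigma2_j Mean(s) and variance(s) of the second Gaussian(s).
#' @return Non-negative numeric vector of W2 distances.
#' @examples
#' w2_distance(c(1, 0), c(1, 1), c(0, 0), c(1, 1))  # 1
#' w2_distance(0, 4, 0, 1)                          # |2 - 1| = 1
#' @export
w2_distance <- function(mu_i, sigma2_i, mu_j, sigma2_j) {
  mu_i <- rbind(mu_i); mu_j <- rbind(mu_j)
  sigma2_i <- rbind(sigma2_i); sigma2_j <- rbind(sigma2_j)
  if (!all(dim(mu_i) == dim(mu_j)) || !all(dim(mu_i) == dim(sigma2_i)) ||
      !all(dim(mu_i) == dim(sigma2_j))) {
    stop("all inputs must share the same dimension", call. = FALSE)
  }
  if (any(sigma2_i <= 0) || any(sigma2_j <= 0)) {
    stop("variances must be strictly positive", call. = FALSE)
  }
  dm <- mu_i - mu_j
  ds <- sqrt(sigma2_i) - sqrt(sigma2_j)
  unname(sqrt(rowSums(dm * dm) + rowSums(ds * ds)))
}

# Locate the graph index for a (subject, session) pair in an embedding.
graph_slot <- function(embedding, subject, session) {
  hit <- which(embedding$index$subject_id == subject &
                 embedding$index$session == session)
  if (length(hit) != 1L) {
    stop(sprintf("subject %s is missing a unique '%s' session embedding",
                 subject, session), call. = FALSE)
  }
  hit
}

#' Per-ROI within-subject pre/post Wasserstein-2 change
#'
#' For every subject with both sessions embedded in the shared latent space,
#' computes the W2 distance between its pre- and post-intervention Gaussian
#' for each node.
#'
#' @param embedding A `gaussian_embedding` whose index contains `pre` and
#'   `post` sessions per subject.
#' @param subjects Optional character vector restricting/ordering the
#'   subjects; defaults to all subjects in the index.
#' @return N x S numeric matrix of W2 distances (rows = ROIs, columns =
#'   subjects).
#' @export
within_subject_change <- function(embedding, subjects = NULL) {
  subjects <- subjects %||% unique(embedding$index$subject_id)
  w2 <- vapply(subjects, function(s) {
    pre <- graph_slot(embedding, s, "pre")
    post <- graph_slot(embedding, s, "post")
    w2_distance(embedding$mu[[pre]], embedding$sigma2[[pre]],
                embedding$mu[[post]], embedding$sigma2[[post]])
  }, numeric(nrow(embedding$mu[[1L]])))
  colnames(w2) <- subjects
  w2
}

#' Count top-k changing ROIs per functional system
#'
#' Ranks ROIs by within-subject W2 change and counts how many of the top-k
#' fall into each functional system of the atlas. With
#' `aggregate = "per_subject"` (default) each subject contributes its own
#' top-k ROIs and counts are pooled, so counts sum to `k * S`; with
#' `aggregate = "pooled_mean"` ROIs are ranked once by their mean W2 across
#' subjects and counts sum to `k`. Ties are broken by lowest ROI index.
#'
#' @param w2 N x S matrix from [within_subject_change()].
#' @param atlas Atlas data frame (see [read_atlas()]).
#' @param k Number of top ROIs (default 15).
#' @param aggregate `"per_subject"` or `"pooled_mean"`.
#' @return Data frame with columns `system_name` and `count`, covering every
#'   system in the atlas (zeros included), ordered by decreasing count.
#' @export
top_k_system_counts <- function(w2, atlas, k = 15L,
                                aggregate = c("per_subject", "pooled_mean")) {
  aggregate <- match.arg(aggregate)
  atlas <- validate_atlas(atlas)
  w2 <- as.matrix(w2)
  k <- as.integer(k)
  if (k > nrow(w2)) stop(sprintf("k = %d exceeds the number of ROIs (%d)",
                                 k, nrow(w2)), call. = FALSE)
  if (nrow(atlas) != nrow(w2)) stop("atlas and W2 table disagree on N", call. = FALSE)
  top_of <- function(x) order(-x, seq_along(x))[seq_len(k)]
  picked <- switch(aggregate,
                   per_subject = unlist(apply(w2, 2L, top_of, simplify = FALSE)),
                   pooled_mean = top_of(rowMeans(w2)))
  systems <- unique(atlas$system_name)
  counts <- vapply(systems, function(s) {
    sum(atlas$system_name[picked] == s)
  }, numeric(1))
  out <- data.frame(system_name = systems, count = as.integer(counts))
  out[order(-out$count, out$system_name), , drop = FALSE]
}

#' Cross-subject reorganization index with group-level statistics
#'
#' For every unordered pair of different subjects \{a, b\} and every ROI,
#' computes a between-pair W2 distance (one subject before, the other after
#' intervention; both orientations averaged) and a within-pair baseline W2
#' distance (both subjects before intervention). The reorganization index of
#' an ROI is the mean of the between-minus-within differences across the
#' S(S-1)/2 pairs; a one-sample t-test per ROI (against zero mean), followed
#' by Benjamini-Hochberg FDR correction across ROIs, flags significantly
#' reorganized regions.
#'
#' @param embedding A `gaussian_embedding` with `pre` and `post` sessions.
#' @param subjects Optional subject subset/order (at least 2 subjects).
#' @param alternative `"two.sided"` (default) or `"greater"` (mean > 0).
#' @param fdr_level Significance level on the adjusted p-values
#'   (default 0.05).
#' @return List of class `ri_result` with `table` (data frame: `roi`, `ri`,
#'   `t`, `p`, `q`, `significant`), `between` and `within` (N x npair
#'   matrices of W2 distances) and `pairs` (2 x npair subject index matrix).
#' @export
reorganization_index <- function(embedding, subjects = NULL,
                                 alternative = c("two.sided", "greater"),
                                 fdr_level = 0.05) {
  alternative <- match.arg(alternative)
  subjects <- subjects %||% unique(embedding$index$subject_id)
  S <- length(subjects)
  if (S < 2L) stop("at least 2 subjects are required", call. = FALSE)
  pre <- vapply(subjects, function(s) graph_slot(embedding, s, "pre"), integer(1))
  post <- vapply(subjects, function(s) graph_slot(embedding, s, "post"), integer(1))
  N <- nrow(embedding$mu[[1L]])
  prs <- utils::combn(S, 2L)
  npair <- ncol(prs)

  w2_between_graphs <- function(g1, g2) {
    w2_distance(embedding$mu[[g1]], embedding$sigma2[[g1]],
                embedding$mu[[g2]], embedding$sigma2[[g2]])
  }
  between <- matrix(NA_real_, N, npair)
  within <- matrix(NA_real_, N, npair)
  for (p in seq_len(npair)) {
    a <- prs[1L, p]; b <- prs[2L, p]
    between[, p] <- 0.5 * (w2_between_graphs(pre[a], post[b]) +
                             w2_between_graphs(pre[b], post[a]))
    within[, p] <- w2_between_graphs(pre[a], pre[b])
  }
  diffs <- between - within
  ri <- rowMeans(diffs)
  if (npair < 2L) {
    # a single subject pair admits no t-test: report RI without inference
    tstat <- rep(NA_real_, N)
    p <- rep(NA_real_, N)
  } else {
    sds <- apply(diffs, 1L, stats::sd)
    tstat <- ifelse(sds > 0, ri / (sds / sqrt(npair)), ifelse(ri == 0, 0, Inf * sign(ri)))
    df <- npair - 1L
    p <- ifelse(sds > 0,
                switch(alternative,
                       two.sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
                       greater = stats::pt(tstat, df, lower.tail = FALSE)),
                ifelse(ri == 0, 1, 0))
  }
  q <- stats::p.adjust(p, method = "BH")
  table <- data.frame(roi = seq_len(N), ri = ri, t = tstat, p = p, q = q,
                      significant = !is.na(q) & q < fdr_level)
  structure(list(table = table, between = between, within = within,
                 pairs = prs, subjects = subjects, fdr_level = fdr_level),
            class = "ri_result")
}

#' @export
print.ri_result <- function(x, ...) {
  cat(sprintf("<ri_result> %d ROIs, %d subject pairs; %d significant at q < %g\n",
              nrow(x$table), ncol(x$between), sum(x$table$significant), x$fdr_level))
  invisible(x)
}

#' Per-dimension uncertainty profile and effective latent dimension
#'
#' Summarizes the learned variances across all nodes and graphs by the
#' median per latent dimension. A dimension is flagged unstable when its
#' median variance exceeds `gamma` times the median of the per-dimension
#' medians; such high-uncertainty dimensions do not contribute to the
#' low-dimensional representation, so the effective latent dimension is L
#' minus the number of flagged dimensions.
#'
#' @param embedding A `gaussian_embedding`.
#' @param gamma Instability multiplier (default 2).
#' @return List of class `uncertainty_profile` with `dim_variance` (length-L
#'   median variance per dimension), `unstable_dims`, `effective_dim` and
#'   `gamma`.
#' @export
uncertainty_profile <- function(embedding, gamma = 2.0) {
  assert_scalar_number(gamma, "gamma", lower = 0)
  S2 <- do.call(rbind, embedding$sigma2)
  med <- apply(S2, 2L, stats::median)
  ref <- stats::median(med)
  unstable <- which(med > gamma * ref)
  structure(list(dim_variance = med, unstable_dims = unstable,
                 effective_dim = as.integer(length(med) - length(unstable)),
                 gamma = gamma),
            class = "uncertainty_profile")
}

#' @export
print.uncertainty_profile <- function(x, ...) {
  cat(sprintf("<uncertainty_profile> L = %d, unstable dims: %s, effective dimension = %d\n",
              length(x$dim_variance),
              if (length(x$unstable_dims)) paste(x$unstable_dims, collapse = ", ") else "none",
              x$effective_dim))
  invisible(x)
}

#' Write an ROI change table as tab-delimited text
#'
#' Combines per-subject W2 changes, the reorganization index statistics and
#' the atlas annotation into one table (one row per ROI).
#'
#' @param w2 N x S matrix from [within_subject_change()].
#' @param ri An `ri_result` from [reorganization_index()].
#' @param atlas Atlas data frame.
#' @param path Destination file path.
#' @export
write_roi_change_table <- function(w2, ri, atlas, path) {
  atlas <- validate_atlas(atlas)
  out <- data.frame(roi_index = atlas$roi_index, roi_name = atlas$roi_name,
                    system_name = atlas$system_name,
                    w2, ri$table[, c("ri", "t", "p", "q", "significant")],
                    check.names = FALSE)
  names(out) <- c("roi_index", "roi_name", "system_name",
                  sprintf("w2_%s", colnames(w2)), "ri", "t", "p", "q", "significant")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
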