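# Edge hold-out splitting and AUC evaluation of the learned embeddings.

#' Split the edges of a weighted adjacency matrix into train/validation/test
#'
#' Randomly partitions the undirected edges into three disjoint sets using
#' largest-remainder rounding of the requested fractions, zeroes the held-out
#' edges to form the training adjacency, and samples an equal number of true
#' non-edges (negatives) for the validation and test sets.
#'
#' @param a Weighted adjacency matrix, e.g. from [threshold_adjacency()].
#' @param fractions Length-3 vector of train/validation/test fractions
#'   summing to 1 (default `c(0.85, 0.10, 0.05)`).
#' @param seed Integer RNG seed.
#' @return Object of class `edge_split`: list with `train_edges`,
#'   `val_edges`, `test_edges`, `val_neg`, `test_neg` (2-column node-pair
#'   matrices, i < j), `train_adjacency` and `seed`.
#' @export
split_edges <- function(a, fractions = c(0.85, 0.10, 0.05), seed = 1L) {
  a <- symmetrize_checked(a, "a")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three positive numbers summing to 1", call. = FALSE)
  }
  ut <- upper.tri(a)
  eidx <- which(ut & a > 0, arr.ind = TRUE)
  m <- nrow(eidx)
  counts <- floor(m * fractions)
  rem <- m * fractions - counts
  short <- m - sum(counts)
  if (short > 0L) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[give] <- counts[give] + 1L
  }
  if (any(counts == 0L)) {
    stop(sprintf("too few edges (%d) to form non-empty train/val/test sets", m),
         call. = FALSE)
  }
  nidx <- which(ut & a == 0, arr.ind = TRUE)
  n_neg_needed <- counts[2L] + counts[3L]
  if (nrow(nidx) < n_neg_needed) {
    stop("not enough non-edges to sample negatives", call. = FALSE)
  }
  with_seed(seed, {
    perm <- sample.int(m)
    tr <- eidx[perm[seq_len(counts[1L])], , drop = FALSE]
    va <- eidx[perm[counts[1L] + seq_len(counts[2L])], , drop = FALSE]
    te <- eidx[perm[counts[1L] + counts[2L] + seq_len(counts[3L])], , drop = FALSE]
    negs <- nidx[sample.int(nrow(nidx), n_neg_needed), , drop = FALSE]
  })
  va_neg <- negs[seq_len(counts[2L]), , drop = FALSE]
  te_neg <- negs[counts[2L] + seq_len(counts[3L]), , drop = FALSE]

  train_a <- a
  held <- rbind(va, te)
  train_a[held] <- 0
  train_a[held[, c(2L, 1L), drop = FALSE]] <- 0

  lab <- function(x) { colnames(x) <- c("i", "j"); x }
  structure(list(train_edges = lab(tr), val_edges = lab(va), test_edges = lab(te),
                 val_neg = lab(va_neg), test_neg = lab(te_neg),
                 train_adjacency = train_a, seed = seed),
            class = "edge_split")
}

#' Score node pairs from a single graph's Gaussian embedding
#'
#' The score of a pair (i, j) is minus the symmetrized KL energy,
#' `-(KL(N_j || N_i) + KL(N_i || N_j)) / 2`, so higher scores mean "more
#' likely an edge" and identical Gaussians attain the maximum score 0.
#'
#' @param embedding List with `mu` (N x L) and `sigma2` (N x L) for one graph.
#' @param pairs 2-column matrix of node indices.
#' @return Numeric vector of scores (all `<= 0`).
#' @export
score_pairs <- function(embedding, pairs) {
  pairs <- rbind(pairs)
  Mu <- embedding$mu; S2 <- embedding$sigma2
  a <- pairs[, 1L]; b <- pairs[, 2L]
  -0.5 * (kl_energy(Mu[a, , drop = FALSE], S2[a, , drop = FALSE],
                    Mu[b, , drop = FALSE], S2[b, , drop = FALSE]) +
            kl_energy(Mu[b, , drop = FALSE], S2[b, , drop = FALSE],
                      Mu[a, , drop = FALSE], S2[a, , drop = FALSE]))
}

#' Area under the ROC curve from positive and negative scores
#'
#' Mann-Whitney rank formulation: the probability that a random positive
#' scores above a random negative, counting ties as 1/2.
#'
#' @param scores_pos Scores of true edges.
#' @param scores_neg Scores of non-edges.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(3, 1), c(2, 0))  # 0.75
#' @export
auc_score <- function(scores_pos, scores_neg) {
  np <- as.numeric(length(scores_pos)); nn <- as.numeric(length(scores_neg))
  if (np == 0 || nn == 0) stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Write an edge-split manifest for reproducibility
#'
#' @param split An `edge_split`.
#' @param path Destination file path (tab-delimited: i, j, set).
#' @export
write_split_manifest <- function(split, path) {
  sets <- c("train", "val", "test", "val_neg", "test_neg")
  keys <- c("train_edges", "val_edges", "test_edges", "val_neg", "test_neg")
  rows <- do.call(rbind, lapply(seq_along(sets), function(k) {
    e <- split[[keys[k]]]
    if (nrow(e) == 0L) return(NULL)
    data.frame(i = e[, 1L], j = e[, 2L], set = sets[k])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
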