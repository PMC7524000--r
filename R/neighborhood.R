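# Weighted shortest-path "hop" strata and triplet sampling for the ranking
# loss. Stronger connections are treated as shorter edges, so the hop strata
# order nodes by weighted proximity to each anchor.

#' Weighted shortest-path distance matrix
#'
#' Converts edge weights to edge lengths (stronger correlation = shorter
#' edge) and computes all-pairs shortest-path distances with Dijkstra's
#' algorithm. Unreachable pairs are `Inf`.
#'
#' @param a Weighted adjacency matrix (symmetric, non-negative, zero
#'   diagonal), e.g. from [threshold_adjacency()].
#' @param length_transform Either `"inverse"` (length = 1/w, the default) or
#'   `"one_minus"` (length = 1 - w, floored at a small positive value).
#' @param floor Positive floor applied to `one_minus` lengths.
#' @return Symmetric N x N matrix of shortest-path distances with zero
#'   diagonal.
#' @export
weighted_shortest_distances <- function(a,
                                        length_transform = c("inverse", "one_minus"),
                                        floor = 1e-6) {
  length_transform <- match.arg(length_transform)
  a <- symmetrize_checked(a, "a")
  if (any(a < 0)) stop("`a` must be non-negative", call. = FALSE)
  len <- a
  pos <- a > 0
  len[pos] <- switch(length_transform,
                     inverse = 1 / a[pos],
                     one_minus = pmax(1 - a[pos], floor))
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Stratify nodes into k-hop neighbourhoods per anchor
#'
#' For every anchor node, partitions the remaining nodes into K disjoint
#' "hop" strata of increasing distance. In `"quantile"` mode (the default)
#' the cut points are global quantiles of the finite off-diagonal distance
#' distribution, splitting it into K equal-mass bins; stratum k of anchor i
#' contains the nodes whose distance to i falls in bin k. In
#' `"quantile_anchor"` mode the cut points are computed per anchor from that
#' anchor's own finite distances, which adapts the notion of "near" to each
#' node's neighbourhood scale (anchors with fewer than K distinct finite
#' distances are skipped). In `"bfs"` mode stratum k contains the nodes at
#' unweighted hop distance exactly k on the binarized graph. Nodes
#' unreachable from an anchor appear in none of its strata.
#'
#' @param dists Distance matrix from [weighted_shortest_distances()].
#' @param K Number of strata (at least 2; default 2).
#' @param mode `"quantile"`, `"quantile_anchor"` or `"bfs"`.
#' @param adjacency Weighted adjacency matrix; required for `"bfs"` mode.
#' @param probs Quantile mode only: K strictly increasing cumulative masses
#'   ending at 1 defining the bins (default `seq_len(K) / K`, equal mass).
#' @return Object of class `hop_strata`: a list with one element per node,
#'   each a list of K integer vectors (possibly empty), plus attributes `K`,
#'   `mode` and (quantile mode) `cut_points`.
#' @export
stratify_hops <- function(dists, K = 2L,
                          mode = c("quantile", "quantile_anchor", "bfs"),
                          adjacency = NULL, probs = NULL) {
  mode <- match.arg(mode)
  assert_square_matrix(dists, "dists")
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be at least 2", call. = FALSE)
  n <- nrow(dists)

  if (mode == "quantile_anchor") {
    probs <- probs %||% (seq_len(K) / K)
    strata <- lapply(seq_len(n), function(i) {
      d <- dists[i, ]
      d[i] <- Inf
      fin <- d[is.finite(d)]
      if (length(unique(fin)) < K) {
        return(rep(list(integer(0)), K))
      }
      cuts <- stats::quantile(fin, probs = probs, names = FALSE, type = 7)
      lower <- c(0, cuts[-K])
      lapply(seq_len(K), function(k) {
        which(is.finite(d) & d > lower[k] & d <= cuts[k])
      })
    })
    return(structure(strata, class = "hop_strata", K = K, mode = mode,
                     n_nodes = n))
  }

  if (mode == "quantile") {
    probs <- probs %||% (seq_len(K) / K)
    if (length(probs) != K || is.unsorted(probs, strictly = TRUE) ||
        any(probs <= 0) || probs[K] != 1) {
      stop("`probs` must be K strictly increasing cumulative masses ending at 1",
           call. = FALSE)
    }
    off <- dists[upper.tri(dists) | lower.tri(dists)]
    finite <- off[is.finite(off)]
    if (length(unique(finite)) < K) {
      stop(sprintf("K = %d exceeds the number of distinct finite distances (%d)",
                   K, length(unique(finite))), call. = FALSE)
    }
    cuts <- stats::quantile(finite, probs = probs, names = FALSE, type = 7)
    lower <- c(0, cuts[-K])
    strata <- lapply(seq_len(n), function(i) {
      d <- dists[i, ]
      d[i] <- Inf   # the anchor itself belongs to no stratum
      lapply(seq_len(K), function(k) {
        which(is.finite(d) & d > lower[k] & d <= cuts[k])
      })
    })
    out <- structure(strata, class = "hop_strata", K = K, mode = mode,
                     cut_points = cuts, n_nodes = n)
    return(out)
  }

  # bfs mode: strata by unweighted hop count on the binarized graph
  if (is.null(adjacency)) {
    stop("`adjacency` is required for mode = \"bfs\"", call. = FALSE)
  }
  adjacency <- symmetrize_checked(adjacency, "adjacency")
  g <- igraph::graph_from_adjacency_matrix((adjacency > 0) * 1, mode = "undirected",
                                           diag = FALSE)
  hop <- igraph::distances(g)
  strata <- lapply(seq_len(n), function(i) {
    lapply(seq_len(K), function(k) which(hop[i, ] == k))
  })
  structure(strata, class = "hop_strata", K = K, mode = mode, n_nodes = n)
}

#' @export
print.hop_strata <- function(x, ...) {
  sizes <- vapply(x, function(s) sum(lengths(s)), numeric(1))
  cat(sprintf("<hop_strata> %d nodes, K = %d (%s mode); mean stratified nodes per anchor: %.1f\n",
              length(x), attr(x, "K"), attr(x, "mode"), mean(sizes)))
  invisible(x)
}

#' Sample ranking triplets from hop strata
#'
#' For every anchor with at least two non-empty strata, draws one node per
#' non-empty stratum per sampling round and emits every stratum-ordered pair
#' as a triple (anchor, nearer node, farther node). Anchors lacking two
#' non-empty strata are skipped. Sampling is reproducible given `seed`.
#'
#' @param strata A `hop_strata` object.
#' @param per_anchor Number of sampling rounds per anchor (default 3).
#' @param seed Integer RNG seed.
#' @return Object of class `triplet_set`: an integer matrix with columns
#'   `anchor`, `near`, `far`, one row per triple, with attribute `seed`.
#' @export
sample_triplets <- function(strata, per_anchor = 3L, seed = 1L) {
  if (!inherits(strata, "hop_strata")) stop("`strata` must be a hop_strata object",
                                            call. = FALSE)
  per_anchor <- as.integer(per_anchor)
  if (per_anchor < 1L) stop("`per_anchor` must be at least 1", call. = FALSE)

  # Flatten the (anchor, stratum) cells once so that one draw per cell per
  # round can be taken in a single vectorized step.
  K <- attr(strata, "K")
  cell_members <- list()
  cell_anchor <- integer(0)
  pairA <- integer(0); pairB <- integer(0)   # cell indices of (near, far)
  ncell <- 0L
  for (i in seq_along(strata)) {
    ne <- which(lengths(strata[[i]]) > 0L)
    if (length(ne) < 2L) next
    ids <- ncell + seq_along(ne)
    cell_members[ids] <- strata[[i]][ne]
    cell_anchor[ids] <- i
    cmb <- utils::combn(ids, 2L)     # strata already in increasing-k order
    pairA <- c(pairA, cmb[1L, ])
    pairB <- c(pairB, cmb[2L, ])
    ncell <- ncell + length(ne)
  }
  if (ncell == 0L) {
    stop("no anchor has two non-empty strata: graph too sparse for triplet sampling",
         call. = FALSE)
  }
  lens <- lengths(cell_members)
  flat <- unlist(cell_members, use.names = FALSE)
  offs <- cumsum(lens) - lens
  rows <- with_seed(seed, {
    blocks <- vector("list", per_anchor)
    for (round in seq_len(per_anchor)) {
      draws <- flat[offs + as.integer(floor(stats::runif(ncell) * lens)) + 1L]
      blocks[[round]] <- cbind(cell_anchor[pairA], draws[pairA], draws[pairB])
    }
    do.call(rbind, blocks)
  })
  storage.mode(rows) <- "integer"
  colnames(rows) <- c("anchor", "near", "far")
  structure(rows, class = c("triplet_set", class(rows)), seed = seed)
}

# Strata for every graph of a multigraph, computed from each graph's own
# (training) adjacency so that held-out edges never leak into the
# neighbourhood structure.
#' Hop strata for every graph of a multigraph
#'
#' Convenience wrapper applying [weighted_shortest_distances()] and
#' [stratify_hops()] to every graph of a [build_multigraph()] object.
#'
#' @param mg A `multigraph` object.
#' @param K Number of strata.
#' @param mode Stratification mode, see [stratify_hops()].
#' @param length_transform Edge length transform, see
#'   [weighted_shortest_distances()].
#' @return List of `hop_strata`, one per graph.
#' @export
multigraph_strata <- function(mg, K = 2L,
                              mode = c("quantile", "quantile_anchor", "bfs"),
                              length_transform = c("inverse", "one_minus"),
                              probs = NULL) {
  mode <- match.arg(mode)
  length_transform <- match.arg(length_transform)
  lapply(mg$graphs, function(a) {
    d <- weighted_shortest_distances(a, length_transform = length_transform)
    stratify_hops(d, K = K, mode = mode, adjacency = a, probs = probs)
  })
}
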