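# Independent oracles used to validate the package implementations. These
# deliberately use naive, brute-force or numerical formulations and never
# call the code paths they check.

# Two-loop Pearson correlation.
naive_pearson <- function(ts) {
  n <- ncol(ts)
  out <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- ts[, i] - mean(ts[, i])
      xj <- ts[, j] - mean(ts[, j])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# Exhaustive shortest path by enumerating every simple path (tiny graphs).
brute_shortest <- function(len, from, to) {
  n <- nrow(len)
  best <- if (from == to) 0 else Inf
  walk <- function(node, visited, acc) {
    if (node == to) {
      best <<- min(best, acc)
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && is.finite(len[node, nxt])) {
        visited[nxt] <- TRUE
        walk(nxt, visited, acc + len[node, nxt])
        visited[nxt] <- FALSE
      }
    }
  }
  v <- rep(FALSE, n); v[from] <- TRUE
  if (from != to) walk(from, v, 0)
  best
}

brute_shortest_matrix <- function(adj, transform = c("inverse", "one_minus")) {
  transform <- match.arg(transform)
  n <- nrow(adj)
  len <- matrix(Inf, n, n)
  pos <- adj > 0
  len[pos] <- if (transform == "inverse") 1 / adj[pos] else pmax(1 - adj[pos], 1e-6)
  out <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) out[i, j] <- brute_shortest(len, i, j)
  out
}

# AUC by exhaustive pair counting, ties as 1/2.
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Monte-Carlo estimate of KL(N_j || N_i) for diagonal Gaussians: expectation
# under N_j of the log-density ratio.
mc_kl <- function(mu_i, s2_i, mu_j, s2_j, n = 1e5, seed = 1) {
  set.seed(seed)
  L <- length(mu_j)
  x <- matrix(stats::rnorm(n * L, mean = rep(mu_j, each = n),
                           sd = rep(sqrt(s2_j), each = n)), nrow = n)
  lr <- rowSums(matrix(stats::dnorm(x, rep(mu_j, each = n), rep(sqrt(s2_j), each = n),
                                    log = TRUE), nrow = n)) -
    rowSums(matrix(stats::dnorm(x, rep(mu_i, each = n), rep(sqrt(s2_i), each = n),
                                log = TRUE), nrow = n))
  list(est = mean(lr), se = stats::sd(lr) / sqrt(n))
}

# Numerical optimal-transport W2 between diagonal Gaussians: the squared
# distance factorizes over dimensions, and each 1-D term is the integral of
# the squared quantile-function difference.
numeric_w2 <- function(mu_i, s2_i, mu_j, s2_j) {
  terms <- vapply(seq_along(mu_i), function(d) {
    stats::integrate(function(u) {
      (stats::qnorm(u, mu_i[d], sqrt(s2_i[d])) -
         stats::qnorm(u, mu_j[d], sqrt(s2_j[d])))^2
    }, 0, 1, rel.tol = 1e-9)$value
  }, numeric(1))
  sqrt(sum(terms))
}

# Sign-flip permutation p-value for a one-sample location test of zero mean.
perm_pvalue <- function(d, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(d))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    hits <- hits + (abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE))) >= obs)
  }
  (hits + 1) / (n_perm + 1)
}

# Random connected equal-weight graph with diameter <= 2 (dense), for the
# bfs/quantile stratification agreement property.
random_dense_graph <- function(n = 16, w = 0.5, p = 0.65, seed = 1) {
  set.seed(seed)
  repeat {
    a <- matrix(0, n, n)
    up <- upper.tri(a)
    a[up] <- w * (stats::runif(sum(up)) < p)
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix((a > 0) * 1, mode = "undirected")
    if (igraph::is_connected(g) && igraph::diameter(g) <= 2 &&
        mean(a[up] > 0) >= 0.5) {
      return(a)
    }
  }
}

# Gaussian embedding object built directly from matrices (no training), for
# testing the downstream analytics in isolation.
make_embedding <- function(mu_list, s2_list, subjects, sessions) {
  mgembed:::new_gaussian_embedding(
    mu_list, s2_list,
    data.frame(subject_id = subjects, session = sessions,
               stringsAsFactors = FALSE),
    ncol(mu_list[[1]])
  )
}

# Random diagonal Gaussians.
rand_gauss <- function(n, L, seed) {
  set.seed(seed)
  list(mu = matrix(stats::rnorm(n * L), n),
       s2 = matrix(stats::rexp(n * L) + 0.05, n))
}
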