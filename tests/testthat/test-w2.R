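test_that("w2_distance reproduces closed-form cases and the numerical OT oracle", {
  # identical Gaussians -> 0
  g <- rand_gauss(20, 4, seed = 2)
  expect_equal(w2_distance(g$mu, g$s2, g$mu, g$s2), rep(0, 20))

  # 2-D, mean difference (1, 0), equal variances -> W2 = 1
  expect_equal(w2_distance(c(1, 0), c(1, 1), c(0, 0), c(1, 1)), 1)

  # 1-D, equal means, variances 4 and 1 -> W2 = |2 - 1| = 1
  expect_equal(w2_distance(0, 4, 0, 1), 1)

  # numerical optimal-transport oracle on random small-L pairs
  for (seed in 1:5) {
    set.seed(seed + 70)
    L <- sample(1:3, 1)
    mu_i <- rnorm(L); mu_j <- rnorm(L)
    s2_i <- rexp(L) + 0.1; s2_j <- rexp(L) + 0.1
    expect_equal(w2_distance(mu_i, s2_i, mu_j, s2_j),
                 numeric_w2(mu_i, s2_i, mu_j, s2_j), tolerance = 1e-6)
  }

  expect_error(w2_distance(0, -1, 0, 1), "strictly positive")
})

test_that("w2_distance is a metric on diagonal Gaussians", {
  a <- rand_gauss(300, 3, seed = 11)
  b <- rand_gauss(300, 3, seed = 12)
  c <- rand_gauss(300, 3, seed = 13)
  dab <- w2_distance(a$mu, a$s2, b$mu, b$s2)
  dba <- w2_distance(b$mu, b$s2, a$mu, a$s2)
  dac <- w2_distance(a$mu, a$s2, c$mu, c$s2)
  dcb <- w2_distance(c$mu, c$s2, b$mu, b$s2)
  expect_equal(dab, dba)                       # symmetry
  expect_true(all(dab >= 0))
  expect_true(all(dab <= dac + dcb + 1e-12))   # triangle inequality
  # identity of indiscernibles: zero only for identical parameters
  expect_true(all(dab[rowSums(abs(a$mu - b$mu)) + rowSums(abs(a$s2 - b$s2)) > 0] > 0))
})

test_that("within-subject change tables have the right shape and hand values", {
  # pre = post -> all-zero table
  g <- rand_gauss(5, 3, seed = 4)
  emb_same <- make_embedding(list(g$mu, g$mu), list(g$s2, g$s2),
                             c("s1", "s1"), c("pre", "post"))
  expect_equal(unname(within_subject_change(emb_same)), matrix(0, 5, 1))

  # 2 subjects x 3 ROIs toy with hand-set Gaussians
  mu_pre <- matrix(0, 3, 2); s2_pre <- matrix(1, 3, 2)
  mu_post <- rbind(c(1, 0), c(0, 0), c(3, 4)); s2_post <- matrix(1, 3, 2)
  emb <- make_embedding(list(mu_pre, mu_post, mu_pre, mu_pre),
                        list(s2_pre, s2_post, s2_pre, s2_pre),
                        c("a", "a", "b", "b"), c("pre", "post", "pre", "post"))
  w2 <- within_subject_change(emb)
  expect_equal(dim(w2), c(3L, 2L))             # N rows, S columns
  expect_equal(unname(w2[, "a"]), c(1, 0, 5))  # ||(1,0)|| = 1, 0, ||(3,4)|| = 5
  expect_equal(unname(w2[, "b"]), c(0, 0, 0))

  # a missing session is an error
  emb_miss <- make_embedding(list(mu_pre), list(s2_pre), "a", "pre")
  expect_error(within_subject_change(emb_miss), "missing a unique 'post'")
})

test_that("top-k system counts follow the tie rule and conserve k", {
  at <- synthetic_atlas(synthetic_spec(N = 12, n_systems = 3, S = 1))
  systems <- unique(at$system_name)

  # all W2 equal: ties broken by lowest ROI index, so the first k ROIs win
  w2_flat <- matrix(1, 12, 2)
  ct <- top_k_system_counts(w2_flat, at, k = 4, aggregate = "pooled_mean")
  expect_equal(sum(ct$count), 4L)
  expect_equal(ct$count[ct$system_name == at$system_name[1]], 4L)

  # per-subject aggregate pools each subject's top-k: counts sum to k * S
  ctps <- top_k_system_counts(w2_flat, at, k = 4, aggregate = "per_subject")
  expect_equal(sum(ctps$count), 8L)

  # a system given 10x larger W2 dominates the counts
  set.seed(8)
  w2 <- matrix(rexp(24), 12, 2)
  boost <- at$system_name == systems[2]
  w2[boost, ] <- w2[boost, ] * 10 + 10
  ct2 <- top_k_system_counts(w2, at, k = 4, aggregate = "pooled_mean")
  expect_equal(ct2$system_name[1], systems[2])
  expect_equal(ct2$count[1], 4L)

  expect_error(top_k_system_counts(w2, at, k = 13), "exceeds")
})

test_that("reorganization index counts pairs, detects planted shifts and matches a permutation oracle", {
  set.seed(19)
  S <- 8; N <- 6; L <- 8
  subjects <- sprintf("s%02d", 1:S)
  base <- lapply(1:S, function(s) rand_gauss(N, L, seed = 300 + s))
  # post = pre + a fixed mean shift on ROIs 1-2; no session noise, so the
  # remaining ROIs are exact nulls with all-zero pair differences
  shift <- c(0.8, 0.8, 0, 0, 0, 0)
  mu_list <- list(); s2_list <- list(); subj <- c(); sess <- c()
  for (s in 1:S) {
    mu_list <- c(mu_list, list(base[[s]]$mu, base[[s]]$mu + shift))
    s2_list <- c(s2_list, list(base[[s]]$s2, base[[s]]$s2))
    subj <- c(subj, subjects[s], subjects[s])
    sess <- c(sess, "pre", "post")
  }
  emb <- make_embedding(mu_list, s2_list, subj, sess)
  ri <- reorganization_index(emb)

  expect_equal(ncol(ri$between), S * (S - 1) / 2)
  expect_equal(ncol(ri$within), S * (S - 1) / 2)

  # planted ROIs carry the largest RI and are the significant set
  expect_setequal(order(-ri$table$ri)[1:2], 1:2)
  expect_true(all(ri$table$significant[1:2]))
  expect_false(any(ri$table$significant[3:6]))

  # t-test p-values agree with a sign-flip permutation oracle: a planted
  # ROI, a degenerate null ROI (both p = 1), and a weakly shifted ROI
  d <- ri$between - ri$within
  d[5, ] <- d[1, ] * 0.02 + rnorm(ncol(d), sd = 0.05)
  for (r in c(1, 3)) {
    pp <- perm_pvalue(d[r, ], n_perm = 1e4, seed = r)
    expect_lt(abs(ri$table$p[r] - pp), 0.06 + 3 * sqrt(pp * (1 - pp) / 1e4))
  }
  p_weak_t <- stats::t.test(d[5, ])$p.value
  pp_weak <- perm_pvalue(d[5, ], n_perm = 1e4, seed = 5)
  expect_lt(abs(p_weak_t - pp_weak), 0.06 + 3 * sqrt(pp_weak * (1 - pp_weak) / 1e4))

  # identical embeddings across all subjects and sessions: RI = 0, none significant
  g <- rand_gauss(N, L, seed = 5)
  emb0 <- make_embedding(rep(list(g$mu), 2 * S), rep(list(g$s2), 2 * S), subj, sess)
  ri0 <- reorganization_index(emb0)
  expect_equal(ri0$table$ri, rep(0, N))
  expect_equal(ri0$table$p, rep(1, N))
  expect_false(any(ri0$table$significant))

  expect_error(reorganization_index(emb, subjects = subjects[1]), "at least 2")
})

test_that("uncertainty profile flags inflated dimensions and is node-order invariant", {
  L <- 16
  g <- rand_gauss(40, L, seed = 21)
  s2 <- matrix(1, 40, L) + g$s2 * 0.01       # near-equal variances

  emb <- make_embedding(list(g$mu), list(s2), "s1", "pre")
  up <- uncertainty_profile(emb)
  expect_equal(up$effective_dim, L)
  expect_length(up$unstable_dims, 0)

  # exactly 3 dimensions inflated 10x -> effective dimension L - 3 = 13
  s2b <- s2; s2b[, c(8, 10, 11)] <- s2b[, c(8, 10, 11)] * 10
  emb2 <- make_embedding(list(g$mu), list(s2b), "s1", "pre")
  up2 <- uncertainty_profile(emb2, gamma = 2)
  expect_equal(up2$unstable_dims, c(8L, 10L, 11L))
  expect_equal(up2$effective_dim, 13L)

  # flagged set invariant to node ordering
  perm <- sample(40)
  emb3 <- make_embedding(list(g$mu[perm, ]), list(s2b[perm, ]), "s1", "pre")
  expect_equal(uncertainty_profile(emb3, gamma = 2)$unstable_dims, up2$unstable_dims)
})

test_that("the ROI change table file combines atlas, W2 and RI columns", {
  at <- synthetic_atlas(synthetic_spec(N = 6, n_systems = 2, S = 1))
  g <- rand_gauss(6, 4, seed = 2); h <- rand_gauss(6, 4, seed = 3)
  emb <- make_embedding(list(g$mu, h$mu, h$mu, g$mu), list(g$s2, h$s2, h$s2, g$s2),
                        c("a", "a", "b", "b"), c("pre", "post", "pre", "post"))
  w2 <- within_subject_change(emb)
  ri <- reorganization_index(emb)
  f <- tempfile(fileext = ".tsv")
  write_roi_change_table(w2, ri, at, f)
  out <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(out), 6L)
  expect_true(all(c("roi_index", "system_name", "ri", "q", "significant") %in% names(out)))
  unlink(f)
})
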