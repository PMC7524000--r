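toy_multigraph <- function(N = 40, n_systems = 4, S = 1, seed = 3, P_copies = NULL) {
  spec <- synthetic_spec(N = N, n_systems = n_systems, S = S, seed = seed)
  conn <- generate_connectomes(spec)
  mats <- conn$matrices
  if (!is.null(P_copies)) mats <- rep(mats[1], P_copies)
  list(mg = build_multigraph(mats, t = 0.1), labels = conn$labels)
}

test_that("forward pass reproduces hand-evaluated layer equations", {
  # zero weights and biases: mu = 0, sigma^2 = elu(0) + 1 = 1 everywhere
  cfg <- encoder_config(L = 2, M = 2, seed = 1)
  p0 <- mgembed:::init_encoder(cfg, D = 2)
  p0 <- lapply(p0, function(x) if (is.list(x)) lapply(x, function(y) y * 0) else x * 0)
  out0 <- encoder_forward(p0, matrix(rnorm(6), 3))
  expect_equal(out0$mu, matrix(0, 3, 2))
  expect_equal(out0$sigma2, matrix(1, 3, 2))

  # hand-set weights on a 1-node, 2-attribute, L = 2 toy:
  # z = x W1 + b1 = (0.5, -1.5); h = ReLU(z) = (0.5, 0)
  # mu = h Wmu + bmu = (0.6, 0.9); zs = h Wsig = (1, -1)
  # sigma^2 = (1 + 1, exp(-1))
  params <- list(Wh = list(matrix(c(1, 0.5, -0.5, 1), 2)), bh = list(c(0, 0)),
                 Wmu = matrix(c(1, 3, 2, 4), 2), bmu = c(0.1, -0.1),
                 Wsig = matrix(c(2, 0, -2, 0), 2), bsig = c(0, 0))
  out <- encoder_forward(params, matrix(c(1, -1), 1))
  expect_equal(out$mu, matrix(c(0.6, 0.9), 1), tolerance = 1e-12)
  expect_equal(out$sigma2, matrix(c(2, exp(-1)), 1), tolerance = 1e-12)

  # variances are strictly positive for arbitrary finite inputs
  set.seed(2)
  pr <- mgembed:::init_encoder(encoder_config(L = 4, M = 8, seed = 2), D = 5)
  out2 <- encoder_forward(pr, matrix(rnorm(50, sd = 10), 10))
  expect_true(all(out2$sigma2 > 0))

  # non-finite parameters are rejected
  pbad <- params; pbad$Wmu[1, 1] <- NaN
  expect_error(encoder_forward(pbad, matrix(0, 1, 2)), "non-finite")
})

test_that("kl_energy matches closed-form cases and a Monte-Carlo oracle", {
  # identical Gaussians -> 0 exactly
  g <- rand_gauss(50, 4, seed = 6)
  expect_equal(kl_energy(g$mu, g$s2, g$mu, g$s2), rep(0, 50))

  # 1-D worked example: mu_j = 1, mu_i = 0, unit variances -> 0.5
  expect_equal(kl_energy(0, 1, 1, 1), 0.5)

  # non-negativity on random pairs
  a <- rand_gauss(200, 3, seed = 7); b <- rand_gauss(200, 3, seed = 8)
  expect_true(all(kl_energy(a$mu, a$s2, b$mu, b$s2) >= 0))

  # closed form vs Monte-Carlo within 3 standard errors (3-D pairs)
  for (seed in 1:3) {
    set.seed(seed + 40)
    mu_i <- rnorm(3); mu_j <- rnorm(3)
    s2_i <- rexp(3) + 0.2; s2_j <- rexp(3) + 0.2
    mc <- mc_kl(mu_i, s2_i, mu_j, s2_j, n = 1e5, seed = seed)
    expect_lt(abs(kl_energy(mu_i, s2_i, mu_j, s2_j) - mc$est), 3 * mc$se)
  }

  # non-positive variances are an error
  expect_error(kl_energy(0, 0, 1, 1), "strictly positive")
})

test_that("square-exponential loss reproduces the direct formula and is order-invariant", {
  # anchor N(0,1), near N(sqrt(2),1), far N(sqrt(2),1): E_pos = E_neg = 1
  emb <- list(mu = matrix(c(0, sqrt(2), sqrt(2)), 3), sigma2 = matrix(1, 3, 1))
  tri <- matrix(c(1L, 2L, 3L), 1)
  expect_equal(square_exponential_loss(emb, tri), 1 + exp(-1), tolerance = 1e-12)

  # sum over triples is invariant to their ordering
  set.seed(5)
  g <- rand_gauss(10, 3, seed = 5)
  emb2 <- list(mu = g$mu, sigma2 = g$s2)
  tris <- cbind(sample(1:3, 6, TRUE), sample(4:6, 6, TRUE), sample(7:10, 6, TRUE))
  expect_equal(square_exponential_loss(emb2, tris),
               square_exponential_loss(emb2, tris[sample(6), ]))

  # perfect-ranking limit: E_pos = 0 and E_neg large drives the loss to ~0
  embp <- list(mu = matrix(c(0, 0, 50), 3), sigma2 = matrix(1, 3, 1))
  expect_lt(square_exponential_loss(embp, tri), 1e-12)

  expect_error(square_exponential_loss(emb, tri[0, , drop = FALSE]), "empty")
})

test_that("analytic gradients agree with finite differences", {
  D <- 5; N <- 8
  cfg <- encoder_config(L = 3, M = 4, seed = 3)
  params <- mgembed:::init_encoder(cfg, D)
  set.seed(11)
  X <- matrix(rnorm(N * D), N)
  ia <- c(1L, 2L, 5L); ja <- c(3L, 4L, 6L); ka <- c(7L, 8L, 2L)
  lossfun <- function(p) {
    fw <- mgembed:::forward_full(p, X)
    mgembed:::loss_and_output_grads(fw$Mu, fw$S2, ia, ja, ka)$loss
  }
  fw <- mgembed:::forward_full(params, X)
  og <- mgembed:::loss_and_output_grads(fw$Mu, fw$S2, ia, ja, ka)
  gr <- mgembed:::backward_pass(params, fw, X, og$dMu, og$dS2)
  fp <- mgembed:::flatten_params(params)
  fg <- mgembed:::flatten_params(gr)
  eps <- 1e-6
  set.seed(12)
  for (i in seq_along(fp)) {
    for (j in sample(length(fp[[i]]), min(4, length(fp[[i]])))) {
      p2 <- fp; p2[[i]][j] <- p2[[i]][j] + eps
      up <- lossfun(mgembed:::unflatten_params(p2, params))
      p2[[i]][j] <- p2[[i]][j] - 2 * eps
      dn <- lossfun(mgembed:::unflatten_params(p2, params))
      expect_equal(fg[[i]][j], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("training reduces the loss and orders planted strata by energy", {
  toy <- toy_multigraph(N = 40, n_systems = 2, S = 1, seed = 13)
  strata <- multigraph_strata(toy$mg, K = 2)
  cfg <- encoder_config(L = 4, M = 16, max_epochs = 60, seed = 2)
  fit <- train_embedding(toy$mg, strata, cfg)
  tr <- fit$trace$loss
  # monotone trend over windows, not per step
  expect_lt(mean(tail(tr, 10)), mean(head(tr, 10)))
  expect_true(all(is.finite(tr)))

  # sigma positivity for every trained embedding
  expect_true(all(fit$embedding$sigma2[[1]] > 0))

  # mean energy over stratum-1 pairs < mean over stratum-2 pairs
  emb <- fit$embedding
  st <- strata[[1]]
  e_near <- c(); e_far <- c()
  for (i in seq_along(st)) {
    for (j in st[[i]][[1]]) {
      e_near <- c(e_near, kl_energy(emb$mu[[1]][i, ], emb$sigma2[[1]][i, ],
                                    emb$mu[[1]][j, ], emb$sigma2[[1]][j, ]))
    }
    for (j in st[[i]][[2]]) {
      e_far <- c(e_far, kl_energy(emb$mu[[1]][i, ], emb$sigma2[[1]][i, ],
                                  emb$mu[[1]][j, ], emb$sigma2[[1]][j, ]))
    }
  }
  expect_lt(mean(e_near), mean(e_far))
})

test_that("the shared encoder embeds identical graphs identically and respects max_epochs = 0", {
  toy <- toy_multigraph(N = 30, n_systems = 3, S = 1, seed = 4, P_copies = 3)
  strata <- multigraph_strata(toy$mg, K = 2)
  cfg <- encoder_config(L = 4, M = 8, max_epochs = 5, seed = 9)
  fit <- train_embedding(toy$mg, strata, cfg)
  expect_identical(fit$embedding$mu[[1]], fit$embedding$mu[[2]])
  expect_identical(fit$embedding$sigma2[[1]], fit$embedding$sigma2[[3]])

  # max_epochs = 0 returns the initialization unchanged
  cfg0 <- encoder_config(L = 4, M = 8, max_epochs = 0, seed = 9)
  fit0 <- train_embedding(toy$mg, strata, cfg0)
  expect_equal(fit0$params, mgembed:::init_encoder(cfg0, D = toy$mg$D))
  expect_equal(nrow(fit0$trace), 0L)

  # training is reproducible from the seed
  fit2 <- train_embedding(toy$mg, strata, cfg)
  expect_identical(fit$trace$loss, fit2$trace$loss)
  expect_identical(fit$embedding$mu[[1]], fit2$embedding$mu[[1]])
})

test_that("embeddings round-trip through the delimited writer", {
  g1 <- rand_gauss(6, 3, seed = 1); g2 <- rand_gauss(6, 3, seed = 2)
  emb <- make_embedding(list(g1$mu, g2$mu), list(g1$s2, g2$s2),
                        c("s1", "s1"), c("pre", "post"))
  f <- tempfile(fileext = ".tsv")
  write_embedding(emb, f)
  back <- read_embedding(f)
  expect_equal(back$mu, emb$mu, tolerance = 1e-12)
  expect_equal(back$sigma2, emb$sigma2, tolerance = 1e-12)
  expect_equal(back$index, emb$index)
  unlink(f)
})
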