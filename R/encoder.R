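# The Gaussian graph encoder: a shared feed-forward network mapping the node
# attribute vectors of all P graphs into per-node multivariate Gaussians
# (mean vector mu and diagonal variance sigma^2), trained by minimizing a
# square-exponential ranking loss over KL-divergence energies of sampled
# node triplets, with Adam. Because the encoder parameters are shared across
# graphs, all embeddings live in one common latent space, which is what makes
# pre/post-intervention and cross-subject Wasserstein comparisons meaningful.

#' Encoder configuration
#'
#' @param L Embedding size: number of latent Gaussian dimensions (default 16).
#' @param M Hidden layer width (default 128).
#' @param n_hidden_layers Number of ReLU hidden layers (default 1).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param max_epochs Maximum training epochs (default 1000).
#' @param seed Integer seed controlling initialization and triplet resampling.
#' @param covariance_shape `"diagonal"` (default) or `"spherical"`.
#' @param per_anchor Triplet sampling rounds per anchor per epoch (default 3).
#' @param val_every Epoch interval at which validation AUC is computed when
#'   validation edges are supplied (default 25).
#' @param patience Number of consecutive non-improving validation checks
#'   tolerated before early stopping; `NULL` (default) disables early
#'   stopping and trains for `max_epochs`.
#' @param lr_decay_epoch Epoch after which the learning rate is multiplied
#'   by `lr_decay_factor` (annealing for the final refinement phase);
#'   `NULL` (default) keeps the initial rate throughout.
#' @param lr_decay_factor Multiplicative decay factor (default 0.2).
#' @param verbose Print per-epoch progress.
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(L = 16L, M = 128L, n_hidden_layers = 1L,
                           learning_rate = 1e-3, max_epochs = 1000L,
                           seed = 1L, covariance_shape = c("diagonal", "spherical"),
                           per_anchor = 3L, val_every = 25L, patience = NULL,
                           lr_decay_epoch = NULL, lr_decay_factor = 0.2,
                           verbose = FALSE) {
  covariance_shape <- match.arg(covariance_shape)
  L <- as.integer(L); M <- as.integer(M)
  if (L < 2L) stop("`L` must be at least 2", call. = FALSE)
  if (M < 1L) stop("`M` must be at least 1", call. = FALSE)
  if (n_hidden_layers < 1L) stop("`n_hidden_layers` must be at least 1", call. = FALSE)
  assert_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (max_epochs < 0L) stop("`max_epochs` must be non-negative", call. = FALSE)
  structure(list(L = L, M = M, n_hidden_layers = as.integer(n_hidden_layers),
                 learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), covariance_shape = covariance_shape,
                 per_anchor = as.integer(per_anchor), val_every = as.integer(val_every),
                 patience = patience,
                 lr_decay_epoch = lr_decay_epoch,
                 lr_decay_factor = lr_decay_factor,
                 verbose = isTRUE(verbose)),
            class = "encoder_config")
}

# Scaled (Glorot-style) random initialization of all weights and biases.
init_encoder <- function(config, D) {
  D <- as.integer(D)
  n_sig <- if (config$covariance_shape == "spherical") 1L else config$L
  with_seed(config$seed, {
    glorot <- function(fan_in, fan_out) {
      matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
             nrow = fan_in, ncol = fan_out)
    }
    dims <- c(D, rep(config$M, config$n_hidden_layers))
    Wh <- vector("list", config$n_hidden_layers)
    bh <- vector("list", config$n_hidden_layers)
    for (k in seq_len(config$n_hidden_layers)) {
      Wh[[k]] <- glorot(dims[k], dims[k + 1L])
      bh[[k]] <- numeric(dims[k + 1L])
    }
    list(Wh = Wh, bh = bh,
         Wmu = glorot(config$M, config$L), bmu = numeric(config$L),
         Wsig = glorot(config$M, n_sig), bsig = numeric(n_sig))
  })
}

# Forward pass keeping intermediate activations for backpropagation.
forward_full <- function(params, X) {
  H <- X
  Hs <- vector("list", length(params$Wh) + 1L)
  Hs[[1L]] <- X
  for (k in seq_along(params$Wh)) {
    Z <- sweep(H %*% params$Wh[[k]], 2L, params$bh[[k]], `+`)
    H <- Z * (Z > 0)                       # ReLU
    Hs[[k + 1L]] <- H
  }
  Mu <- sweep(H %*% params$Wmu, 2L, params$bmu, `+`)
  Zs <- sweep(H %*% params$Wsig, 2L, params$bsig, `+`)
  # sigma^2 = elu(z) + 1: z + 1 for z > 0, exp(z) otherwise; strictly positive
  S2head <- ifelse(Zs > 0, Zs + 1, exp(Zs))
  S2 <- if (ncol(S2head) == 1L) S2head[, rep(1L, ncol(Mu)), drop = FALSE] else S2head
  list(Mu = Mu, S2 = S2, S2head = S2head, Zs = Zs, Hs = Hs)
}

#' Encode node attributes as Gaussian distributions (single forward pass)
#'
#' Applies the encoder: one or more ReLU hidden layers, a linear mean head,
#' and a variance head `elu(z) + 1` guaranteeing strictly positive variances.
#'
#' @param params Encoder parameters (as produced during [train_embedding()]).
#' @param attributes N x D numeric matrix of node attribute vectors.
#' @return List with `mu` (N x L) and `sigma2` (N x L), the per-node Gaussian
#'   means and diagonal variances.
#' @export
encoder_forward <- function(params, attributes) {
  attributes <- as.matrix(attributes)
  finite <- all(vapply(c(params$Wh, params$bh,
                         list(params$Wmu, params$bmu, params$Wsig, params$bsig)),
                       function(p) all(is.finite(p)), logical(1)))
  if (!finite) stop("encoder parameters contain non-finite values", call. = FALSE)
  if (ncol(attributes) != nrow(params$Wh[[1L]])) {
    stop(sprintf("attribute dimension %d does not match encoder input dimension %d",
                 ncol(attributes), nrow(params$Wh[[1L]])), call. = FALSE)
  }
  fw <- forward_full(params, attributes)
  list(mu = fw$Mu, sigma2 = fw$S2)
}

#' KL-divergence energy between diagonal Gaussians
#'
#' Closed-form Kullback-Leibler divergence `KL(N_j || N_i)` for Gaussians
#' with diagonal covariance, used as the (asymmetric) energy of the ordered
#' node pair (i, j):
#' `0.5 * sum_d [ s2_j/s2_i + (mu_i - mu_j)^2/s2_i - 1 + log(s2_i/s2_j) ]`.
#' Inputs may be single vectors or row-wise matrices of equal shape.
#'
#' @param mu_i,sigma2_i Mean and variance of the reference Gaussian(s) i.
#' @param mu_j,sigma2_j Mean and variance of Gaussian(s) j.
#' @return Non-negative numeric vector of energies, zero iff the two
#'   Gaussians are identical.
#' @examples
#' kl_energy(0, 1, 1, 1)  # 0.5
#' @export
kl_energy <- function(mu_i, sigma2_i, mu_j, sigma2_j) {
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
  unname(0.5 * rowSums(sigma2_j / sigma2_i + dm * dm / sigma2_i - 1 +
                         log(sigma2_i) - log(sigma2_j)))
}

#' Square-exponential ranking loss over a triplet set
#'
#' For each triple (anchor i, nearer j, farther j') the positive energy is
#' `E_pos = KL(N_j || N_i)` and the negative energy `E_neg = KL(N_j' || N_i)`;
#' the loss is `sum(E_pos^2 + exp(-E_neg))`, summed over all graphs. Driving
#' it down ranks nearer nodes as less divergent from the anchor than farther
#' ones.
#'
#' @param embedding A `gaussian_embedding` (see [train_embedding()]) or a
#'   single-graph list with `mu` and `sigma2` matrices.
#' @param triplets A `triplet_set`, or a list of one triplet set per graph.
#' @return Non-negative scalar loss.
#' @export
square_exponential_loss <- function(embedding, triplets) {
  if (inherits(embedding, "gaussian_embedding")) {
    if (!is.list(triplets) || inherits(triplets, "triplet_set")) {
      stop("for a multi-graph embedding, `triplets` must be a list with one triplet set per graph",
           call. = FALSE)
    }
    if (length(triplets) != length(embedding$mu)) {
      stop("need one triplet set per graph", call. = FALSE)
    }
    return(sum(vapply(seq_along(triplets), function(p) {
      square_exponential_loss(list(mu = embedding$mu[[p]],
                                   sigma2 = embedding$sigma2[[p]]),
                              triplets[[p]])
    }, numeric(1))))
  }
  tr <- unclass(triplets)
  if (is.null(dim(tr)) || nrow(tr) == 0L) {
    stop("empty triplet set", call. = FALSE)
  }
  Mu <- embedding$mu; S2 <- embedding$sigma2
  e_pos <- kl_energy(Mu[tr[, 1L], , drop = FALSE], S2[tr[, 1L], , drop = FALSE],
                     Mu[tr[, 2L], , drop = FALSE], S2[tr[, 2L], , drop = FALSE])
  e_neg <- kl_energy(Mu[tr[, 1L], , drop = FALSE], S2[tr[, 1L], , drop = FALSE],
                     Mu[tr[, 3L], , drop = FALSE], S2[tr[, 3L], , drop = FALSE])
  sum(e_pos^2) + sum(exp(-e_neg))
}

# Loss and gradients w.r.t. Mu and S2 for stacked embeddings and globally
# indexed triples (ia, ja, ka). Energies are KL(N_b || N_a) with a = anchor.
loss_and_output_grads <- function(Mu, S2, ia, ja, ka) {
  kl_parts <- function(a, b) {
    s2a <- S2[a, , drop = FALSE]; s2b <- S2[b, , drop = FALSE]
    dm <- Mu[a, , drop = FALSE] - Mu[b, , drop = FALSE]
    list(kl = 0.5 * rowSums(s2b / s2a + dm * dm / s2a - 1 + log(s2a) - log(s2b)),
         s2a = s2a, s2b = s2b, dm = dm)
  }
  pos <- kl_parts(ia, ja)
  neg <- kl_parts(ia, ka)
  loss <- sum(pos$kl^2) + sum(exp(-neg$kl))

  gp <- 2 * pos$kl          # dLoss/dE_pos
  gn <- -exp(-neg$kl)       # dLoss/dE_neg

  pair_grads <- function(o, g) {
    dmu_a <- g * (o$dm / o$s2a)
    ds2_a <- g * 0.5 * (1 / o$s2a - o$s2b / o$s2a^2 - o$dm^2 / o$s2a^2)
    ds2_b <- g * 0.5 * (1 / o$s2a - 1 / o$s2b)
    list(dmu_a = dmu_a, dmu_b = -dmu_a, ds2_a = ds2_a, ds2_b = ds2_b)
  }
  pg <- pair_grads(pos, gp)
  ng <- pair_grads(neg, gn)

  idx <- c(ia, ja, ia, ka)
  accum <- function(c1, c2, c3, c4) {
    acc <- rowsum(rbind(c1, c2, c3, c4), group = idx)
    out <- matrix(0, nrow = nrow(Mu), ncol = ncol(Mu))
    out[as.integer(rownames(acc)), ] <- acc
    out
  }
  list(loss = loss,
       dMu = accum(pg$dmu_a, pg$dmu_b, ng$dmu_a, ng$dmu_b),
       dS2 = accum(pg$ds2_a, pg$ds2_b, ng$ds2_a, ng$ds2_b))
}

# Full backward pass: gradients of the loss w.r.t. all encoder parameters.
backward_pass <- function(params, fw, X, dMu, dS2) {
  # variance head: d sigma^2/dz = 1 for z > 0, exp(z) = sigma^2 otherwise
  dElu <- pmin(fw$S2, 1)
  if (ncol(fw$S2head) == 1L) {
    dZs <- rowSums(dS2 * dElu)
    dZs <- matrix(dZs, ncol = 1L)
  } else {
    dZs <- dS2 * dElu
  }
  H <- fw$Hs[[length(fw$Hs)]]
  grads <- list(
    Wmu = crossprod(H, dMu), bmu = colSums(dMu),
    Wsig = crossprod(H, dZs), bsig = colSums(dZs)
  )
  dH <- tcrossprod(dMu, params$Wmu) + tcrossprod(dZs, params$Wsig)
  nl <- length(params$Wh)
  grads$Wh <- vector("list", nl)
  grads$bh <- vector("list", nl)
  for (k in rev(seq_len(nl))) {
    dZ <- dH * (fw$Hs[[k + 1L]] > 0)
    grads$Wh[[k]] <- crossprod(fw$Hs[[k]], dZ)
    grads$bh[[k]] <- colSums(dZ)
    if (k > 1L) dH <- dZ %*% t(params$Wh[[k]])
  }
  grads
}

flatten_params <- function(p) c(p$Wh, p$bh, list(p$Wmu, p$bmu, p$Wsig, p$bsig))

unflatten_params <- function(flat, template) {
  nl <- length(template$Wh)
  list(Wh = flat[seq_len(nl)], bh = flat[nl + seq_len(nl)],
       Wmu = flat[[2L * nl + 1L]], bmu = flat[[2L * nl + 2L]],
       Wsig = flat[[2L * nl + 3L]], bsig = flat[[2L * nl + 4L]])
}

adam_init <- function(params) {
  fl <- flatten_params(params)
  list(m = lapply(fl, function(p) p * 0), v = lapply(fl, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(fp)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * fg[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * fg[[i]]^2
    fp[[i]] <- fp[[i]] - lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = unflatten_params(fp, params), state = state)
}

new_gaussian_embedding <- function(mu_list, sigma2_list, index, L) {
  structure(list(mu = mu_list, sigma2 = sigma2_list, index = index, L = L),
            class = "gaussian_embedding")
}

#' @export
print.gaussian_embedding <- function(x, ...) {
  cat(sprintf("<gaussian_embedding> P = %d graphs, N = %d nodes, L = %d latent dimensions\n",
              length(x$mu), nrow(x$mu[[1L]]), x$L))
  invisible(x)
}

#' Train the shared Gaussian encoder on a multi-graph set
#'
#' Jointly embeds all P graphs into one latent space: a single encoder maps
#' every graph's node attribute matrix to per-node Gaussians, and is trained
#' by Adam on the square-exponential KL ranking loss over hop-stratified node
#' triplets. Triplets are resampled every epoch with seeds derived
#' deterministically from `(config$seed, epoch, graph)`, so the full loss
#' trajectory is reproducible.
#'
#' @param mg A `multigraph` from [build_multigraph()]. When evaluating link
#'   prediction, build it from the training adjacency matrices so held-out
#'   edges never leak into attributes or neighbourhoods.
#' @param strata List of `hop_strata`, one per graph (see
#'   [multigraph_strata()]).
#' @param config An [encoder_config()].
#' @param val_edges Optional list with elements `pos` and `neg`, each a list
#'   (one per graph) of 2-column node-pair matrices; when supplied,
#'   validation AUC is tracked every `config$val_every` epochs and, if
#'   `config$patience` is set, training stops early and the best parameters
#'   are returned.
#' @return List of class `mg_fit` with elements `params`, `embedding`
#'   (a `gaussian_embedding`), `trace` (data frame of epoch, loss,
#'   validation AUC) and `config`.
#' @export
train_embedding <- function(mg, strata, config, val_edges = NULL) {
  stopifnot(inherits(mg, "multigraph"))
  if (!inherits(config, "encoder_config")) stop("`config` must be an encoder_config",
                                                call. = FALSE)
  if (length(strata) != mg$P) stop("need one hop_strata per graph", call. = FALSE)

  N <- mg$N
  X <- do.call(rbind, mg$graphs)   # (P*N) x D stacked attributes
  params <- init_encoder(config, D = mg$D)
  state <- adam_init(params)
  offsets <- (seq_len(mg$P) - 1L) * N

  trace <- data.frame(epoch = integer(0), loss = numeric(0), val_auc = numeric(0))
  best <- list(auc = -Inf, params = params, epoch = 0L)
  bad_checks <- 0L

  val_auc_now <- function(fw) {
    sc <- function(pairs_list) {
      unlist(lapply(seq_len(mg$P), function(p) {
        prs <- pairs_list[[p]]
        if (is.null(prs) || nrow(prs) == 0L) return(numeric(0))
        a <- prs[, 1L] + offsets[p]; b <- prs[, 2L] + offsets[p]
        -0.5 * (kl_energy(fw$Mu[a, , drop = FALSE], fw$S2[a, , drop = FALSE],
                          fw$Mu[b, , drop = FALSE], fw$S2[b, , drop = FALSE]) +
                  kl_energy(fw$Mu[b, , drop = FALSE], fw$S2[b, , drop = FALSE],
                            fw$Mu[a, , drop = FALSE], fw$S2[a, , drop = FALSE]))
      }))
    }
    auc_score(sc(val_edges$pos), sc(val_edges$neg))
  }

  epoch <- 0L
  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    trip <- lapply(seq_len(mg$P), function(p) {
      tr <- sample_triplets(strata[[p]], per_anchor = config$per_anchor,
                            seed = derive_seed(config$seed, epoch, p))
      cbind(tr[, 1L] + offsets[p], tr[, 2L] + offsets[p], tr[, 3L] + offsets[p])
    })
    trip <- do.call(rbind, trip)

    fw <- forward_full(params, X)
    og <- loss_and_output_grads(fw$Mu, fw$S2, trip[, 1L], trip[, 2L], trip[, 3L])
    if (!is.finite(og$loss)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
           call. = FALSE)
    }
    grads <- backward_pass(params, fw, X, og$dMu, og$dS2)
    lr <- config$learning_rate
    if (!is.null(config$lr_decay_epoch) && epoch > config$lr_decay_epoch) {
      lr <- lr * config$lr_decay_factor
    }
    upd <- adam_step(params, grads, state, lr = lr)
    params <- upd$params
    state <- upd$state

    va <- NA_real_
    if (!is.null(val_edges) && epoch %% config$val_every == 0L) {
      va <- val_auc_now(forward_full(params, X))
      if (va > best$auc) {
        best <- list(auc = va, params = params, epoch = epoch)
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
      }
    }
    trace <- rbind(trace, data.frame(epoch = epoch, loss = og$loss, val_auc = va))
    if (config$verbose && (epoch %% 25L == 0L || epoch == 1L)) {
      message(sprintf("epoch %4d  loss %.4f%s", epoch, og$loss,
                      if (is.na(va)) "" else sprintf("  val AUC %.4f", va)))
    }
    if (!is.null(config$patience) && !is.null(val_edges) &&
        bad_checks >= config$patience) {
      params <- best$params
      break
    }
  }

  fw <- forward_full(params, X)
  mu_list <- lapply(seq_len(mg$P), function(p) fw$Mu[offsets[p] + seq_len(N), , drop = FALSE])
  s2_list <- lapply(seq_len(mg$P), function(p) fw$S2[offsets[p] + seq_len(N), , drop = FALSE])
  emb <- new_gaussian_embedding(mu_list, s2_list, mg$index, config$L)
  attr(trace, "best_epoch") <- if (is.finite(best$auc)) best$epoch else NA_integer_
  structure(list(params = params, embedding = emb, trace = trace, config = config),
            class = "mg_fit")
}

#' @export
print.mg_fit <- function(x, ...) {
  cat(sprintf("<mg_fit> trained %d epochs, final loss %.4f\n",
              nrow(x$trace), utils::tail(x$trace$loss, 1)))
  print(x$embedding)
  invisible(x)
}

#' Write a Gaussian embedding as tab-delimited text
#'
#' One record per (graph, node) with the L means followed by the L variances.
#'
#' @param embedding A `gaussian_embedding`.
#' @param path Destination file path.
#' @export
write_embedding <- function(embedding, path) {
  L <- embedding$L
  rows <- do.call(rbind, lapply(seq_along(embedding$mu), function(p) {
    n <- nrow(embedding$mu[[p]])
    data.frame(subject_id = embedding$index$subject_id[p],
               session = embedding$index$session[p],
               node = seq_len(n),
               embedding$mu[[p]], embedding$sigma2[[p]],
               check.names = FALSE)
  }))
  names(rows) <- c("subject_id", "session", "node",
                   sprintf("mu_%d", seq_len(L)), sprintf("sigma2_%d", seq_len(L)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Gaussian embedding written by [write_embedding()]
#'
#' @param path File path.
#' @return A `gaussian_embedding`.
#' @export
read_embedding <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  L <- sum(grepl("^mu_", names(d)))
  key <- paste(d$subject_id, d$session, sep = "\r")
  keys <- unique(key)
  mu <- lapply(keys, function(k) as.matrix(d[key == k, sprintf("mu_%d", seq_len(L))]))
  s2 <- lapply(keys, function(k) as.matrix(d[key == k, sprintf("sigma2_%d", seq_len(L))]))
  mu <- lapply(mu, function(m) { dimnames(m) <- NULL; m })
  s2 <- lapply(s2, function(m) { dimnames(m) <- NULL; m })
  first <- !duplicated(key)
  index <- data.frame(subject_id = d$subject_id[first], session = d$session[first],
                      stringsAsFactors = FALSE)
  new_gaussian_embedding(mu, s2, index, L)
}
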