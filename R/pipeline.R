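# Configuration and end-to-end orchestration: simulate -> embed -> evaluate
# -> analyze. Every stage is reproducible from (config, seed) and output
# files embed the configuration hash.

#' Pipeline run configuration
#'
#' Collects all module defaults in one round-trippable object: connectivity
#' threshold `t = 0.1`, hop depth `K = 2`, embedding size `L = 16`, hidden
#' width `M = 128`, Adam learning rate `1e-3`, maximum epochs 1000, edge
#' split 85/10/5, instability multiplier `gamma = 2` and FDR level 0.05.
#'
#' @param threshold Connectivity threshold.
#' @param K Number of hop strata.
#' @param strata_mode `"quantile"` or `"bfs"`.
#' @param strata_probs Optional cumulative stratum masses, see
#'   [stratify_hops()].
#' @param length_transform `"inverse"` or `"one_minus"`.
#' @param per_anchor Triplet sampling rounds per anchor per epoch.
#' @param L,M,n_hidden_layers,learning_rate,max_epochs Encoder settings, see
#'   [encoder_config()].
#' @param split Train/validation/test edge fractions.
#' @param top_k Number of top changing ROIs per subject.
#' @param gamma Uncertainty instability multiplier.
#' @param fdr_level FDR significance level.
#' @param seed Master seed.
#' @param synthetic Named list of [synthetic_spec()] overrides used when the
#'   pipeline generates its own data.
#' @param out_dir Optional output directory; when set, the `run_*` functions
#'   write their result files there.
#' @return Object of class `run_config`.
#' @export
run_config <- function(threshold = 0.1, K = 2L,
                       strata_mode = c("quantile", "quantile_anchor", "bfs"),
                       strata_probs = NULL,
                       length_transform = c("inverse", "one_minus"),
                       per_anchor = 3L, L = 16L, M = 128L, n_hidden_layers = 1L,
                       learning_rate = 1e-3, max_epochs = 1000L,
                       split = c(0.85, 0.10, 0.05), top_k = 15L, gamma = 2.0,
                       fdr_level = 0.05, seed = 1L, synthetic = list(),
                       out_dir = NULL) {
  cfg <- list(threshold = threshold, K = as.integer(K),
              strata_mode = match.arg(strata_mode),
              strata_probs = strata_probs,
              length_transform = match.arg(length_transform),
              per_anchor = as.integer(per_anchor), L = as.integer(L),
              M = as.integer(M), n_hidden_layers = as.integer(n_hidden_layers),
              learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
              split = split, top_k = as.integer(top_k), gamma = gamma,
              fdr_level = fdr_level, seed = as.integer(seed),
              synthetic = synthetic, out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML round trip is lossless for all configuration fields.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$synthetic <- raw$synthetic %||% list()
  do.call(run_config, raw)
}

#' Short hash identifying a run configuration
#'
#' @param config A [run_config()].
#' @return Character MD5 digest of the canonical YAML serialization.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

as_encoder_config <- function(config, seed_offset = 0L) {
  encoder_config(L = config$L, M = config$M,
                 n_hidden_layers = config$n_hidden_layers,
                 learning_rate = config$learning_rate,
                 max_epochs = config$max_epochs,
                 seed = derive_seed(config$seed, 7L, seed_offset),
                 per_anchor = config$per_anchor)
}

config_synthetic_spec <- function(config) {
  args <- config$synthetic
  args$seed <- args$seed %||% derive_seed(config$seed, 11L)
  do.call(synthetic_spec, args)
}

#' Generate a synthetic dataset from a run configuration
#'
#' @param config A [run_config()].
#' @return A `synthetic_connectomes` object; written to `config$out_dir`
#'   when that is set.
#' @export
run_simulate <- function(config) {
  conn <- generate_connectomes(config_synthetic_spec(config))
  if (!is.null(config$out_dir)) write_synthetic_dataset(conn, config$out_dir)
  conn
}

resolve_input <- function(config, data) {
  if (is.null(data)) data <- run_simulate(config)
  if (inherits(data, "synthetic_connectomes")) {
    return(list(matrices = data$matrices, index = data$index,
                atlas = data$atlas, labels = data$labels))
  }
  list(matrices = data$matrices, index = data$index %||% NULL,
       atlas = data$atlas %||% NULL, labels = data$labels %||% NULL)
}

#' Embed a multi-subject dataset (construction, sampling, training)
#'
#' Thresholds the connectivity matrices, computes weighted hop strata and
#' trains the shared Gaussian encoder on the full graphs.
#'
#' @param config A [run_config()].
#' @param data Optional input: a `synthetic_connectomes` object or a list
#'   with elements `matrices` (list of connectivity matrices) and optionally
#'   `index`, `atlas`, `labels`. When `NULL`, a synthetic dataset is
#'   generated from the config.
#' @return List with `fit` (an `mg_fit`), `mg`, `data` and `config_hash`.
#'   When `config$out_dir` is set, the embedding and training trace are
#'   written there.
#' @export
run_embed <- function(config, data = NULL) {
  inp <- resolve_input(config, data)
  mg <- build_multigraph(inp$matrices, t = config$threshold, index = inp$index)
  strata <- multigraph_strata(mg, K = config$K, mode = config$strata_mode,
                              length_transform = config$length_transform,
                              probs = config$strata_probs)
  fit <- train_embedding(mg, strata, as_encoder_config(config))
  hash <- config_hash(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_embedding(fit$embedding, file.path(config$out_dir, "embedding.tsv"))
    tr <- fit$trace
    tr$config_hash <- hash
    utils::write.table(tr, file.path(config$out_dir, "training_trace.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(fit = fit, mg = mg, data = inp, config_hash = hash)
}

#' Link-prediction evaluation with edge hold-out
#'
#' Splits every graph's edges into train/validation/test sets, rebuilds the
#' multigraph from the training adjacency matrices only (so held-out edges
#' leak into neither attributes nor hop strata), trains the encoder, and
#' reports AUC per graph and pooled across graphs.
#'
#' @param config A [run_config()].
#' @param data Optional input as in [run_embed()].
#' @return List with `auc_test_pooled`, `auc_val_pooled`, `auc_test_per_graph`,
#'   `splits`, `fit` and `config_hash`.
#' @export
run_evaluate <- function(config, data = NULL) {
  inp <- resolve_input(config, data)
  full <- build_multigraph(inp$matrices, t = config$threshold, index = inp$index)
  splits <- lapply(seq_len(full$P), function(p) {
    split_edges(full$graphs[[p]], fractions = config$split,
                seed = derive_seed(config$seed, 13L, p))
  })
  train_mats <- lapply(splits, `[[`, "train_adjacency")
  mg <- structure(list(graphs = train_mats, index = full$index, N = full$N,
                       D = full$D, P = full$P, threshold = full$threshold),
                  class = "multigraph")
  strata <- multigraph_strata(mg, K = config$K, mode = config$strata_mode,
                              length_transform = config$length_transform,
                              probs = config$strata_probs)
  val_edges <- list(pos = lapply(splits, `[[`, "val_edges"),
                    neg = lapply(splits, `[[`, "val_neg"))
  fit <- train_embedding(mg, strata, as_encoder_config(config), val_edges = val_edges)

  emb <- fit$embedding
  graph_scores <- function(p, what) {
    score_pairs(list(mu = emb$mu[[p]], sigma2 = emb$sigma2[[p]]), splits[[p]][[what]])
  }
  te_pos <- lapply(seq_len(full$P), graph_scores, what = "test_edges")
  te_neg <- lapply(seq_len(full$P), graph_scores, what = "test_neg")
  va_pos <- lapply(seq_len(full$P), graph_scores, what = "val_edges")
  va_neg <- lapply(seq_len(full$P), graph_scores, what = "val_neg")

  per_graph <- vapply(seq_len(full$P), function(p) {
    auc_score(te_pos[[p]], te_neg[[p]])
  }, numeric(1))
  res <- list(auc_test_pooled = auc_score(unlist(te_pos), unlist(te_neg)),
              auc_val_pooled = auc_score(unlist(va_pos), unlist(va_neg)),
              auc_test_per_graph = per_graph,
              splits = splits, fit = fit, config_hash = config_hash(config))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    rep <- data.frame(graph = c(sprintf("graph%02d", seq_len(full$P)), "pooled"),
                      auc_test = c(per_graph, res$auc_test_pooled),
                      config_hash = res$config_hash)
    utils::write.table(rep, file.path(config$out_dir, "auc_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

#' Full change analysis: W2 profiles, reorganization index, uncertainty
#'
#' Embeds the dataset (or reuses a supplied embedding) and computes the
#' within-subject W2 change table, top-k system counts, the reorganization
#' index with FDR statistics, and the uncertainty profile.
#'
#' @param config A [run_config()].
#' @param data Optional input as in [run_embed()].
#' @param embedding Optional precomputed `gaussian_embedding` (skips
#'   training); `data` must then carry the matching `atlas`.
#' @param atlas Optional atlas override.
#' @return List with `w2` (N x S matrix), `system_counts`, `ri`
#'   (an `ri_result`), `uncertainty` and `config_hash`; files are written to
#'   `config$out_dir` when set.
#' @export
run_analyze <- function(config, data = NULL, embedding = NULL, atlas = NULL) {
  if (is.null(embedding)) {
    emb_run <- run_embed(config, data)
    embedding <- emb_run$fit$embedding
    atlas <- atlas %||% emb_run$data$atlas
  }
  if (is.null(atlas)) stop("an atlas is required for system-level counts", call. = FALSE)
  w2 <- within_subject_change(embedding)
  counts <- top_k_system_counts(w2, atlas, k = config$top_k)
  ri <- reorganization_index(embedding, fdr_level = config$fdr_level)
  unc <- uncertainty_profile(embedding, gamma = config$gamma)
  hash <- config_hash(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_roi_change_table(w2, ri, atlas, file.path(config$out_dir, "roi_change_table.tsv"))
    counts_out <- counts
    counts_out$config_hash <- hash
    utils::write.table(counts_out, file.path(config$out_dir, "system_counts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    unc_out <- data.frame(dimension = seq_along(unc$dim_variance),
                          median_variance = unc$dim_variance,
                          unstable = seq_along(unc$dim_variance) %in% unc$unstable_dims,
                          effective_dim = unc$effective_dim,
                          config_hash = hash)
    utils::write.table(unc_out, file.path(config$out_dir, "uncertainty_profile.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(w2 = w2, system_counts = counts, ri = ri, uncertainty = unc,
       config_hash = hash)
}
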