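# Synthetic multi-subject weighted connectome generator. Emulates the
# structure of resting-state functional connectivity matrices over an atlas
# of N regions grouped into functional systems (communities): strong
# within-system correlation, graded and selective between-system coupling,
# subject- and session-level variability, and an optional localized
# "intervention" perturbation that rewires designated ROIs toward a donor
# community in the post session.
#
# Population weights have three parts: (i) a global baseline w_out shared by
# all pairs, (ii) a community term adding w_in - w_out - w_coupling within
# each community, and (iii) a selective system-pair coupling: every pair of
# communities (c, c') receives a baseline w_coupling * z_cc' with z_cc'
# drawn once per population from Uniform(-1, 1) (z = 1 within a community),
# modulated by smooth node-level strengths. Between-system baselines are
# therefore spread over w_out +/- w_coupling: some system pairs are coupled
# well above the edge threshold, most are not, and few sit near it, so weak
# links carry structure (as in real connectomes) instead of being i.i.d.
# noise. Because the coupling matrix is unstructured (full rank), the
# planted relational geometry is not embeddable in a very low dimension,
# matching connectomes whose intrinsic dimensionality is comparable to the
# number of systems. A low-amplitude node-level residual field (a rank-q
# Gram term over latent node vectors) adds smooth pair-level texture, so
# whether a weak link clears a threshold is mostly determined by structure
# visible in the connectivity profiles -- mirroring the transitivity of real
# correlation matrices -- rather than by i.i.d. noise.

power_system_names <- c(
  "Sensory/somatomotor Hand", "Sensory/somatomotor Mouth",
  "Cingulo-opercular Task Control", "Auditory", "Default mode",
  "Memory retrieval", "Visual", "Fronto-parietal Task Control", "Salience",
  "Subcortical", "Ventral attention", "Dorsal attention", "Cerebellar",
  "Uncertain"
)

#' Specification of a synthetic multi-subject connectome dataset
#'
#' @param N Number of ROIs (default 264).
#' @param n_systems Number of functional systems / communities (default 14).
#' @param system_sizes Optional integer vector of community sizes summing to
#'   `N`; defaults to a near-equal partition.
#' @param S Number of subjects (default 12); each has a `pre` and a `post`
#'   session.
#' @param w_in Mean within-community weight (default 0.6).
#' @param w_out Mean between-community weight, the global coupling baseline
#'   (default 0.02; must satisfy `w_in > w_out >= 0`).
#' @param w_coupling Amplitude of the selective between-system coupling
#'   (default 0.2); between-system baselines spread uniformly over
#'   `w_out ± w_coupling`.
#' @param node_jitter SD of the node-level coupling-strength modulation
#'   (default 0.15), creating within-community heterogeneity.
#' @param w_local Amplitude (SD) of the smooth node-level residual field
#'   (default 0.08): pair (i, j) receives `w_local * <v_i, v_j>` for latent
#'   node vectors v, giving weak links predictable structure.
#' @param local_dim Dimension q of the latent node vectors (default 4).
#' @param edge_sd SD of pair-level population heterogeneity, fixed across
#'   subjects (default 0.02).
#' @param subject_sd SD of subject-level weight noise, shared between a
#'   subject's two sessions (default 0.025).
#' @param session_sd SD of session-level weight noise (default 0.015).
#' @param targets Integer vector of perturbed ROI indices (1-based), or
#'   `NULL` (default) for no intervention effect.
#' @param delta Perturbation effect size in \[0, 1\]: the post-session
#'   connectivity profile of each target is the convex mixture
#'   `(1 - delta) * own + delta * donor-community profile` (default 0.6).
#' @param donors Optional integer vector (same length as `targets`) of donor
#'   community indices; defaults to each target's community shifted by one.
#' @param seed Integer seed making the whole dataset reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(N = 264L, n_systems = 14L, system_sizes = NULL,
                           S = 12L, w_in = 0.6, w_out = 0.02, w_coupling = 0.2,
                           node_jitter = 0.15, w_local = 0.08, local_dim = 4L,
                           edge_sd = 0.02, subject_sd = 0.025,
                           session_sd = 0.015, targets = NULL, delta = 0.6,
                           donors = NULL, seed = 1L) {
  N <- as.integer(N); n_systems <- as.integer(n_systems); S <- as.integer(S)
  if (N < n_systems || n_systems < 1L || S < 1L) {
    stop("need N >= n_systems >= 1 and S >= 1", call. = FALSE)
  }
  if (is.null(system_sizes)) {
    system_sizes <- diff(round(seq(0, N, length.out = n_systems + 1L)))
  }
  system_sizes <- as.integer(system_sizes)
  if (length(system_sizes) != n_systems || sum(system_sizes) != N ||
      any(system_sizes < 1L)) {
    stop("`system_sizes` must be positive and sum to N", call. = FALSE)
  }
  if (!(w_in > w_out && w_out >= 0)) stop("need w_in > w_out >= 0", call. = FALSE)
  if (w_in - w_out - w_coupling <= 0) {
    stop("need w_in > w_out + w_coupling (positive community factor)", call. = FALSE)
  }
  assert_scalar_number(delta, "delta", lower = 0, upper = 1)
  if (!is.null(targets)) {
    targets <- as.integer(targets)
    if (any(targets < 1L | targets > N)) stop("`targets` out of range", call. = FALSE)
  }
  labels <- rep(seq_len(n_systems), system_sizes)
  if (!is.null(donors)) {
    donors <- as.integer(donors)
    if (length(donors) != length(targets)) {
      stop("`donors` must match `targets` in length", call. = FALSE)
    }
    if (any(donors < 1L | donors > n_systems)) stop("`donors` out of range", call. = FALSE)
    if (any(donors == labels[targets])) {
      stop("a donor community must differ from the target's own community", call. = FALSE)
    }
  } else if (!is.null(targets)) {
    donors <- (labels[targets] %% n_systems) + 1L
  }
  structure(list(N = N, n_systems = n_systems, system_sizes = system_sizes,
                 labels = labels, S = S, w_in = w_in, w_out = w_out,
                 w_coupling = w_coupling, node_jitter = node_jitter,
                 w_local = w_local, local_dim = as.integer(local_dim),
                 edge_sd = edge_sd, subject_sd = subject_sd,
                 session_sd = session_sd, targets = targets, delta = delta,
                 donors = donors, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Synthetic atlas table for a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return Atlas data frame (`roi_index` 0-based, `roi_name`, `system_name`)
#'   using the standard names of the 14 resting-state functional systems
#'   (recycled if more communities are requested).
#' @export
synthetic_atlas <- function(spec) {
  sys_names <- rep_len(power_system_names, spec$n_systems)
  if (spec$n_systems > length(power_system_names)) {
    sys_names <- paste0(sys_names, "_", seq_len(spec$n_systems))
  }
  data.frame(roi_index = 0:(spec$N - 1L),
             roi_name = sprintf("ROI_%03d", seq_len(spec$N)),
             system_name = sys_names[spec$labels],
             stringsAsFactors = FALSE)
}

# Population structure: the symmetric system-pair coupling matrix Z (diag 1,
# off-diagonal Uniform(-1, 1)), node-level coupling strengths m, and latent
# node vectors V for the residual field (scaled so <v_i, v_j> has unit SD).
population_structure <- function(spec, seed) {
  with_seed(seed, {
    ns <- spec$n_systems
    Z <- diag(ns)
    Z[upper.tri(Z)] <- stats::runif(ns * (ns - 1L) / 2L, -1, 1)
    Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
    m <- 1 + spec$node_jitter * stats::rnorm(spec$N)
    V <- matrix(stats::rnorm(spec$N * spec$local_dim,
                             sd = spec$local_dim^(-1 / 4)),
                nrow = spec$N)
    list(Z = Z, m = m, V = V)
  })
}

# Connectivity profile node r would have if it belonged to community `donor`:
# the row of population weights implied by donor membership.
donor_profile <- function(spec, st, r, donor) {
  alpha2 <- spec$w_in - spec$w_out - spec$w_coupling
  spec$w_out + alpha2 * (spec$labels == donor) +
    spec$w_coupling * st$Z[donor, spec$labels] * st$m[r] * st$m +
    spec$w_local * drop(st$V %*% st$V[r, ])
}

# Population weight matrices for the pre and post sessions. The post matrix
# mixes each target ROI's profile toward its donor community's profile
# (convex combination with weight delta), then re-symmetrizes.
population_weights <- function(spec) {
  st <- population_structure(spec, derive_seed(spec$seed, 101L))
  alpha2 <- spec$w_in - spec$w_out - spec$w_coupling
  W <- spec$w_out + alpha2 * outer(spec$labels, spec$labels, `==`) +
    spec$w_coupling * st$Z[spec$labels, spec$labels] * tcrossprod(st$m) +
    spec$w_local * tcrossprod(st$V)
  E <- with_seed(derive_seed(spec$seed, 102L), {
    e <- matrix(stats::rnorm(spec$N^2, sd = spec$edge_sd), spec$N)
    (e + t(e)) / sqrt(2)
  })
  W_pre <- W + E
  diag(W_pre) <- 1
  W_post <- W_pre
  if (!is.null(spec$targets) && spec$delta > 0) {
    for (k in seq_along(spec$targets)) {
      r <- spec$targets[k]
      prof <- donor_profile(spec, st, r, spec$donors[k])
      W_post[r, ] <- (1 - spec$delta) * W_post[r, ] + spec$delta * prof
    }
    W_post <- (W_post + t(W_post)) / 2
    diag(W_post) <- 1
  }
  list(pre = W_pre, post = W_post)
}

sym_noise <- function(n, sd, seed) {
  if (sd == 0) return(matrix(0, n, n))
  with_seed(seed, {
    e <- matrix(stats::rnorm(n * n, sd = sd), n)
    (e + t(e)) / sqrt(2)
  })
}

#' Generate synthetic multi-subject connectivity matrices
#'
#' Draws one pre- and one post-intervention connectivity matrix per subject
#' from the population model of the spec: population weights (with planted
#' community structure and, for target ROIs, a delta-scaled post-session
#' profile shift toward a donor community) plus subject-level noise shared
#' between sessions and independent session-level noise. Entries are clipped
#' to \[-1, 1\] and the diagonal is 1.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_connectomes` with `matrices` (list of
#'   2S connectivity matrices, each carrying `subject_id`/`session`
#'   attributes), `index` (data frame), `labels` (ground-truth community of
#'   every ROI), `atlas` and `spec`.
#' @export
generate_connectomes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pop <- population_weights(spec)
  sessions <- c("pre", "post")
  mats <- vector("list", 2L * spec$S)
  index <- data.frame(subject_id = character(2L * spec$S),
                      session = character(2L * spec$S),
                      stringsAsFactors = FALSE)
  g <- 0L
  for (s in seq_len(spec$S)) {
    subj_noise <- sym_noise(spec$N, spec$subject_sd, derive_seed(spec$seed, 200L, s))
    sid <- sprintf("subj%02d", s)
    for (sess in sessions) {
      g <- g + 1L
      W <- (if (sess == "pre") pop$pre else pop$post) + subj_noise +
        sym_noise(spec$N, spec$session_sd,
                  derive_seed(spec$seed, 300L, s, match(sess, sessions)))
      W[W > 1] <- 1
      W[W < -1] <- -1
      diag(W) <- 1
      attr(W, "subject_id") <- sid
      attr(W, "session") <- sess
      mats[[g]] <- W
      index$subject_id[g] <- sid
      index$session[g] <- sess
    }
  }
  structure(list(matrices = mats, index = index, labels = spec$labels,
                 atlas = synthetic_atlas(spec), spec = spec),
            class = "synthetic_connectomes")
}

#' @export
print.synthetic_connectomes <- function(x, ...) {
  cat(sprintf("<synthetic_connectomes> %d subjects x 2 sessions, N = %d ROIs, %d systems%s\n",
              x$spec$S, x$spec$N, x$spec$n_systems,
              if (length(x$spec$targets)) sprintf(", %d perturbed ROIs (delta = %g)",
                                                  length(x$spec$targets), x$spec$delta)
              else ""))
  invisible(x)
}

# Repair a symmetric matrix into a positive-definite correlation matrix by
# clipping eigenvalues and rescaling the diagonal to 1.
repair_correlation <- function(W, eps = 1e-6, quiet = FALSE) {
  ei <- eigen(W, symmetric = TRUE)
  if (min(ei$values) < eps) {
    if (!quiet) {
      message(sprintf("target covariance not positive definite (min eigenvalue %.3g); repaired by diagonal loading",
                      min(ei$values)))
    }
    v <- pmax(ei$values, eps)
    W <- ei$vectors %*% (v * t(ei$vectors))
    d <- sqrt(diag(W))
    W <- W / tcrossprod(d)
  }
  (W + t(W)) / 2
}

#' Generate synthetic ROI time series
#'
#' Draws multivariate Gaussian time series whose population correlation
#' matrix has the spec's block structure (the same per-subject/session
#' target matrices as [generate_connectomes()], repaired to positive
#' definiteness by diagonal loading when necessary). Sample Pearson
#' connectivity matrices computed from these series converge to the
#' population matrices as T grows.
#'
#' @param spec A [synthetic_spec()].
#' @param T_len Number of timepoints per session (default 220, i.e. a common
#'   resting-state acquisition length after dropping initial volumes).
#' @param quiet Suppress the diagonal-loading repair message.
#' @return List of class `synthetic_timeseries` with `series` (list of
#'   T x N matrices with `subject_id`/`session` attributes), `targets`
#'   (the population correlation matrix of every series), `index`, `labels`,
#'   `atlas` and `spec`.
#' @export
generate_timeseries <- function(spec, T_len = 220L, quiet = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  T_len <- as.integer(T_len)
  if (T_len < 2L) stop("`T_len` must be at least 2", call. = FALSE)
  conn <- generate_connectomes(spec)
  series <- vector("list", length(conn$matrices))
  targets <- vector("list", length(conn$matrices))
  for (g in seq_along(conn$matrices)) {
    Sigma <- repair_correlation(unclass_matrix(conn$matrices[[g]]), quiet = quiet)
    R <- chol(Sigma)
    Z <- with_seed(derive_seed(spec$seed, 400L, g), {
      matrix(stats::rnorm(T_len * spec$N), nrow = T_len)
    })
    ts <- Z %*% R
    attr(ts, "subject_id") <- conn$index$subject_id[g]
    attr(ts, "session") <- conn$index$session[g]
    series[[g]] <- ts
    targets[[g]] <- Sigma
  }
  structure(list(series = series, targets = targets, index = conn$index,
                 labels = spec$labels, atlas = conn$atlas, spec = spec),
            class = "synthetic_timeseries")
}

unclass_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

#' Write a synthetic dataset to delimited files
#'
#' Writes one tab-delimited matrix file per subject-session (named
#' `<subject>_<session>.tsv`), the atlas table and a ground-truth community
#' labels file into a directory.
#'
#' @param conn A `synthetic_connectomes` object.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_synthetic_dataset <- function(conn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in seq_along(conn$matrices)) {
    f <- file.path(dir, sprintf("%s_%s.tsv", conn$index$subject_id[g],
                                conn$index$session[g]))
    write_matrix_file(unclass_matrix(conn$matrices[[g]]), f)
  }
  write_atlas(conn$atlas, file.path(dir, "atlas.tsv"))
  utils::write.table(data.frame(roi_index = 0:(conn$spec$N - 1L),
                                community = conn$labels),
                     file.path(dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
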