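#' Center gene rows
#'
#' Subtracts each gene's mean across samples, keeping the means for later
#' projection. Constant genes become zero rows and are flagged.
#'
#' @param X expression matrix (genes x samples).
#' @return list with `values` (centered matrix), `gene_means`, and
#'   `constant_genes` (ids of zero-variance rows).
#' @export
center_genes <- function(X) {
  X <- as_expression_matrix(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  const <- rownames(X)[apply(Xc, 1L, function(r) all(r == 0))]
  list(values = unclass(Xc), gene_means = mu, constant_genes = const)
}

#' Whiten a centered expression matrix by truncated SVD
#'
#' Retains `d` principal axes (or the smallest number reaching
#' `var_target` cumulative variance) and rotates/rescales so that the d
#' whitened rows have unit variance and zero pairwise covariance across
#' samples.
#'
#' @param centered output of [center_genes()].
#' @param d retained dimension; `NULL` to use `var_target`.
#' @param var_target cumulative explained-variance target (default 0.9).
#' @return object of class `whitened_data`: `Z` (d x samples),
#'   `projection` (d x genes, `Z = projection %*% Xc`), `gene_means`, `d`,
#'   `explained_variance`, plus the SVD factors and the centered matrix used
#'   by downstream consensus steps.
#' @export
whiten <- function(centered, d = NULL, var_target = 0.9) {
  # remove per-sample offsets as well: activities must reflect contrasts
  # between genes, not profile-wide shifts, and this puts the component
  # column space exactly orthogonal to the constant gene vector
  Xc <- sweep(centered$values, 2L, colMeans(centered$values))
  n <- ncol(Xc)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1L])
  ev <- sv$d^2 / sum(sv$d^2)
  if (is.null(d)) {
    d <- which(cumsum(ev) >= var_target)[1L]
    if (is.na(d)) d <- rank
  }
  assert_that(d >= 1, "d must be >= 1")
  if (d > rank) {
    stop_(sprintf("requested dimension %d exceeds achievable rank %d", d, rank))
  }
  assert_that(d <= min(nrow(Xc), n - 1L), "d must be <= min(genes, samples-1)")
  Z <- sqrt(n - 1) * t(sv$v[, seq_len(d), drop = FALSE])
  colnames(Z) <- colnames(Xc)
  structure(list(
    Z = Z,
    projection = sqrt(n - 1) * (t(sv$u[, seq_len(d), drop = FALSE]) / sv$d[seq_len(d)]),
    gene_means = centered$gene_means,
    d = d,
    explained_variance = ev[seq_len(d)],
    U = sv$u[, seq_len(d), drop = FALSE],
    singular_values = sv$d[seq_len(d)],
    Xc = Xc,
    gene_ids = rownames(Xc),
    sample_ids = colnames(Xc)
  ), class = "whitened_data")
}

# Whitened gene-observation matrix (d x genes): genes are the realizations
# over which source independence/non-Gaussianity is measured, so FastICA
# iterates on this representation. Rows are exactly uncorrelated (orthogonal
# singular vectors) with variance ~1 over genes.
gene_space_white <- function(W) {
  sqrt(nrow(W$U)) * t(W$U)
}

sym_decorrelate <- function(Wm) {
  e <- eigen(Wm %*% t(Wm), symmetric = TRUE)
  e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-300))) %*% Wm
}

#' One randomized FastICA run
#'
#' Symmetric fixed-point FastICA with the logcosh contrast on the whitened
#' data, from a seeded random orthonormal start. Non-convergence within
#' `max_iter` is flagged but the run is kept, since the consensus averages
#' over restarts.
#'
#' @param W [whiten()] output.
#' @param k number of components (<= `W$d`).
#' @param seed RNG seed for the initial rotation.
#' @param tol convergence tolerance on the rotation update (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @return list `components` (d x k unmixing directions, unit norm),
#'   `seed`, `converged`, `iterations`.
#' @export
fastica_run <- function(W, k, seed = 1L, tol = 1e-6, max_iter = 500L) {
  assert_that(k >= 1, "k must be positive")
  assert_that(k <= W$d, "k must be <= whitening dimension d")
  G <- gene_space_white(W)
  p <- ncol(G)
  Wm <- with_seed(seed, matrix(rnorm(k * W$d), k, W$d))
  Wm <- sym_decorrelate(Wm)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y <- Wm %*% G
    gy <- tanh(Y)
    W_new <- gy %*% t(G) / p - rowMeans(1 - gy^2) * Wm
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * Wm)) - 1))
    Wm <- W_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(components = t(Wm), seed = seed, converged = converged, iterations = it)
}

# Back-project run-space unmixing directions to standardized gene-space
# source estimates (genes x k).
back_project_run <- function(run, W) {
  standardize_cols(W$U %*% run$components)
}

apply_sign_convention <- function(S) {
  for (j in seq_len(ncol(S))) {
    i <- which.max(abs(S[, j]))
    if (S[i, j] < 0) S[, j] <- -S[, j]
  }
  S
}

#' Build consensus components across randomized ICA runs
#'
#' Back-projects every run's sources to gene space, greedily clusters them
#' across runs by absolute Pearson correlation, keeps clusters present in at
#' least `min_occupancy` of the runs, and averages sign-aligned members into
#' consensus transcriptional components (TCs). Per-TC credibility is the mean
#' pairwise absolute correlation within the cluster. The consensus mixing
#' matrix is obtained by projecting the training data onto the consensus TCs
#' with the same least-squares operator used for cross-study projection
#' ([project()]), so self-projection reproduces it exactly.
#'
#' @param runs list of [fastica_run()] results (>= 2).
#' @param W [whiten()] output the runs were computed on.
#' @param match_threshold minimum |r| to join a cluster (default 0.8).
#' @param min_occupancy minimum fraction of runs a cluster must appear in
#'   (default 0.5).
#' @return object of class `cica_result`: `S` (genes x k consensus weights,
#'   each column mean 0 / variance 1 with the largest-|weight| gene
#'   positive), `M` (samples x k activities), `credibility`, `cluster_sizes`,
#'   `n_runs`, `k`, `reconstruction_residual`, `gene_means`.
#' @export
consensus_components <- function(runs, W, match_threshold = 0.8,
                                 min_occupancy = 0.5) {
  assert_that(length(runs) >= 2L, "need at least 2 runs")
  mats <- lapply(runs, back_project_run, W = W)
  clusters <- list()  # each: members (list of vectors), runs (int), centroid
  for (r in seq_along(mats)) {
    for (j in seq_len(ncol(mats[[r]]))) {
      v <- mats[[r]][, j]
      best <- 0
      best_i <- 0L
      for (i in seq_along(clusters)) {
        if (r %in% clusters[[i]]$runs) next  # one member per run
        rc <- abs(cor(v, clusters[[i]]$centroid))
        if (rc > best) {
          best <- rc
          best_i <- i
        }
      }
      if (best_i > 0L && best >= match_threshold) {
        cl <- clusters[[best_i]]
        if (cor(v, cl$centroid) < 0) v <- -v
        cl$members <- c(cl$members, list(v))
        cl$runs <- c(cl$runs, r)
        cl$centroid <- rowMeans(do.call(cbind, cl$members))
        clusters[[best_i]] <- cl
      } else {
        clusters <- c(clusters, list(list(members = list(v), runs = r,
                                          centroid = v)))
      }
    }
  }
  keep <- vapply(clusters, function(cl) {
    length(unique(cl$runs)) / length(runs) >= min_occupancy
  }, logical(1L))
  clusters <- clusters[keep]
  if (length(clusters) == 0L) {
    stop_("no consensus clusters survived; lower k or match_threshold")
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1L))
  cred <- vapply(clusters, function(cl) {
    if (length(cl$members) < 2L) return(1)
    cm <- abs(cor(do.call(cbind, cl$members)))
    mean(cm[upper.tri(cm)])
  }, numeric(1L))
  ord <- order(-sizes, -cred)
  clusters <- clusters[ord]
  sizes <- sizes[ord]
  cred <- cred[ord]
  S <- vapply(clusters, function(cl) cl$centroid, numeric(nrow(mats[[1L]])))
  S <- apply_sign_convention(standardize_cols(S))
  tc_ids <- paste0("TC", seq_len(ncol(S)))
  dimnames(S) <- list(W$gene_ids, tc_ids)
  M <- project(S, W$Xc)
  fit <- S %*% t(M)
  structure(list(
    S = S, M = M,
    credibility = setNames(cred, tc_ids),
    cluster_sizes = setNames(sizes, tc_ids),
    n_runs = length(runs), k = ncol(S),
    n_converged = sum(vapply(runs, `[[`, logical(1L), "converged")),
    reconstruction_residual = norm(W$Xc - fit, "F") / norm(W$Xc, "F"),
    gene_means = W$gene_means
  ), class = "cica_result")
}

#' @export
print.cica_result <- function(x, ...) {
  cat(sprintf("consensus ICA: %d TCs from %d runs (%d converged)\n",
              x$k, x$n_runs, x$n_converged))
  cat(sprintf("  genes: %d  samples: %d\n", nrow(x$S), nrow(x$M)))
  cat(sprintf("  credibility: median %.3f (min %.3f)\n",
              median(x$credibility), min(x$credibility)))
  cat(sprintf("  reconstruction residual: %.4f\n", x$reconstruction_residual))
  invisible(x)
}

#' Run the full consensus-ICA pipeline
#'
#' Convenience wrapper: center, whiten, `n_runs` randomized FastICA runs
#' with seeds derived from `seed`, consensus clustering.
#'
#' @param X expression matrix (genes x samples, log scale).
#' @param k components per run; defaults to the whitening dimension.
#' @param n_runs number of randomized runs (default 25).
#' @param seed base seed; per-run seeds are drawn from it.
#' @param d,var_target whitening dimension control (see [whiten()]).
#' @param match_threshold,min_occupancy consensus clustering control.
#' @return a `cica_result` (see [consensus_components()]).
#' @export
consensus_ica <- function(X, k = NULL, n_runs = 25L, seed = 1L, d = NULL,
                          var_target = 0.9, match_threshold = 0.8,
                          min_occupancy = 0.5) {
  W <- whiten(center_genes(X), d = d, var_target = var_target)
  if (is.null(k)) k <- W$d
  run_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_runs))
  runs <- lapply(run_seeds, function(s) fastica_run(W, k = k, seed = s))
  consensus_components(runs, W, match_threshold = match_threshold,
                       min_occupancy = min_occupancy)
}

#' Reconstruct expression from components and activities
#'
#' Returns the model fit `S %*% t(M)` (plus gene means when available) and,
#' when the data matrix is supplied, the relative Frobenius residual of the
#' fit to the gene-centered data.
#'
#' @param S genes x k weights (or a `cica_result`).
#' @param M samples x k activities (ignored when `S` is a `cica_result`).
#' @param X optional expression matrix to score the fit against.
#' @return list `estimate` (genes x samples) and `residual_fraction`
#'   (NA without `X`).
#' @export
reconstruct <- function(S, M = NULL, X = NULL) {
  gene_means <- 0
  if (inherits(S, "cica_result")) {
    fit <- S
    S <- fit$S
    M <- fit$M
    gene_means <- fit$gene_means
  }
  assert_that(ncol(S) == ncol(M), "S and M must share k")
  if (!is.null(colnames(S)) && !is.null(colnames(M))) {
    assert_that(identical(colnames(S), colnames(M)), "S/M component id mismatch")
  }
  est <- S %*% t(M) + gene_means
  resid <- NA_real_
  if (!is.null(X)) {
    assert_that(identical(rownames(X), rownames(S)), "gene id mismatch with X")
    Xc <- X - rowMeans(X)
    Xc <- sweep(Xc, 2L, colMeans(Xc))  # same double-centered space as the fit
    resid <- norm(Xc - (est - gene_means), "F") / norm(Xc, "F")
  }
  list(estimate = est, residual_fraction = resid)
}
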