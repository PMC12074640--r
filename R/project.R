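#' Project fixed transcriptional components onto new expression profiles
#'
#' Intersects genes, centers each gene within the new dataset, and solves an
#' ordinary-least-squares fit of each sample's profile on the component
#' weight matrix (normal equations with a small ridge for conditioning). The
#' per-sample coefficients are the component activity scores; applying the
#' operator to the training data returns the stored mixing matrix exactly.
#'
#' With `scale_genes = TRUE` each gene is additionally rescaled to unit SD
#' within the new dataset before fitting, for use across platforms with
#' incomparable per-gene scales.
#'
#' @param S genes x k component weight matrix (or a `cica_result`).
#' @param X_new genes x samples expression matrix; at least `min_coverage`
#'   of S's genes must be present.
#' @param scale_genes rescale genes of `X_new` to unit SD (default FALSE).
#' @param ridge ridge added to the normal equations (default 1e-8).
#' @param min_coverage minimum shared-gene fraction (default 0.5).
#' @return samples x k activity matrix.
#' @export
project <- function(S, X_new, scale_genes = FALSE, ridge = 1e-8,
                    min_coverage = 0.5) {
  if (inherits(S, "cica_result")) S <- S$S
  shared <- intersect(rownames(S), rownames(X_new))
  coverage <- length(shared) / nrow(S)
  if (coverage < min_coverage) {
    stop_(sprintf(
      "only %.1f%% of component genes present in the new data (%d of %d); need >= %.0f%%",
      100 * coverage, length(shared), nrow(S), 100 * min_coverage))
  }
  Ss <- S[shared, , drop = FALSE]
  Xs <- X_new[shared, , drop = FALSE]
  # single profiles carry no within-dataset baseline to remove
  if (ncol(Xs) > 1L) Xs <- Xs - rowMeans(Xs)
  if (scale_genes) {
    sds <- sqrt(rowSums(Xs^2) / (ncol(Xs) - 1L))
    sds[sds == 0] <- 1
    Xs <- Xs / sds
  }
  # per-profile offsets are nuisance, not component activity
  Xs <- sweep(Xs, 2L, colMeans(Xs))
  G <- crossprod(Ss) + ridge * diag(ncol(Ss))
  A <- tryCatch(solve(G, crossprod(Ss, Xs)),
                error = function(e) stop_("projection design is singular beyond the ridge"))
  out <- t(A)
  dimnames(out) <- list(colnames(X_new), colnames(S))
  out
}

#' Flag samples with outlying component activity
#'
#' @param A activity matrix (samples x components).
#' @param threshold absolute activity cut-off (default 0.05).
#' @return logical matrix of flags, with per-component flagged counts in
#'   attribute `n_flagged`.
#' @export
flag_outlier_activity <- function(A, threshold = 0.05) {
  assert_that(all(is.finite(A)), "activity matrix must be finite")
  flags <- abs(A) > threshold
  attr(flags, "n_flagged") <- colSums(flags)
  flags
}

#' Permutation significance map of component activity over spots
#'
#' Projects the components onto each spot profile, then builds a null
#' distribution per (component, spot) by shuffling the gene-to-weight
#' assignment within each component column and re-projecting, `n_perm`
#' times. Two-sided p-values use the add-one permutation estimator and are
#' converted to signed z-scores `sign(activity) * |qnorm(p/2)|`.
#'
#' @param S genes x k component weights (or a `cica_result`).
#' @param spot_profiles normalized genes x spots matrix
#'   (see [normalize_counts()]).
#' @param n_perm number of permutations (default 3000).
#' @param seed RNG seed.
#' @param ridge,min_coverage passed to the projection (see [project()]).
#' @return object of class `spatial_activity_map`: spots x k matrices
#'   `activity`, `p`, `z`.
#' @export
spot_pvalues <- function(S, spot_profiles, n_perm = 3000L, seed = 1L,
                         ridge = 1e-8, min_coverage = 0.5) {
  if (inherits(S, "cica_result")) S <- S$S
  if (n_perm < 100L) warning("n_perm < 100: tail quantiles will be unstable")
  obs <- project(S, spot_profiles, ridge = ridge, min_coverage = min_coverage)
  shared <- intersect(rownames(S), rownames(spot_profiles))
  Ss <- S[shared, , drop = FALSE]
  Xs <- spot_profiles[shared, , drop = FALSE]
  if (ncol(Xs) > 1L) Xs <- Xs - rowMeans(Xs)
  Xs <- sweep(Xs, 2L, colMeans(Xs))
  k <- ncol(Ss)
  count <- matrix(0L, nrow(obs), ncol(obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Sp <- vapply(seq_len(k), function(j) Ss[sample.int(nrow(Ss)), j],
                   numeric(nrow(Ss)))
      G <- crossprod(Sp) + ridge * diag(k)
      Ab <- t(solve(G, crossprod(Sp, Xs)))
      count <- count + (abs(Ab) >= abs(obs))
    }
  })
  p <- (1 + count) / (n_perm + 1)
  z <- sign(obs) * qnorm(1 - p / 2)
  dimnames(p) <- dimnames(z) <- dimnames(obs)
  structure(list(activity = obs, p = p, z = z, n_perm = n_perm, seed = seed),
            class = "spatial_activity_map")
}

jaccard <- function(a, b) {
  if (!any(a) || !any(b)) return(0)
  sum(a & b) / sum(a | b)
}

#' Colocalization score of two signed spatial significance maps
#'
#' Thresholds each map's signed z into a positive and a negative active
#' region and combines Jaccard overlaps:
#' `2*[J(A+,B+) + J(A-,B-)] - 2*[J(A+,B-) + J(A-,B+)]`.
#' The score is symmetric, bounded in \[-4, 4\]: 4 when both signed regions
#' coincide exactly, -4 when they are exactly sign-inverted, 0 when the
#' active regions are spatially separated.
#'
#' @param z_a,z_b signed z vectors over the same spots (names checked when
#'   present).
#' @param z_threshold region-membership threshold (default 1.96).
#' @return a single score in \[-4, 4\].
#' @export
colocalization <- function(z_a, z_b, z_threshold = 1.96) {
  assert_that(length(z_a) == length(z_b), "maps must share the spot set")
  if (!is.null(names(z_a)) && !is.null(names(z_b))) {
    assert_that(identical(names(z_a), names(z_b)), "spot ids differ between maps")
  }
  ap <- z_a > z_threshold
  an <- z_a < -z_threshold
  bp <- z_b > z_threshold
  bn <- z_b < -z_threshold
  2 * (jaccard(ap, bp) + jaccard(an, bn)) - 2 * (jaccard(ap, bn) + jaccard(an, bp))
}

#' Pairwise colocalization matrix of a spatial activity map
#'
#' @param map `spatial_activity_map` (or a spots x k signed-z matrix).
#' @param z_threshold see [colocalization()].
#' @return symmetric k x k score matrix.
#' @export
colocalization_matrix <- function(map, z_threshold = 1.96) {
  Z <- if (inherits(map, "spatial_activity_map")) map$z else map
  k <- ncol(Z)
  out <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j >= i) out[i, j] <- out[j, i] <- colocalization(Z[, i], Z[, j], z_threshold)
    }
  }
  dimnames(out) <- list(colnames(Z), colnames(Z))
  out
}
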