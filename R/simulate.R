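#' Synthetic gene annotation on a compact genome
#'
#' Lays `n_genes` out over `n_chrom` chromosomes in equal contiguous blocks,
#' 10 kb apart. Only gene order within a chromosome matters downstream, so
#' positions are schematic.
#'
#' @param n_genes number of genes.
#' @param n_chrom number of chromosomes.
#' @return annotation data.frame (gene_id, chromosome, start, end).
#' @export
make_gene_annotation <- function(n_genes, n_chrom = 4L) {
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), length.out = n_genes)
  chrom <- sort(chrom)  # contiguous blocks per chromosome
  idx <- unlist(lapply(table(chrom)[unique(chrom)], seq_len), use.names = FALSE)
  data.frame(gene_id = gene_id, chromosome = chrom,
             start = idx * 10000L, end = idx * 10000L + 5000L,
             stringsAsFactors = FALSE)
}

#' Plant sparse leptokurtic source components
#'
#' Non-CNA components have a `sparsity` fraction of genes with heavy-tailed
#' (Laplace) weights and the rest zero. CNA components mimic the dosage
#' footprint of a copy-number alteration: one contiguous run of 30-80 genes
#' in genomic order on a single chromosome carries same-sign elevated
#' weights, the rest near-zero noise. All columns are scaled to unit
#' variance (planted zeros stay exactly zero) and checked for mutual
#' decorrelation (max |r| < 0.2, regenerated if violated).
#'
#' @param n_genes,k matrix dimensions (genes x components).
#' @param sparsity fraction of non-zero weights per non-CNA component.
#' @param cna_fraction fraction of components planted as CNA footprints.
#' @param annotation gene annotation (required when `cna_fraction > 0`);
#'   rownames of the result follow `annotation$gene_id` when given.
#' @param seed RNG seed.
#' @param laplace_scale scale of the Laplace weight draw.
#' @return genes x k matrix with attributes `cna_components` (indices) and
#'   `cna_blocks` (list of planted gene-index runs, in genomic order).
#' @export
make_sources <- function(n_genes, k, sparsity = 0.025, cna_fraction = 0,
                         annotation = NULL, seed = 1L, laplace_scale = 3) {
  assert_that(sparsity > 0 && sparsity < 1, "sparsity must be in (0,1)")
  assert_that(k <= n_genes / 10, "k > n_genes/10: planting under-determined")
  n_cna <- round(cna_fraction * k)
  assert_that(n_cna == 0 || !is.null(annotation),
              "annotation required to plant CNA components")
  if (!is.null(annotation)) {
    assert_that(nrow(annotation) == n_genes, "annotation must cover all genes")
  }
  gene_ids <- if (is.null(annotation)) sprintf("g%05d", seq_len(n_genes)) else annotation$gene_id

  draw <- function(attempt) with_seed(seed + 7919L * (attempt - 1L), {
    S <- matrix(0, n_genes, k)
    cna_idx <- if (n_cna > 0) seq_len(n_cna) else integer(0)
    blocks <- vector("list", k)
    for (j in seq_len(k)) {
      if (j %in% cna_idx) {
        # contiguous same-sign run in genomic order on one chromosome
        ord <- order(annotation$chromosome, annotation$start)
        chrom <- sample(unique(annotation$chromosome), 1L)
        on_chr <- ord[annotation$chromosome[ord] == chrom]
        len <- sample(30:80, 1L)
        assert_that(length(on_chr) >= len, "chromosome too short for CNA block")
        at <- sample(length(on_chr) - len + 1L, 1L)
        run <- on_chr[at:(at + len - 1L)]
        s <- sample(c(-1, 1), 1L)
        S[, j] <- rnorm(n_genes, 0, 0.05)
        S[run, j] <- s * abs(rnorm(len, mean = 3, sd = 0.5))
        blocks[[j]] <- run
      } else {
        nz <- max(1L, round(sparsity * n_genes))
        S[sample(n_genes, nz), j] <- rlaplace(nz, scale = laplace_scale)
      }
    }
    # scale-only standardization keeps planted zeros exactly zero
    sds <- apply(S, 2L, sd)
    list(S = sweep(S, 2L, sds, "/"), cna_idx = cna_idx, blocks = blocks)
  })

  for (attempt in 1:20) {
    out <- draw(attempt)
    if (k == 1L) break
    r <- cor(out$S)
    if (max(abs(r[upper.tri(r)])) < 0.2) break
    assert_that(attempt < 20, "could not plant decorrelated sources")
  }
  S <- out$S
  dimnames(S) <- list(gene_ids, paste0("src", seq_len(k)))
  attr(S, "cna_components") <- out$cna_idx
  attr(S, "cna_blocks") <- out$blocks
  S
}

#' Plant sample activity scores
#'
#' Independent standard-normal activities, column-standardized.
#'
#' @param n_samples,k dimensions (samples x components); needs
#'   `n_samples >= 3k` for identifiable downstream decomposition.
#' @param seed RNG seed.
#' @export
make_mixing <- function(n_samples, k, seed = 1L) {
  assert_that(n_samples >= 3 * k, "need n_samples >= 3k")
  M <- with_seed(seed, matrix(rnorm(n_samples * k), n_samples, k))
  M <- standardize_cols(M)
  dimnames(M) <- list(sprintf("s%04d", seq_len(n_samples)),
                      paste0("src", seq_len(k)))
  M
}

#' Mix planted sources into an expression matrix
#'
#' `X = S M' + E` with i.i.d. Gaussian noise of sd `noise_sd`.
#'
#' @param S_true genes x k sources.
#' @param M_true samples x k activities.
#' @param noise_sd noise standard deviation (>= 0).
#' @param seed RNG seed for the noise.
#' @export
make_expression <- function(S_true, M_true, noise_sd = 0.2, seed = 1L) {
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(ncol(S_true) == ncol(M_true), "S and M must share k")
  X <- S_true %*% t(M_true)
  if (noise_sd > 0) {
    X <- X + with_seed(seed, matrix(rnorm(length(X), 0, noise_sd), nrow(X)))
  }
  dimnames(X) <- list(rownames(S_true), rownames(M_true))
  as_expression_matrix(X)
}

#' Generate proportional-hazards survival outcomes from planted activities
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(sum_j beta_j m_ij + beta_age (age-60)/10 + beta_stage (stage-3))`,
#' censoring is independent exponential at `censor_rate` (0 = none). Age is
#' Normal(60, 10) years, stage categorical on 1-4; times are in months.
#'
#' @param M_true samples x k activity matrix.
#' @param survival_betas named or indexed numeric vector of log-hazard
#'   coefficients; names/indices refer to columns of `M_true`.
#' @param covariate_spec list with `beta_age`, `beta_stage` (per the
#'   standardized covariates above).
#' @param baseline_rate exponential baseline hazard per month (> 0).
#' @param censor_rate exponential censoring rate per month (0 disables).
#' @param seed RNG seed.
#' @return a clinical data.frame (see [as_clinical()]).
#' @export
make_clinical <- function(M_true, survival_betas = numeric(0),
                          covariate_spec = list(beta_age = 0.3, beta_stage = 0.3),
                          baseline_rate = 1 / 60, censor_rate = 1 / 120,
                          seed = 1L) {
  assert_that(baseline_rate > 0, "baseline_rate must be > 0")
  n <- nrow(M_true)
  if (is.null(names(survival_betas))) {
    idx <- seq_along(survival_betas)  # aligned to leading columns
  } else {
    # names are column names or integer component indices
    idx <- match(names(survival_betas), colnames(M_true))
    num <- suppressWarnings(as.integer(names(survival_betas)))
    idx[is.na(idx)] <- num[is.na(idx)]
  }
  assert_that(!anyNA(idx) && all(idx >= 1 & idx <= ncol(M_true)),
              "survival_betas reference unknown components")
  with_seed(seed, {
    age <- rnorm(n, 60, 10)
    stage <- sample(1:4, n, replace = TRUE, prob = c(0.10, 0.15, 0.45, 0.30))
    grade <- sample(1:3, n, replace = TRUE)
    debulking <- sample(c("complete", "incomplete"), n, replace = TRUE)
    lp <- as.vector(M_true[, idx, drop = FALSE] %*% as.numeric(survival_betas)) +
      covariate_spec$beta_age * (age - 60) / 10 +
      covariate_spec$beta_stage * (stage - 3)
    t_event <- rexp(n, rate = baseline_rate * exp(lp))
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
    as_clinical(data.frame(
      sample_id = rownames(M_true),
      os_time = pmin(t_event, t_cens),
      os_event = as.integer(t_event <= t_cens),
      age = age, stage = stage, grade = grade, debulking = debulking,
      platinum_treated = 1L, stringsAsFactors = FALSE))
  })
}

#' Generate a spatial dataset with regionally localized components
#'
#' Spots on a `rows x cols` grid are partitioned into regions; components
#' assigned to a region have planted activity `activity` at its spots and 0
#' elsewhere. Counts are Poisson with per-gene intensity proportional to
#' `softplus(S %*% m_spot)` plus a flat background, scaled so spot totals are
#' about `depth`.
#'
#' @param S_true genes x k sources.
#' @param grid `c(rows, cols)`.
#' @param regions integer matrix of dim `grid` assigning each spot a region
#'   id `1..R` (a partition of the grid).
#' @param region_components list of length R; element r holds the component
#'   indices active in region r (may be empty).
#' @param depth target total counts per spot.
#' @param activity planted activity value.
#' @param background flat per-gene background intensity.
#' @param seed RNG seed.
#' @return spatial dataset list (as [read_visium()]) with attributes
#'   `true_activity` (spots x k) and `regions` (per-spot region id).
#' @export
make_spatial <- function(S_true, grid, regions, region_components,
                         depth = 2000, activity = 2, background = 0.1,
                         seed = 1L) {
  assert_that(all(dim(regions) == grid), "regions must have dim = grid")
  n_region <- max(regions)
  assert_that(all(seq_len(n_region) %in% regions),
              "empty region in the grid partition")
  assert_that(length(region_components) == n_region,
              "region_components must have one entry per region")
  k <- ncol(S_true)
  coords <- expand.grid(array_row = seq_len(grid[1]) - 1L,
                        array_col = seq_len(grid[2]) - 1L)
  n_spot <- nrow(coords)
  region_of <- regions[cbind(coords$array_row + 1L, coords$array_col + 1L)]
  m <- matrix(0, n_spot, k)
  for (r in seq_len(n_region)) {
    comps <- region_components[[r]]
    if (length(comps)) m[region_of == r, comps] <- activity
  }
  softplus <- function(x) log1p(exp(pmin(x, 30)))
  lin <- S_true %*% t(m)                       # genes x spots
  intensity <- softplus(lin) + background
  rate <- sweep(intensity, 2L, colSums(intensity) / depth, "/")
  counts <- with_seed(seed, matrix(rpois(length(rate), rate), nrow(rate)))
  barcodes <- sprintf("spot_%03d_%03d", coords$array_row, coords$array_col)
  dimnames(counts) <- list(rownames(S_true), barcodes)
  out <- list(counts = counts, barcodes = barcodes,
              gene_ids = rownames(S_true),
              positions = data.frame(barcode = barcodes,
                                     array_row = coords$array_row,
                                     array_col = coords$array_col))
  rownames(m) <- barcodes
  colnames(m) <- colnames(S_true)
  attr(out, "true_activity") <- m
  attr(out, "regions") <- setNames(region_of, barcodes)
  out
}

#' Generate gene sets with planted enrichment
#'
#' For each component, `n_enriched_per_component` sets draw most of their
#' members from the component's top positive-weight genes (capped at
#' `top_pool` and at the number of genes with positive weight) and the rest
#' uniformly; `n_null` sets are uniform draws. The pool is directional
#' because the enrichment stage scores a signed mean shift in component
#' weights: a set mixing the component's strong positive and strong
#' negative genes would not be enriched in that sense.
#'
#' @param S_true genes x k sources.
#' @param n_enriched_per_component,n_null set counts.
#' @param set_size genes per set (< n_genes/2).
#' @param seed RNG seed.
#' @param top_pool size of the high-weight pool enriched sets draw from.
#' @return named list of gene-id vectors; enriched sets are named
#'   `enriched_src<j>_<i>`, null sets `null_<i>`.
#' @export
make_gene_sets <- function(S_true, n_enriched_per_component = 1L, n_null = 50L,
                           set_size = 30L, seed = 1L, top_pool = 100L) {
  n_genes <- nrow(S_true)
  assert_that(set_size < n_genes / 2, "set_size must be < n_genes/2")
  genes <- rownames(S_true)
  with_seed(seed, {
    sets <- list()
    for (j in seq_len(ncol(S_true))) {
      ord <- order(-S_true[, j])
      pool <- genes[ord][seq_len(min(top_pool, sum(S_true[, j] > 0)))]
      for (i in seq_len(n_enriched_per_component)) {
        n_top <- min(round(0.8 * set_size), length(pool))
        sets[[sprintf("enriched_src%d_%d", j, i)]] <-
          c(sample(pool, n_top), sample(setdiff(genes, pool), set_size - n_top))
      }
    }
    for (i in seq_len(n_null)) {
      sets[[sprintf("null_%d", i)]] <- sample(genes, set_size)
    }
    sets
  })
}
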