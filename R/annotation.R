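#' Top genes of a component by absolute weight
#'
#' @param S genes x k weight matrix (or a `cica_result`).
#' @param tc_id component column name or index.
#' @param n number of genes to return (default 100, the conventional
#'   top-gene window for component interpretation).
#' @return character vector of gene ids, decreasing |weight|, ties broken
#'   lexicographically.
#' @export
top_genes <- function(S, tc_id, n = 100L) {
  if (inherits(S, "cica_result")) S <- S$S
  assert_that(n <= nrow(S), "n exceeds the number of genes")
  w <- S[, tc_id]
  ord <- order(-abs(w), rownames(S))
  rownames(S)[ord][seq_len(n)]
}

#' Competitive parametric gene-set enrichment Z-score
#'
#' PAGE-style statistic: the mean component weight inside the set is
#' contrasted with the mean over all genes and standardized by the global
#' weight SD times `sqrt(set size)`. Two-sided normal p-value; Bonferroni
#' correction multiplies by `collection_size`.
#'
#' @param S genes x k weight matrix (or a `cica_result`).
#' @param tc_id component column name or index.
#' @param gene_set character vector of member gene ids (ids outside the
#'   matrix are ignored; fewer than 3 usable members flags the result
#'   untestable).
#' @param collection_size number of sets in the collection, for Bonferroni.
#' @return one-row data.frame: `tc_id`, `n_members`, `z`, `p`,
#'   `p_bonferroni`, `untestable`.
#' @export
enrichment_z <- function(S, tc_id, gene_set, collection_size = 1L) {
  if (inherits(S, "cica_result")) S <- S$S
  w <- S[, tc_id]
  members <- intersect(gene_set, rownames(S))
  m <- length(members)
  tc_name <- if (is.character(tc_id)) tc_id else colnames(S)[tc_id]
  if (m < 3L) {
    return(data.frame(tc_id = tc_name, n_members = m, z = NA_real_,
                      p = NA_real_, p_bonferroni = NA_real_, untestable = TRUE,
                      stringsAsFactors = FALSE))
  }
  z <- (mean(w[members]) - mean(w)) * sqrt(m) / sd(w)
  p <- 2 * pnorm(-abs(z))
  p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  data.frame(tc_id = tc_name, n_members = m, z = z, p = p,
             p_bonferroni = min(1, p * collection_size), untestable = FALSE,
             stringsAsFactors = FALSE)
}

#' Enrichment of a full gene-set collection against every component
#'
#' @param S genes x k weight matrix (or a `cica_result`).
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @return data.frame with one row per (component, set).
#' @export
enrich_collection <- function(S, sets) {
  if (inherits(S, "cica_result")) S <- S$S
  n_sets <- length(sets)
  rows <- list()
  for (j in seq_len(ncol(S))) {
    for (nm in names(sets)) {
      r <- enrichment_z(S, j, sets[[nm]], collection_size = n_sets)
      r$set_name <- nm
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out[, c("tc_id", "set_name", "n_members", "z", "p", "p_bonferroni",
          "untestable")]
}

# window means of w for window length wg: positions 1..(L-wg+1)
window_means <- function(w, wg) {
  cs <- cumsum(c(0, w))
  (cs[(wg + 1L):length(cs)] - cs[1L:(length(cs) - wg)]) / wg
}

#' Detect copy-number-alteration footprints in component gene weights
#'
#' A component driven by the downstream dosage effect of a CNA carries a
#' contiguous run of same-sign weights in genomic gene order. Per
#' chromosome, genes are ordered by position and a sliding window mean of
#' the signed weights is scanned; the null re-draws the window means after
#' shuffling gene order within the chromosome (`null = "permute"`, the
#' default, which breaks contiguity while preserving the weight
#' distribution; `"circular"` rotates the weight vector instead). A window
#' is significant when its |mean| exceeds the `1 - alpha/n_windows` quantile
#' of the pooled null, and overlapping significant windows merge into one
#' region call.
#'
#' @param S genes x k weight matrix (or a `cica_result`).
#' @param tc_id component column name or index.
#' @param annotation gene annotation covering >= 80% of matrix genes.
#' @param window_genes sliding-window width in genes (default 30, >= 10).
#' @param n_perm null draws per chromosome (default 1000).
#' @param alpha family-wise significance level (default 0.01).
#' @param seed RNG seed for the null.
#' @param null `"permute"` (default) or `"circular"`.
#' @return list with `calls` (data.frame: chromosome, start_gene_index,
#'   end_gene_index, start, end, window_mean_weight, p_perm) and
#'   `is_cna_tc` flag.
#' @export
detect_cna_regions <- function(S, tc_id, annotation, window_genes = 30L,
                               n_perm = 1000L, alpha = 0.01, seed = 1L,
                               null = c("permute", "circular")) {
  if (inherits(S, "cica_result")) S <- S$S
  null <- match.arg(null)
  window_genes <- as.integer(window_genes)
  assert_that(window_genes >= 10L, "window_genes must be >= 10")
  shared <- intersect(rownames(S), annotation$gene_id)
  assert_that(length(shared) >= 0.8 * nrow(S),
              "annotation must cover >= 80% of matrix genes")
  ann <- annotation[match(shared, annotation$gene_id), ]
  ann <- ann[order(ann$chromosome, ann$start), ]
  w_all <- S[ann$gene_id, tc_id]
  chroms <- split(seq_len(nrow(ann)), ann$chromosome)
  usable <- vapply(chroms, function(ix) length(ix) >= window_genes, logical(1L))
  if (any(!usable)) {
    warning(sprintf("skipping chromosome(s) with < %d genes: %s", window_genes,
                    paste(names(chroms)[!usable], collapse = ", ")))
  }
  chroms <- chroms[usable]
  n_windows <- sum(vapply(chroms, function(ix) length(ix) - window_genes + 1L,
                          integer(1L)))
  calls <- list()
  with_seed(seed, {
    for (chrom in names(chroms)) {
      ix <- chroms[[chrom]]
      w <- w_all[ix]
      L <- length(w)
      obs <- window_means(w, window_genes)
      null_pool <- unlist(lapply(seq_len(n_perm), function(b) {
        wb <- if (null == "permute") {
          w[sample.int(L)]
        } else {
          s <- sample.int(L, 1L)
          w[c(seq.int(s, L), seq_len(s - 1L))]
        }
        window_means(wb, window_genes)
      }), use.names = FALSE)
      thr <- quantile(abs(null_pool), 1 - alpha / n_windows, names = FALSE)
      sig <- which(abs(obs) > thr)
      if (length(sig)) {
        # merge windows whose spans overlap
        grp <- cumsum(c(1L, diff(sig) >= window_genes))
        for (g in unique(grp)) {
          pos <- sig[grp == g]
          lo <- min(pos)
          hi <- max(pos) + window_genes - 1L
          peak <- pos[which.max(abs(obs[pos]))]
          p_perm <- (1 + sum(abs(null_pool) >= abs(obs[peak]))) /
            (length(null_pool) + 1)
          calls[[length(calls) + 1L]] <- data.frame(
            chromosome = chrom, start_gene_index = lo, end_gene_index = hi,
            start = ann$start[ix[lo]], end = ann$end[ix[hi]],
            window_mean_weight = obs[peak], p_perm = p_perm,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chromosome = character(0), start_gene_index = integer(0),
               end_gene_index = integer(0), start = integer(0),
               end = integer(0), window_mean_weight = numeric(0),
               p_perm = numeric(0))
  list(calls = calls, is_cna_tc = nrow(calls) > 0L)
}

#' Co-functionality clusters among a gene list
#'
#' Builds a graph over `gene_list` with edges where the supplied gene-gene
#' similarity exceeds `r_threshold`, and returns connected components with
#' at least `min_size` members. When a weight matrix and gene-set collection
#' are supplied, each cluster is scored for functional enrichment with the
#' same competitive Z statistic, using the cluster indicator as the score
#' vector.
#'
#' @param gene_list character vector of genes to cluster.
#' @param similarity symmetric gene x gene matrix in \[-1, 1\] with dimnames
#'   covering `gene_list`.
#' @param r_threshold edge threshold (default 0.7).
#' @param min_size minimum cluster size (default 5).
#' @param sets optional gene-set collection for cluster enrichment.
#' @param universe gene universe for the enrichment (defaults to the
#'   similarity matrix's genes).
#' @return list of clusters, each with sorted `members` and optionally an
#'   `enrichment` data.frame; ordered by decreasing size then first member.
#' @export
cofunctionality_clusters <- function(gene_list, similarity, r_threshold = 0.7,
                                     min_size = 5L, sets = NULL,
                                     universe = rownames(similarity)) {
  gene_list <- sort(unique(gene_list))
  assert_that(all(gene_list %in% rownames(similarity)),
              "similarity matrix must cover gene_list")
  sim <- similarity[gene_list, gene_list, drop = FALSE]
  assert_that(isTRUE(all.equal(sim, t(sim), tolerance = 1e-8)),
              "similarity matrix must be symmetric")
  adj <- sim > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- split(gene_list, comp$membership)
  clusters <- Filter(function(cl) length(cl) >= min_size, clusters)
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1L), 1L))
  clusters <- unname(clusters[ord])
  lapply(clusters, function(cl) {
    out <- list(members = cl)
    if (!is.null(sets)) {
      ind <- matrix(as.numeric(universe %in% cl), ncol = 1L,
                    dimnames = list(universe, "cluster"))
      out$enrichment <- enrich_collection(ind, sets)
    }
    out
  })
}

#' Components in which a gene is prominent
#'
#' @param S genes x k standardized weight matrix (or a `cica_result`).
#' @param gene_id gene to look up.
#' @param weight_threshold absolute standardized weight cut-off (default 3).
#' @return character vector of component ids.
#' @export
prominent_gene_tcs <- function(S, gene_id, weight_threshold = 3) {
  if (inherits(S, "cica_result")) S <- S$S
  assert_that(gene_id %in% rownames(S), sprintf("gene '%s' not in matrix", gene_id))
  colnames(S)[abs(S[gene_id, ]) > weight_threshold]
}
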