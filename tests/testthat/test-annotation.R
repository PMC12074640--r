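test_that("top genes rank by absolute weight with lexicographic ties", {
  S <- matrix(c(3, -5, 1), 3, 1, dimnames = list(c("a", "b", "c"), "TC1"))
  expect_equal(top_genes(S, "TC1", 2), c("b", "a"))
  expect_setequal(top_genes(S, "TC1", 3), c("a", "b", "c"))

  Stie <- matrix(c(2, 2, 1), 3, 1, dimnames = list(c("zz", "aa", "mm"), "TC1"))
  expect_equal(top_genes(Stie, "TC1", 2), c("aa", "zz"))

  set.seed(1)
  Sr <- matrix(rnorm(1000), 1000, 1,
               dimnames = list(sprintf("g%04d", 1:1000), "TC1"))
  oracle <- rownames(Sr)[order(-abs(Sr[, 1]), rownames(Sr))]
  expect_equal(top_genes(Sr, "TC1", 1000), oracle)
})

test_that("enrichment Z matches its definition, flips sign, and tracks a permutation oracle", {
  set.seed(5)
  S <- matrix(rnorm(2000), 2000, 1,
              dimnames = list(sprintf("g%04d", 1:2000), "TC1"))
  # set = all genes -> Z exactly 0
  expect_equal(enrichment_z(S, "TC1", rownames(S))$z, 0)

  gs <- rownames(S)[1:40]
  z1 <- enrichment_z(S, "TC1", gs)$z
  expect_equal(enrichment_z(-S, "TC1", gs)$z, -z1)

  # permutation oracle: Z from 10,000 random same-size sets
  obs <- mean(S[gs, 1])
  set.seed(6)
  null_means <- vapply(1:10000, function(b) mean(S[sample(2000, 40), 1]),
                       numeric(1))
  z_perm <- (obs - mean(null_means)) / sd(null_means)
  expect_lt(abs(z1 - z_perm), 0.15)

  # under 3 usable members -> untestable
  r <- enrichment_z(S, "TC1", c("g0001", "g0002", "not_a_gene"))
  expect_true(r$untestable)

  # planted enriched set exceeds the |Z| > 2 reporting threshold
  Sp <- make_sources(1000, 4, sparsity = 0.03, seed = 2)
  sets <- make_gene_sets(Sp, 1, 10, seed = 3)
  zz <- enrichment_z(Sp, 2, sets[["enriched_src2_1"]], collection_size = 14)
  expect_gt(abs(zz$z), 2)
})

test_that("CNA region detection finds planted blocks and respects degenerate inputs", {
  ann <- make_gene_annotation(2000, 4)
  S <- make_sources(2000, 4, cna_fraction = 0.25, annotation = ann, seed = 11)
  j <- attr(S, "cna_components")[1]
  res <- detect_cna_regions(S, j, ann, n_perm = 500, seed = 1)
  expect_true(res$is_cna_tc)
  # the merged call overlaps the planted block
  blk <- attr(S, "cna_blocks")[[j]]
  ord <- order(ann$chromosome, ann$start)
  blk_chrom <- ann$chromosome[blk[1]]
  on_chr <- which(ann$chromosome[ord] == blk_chrom)
  blk_pos <- match(blk, ord[on_chr])  # positions within the chromosome
  call <- res$calls[res$calls$chromosome == blk_chrom, ][1, ]
  expect_true(call$start_gene_index <= max(blk_pos) &&
                call$end_gene_index >= min(blk_pos))

  # sparse (non-CNA) component is not flagged
  j2 <- setdiff(seq_len(4), attr(S, "cna_components"))[1]
  expect_false(detect_cna_regions(S, j2, ann, n_perm = 500, seed = 1)$is_cna_tc)

  # window wider than every chromosome -> no calls, warning
  ann_small <- make_gene_annotation(60, 4)
  Ss <- make_sources(60, 2, sparsity = 0.2, seed = 1)
  rownames(Ss) <- ann_small$gene_id
  expect_warning(r0 <- detect_cna_regions(Ss, 1, ann_small, window_genes = 30,
                                          n_perm = 100, seed = 1),
                 "skipping")
  expect_false(r0$is_cna_tc)
  expect_equal(nrow(r0$calls), 0L)
})

test_that("co-functionality clusters equal graph components above the similarity cut", {
  genes <- sprintf("g%02d", 1:15)
  sim <- diag(1, 15)
  dimnames(sim) <- list(genes, genes)
  sim[1:6, 1:6] <- 0.9
  sim[7:12, 7:12] <- 0.9
  diag(sim) <- 1
  cl <- cofunctionality_clusters(genes, sim, r_threshold = 0.7, min_size = 5)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$members, genes[1:6])
  expect_equal(cl[[2]]$members, genes[7:12])

  expect_length(cofunctionality_clusters(genes, sim, r_threshold = 1.0), 0L)

  bad <- sim
  bad[1, 2] <- 0
  expect_error(cofunctionality_clusters(genes, bad), "symmetric")

  # invariance to gene-list ordering
  cl2 <- cofunctionality_clusters(rev(genes), sim, r_threshold = 0.7, min_size = 5)
  expect_identical(cl, cl2)

  # union-find oracle over random graphs
  uf_components <- function(adj) {
    n <- nrow(adj)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (adj[i, j]) parent[find(j)] <- find(i)
    }
    vapply(seq_len(n), find, integer(1))
  }
  for (s in 1:50) {
    set.seed(s)
    n <- 12
    g <- sprintf("x%02d", 1:n)
    m <- matrix(runif(n * n), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    dimnames(m) <- list(g, g)
    got <- cofunctionality_clusters(g, m, r_threshold = 0.8, min_size = 2)
    adj <- m > 0.8
    diag(adj) <- FALSE
    parent <- uf_components(adj)
    want <- unname(Filter(function(v) length(v) >= 2, split(g, parent)))
    want <- lapply(want, sort)
    want <- want[order(-lengths(want), vapply(want, `[`, character(1), 1))]
    expect_identical(lapply(got, `[[`, "members"), want)
  }
})

test_that("prominent-gene lookup applies the absolute weight threshold", {
  S <- matrix(0, 4, 3, dimnames = list(letters[1:4], paste0("TC", 1:3)))
  expect_length(prominent_gene_tcs(S, "a"), 0L)
  S["b", c(1, 3)] <- c(3.5, -3.5)
  expect_equal(prominent_gene_tcs(S, "b"), c("TC1", "TC3"))

  set.seed(2)
  Sr <- matrix(rnorm(300, sd = 2), 30, 10,
               dimnames = list(sprintf("g%02d", 1:30), paste0("TC", 1:10)))
  for (g in c("g01", "g15", "g30")) {
    expect_equal(prominent_gene_tcs(Sr, g),
                 colnames(Sr)[which(abs(Sr[g, ]) > 3)])
  }
  expect_error(prominent_gene_tcs(Sr, "nope"), "not in matrix")
})
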