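test_that("planted sources have the requested sparsity, CNA count, and decorrelation", {
  S <- make_sources(1000, 1, sparsity = 0.01, seed = 1)
  expect_equal(sum(S != 0), 10L)

  ann <- make_gene_annotation(1000, 4)
  S <- make_sources(1000, 4, cna_fraction = 0.5, annotation = ann, seed = 2)
  expect_length(attr(S, "cna_components"), 2L)
  expect_equal(unname(apply(S, 2, sd)), rep(1, 4), tolerance = 1e-12)

  # mutual decorrelation across 20 seeds
  worst <- vapply(1:20, function(s) {
    S <- make_sources(1000, 10, sparsity = 0.03, seed = s)
    r <- cor(S)
    max(abs(r[upper.tri(r)]))
  }, numeric(1))
  expect_all_true(worst < 0.2)

  expect_error(make_sources(100, 20, seed = 1), "under-determined")
})

test_that("CNA components carry one contiguous same-sign genomic run", {
  ann <- make_gene_annotation(2000, 4)
  S <- make_sources(2000, 5, cna_fraction = 0.4, annotation = ann, seed = 9)
  for (j in attr(S, "cna_components")) {
    blk <- attr(S, "cna_blocks")[[j]]
    expect_true(length(blk) >= 30 && length(blk) <= 80)
    expect_true(length(unique(ann$chromosome[blk])) == 1L)
    expect_true(all(sign(S[blk, j]) == sign(S[blk[1], j])))
    # block weights dominate the off-block noise
    expect_gt(min(abs(S[blk, j])), max(abs(S[-blk, j])))
  }
})

test_that("planted activities are standardized and deterministic", {
  M <- make_mixing(300, 10, seed = 5)
  expect_equal(dim(M), c(300L, 10L))
  expect_all_true(abs(colMeans(M)) < 0.05)
  expect_all_true(abs(apply(M, 2, sd) - 1) < 0.1)
  expect_identical(M, make_mixing(300, 10, seed = 5))
  M1 <- make_mixing(3, 1, seed = 1)
  expect_equal(sd(M1), 1, tolerance = 0.1)
  expect_error(make_mixing(10, 4, seed = 1), "3k")
})

test_that("expression mixing follows X = S M' + noise", {
  S <- make_sources(400, 4, sparsity = 0.05, seed = 1)
  M <- make_mixing(30, 4, seed = 2)
  X0 <- make_expression(S, M, noise_sd = 0, seed = 3)
  expect_equal(unname(unclass(X0)), unname(S %*% t(M)))
  expect_lte(qr(X0)$rank, 4L)

  S2 <- make_sources(2000, 10, sparsity = 0.025, seed = 4)
  M2 <- make_mixing(300, 10, seed = 5)
  X <- make_expression(S2, M2, noise_sd = 0.2, seed = 6)
  resid <- X - S2 %*% t(M2)
  expect_equal(sd(resid), 0.2, tolerance = 0.01)
  expect_error(make_expression(S, M, noise_sd = -1), "non-negative")
})

test_that("survival generator is PH-consistent: Cox recovers planted effects", {
  M <- make_mixing(60, 2, seed = 1)
  cl <- make_clinical(M, survival_betas = numeric(0),
                      covariate_spec = list(beta_age = 0, beta_stage = 0),
                      censor_rate = 0, seed = 2)
  expect_equal(mean(cl$os_event), 1.0)
  expect_all_true(cl$os_time > 0)
  expect_identical(cl, make_clinical(M, survival_betas = numeric(0),
                                     covariate_spec = list(beta_age = 0, beta_stage = 0),
                                     censor_rate = 0, seed = 2))

  # oracle Cox fit on the true activity, beta = log(3), n = 2000
  M <- make_mixing(2000, 3, seed = 3)
  cl <- make_clinical(M, survival_betas = c(src1 = log(3)),
                      covariate_spec = list(beta_age = 0, beta_stage = 0),
                      seed = 4)
  fit <- survival::coxph(survival::Surv(cl$os_time, cl$os_event) ~ M[, 1])
  expect_gt(exp(coef(fit)), 2.6)
  expect_lt(exp(coef(fit)), 3.5)

  # planted beta inside its 95% CI in >= 90% of replicates
  hits <- vapply(1:100, function(s) {
    Mi <- make_mixing(2000, 1, seed = 200 + s)
    cli <- make_clinical(Mi, survival_betas = c(src1 = log(2)),
                         covariate_spec = list(beta_age = 0, beta_stage = 0),
                         seed = 300 + s)
    f <- survival::coxph(survival::Surv(cli$os_time, cli$os_event) ~ Mi[, 1])
    ci <- confint(f)
    ci[1] <= log(2) && log(2) <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(make_clinical(M, baseline_rate = 0), "baseline_rate")
})

test_that("spatial generator localizes components and scales with depth", {
  S <- make_sources(500, 3, sparsity = 0.05, seed = 1)
  regions <- matrix(1L, 10, 10)
  expect_error(make_spatial(S, c(10, 10), regions, list(1L, 2L)),
               "one entry per region")
  sd1 <- make_spatial(S, c(10, 10), regions, list(1L), depth = 1000, seed = 2)
  expect_equal(ncol(sd1$counts), 100L)
  expect_false(anyDuplicated(sd1$positions[, c("array_row", "array_col")]) > 0)

  # planted component's top genes show elevated counts over background genes
  top <- order(-abs(S[, 1]))[1:20]
  up <- top[S[top, 1] > 0]
  bg <- which(S[, 1] == 0)
  expect_gt(mean(sd1$counts[up, ]), mean(sd1$counts[bg, ]))

  sd2 <- make_spatial(S, c(10, 10), regions, list(1L), depth = 2000, seed = 2)
  expect_equal(mean(colSums(sd2$counts)) / mean(colSums(sd1$counts)), 2,
               tolerance = 0.05)

  bad <- regions
  bad[1, 1] <- 3L  # region 2 has no spots
  expect_error(make_spatial(S, c(10, 10), bad, list(1L, 2L, 3L)), "empty region")
})

test_that("gene-set generator plants enrichment where promised", {
  S <- make_sources(1000, 10, sparsity = 0.03, seed = 7)
  sets <- make_gene_sets(S, n_enriched_per_component = 1, n_null = 50,
                         set_size = 30, seed = 8)
  expect_length(sets, 60L)
  for (j in c(1, 5, 10)) {
    mem <- sets[[sprintf("enriched_src%d_1", j)]]
    expect_gt(mean(abs(S[mem, j])), mean(abs(S[, j])))
  }
  expect_identical(sets, make_gene_sets(S, 1, 50, 30, seed = 8))
})
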