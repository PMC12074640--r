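test_that("log-rank test matches hand computation, survdiff, and a permutation null", {
  # identical groups -> chi2 0, p 1
  r <- logrank_test(c(3, 5, 7), c(1, 0, 1), c(3, 5, 7), c(1, 0, 1))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  # fully separated groups, no censoring: hand-computed O-E and V oracle
  ta <- c(1, 2, 3); tb <- c(4, 5, 6)
  oracle <- local({
    time <- c(ta, tb); event <- rep(1, 6); ina <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    oe <- 0; v <- 0
    for (t in sort(unique(time))) {
      at <- time >= t
      nj <- sum(at); n1 <- sum(at & ina); dj <- sum(time == t); d1 <- sum(time == t & ina)
      oe <- oe + d1 - dj * n1 / nj
      if (nj > 1) v <- v + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
    }
    list(chi2 = oe^2 / v, p = pchisq(oe^2 / v, 1, lower.tail = FALSE))
  })
  r <- logrank_test(ta, rep(1, 3), tb, rep(1, 3))
  expect_equal(r$chi2, oracle$chi2)
  expect_equal(r$p, oracle$p)

  # independent reference implementation on random censored fixtures
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    time <- rexp(n, 1 / 50); event <- rbinom(n, 1, 0.7); grp <- rbinom(n, 1, 0.5) == 1
    if (sum(event) == 0 || !any(grp) || all(grp)) next
    mine <- logrank_test(time[grp], event[grp], time[!grp], event[!grp])
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(mine$chi2, ref$chisq, tolerance = 1e-10)
  }

  # label-permutation p agrees within 2 Monte-Carlo SE on a fixed fixture
  set.seed(77)
  n <- 40
  time <- rexp(n, 1 / 50); event <- rbinom(n, 1, 0.8)
  grp <- c(rep(TRUE, 20), rep(FALSE, 20))
  time[grp] <- time[grp] * 0.6
  obs <- logrank_test(time[grp], event[grp], time[!grp], event[!grp])
  B <- 5000
  exceed <- vapply(seq_len(B), function(b) {
    g <- sample(grp)
    cicasurv:::logrank_stat(time, event, g)$chi2 >= obs$chi2
  }, logical(1))
  p_perm <- mean(exceed)
  mc_se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(obs$p - p_perm), 2 * max(mc_se, 1e-3))

  expect_error(logrank_test(1:3, c(0, 0, 0), 4:6, c(0, 0, 0)), "no events")
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("best split finds a planted survival threshold and refuses inadmissible nodes", {
  set.seed(1)
  n <- 200
  x <- runif(n, 0, 10)
  s <- sim_surv(n, log(4) * (x > 5), seed = 2)
  cl <- quick_clinical(s$time, s$event)
  noise <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("n1", "n2")))
  sp <- best_split(cl, cbind(tc = x, noise))
  expect_equal(sp$classifier_name, "tc")
  expect_lt(abs(sp$cutoff - 5), 0.5)
  expect_equal(sp$n_left + sp$n_right, n)
  expect_gte(min(sp$n_left, sp$n_right), 17)

  # 20 patients cannot satisfy min_child 17 on both sides
  cl20 <- quick_clinical(s$time[1:20], rep(1, 20))
  expect_null(best_split(cl20, cbind(tc = x[1:20])))

  # constant classifier has no plausible cutoff
  expect_null(best_split(cl, cbind(const = rep(1, n))))
})

test_that("stopping rules produce single-leaf trees at the documented bounds", {
  s <- sim_surv(49, rep(0, 49), seed = 3)
  tree49 <- grow_tree(quick_clinical(s$time, s$event),
                      cbind(x = rnorm(49)))
  expect_length(tree49$leaves, 1L)

  # 100 patients but only 24 events
  s <- sim_surv(100, rep(0, 100), seed = 4)
  ev <- s$event
  ev[] <- 0L
  ev[1:24] <- 1L
  tree24 <- grow_tree(quick_clinical(s$time, ev), cbind(x = rnorm(100)))
  expect_length(tree24$leaves, 1L)

  cl1 <- quick_clinical(1, 1)
  expect_error(grow_tree(cl1[0, ], matrix(numeric(0), 0, 1,
                                          dimnames = list(NULL, "x"))),
               "empty cohort")
})

test_that("the tree recovers a planted two-level structure and partitions patients", {
  gen <- function(seed) {
    set.seed(seed)
    n <- 400
    tc <- runif(n, 0, 10)
    age <- rnorm(n, 60, 10)
    lp <- log(4) * (tc > 5) + log(2.5) * (age > 60)
    s <- sim_surv(n, lp, seed = seed + 1)
    list(cl = quick_clinical(s$time, s$event, age = age),
         cf = cbind(tc = tc, age = age, noise = rnorm(n)))
  }
  hits <- vapply(1:20, function(s) {
    d <- gen(s)
    tr <- grow_tree(d$cl, d$cf)
    root <- tr$nodes[[tr$root]]
    if (root$is_leaf || root$split$classifier_name != "tc") return(FALSE)
    kids <- tr$nodes[root$children]
    all(vapply(kids, function(nd) {
      nd$is_leaf || nd$split$classifier_name == "age"
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  d <- gen(1)
  tr <- grow_tree(d$cl, d$cf)
  # leaves partition the cohort exactly
  ids <- unlist(lapply(tr$nodes[tr$leaves], `[[`, "patient_ids"))
  expect_setequal(ids, d$cl$sample_id)
  expect_equal(length(ids), nrow(d$cl))
  leaf <- assign_leaves(tr, d$cl, d$cf)
  for (l in tr$leaves) {
    expect_setequal(d$cl$sample_id[leaf == tr$nodes[[l]]$leaf_label],
                    tr$nodes[[l]]$patient_ids)
  }
  # at-risk tables start from the full leaf size
  expect_equal(sum(vapply(tr$nodes[tr$leaves],
                          function(nd) nd$km$at_risk$n_risk[1], numeric(1))),
               nrow(d$cl))

  # invariance to patient row order and classifier column order
  perm <- sample(nrow(d$cl))
  tr2 <- grow_tree(d$cl[perm, ], d$cf[perm, ])
  tr3 <- grow_tree(d$cl, d$cf[, c(3, 1, 2)])
  for (alt in list(tr2, tr3)) {
    expect_equal(length(alt$leaves), length(tr$leaves))
    expect_equal(alt$nodes[[alt$root]]$split$cutoff,
                 tr$nodes[[tr$root]]$split$cutoff)
  }
})

test_that("subsample robustness separates dominant classifiers from noise", {
  set.seed(9)
  n <- 200
  x <- runif(n, 0, 10)
  s <- sim_surv(n, log(5) * (x > 5), seed = 10)
  cl <- quick_clinical(s$time, s$event)
  cf <- cbind(tc = x, matrix(rnorm(n * 3), n, 3,
                             dimnames = list(NULL, paste0("n", 1:3))))
  rb <- tree_robustness(cl, cf, n_iter = 200, seed = 1)
  expect_gte(rb$median, 0.8)
  expect_identical(rb$correlations,
                   tree_robustness(cl, cf, n_iter = 200, seed = 1)$correlations)
  # the dominant classifier tops nearly every subsample ranking
  expect_gte(mean(rb$top_classifier == "tc", na.rm = TRUE), 0.9)

  # statistic stays a valid correlation summary on pure-noise classifiers
  # (subsample overlap keeps rank correlations positive even under noise,
  # so no near-zero expectation applies; see the methods vignette)
  cfn <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("n", 1:4)))
  rbn <- tree_robustness(cl, cfn, n_iter = 200, seed = 2)
  expect_true(rbn$median >= -1 && rbn$median <= 1)
  expect_gte(rbn$iqr, 0)

  # iterations without an admissible split are recorded as missing
  small <- quick_clinical(s$time[1:22], s$event[1:22])
  expect_warning(
    rbs <- tree_robustness(small, cbind(tc = x[1:22]), n_iter = 50, seed = 3),
    "no iteration admitted")
  expect_equal(rbs$n_missing, 50L)
})

test_that("concordance is 1 for perfect leaf separation and ~0.5 for random risk", {
  # two leaves with disjoint survival ranges, no censoring
  n <- 120
  x <- c(rep(0, 60), rep(1, 60))
  time <- c(runif(60, 1, 10), runif(60, 20, 30))
  cl <- quick_clinical(time, rep(1, n))
  tr <- grow_tree(cl, cbind(x = x), min_node = 50, min_events = 25)
  expect_length(tr$leaves, 2L)
  cc <- tree_concordance(tr, cl, cbind(x = x))
  # perfect leaf ordering: every between-leaf comparable pair is concordant
  # (within-leaf pairs share a risk score and count half, capping C below 1)
  expect_equal(cc$n_discordant, 0)
  expect_equal(cc$c_index, (cc$n_concordant + 0.5 * cc$n_tied) / cc$n_pairs)
  expect_gt(cc$c_index, 0.7)

  # random risk scores give C ~ 0.5
  set.seed(3)
  s <- sim_surv(1000, rep(0, 1000), seed = 4)
  hc <- harrell_c(rnorm(1000), s$time, s$event)
  expect_lt(abs(hc$c_index - 0.5), 0.05)

  # brute-force pairwise oracle on a 30-patient fixture
  set.seed(5)
  time <- rexp(30, 1 / 20); event <- rbinom(30, 1, 0.7); risk <- sample(1:5, 30, TRUE)
  conc <- 0; ties <- 0; np <- 0
  for (i in 1:29) for (j in (i + 1):30) {
    ti <- time[i]; tj <- time[j]
    first <- if (ti < tj && event[i]) i else if (tj < ti && event[j]) j else
      if (ti == tj && event[i] != event[j]) c(i, j)[c(event[i], event[j]) == 1] else 0
    if (first == 0) next
    np <- np + 1
    other <- if (first == i) j else i
    if (risk[first] > risk[other]) conc <- conc + 1
    if (risk[first] == risk[other]) ties <- ties + 1
  }
  mine <- harrell_c(risk, time, event)
  expect_equal(mine$c_index, (conc + ties / 2) / np)
  expect_equal(mine$n_pairs, np)
  # cross-check against the survival package on a tie-free fixture
  time2 <- sort(rexp(30, 1 / 20)) + seq(0, 0.29, 0.01)
  ref <- survival::concordance(survival::Surv(time2, event) ~ risk,
                               reverse = TRUE)
  mine2 <- harrell_c(risk, time2, event)
  expect_equal(mine2$c_index, unname(ref$concordance), tolerance = 1e-10)

  single <- grow_tree(quick_clinical(s$time[1:40], s$event[1:40]),
                      cbind(x = rnorm(40)))
  expect_error(tree_concordance(single, cl, cbind(x = x)), "single-leaf")
})
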