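#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: over the pooled distinct event times,
#' `chi2 = (sum(O - E))^2 / sum(V)` with the hypergeometric variance, and p
#' from the chi-square distribution with 1 df.
#'
#' @param time_a,event_a times and 0/1 event indicators of group A.
#' @param time_b,event_b likewise for group B.
#' @return list `chi2`, `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  assert_that(length(time_a) > 0L && length(time_b) > 0L,
              "both groups must be non-empty")
  assert_that(sum(event_a) + sum(event_b) > 0L, "no events in either group")
  st <- logrank_stat(c(time_a, time_b), c(event_a, event_b),
                     c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b))))
  list(chi2 = st$chi2, p = st$p)
}

# core log-rank computation for one group indicator; O(n log n)
logrank_stat <- function(time, event, in_a) {
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  a_s <- as.numeric(in_a[ord])
  n <- length(t_s)
  dt <- !duplicated(t_s)
  grp <- cumsum(dt)
  nj <- (n:1)[dt]                                  # at risk, all
  n1 <- rev(cumsum(rev(a_s)))[dt]                  # at risk, group A
  dj <- rowsum(e_s, grp)[, 1L]
  d1 <- rowsum(e_s * a_s, grp)[, 1L]
  has <- dj > 0
  oe <- sum(d1[has] - dj[has] * n1[has] / nj[has])
  v <- sum(dj[has] * (n1[has] / nj[has]) * (1 - n1[has] / nj[has]) *
             (nj[has] - dj[has]) / pmax(nj[has] - 1, 1))
  if (v <= 0) return(list(chi2 = 0, p = 1, oe = oe, v = v))
  chi2 <- oe^2 / v
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), oe = oe, v = v)
}

# All-cutoff log-rank scan for one numeric classifier. Candidate cutoffs are
# midpoints between consecutive distinct sorted values; candidates leaving a
# child below min_child are discarded. Returns the best candidate (smallest
# p, ties by larger chi2 then smaller cutoff) or NULL.
scan_classifier <- function(x, time, event, min_child) {
  ok <- !is.na(x)
  x <- x[ok]
  time <- time[ok]
  event <- event[ok]
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  cuts <- (ux[-length(ux)] + ux[-1L]) / 2
  n_left <- vapply(cuts, function(ct) sum(x <= ct), integer(1L))
  keep <- n_left >= min_child & (length(x) - n_left) >= min_child
  if (!any(keep)) return(NULL)
  cuts <- cuts[keep]
  n_left <- n_left[keep]
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  n <- length(t_s)
  dt <- !duplicated(t_s)
  grp <- cumsum(dt)
  nj <- (n:1)[dt]
  dj <- rowsum(e_s, grp)[, 1L]
  A_s <- (outer(x, cuts, "<="))[ord, , drop = FALSE] * 1
  rc <- apply(A_s[n:1, , drop = FALSE], 2L, cumsum)[n:1, , drop = FALSE]
  n1 <- rc[dt, , drop = FALSE]                       # T x C at-risk in A
  d1 <- rowsum(e_s * A_s, grp)                       # T x C events in A
  has <- dj > 0
  frac <- n1[has, , drop = FALSE] / nj[has]
  oe <- colSums(d1[has, , drop = FALSE] - dj[has] * frac)
  v <- colSums(dj[has] * frac * (1 - frac) * (nj[has] - dj[has]) /
                 pmax(nj[has] - 1, 1))
  chi2 <- ifelse(v > 0, oe^2 / v, 0)
  p <- ifelse(v > 0, pchisq(chi2, 1, lower.tail = FALSE), 1)
  best <- order(p, -chi2, cuts)[1L]
  list(cutoff = cuts[best], chi2 = chi2[best], p = p[best],
       n_left = n_left[best], n_right = length(x) - n_left[best])
}

#' Best log-rank split of a patient set
#'
#' Scans every classifier at every plausible cutoff (midpoints between
#' consecutive distinct values) and returns the candidate with the smallest
#' log-rank p-value; ties break by larger chi2, then classifier name, then
#' smaller cutoff. Candidates leaving a child with fewer than `min_child`
#' patients are discarded.
#'
#' @param clinical clinical table for the node's patients.
#' @param classifiers numeric matrix/data.frame (patients x classifiers)
#'   aligned with `clinical` rows; ordinal covariates pre-coded numeric.
#' @param min_child minimum child size (default 17).
#' @return list `classifier_name`, `cutoff`, `chi2`, `p`, `n_left`,
#'   `n_right`, or `NULL` when no candidate is admissible.
#' @export
best_split <- function(clinical, classifiers, min_child = 17L) {
  classifiers <- as.matrix(classifiers)
  assert_that(nrow(classifiers) == nrow(clinical),
              "classifiers not aligned with clinical rows")
  best <- NULL
  for (nm in sort(colnames(classifiers))) {
    cand <- scan_classifier(classifiers[, nm], clinical$os_time,
                            clinical$os_event, min_child)
    if (is.null(cand)) next
    cand$classifier_name <- nm
    if (is.null(best) ||
        cand$p < best$p ||
        (cand$p == best$p && cand$chi2 > best$chi2) ||
        (cand$p == best$p && cand$chi2 == best$chi2 && cand$cutoff < best$cutoff)) {
      best <- cand
    }
  }
  best
}

km_summary <- function(clinical) {
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ 1,
                           data = clinical)
  med <- unname(summary(fit)$table["median"])
  list(n = nrow(clinical), events = sum(clinical$os_event), median_os = med,
       at_risk = data.frame(time = fit$time, n_risk = fit$n.risk,
                            n_event = fit$n.event, surv = fit$surv))
}

#' Grow a log-rank recursive-partitioning survival tree
#'
#' Depth-first binary splitting on the most significant classifier at its
#' optimal cutoff ([best_split()]). A node becomes a leaf when its patient
#' count is below `min_node` (50), its event count is below `min_events`
#' (25), or no split leaves both children with at least `min_child` (17)
#' patients. Leaves are labelled in left-to-right (low, high) order.
#'
#' @param clinical clinical table (only `surv_usable` rows are used).
#' @param classifiers numeric matrix/data.frame aligned with `clinical`
#'   rows (component activities and clinicopathological variables).
#' @param min_node,min_events,min_child stopping thresholds.
#' @return object of class `survival_tree` with `nodes` (list), `leaves`
#'   (leaf node ids in left-to-right order), and the classifier matrix
#'   columns used.
#' @export
grow_tree <- function(clinical, classifiers, min_node = 50L, min_events = 25L,
                      min_child = 17L) {
  assert_that(nrow(clinical) > 0L, "empty cohort")
  classifiers <- as.matrix(classifiers)
  assert_that(nrow(classifiers) == nrow(clinical),
              "classifiers not aligned with clinical rows")
  keep <- clinical$surv_usable
  clinical <- clinical[keep, , drop = FALSE]
  classifiers <- classifiers[keep, , drop = FALSE]
  nodes <- list()
  new_node <- function(idx, depth) {
    id <- length(nodes) + 1L
    node <- list(id = id, depth = depth,
                 patient_ids = clinical$sample_id[idx],
                 km = km_summary(clinical[idx, , drop = FALSE]),
                 split = NULL, children = NULL, is_leaf = TRUE)
    nodes[[id]] <<- node
    cl <- clinical[idx, , drop = FALSE]
    if (nrow(cl) < min_node || sum(cl$os_event) < min_events) return(id)
    sp <- best_split(cl, classifiers[idx, , drop = FALSE], min_child)
    if (is.null(sp)) return(id)
    x <- classifiers[idx, sp$classifier_name]
    lo <- new_node(idx[!is.na(x) & x <= sp$cutoff], depth + 1L)
    hi <- new_node(idx[is.na(x) | x > sp$cutoff], depth + 1L)
    nodes[[id]]$split <<- sp
    nodes[[id]]$children <<- c(low = lo, high = hi)
    nodes[[id]]$is_leaf <<- FALSE
    id
  }
  root <- new_node(seq_len(nrow(clinical)), 0L)
  leaf_ids <- integer(0)
  walk <- function(id) {
    nd <- nodes[[id]]
    if (nd$is_leaf) {
      leaf_ids <<- c(leaf_ids, id)
    } else {
      walk(nd$children[["low"]])
      walk(nd$children[["high"]])
    }
  }
  walk(root)
  for (i in seq_along(leaf_ids)) nodes[[leaf_ids[i]]]$leaf_label <- i
  structure(list(nodes = nodes, root = root, leaves = leaf_ids,
                 classifier_names = colnames(classifiers)),
            class = "survival_tree")
}

#' @export
print.survival_tree <- function(x, ...) {
  cat(sprintf("survival tree: %d nodes, %d leaves\n",
              length(x$nodes), length(x$leaves)))
  rec <- function(id, indent) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$is_leaf) {
      cat(sprintf("%sleaf %d: n=%d events=%d median OS=%s\n", pad,
                  nd$leaf_label, nd$km$n, nd$km$events,
                  ifelse(is.na(nd$km$median_os), "NR",
                         sprintf("%.1f", nd$km$median_os))))
    } else {
      cat(sprintf("%s%s <= %.3g (p=%.3g, n=%d)\n", pad,
                  nd$split$classifier_name, nd$split$cutoff, nd$split$p,
                  nd$km$n))
      rec(nd$children[["low"]], indent + 1L)
      rec(nd$children[["high"]], indent + 1L)
    }
  }
  rec(x$root, 0L)
  invisible(x)
}

#' Assign patients to tree leaves
#'
#' @param tree a `survival_tree`.
#' @param clinical clinical table.
#' @param classifiers classifier matrix aligned with `clinical` rows.
#' @return integer vector of leaf labels per patient.
#' @export
assign_leaves <- function(tree, clinical, classifiers) {
  classifiers <- as.matrix(classifiers)
  vapply(seq_len(nrow(clinical)), function(i) {
    id <- tree$root
    repeat {
      nd <- tree$nodes[[id]]
      if (nd$is_leaf) return(nd$leaf_label)
      x <- classifiers[i, nd$split$classifier_name]
      id <- if (!is.na(x) && x <= nd$split$cutoff) nd$children[["low"]] else
        nd$children[["high"]]
    }
  }, integer(1L))
}

#' Subsample robustness of the root classifier ranking
#'
#' Repeatedly draws `subsample_fraction` of the patients without
#' replacement, recomputes each classifier's best root-split log-rank
#' p-value, and Spearman-correlates the significance-based classifier ranks
#' with those of the full cohort. Iterations where no classifier admits a
#' split are recorded as missing.
#'
#' @param clinical clinical table.
#' @param classifiers classifier matrix aligned with `clinical` rows.
#' @param n_iter number of subsample iterations (20000 in the full-scale
#'   analysis; >= 100 for stable quantiles).
#' @param subsample_fraction fraction drawn per iteration (default 0.8).
#' @param seed RNG seed.
#' @param min_child admissibility threshold for splits.
#' @return list `median`, `iqr`, `correlations`, `n_missing`,
#'   `primary_p` (full-cohort per-classifier p-values).
#' @export
tree_robustness <- function(clinical, classifiers, n_iter = 1000L,
                            subsample_fraction = 0.8, seed = 1L,
                            min_child = 17L) {
  classifiers <- as.matrix(classifiers)
  keep <- clinical$surv_usable
  clinical <- clinical[keep, , drop = FALSE]
  classifiers <- classifiers[keep, , drop = FALSE]
  per_classifier_p <- function(cl, cf) {
    vapply(colnames(cf), function(nm) {
      cand <- scan_classifier(cf[, nm], cl$os_time, cl$os_event, min_child)
      if (is.null(cand)) NA_real_ else cand$p
    }, numeric(1L))
  }
  primary <- per_classifier_p(clinical, classifiers)
  n <- nrow(clinical)
  m <- max(2L, round(subsample_fraction * n))
  res <- with_seed(seed, lapply(seq_len(n_iter), function(b) {
    idx <- sample.int(n, m)
    pb <- per_classifier_p(clinical[idx, , drop = FALSE],
                           classifiers[idx, , drop = FALSE])
    if (all(is.na(pb)) || all(is.na(primary))) {
      return(list(rho = NA_real_, top = NA_character_))
    }
    list(rho = suppressWarnings(cor(primary, pb, method = "spearman",
                                    use = "pairwise.complete.obs")),
         top = colnames(classifiers)[which.min(pb)])
  }))
  rho <- vapply(res, `[[`, numeric(1L), "rho")
  if (all(is.na(rho))) {
    warning("no iteration admitted a split; robustness undefined")
    return(list(median = NA_real_, iqr = NA_real_, correlations = rho,
                n_missing = length(rho),
                top_classifier = rep(NA_character_, length(rho)),
                primary_p = primary))
  }
  list(median = median(rho, na.rm = TRUE),
       iqr = unname(diff(quantile(rho, c(0.25, 0.75), na.rm = TRUE))),
       correlations = rho, n_missing = sum(is.na(rho)),
       top_classifier = vapply(res, `[[`, character(1L), "top"),
       primary_p = primary)
}

#' Harrell's concordance of the tree's leaf risk ordering
#'
#' Leaves are ordered by Kaplan-Meier median overall survival (never-reached
#' medians rank last, ties broken by the leaf survival-curve mean); each
#' patient's risk score is the negative of its leaf's rank in that ordering.
#' C is the fraction of comparable patient pairs (the earlier time is an
#' event) where the higher-risk patient fails first, with risk ties counted
#' half; the standard error is the Noether binomial-type estimate over
#' comparable pairs.
#'
#' @param tree a `survival_tree` with >= 2 leaves.
#' @param clinical clinical table.
#' @param classifiers classifier matrix aligned with `clinical` rows.
#' @return list `c_index`, `se`, `n_pairs`, `risk` (per patient).
#' @export
tree_concordance <- function(tree, clinical, classifiers) {
  assert_that(length(tree$leaves) >= 2L,
              "concordance undefined for a single-leaf tree")
  keep <- clinical$surv_usable
  clinical <- clinical[keep, , drop = FALSE]
  classifiers <- as.matrix(classifiers)[keep, , drop = FALSE]
  leaf <- assign_leaves(tree, clinical, classifiers)
  med <- vapply(tree$leaves, function(id) tree$nodes[[id]]$km$median_os,
                numeric(1L))
  mean_surv <- vapply(tree$leaves, function(id) {
    ar <- tree$nodes[[id]]$km$at_risk
    sum(diff(c(0, ar$time)) * c(1, head(ar$surv, -1L)))
  }, numeric(1L))
  ord <- order(ifelse(is.na(med), Inf, med), mean_surv)
  risk_of_label <- integer(length(tree$leaves))
  risk_of_label[ord] <- length(tree$leaves):1  # shortest median = highest risk
  risk <- risk_of_label[leaf]
  hc <- harrell_c(risk, clinical$os_time, clinical$os_event)
  c(hc, list(risk = risk))
}

#' Harrell's C by exhaustive pair counting
#'
#' @param risk numeric risk scores (higher = expected earlier failure).
#' @param time,event survival outcome.
#' @return list `c_index`, `se` (Noether binomial-type), `n_pairs`.
#' @export
harrell_c <- function(risk, time, event) {
  n <- length(risk)
  conc <- 0
  ties <- 0
  n_pairs <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    earlier_i <- (time[i] < time[j] & event[i] == 1L) |
      (time[i] == time[j] & event[i] == 1L & event[j] == 0L)
    earlier_j <- (time[j] < time[i] & event[j] == 1L) |
      (time[i] == time[j] & event[j] == 1L & event[i] == 0L)
    comp <- earlier_i | earlier_j
    if (!any(comp)) next
    hi_risk_first <- ifelse(earlier_i[comp], risk[i] > risk[j][comp],
                            risk[j][comp] > risk[i])
    tied <- risk[i] == risk[j][comp]
    n_pairs <- n_pairs + sum(comp)
    conc <- conc + sum(hi_risk_first & !tied)
    ties <- ties + sum(tied)
  }
  assert_that(n_pairs > 0, "no comparable pairs")
  cidx <- (conc + 0.5 * ties) / n_pairs
  list(c_index = cidx, se = sqrt(cidx * (1 - cidx) / n_pairs),
       n_pairs = n_pairs, n_concordant = conc, n_tied = ties,
       n_discordant = n_pairs - conc - ties)
}
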