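prep_covariates <- function(clinical, covariates) {
  if (length(covariates) == 0L) {
    return(list(frame = NULL, complete = rep(TRUE, nrow(clinical))))
  }
  assert_that(all(covariates %in% names(clinical)),
              paste("unknown covariate(s):",
                    paste(setdiff(covariates, names(clinical)), collapse = ", ")))
  fr <- clinical[, covariates, drop = FALSE]
  if ("debulking" %in% covariates) {
    fr$debulking <- factor(fr$debulking, levels = c("complete", "incomplete"))
  }
  list(frame = fr, complete = complete.cases(fr))
}

#' Cox proportional-hazards fit for one component activity
#'
#' Standardizes the activity to unit SD over the usable samples, then fits
#' `coxph` (Efron ties) of overall survival on the activity plus any
#' clinicopathological covariates. Samples missing outcome or a required
#' covariate are dropped and counted. A non-converged fit is returned
#' flagged with p = 1 rather than erroring, since it still occupies a slot
#' in genome-wide scans.
#'
#' @param activity numeric per-sample activity, aligned with `clinical`
#'   rows (or named by sample id).
#' @param clinical clinical table (see [as_clinical()]).
#' @param covariates character vector of covariate column names
#'   (e.g. `c("age", "stage", "debulking", "grade")`).
#' @param tc_id label for the result row.
#' @return one-row data.frame: `tc_id`, `coefficient` (log hazard per
#'   activity SD), `hr`, `se`, `p` (Wald two-sided), `model`, `n_used`,
#'   `n_events`, `converged`.
#' @export
cox_fit <- function(activity, clinical, covariates = character(0),
                    tc_id = "activity") {
  if (!is.null(names(activity))) {
    activity <- activity[clinical$sample_id]
  }
  assert_that(length(activity) == nrow(clinical),
              "activity and clinical table are not aligned")
  cov <- prep_covariates(clinical, covariates)
  usable <- clinical$surv_usable & cov$complete & !is.na(activity)
  cl <- clinical[usable, ]
  n_events <- sum(cl$os_event)
  assert_that(n_events > 0L, "no events among usable samples")
  if (n_events < 10L) warning("fewer than 10 events; fit will be unstable")
  a <- as.numeric(scale(activity[usable]))
  df <- data.frame(os_time = cl$os_time, os_event = cl$os_event, activity = a)
  if (!is.null(cov$frame)) df <- cbind(df, cov$frame[usable, , drop = FALSE])
  form <- stats::as.formula(paste(
    "survival::Surv(os_time, os_event) ~ activity",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  co <- sm["activity", "coef"]
  se <- sm["activity", "se(coef)"]
  p <- if (converged) sm["activity", "Pr(>|z|)"] else 1
  if (!converged) warning(sprintf("%s: Cox fit did not converge; p set to 1", tc_id))
  data.frame(tc_id = tc_id, coefficient = co, hr = exp(co), se = se, p = p,
             model = if (length(covariates)) "multivariate" else "univariate",
             n_used = sum(usable), n_events = n_events, converged = converged,
             stringsAsFactors = FALSE)
}

#' Cox fits for every component activity
#'
#' @param M samples x k activity matrix (rownames = sample ids).
#' @param clinical clinical table.
#' @param covariates covariate column names (empty = univariate).
#' @return data.frame with one [cox_fit()] row per component.
#' @export
cox_activity_scan <- function(M, clinical, covariates = character(0)) {
  M <- M[clinical$sample_id, , drop = FALSE]
  do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
    cox_fit(M[, j], clinical, covariates, tc_id = colnames(M)[j])
  }))
}

# n_perm random permutations of 1..n as an n_perm x n index matrix; the
# identity permutation is excluded (it belongs to the observed data, not the
# null).
draw_permutations <- function(n, n_perm) {
  idx <- seq_len(n)
  t(vapply(seq_len(n_perm), function(b) {
    repeat {
      pi <- sample.int(n)
      if (!identical(pi, idx)) return(pi)
    }
  }, integer(n)))
}

# Log-rank (Cox score) weights a_i for the linear statistic U_j = sum a_i z_ij:
# a_i = delta_i - sum over event times t_e <= t_i of d_e / n_e (Breslow).
# sum(a) = 0, so U has exact permutation moments
#   Var(U_j) = sum(a^2) * sum((z - zbar)^2) / (n - 1).
logrank_score_weights <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  at_risk <- n:1                      # at risk at each sorted position's time
  # aggregate ties: events and at-risk per distinct time
  dt <- !duplicated(t_s)
  grp <- cumsum(dt)
  d_e <- rowsum(e_s, grp)[, 1L]
  n_e <- at_risk[dt]
  haz <- d_e / n_e
  cumhaz <- cumsum(haz)[grp]          # Nelson-Aalen at each sample's time
  a <- numeric(n)
  a[ord] <- e_s - cumhaz
  a
}

score_pvalues_from_weights <- function(Zc, a) {
  s_a2 <- sum(a^2)                    # mean(a) = 0 by construction
  s_z2 <- colSums(Zc^2)
  u <- as.vector(crossprod(Zc, a))
  tstat <- u / sqrt(s_a2 * s_z2 / (length(a) - 1))
  2 * pnorm(-abs(tstat))
}

#' Permutation-score p-values of component activities against survival
#'
#' Computes, for every component, the two-sided p-value of the Cox
#' partial-likelihood score (log-rank-type) statistic, standardized by its
#' exact permutation moments. With covariates, the weights are the
#' martingale residuals of the covariate-only null Cox model, giving an
#' adjusted score test. This is the statistic the permutation null
#' ([permutation_null_pvalues()]) recomputes, so observed and null p-values
#' are exchangeable.
#'
#' @param M samples x k activity matrix (rownames = sample ids).
#' @param clinical clinical table.
#' @param covariates covariate names for the adjusted test.
#' @return named numeric vector of p-values.
#' @export
observed_score_pvalues <- function(M, clinical, covariates = character(0)) {
  pre <- score_test_setup(M, clinical, covariates)
  setNames(score_pvalues_from_weights(pre$Zc, pre$a), colnames(M))
}

score_test_setup <- function(M, clinical, covariates) {
  M <- M[clinical$sample_id, , drop = FALSE]
  cov <- prep_covariates(clinical, covariates)
  usable <- clinical$surv_usable & cov$complete
  cl <- clinical[usable, ]
  assert_that(sum(cl$os_event) > 0L, "no events among usable samples")
  Zc <- sweep(M[usable, , drop = FALSE], 2L, colMeans(M[usable, , drop = FALSE]))
  a <- if (length(covariates) == 0L) {
    logrank_score_weights(cl$os_time, cl$os_event)
  } else {
    df <- cbind(data.frame(os_time = cl$os_time, os_event = cl$os_event),
                cov$frame[usable, , drop = FALSE])
    null_fit <- survival::coxph(stats::as.formula(paste(
      "survival::Surv(os_time, os_event) ~",
      paste(covariates, collapse = " + "))), data = df, ties = "efron")
    r <- stats::residuals(null_fit, type = "martingale")
    r - mean(r)
  }
  list(Zc = Zc, a = a, usable = usable)
}

#' Joint permutation null for all component p-values
#'
#' Each permutation jointly shuffles the outcome (and covariate) rows
#' against the activity rows — preserving the correlation structure among
#' the k test statistics — and recomputes all k score p-values. The
#' identity permutation is excluded. Seeded and reproducible.
#'
#' @param M samples x k activity matrix.
#' @param clinical clinical table.
#' @param covariates covariate names (adjusted test; see
#'   [observed_score_pvalues()]).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return `n_perm` x k matrix of p-values, with the observed p-vector in
#'   attribute `observed_p`.
#' @export
permutation_null_pvalues <- function(M, clinical, covariates = character(0),
                                     n_perm = 10000L, seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100: tail quantiles will be unstable")
  pre <- score_test_setup(M, clinical, covariates)
  n <- length(pre$a)
  perms <- with_seed(seed, draw_permutations(n, n_perm))
  A <- matrix(pre$a[perms], n_perm, n)
  U <- A %*% pre$Zc                    # n_perm x k
  s_a2 <- sum(pre$a^2)
  s_z2 <- colSums(pre$Zc^2)
  tstat <- sweep(U, 2L, sqrt(s_a2 * s_z2 / (n - 1)), "/")
  P <- 2 * pnorm(-abs(tstat))
  colnames(P) <- colnames(M)
  attr(P, "observed_p") <- score_pvalues_from_weights(pre$Zc, pre$a)
  P
}

#' Multivariate-permutation false-discovery selection
#'
#' Korn-style step-down procedure controlling the false-discovery
#' proportion: for a candidate rejection count r over the sorted observed
#' p-values, `u(r) = floor(gamma * r)` false discoveries are tolerated, and
#' the r smallest p-values are rejected iff the (u(r)+1)-th smallest
#' observed p falls below the (1 - confidence) empirical quantile of the
#' (u(r)+1)-th order statistic across the permutation p-vectors. The
#' selection is the largest admissible prefix, so P(FDP > gamma) is about
#' 1 - confidence under the global null.
#'
#' @param observed_p named per-component p-values.
#' @param perm_p permutations x k p-value matrix (columns matching
#'   `observed_p` order).
#' @param gamma acceptable false-discovery proportion (default 0.01; the
#'   companion Results-level convention of 0.05 is a valid alternative).
#' @param confidence confidence level of the FDP bound (default 0.8).
#' @return list: `selected_tc_ids`, `observed_p`, `n_perm`, `gamma`,
#'   `confidence`, `threshold_trace` (per-candidate rejection record).
#' @export
multivariate_permutation_select <- function(observed_p, perm_p, gamma = 0.01,
                                            confidence = 0.8) {
  assert_that(gamma > 0 && gamma < 1, "gamma must be in (0,1)")
  assert_that(confidence > 0 && confidence < 1, "confidence must be in (0,1)")
  k <- length(observed_p)
  assert_that(ncol(perm_p) == k, "perm_p columns must match observed_p")
  ord <- order(observed_p)
  p_sorted <- observed_p[ord]
  trace <- data.frame(r = seq_len(k), u = floor(gamma * seq_len(k)),
                      obs_stat = NA_real_, null_quantile = NA_real_,
                      admissible = FALSE)
  # Step-down: at candidate count r with u(r) tolerated false discoveries,
  # the r - u - 1 most significant components are taken as true discoveries,
  # and the null quantile of the (u+1)-th smallest p is computed over the
  # remaining columns' permutation p-vectors. Stop at the first failure.
  for (r in seq_len(k)) {
    u <- trace$u[r]
    if (u >= r) {                 # all candidate rejections tolerated
      trace$admissible[r] <- TRUE
      next
    }
    j <- u + 1L
    n_excl <- r - j               # most-significant columns set aside
    cols <- if (n_excl > 0L) ord[-seq_len(n_excl)] else ord
    stat <- apply(perm_p[, cols, drop = FALSE], 1L, function(x) {
      sort(x, partial = j)[j]
    })
    q <- quantile(stat, probs = 1 - confidence, type = 1L, names = FALSE)
    trace$obs_stat[r] <- p_sorted[r]
    trace$null_quantile[r] <- q
    trace$admissible[r] <- p_sorted[r] < q
    if (!trace$admissible[r]) break
  }
  r_star <- if (any(trace$admissible)) max(trace$r[trace$admissible]) else 0L
  ids <- names(observed_p)
  if (is.null(ids)) ids <- as.character(seq_len(k))
  list(selected_tc_ids = ids[ord][seq_len(r_star)],
       observed_p = observed_p, n_perm = nrow(perm_p),
       gamma = gamma, confidence = confidence, threshold_trace = trace)
}

#' Select survival-associated components
#'
#' End-to-end: observed score p-values, the joint permutation null, and the
#' multivariate-permutation selection, optionally with full Cox reporting
#' fits for the selected components.
#'
#' @inheritParams permutation_null_pvalues
#' @inheritParams multivariate_permutation_select
#' @param report_cox also fit `coxph` per selected component for hazard
#'   ratios (default TRUE).
#' @return the [multivariate_permutation_select()] list, plus `cox_table`
#'   when requested.
#' @export
select_survival_tcs <- function(M, clinical, covariates = character(0),
                                n_perm = 10000L, gamma = 0.01,
                                confidence = 0.8, seed = 1L,
                                report_cox = TRUE) {
  P <- permutation_null_pvalues(M, clinical, covariates, n_perm = n_perm,
                                seed = seed)
  sel <- multivariate_permutation_select(attr(P, "observed_p"), P,
                                         gamma = gamma, confidence = confidence)
  if (report_cox && length(sel$selected_tc_ids)) {
    sel$cox_table <- do.call(rbind, lapply(sel$selected_tc_ids, function(id) {
      cox_fit(M[clinical$sample_id, id], clinical, covariates, tc_id = id)
    }))
  }
  sel
}
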