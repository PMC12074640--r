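# shared fixture builders; everything is generated in code at test time

quick_clinical <- function(os_time, os_event, age = 60, stage = 3,
                           ids = sprintf("s%03d", seq_along(os_time))) {
  as_clinical(data.frame(sample_id = ids, os_time = os_time,
                         os_event = as.integer(os_event), age = age,
                         stage = stage, stringsAsFactors = FALSE))
}

# exponential survival with a planted step or linear effect
sim_surv <- function(n, lp, seed, base_rate = 1 / 60, censor_rate = 0) {
  set.seed(seed)
  t_ev <- rexp(n, rate = base_rate * exp(lp))
  t_c <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

expect_all_true <- function(x) expect_true(all(x))
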