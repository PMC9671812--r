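# Independent brute-force oracles used to pin down the analytical code paths.
# These are deliberately written as naive double loops over the definitions,
# sharing no code with the package internals.

# classical negative log partial likelihood (Breslow ties), averaged over
# events, with optional eligibility filtering
brute_cox_nll <- function(states, times, events, eligible = NULL) {
  if (is.null(eligible)) eligible <- rep(TRUE, length(states))
  s <- states[eligible]
  t <- times[eligible]
  e <- as.logical(events[eligible])
  d <- sum(e)
  if (d == 0) return(0)
  ll <- 0
  for (i in which(e)) {
    risk <- which(t >= t[i])
    ll <- ll + s[i] - log(sum(exp(s[risk])))
  }
  -ll / d
}

# Harrell's C by explicit pair enumeration: a pair is comparable iff the
# member with the earlier time had an event (tied event/censored pairs count
# the event as earlier; tied event/event pairs are skipped); score ties 0.5
brute_concordance <- function(times, events, scores) {
  n <- length(times)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[i] < times[j] && events[i]) { a <- i; b <- j }
      else if (times[j] < times[i] && events[j]) { a <- j; b <- i }
      else if (times[i] == times[j] && events[i] && !events[j]) { a <- i; b <- j }
      else if (times[i] == times[j] && events[j] && !events[i]) { a <- j; b <- i }
      else next
      den <- den + 1
      if (scores[a] > scores[b]) num <- num + 1
      else if (scores[a] == scores[b]) num <- num + 0.5
    }
  }
  num / den
}

# small random survival instance
random_surv_instance <- function(n, censor_frac = 0.3) {
  list(times = rexp(n), events = as.integer(runif(n) > censor_frac),
       scores = rnorm(n))
}

# tiny two-endpoint cohort config for fast tests
tiny_cohort_config <- function(n = 1500, seed = 1,
                               censoring_rate = 0.02, ...) {
  specs <- list(
    endpoint_spec("strong", target_rate_10y = 0.08,
                  clinical_betas = c(age = 0.3),
                  marker_betas = scale_marker_betas_for_test(1.1, seed),
                  cardiovascular_flag = TRUE),
    endpoint_spec("null_ep", target_rate_10y = 0.08,
                  clinical_betas = c(age = 0.4),
                  marker_betas = numeric(168))
  )
  cohort_config(n, endpoint_specs = specs, seed = seed,
                censoring_rate = censoring_rate, ...)
}

scale_marker_betas_for_test <- function(sd_target, seed) {
  set.seed(seed + 1000)
  pattern <- numeric(168)
  idx <- sample.int(168, 20)
  pattern[idx] <- rnorm(20)
  bs <- default_marker_blocks(168)
  # normalize under the block covariance (rho = 0.5) like the generator does
  blk <- rep(seq_along(bs), bs)
  v <- sum(pattern^2) * 0.5
  for (b in unique(blk)) v <- v + 0.5 * sum(pattern[blk == b])^2
  pattern * sd_target / sqrt(v)
}
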