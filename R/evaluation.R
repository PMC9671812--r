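# Discrimination, risk stratification, calibration and clinical-utility
# metrics with bootstrap uncertainty.

#' Harrell's concordance index
#'
#' Fraction of comparable pairs ranked correctly by the score. A pair is
#' comparable iff the member with the earlier follow-up time had an event
#' (with tied times, an event/censored pair counts the event as earlier and
#' a tied event/event pair is not ordered); tied scores count 0.5. Computed
#' by exhaustive pair enumeration in compiled code.
#'
#' @param times,events outcome vectors.
#' @param scores risk scores (higher = riskier).
#' @return concordance in `[0, 1]`. Errors when no pair is comparable.
#' @export
harrell_c <- function(times, events, scores) {
  res <- cpp_concordance(as.numeric(times), as.integer(events),
                         as.numeric(scores))
  if (res$comparable == 0) stop("no comparable pairs")
  res$cindex
}

#' Percentile bootstrap confidence interval
#'
#' @param statistic function of `(data, idx)` returning a scalar.
#' @param data data object passed through.
#' @param n number of rows to resample (indices `1:n` with replacement).
#' @param B bootstrap iterations (>= 1).
#' @param seed RNG seed; same seed gives the identical interval.
#' @param max_redraws a resample on which the statistic errors or returns
#'   `NA` is redrawn, up to this many extra attempts in total (logged via the
#'   returned `redraws` count).
#' @return list `(median, lo, hi, redraws)` using the 2.5/50/97.5 percentiles.
#' @export
bootstrap_ci <- function(statistic, data, n, B = 1000L, seed = 1L,
                         max_redraws = 100L) {
  stopifnot(B >= 1L)
  set.seed(seed)
  vals <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(statistic(data, idx), error = function(e) NA_real_)
      if (!is.na(v)) { vals[b] <- v; break }
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("statistic undefined on too many bootstrap resamples")
    }
  }
  q <- unname(quantile(vals, c(0.025, 0.5, 0.975), type = 7))
  list(median = q[2], lo = q[1], hi = q[3], redraws = redraws)
}

#' Paired bootstrap delta of two concordance indices
#'
#' Both score vectors must be aligned on the same participants; each bootstrap
#' iteration draws one index vector and evaluates both models on it, so the
#' interval reflects the paired difference. The difference is flagged
#' significant when the 95% CI excludes 0.
#'
#' @param scores_a,scores_b aligned score vectors (delta = C(a) - C(b)).
#' @param times,events shared outcomes.
#' @param B bootstrap iterations.
#' @param seed RNG seed.
#' @return list `(median, lo, hi, significant)`.
#' @export
c_delta <- function(scores_a, scores_b, times, events, B = 1000L, seed = 1L) {
  n <- length(times)
  if (length(scores_a) != n || length(scores_b) != n)
    stop("scores must be paired with the outcomes (equal lengths)")
  ci <- bootstrap_ci(function(d, idx) {
    harrell_c(d$t[idx], d$e[idx], d$a[idx]) -
      harrell_c(d$t[idx], d$e[idx], d$b[idx])
  }, list(t = times, e = events, a = scores_a, b = scores_b), n, B, seed)
  ci$significant <- ci$lo > 0 || ci$hi < 0
  ci
}

score_bins <- function(scores, n_bins) {
  # equal-count bins by score rank; ties broken by order
  r <- rank(scores, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(scores)))
}

#' Observed event frequency by score percentile
#'
#' @param scores continuous risk scores.
#' @param events binary incident outcome.
#' @param n_bins number of equal-count bins (default 100 percentiles).
#' @return data.frame `(bin, n, events, rate)`.
#' @export
event_rate_by_percentile <- function(scores, events, n_bins = 100L) {
  b <- score_bins(scores, n_bins)
  agg <- tapply(as.numeric(events), b, function(x) c(length(x), sum(x)))
  out <- data.frame(bin = as.integer(names(agg)))
  out$n <- vapply(agg, `[`, 0, 1)
  out$events <- vapply(agg, `[`, 0, 2)
  out$rate <- out$events / out$n
  out
}

#' Top-vs-bottom decile event-rate ratio
#'
#' Ratio of the observed event rate in the top 10% of scores to the bottom
#' 10%, with a bootstrap CI. Both the risk ratio and the odds ratio of the
#' two deciles are returned, explicitly labeled. A bottom decile without
#' events makes the point estimate a lower bound, flagged via `lower_bound`.
#'
#' @param scores,events as in [event_rate_by_percentile()].
#' @param B,seed bootstrap settings.
#' @param decile tail fraction (default 0.10).
#' @return list with `rate_top`, `rate_bottom`, `risk_ratio` (+CI),
#'   `odds_ratio`, `lower_bound` flag.
#' @export
decile_rate_ratio <- function(scores, events, B = 1000L, seed = 1L,
                              decile = 0.10) {
  events <- as.numeric(events)
  rr_of <- function(sc, ev) {
    qs <- quantile(sc, c(decile, 1 - decile))
    bot <- ev[sc <= qs[1]]; top <- ev[sc >= qs[2]]
    c(top = mean(top), bottom = mean(bot))
  }
  rates <- rr_of(scores, events)
  lb <- rates["bottom"] == 0
  rr <- if (lb) Inf else unname(rates["top"] / rates["bottom"])
  or <- if (lb || rates["top"] == 1) Inf else
    unname((rates["top"] / (1 - rates["top"])) /
             (rates["bottom"] / (1 - rates["bottom"])))
  ci <- tryCatch(bootstrap_ci(function(d, idx) {
    r <- rr_of(d$s[idx], d$e[idx])
    if (r["bottom"] == 0) return(NA_real_)
    unname(r["top"] / r["bottom"])
  }, list(s = scores, e = events), length(scores), B, seed),
  error = function(e) list(lo = NA_real_, hi = NA_real_))
  list(rate_top = unname(rates["top"]), rate_bottom = unname(rates["bottom"]),
       risk_ratio = rr, lo = ci$lo, hi = ci$hi,
       odds_ratio = or, lower_bound = unname(lb))
}

#' Calibration curve against Kaplan-Meier observed risk
#'
#' Splits participants into equal-count bins of predicted risk; per bin the
#' observed risk is one minus the Kaplan-Meier survival at the horizon, with
#' a Greenwood-variance (log-scale) 95% CI.
#'
#' @param predicted predicted risks in `[0, 1]` at `horizon`.
#' @param times,events outcomes.
#' @param bins number of bins (default 10).
#' @param horizon years.
#' @return data.frame `(bin, n, mean_predicted, observed, lo, hi)`.
#' @export
calibration_curve <- function(predicted, times, events, bins = 10L,
                              horizon = 10) {
  if (any(predicted < 0 | predicted > 1)) stop("risks must be in [0, 1]")
  b <- score_bins(predicted, bins)
  out <- lapply(sort(unique(b)), function(k) {
    sel <- b == k
    if (!any(sel)) stop("empty calibration bin")
    km <- survival::survfit(survival::Surv(times[sel],
                                           as.numeric(events[sel])) ~ 1,
                            conf.type = "log")
    sm <- summary(km, times = min(horizon, max(km$time)), extend = TRUE)
    data.frame(bin = k, n = sum(sel), mean_predicted = mean(predicted[sel]),
               observed = 1 - sm$surv,
               lo = 1 - sm$upper, hi = 1 - sm$lower)
  })
  do.call(rbind, out)
}

horizon_status <- function(times, events, horizon) {
  # outcome status at the horizon; participants censored before the horizon
  # without an event carry no status and are excluded (exclusion reported
  # by callers via the `n_excluded` fields)
  ev <- as.logical(events) & times <= horizon
  known <- ev | (times >= horizon)
  list(event = ev, known = known)
}

#' Decision curve (net benefit and standardized net benefit)
#'
#' At threshold `p_t`: `NB = TP/n - (FP/n) * p_t / (1 - p_t)` with TP/FP the
#' classifications `risk >= p_t` against the outcome status at the horizon;
#' the standardized net benefit divides by the outcome prevalence. Treat-all
#' and treat-none reference curves are included. Participants censored before
#' the horizon without an event are excluded (count reported).
#'
#' @param predicted predicted risks at `horizon`.
#' @param times,events outcomes.
#' @param thresholds risk thresholds in (0,1); default 0.01 to 0.5 by 0.005.
#' @param horizon years.
#' @return data.frame `(threshold, net_benefit, snb, treat_all, treat_none,
#'   snb_treat_all)` with attributes `prevalence` and `n_excluded`.
#' @export
decision_curve <- function(predicted, times, events,
                           thresholds = seq(0.01, 0.5, by = 0.005),
                           horizon = 10) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must be inside (0, 1)")
  hs <- horizon_status(times, events, horizon)
  keep <- hs$known
  y <- hs$event[keep]; p <- predicted[keep]
  n <- length(y)
  prev <- mean(y)
  if (prev == 0)
    stop("no events by the horizon: standardized net benefit undefined")
  out <- data.frame(threshold = thresholds)
  w <- thresholds / (1 - thresholds)
  out$net_benefit <- vapply(seq_along(thresholds), function(i) {
    pos <- p >= thresholds[i]
    sum(pos & y) / n - sum(pos & !y) / n * w[i]
  }, 0)
  out$treat_all <- prev - (1 - prev) * w
  out$treat_none <- 0
  out$snb <- out$net_benefit / prev
  out$snb_treat_all <- out$treat_all / prev
  attr(out, "prevalence") <- prev
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Net benefit from explicit classification counts
#'
#' Direct evaluation of `NB = TP/n - (FP/n) * p_t/(1 - p_t)` and
#' `sNB = NB / prevalence` on a given confusion table.
#'
#' @param tp,fp,n true positives, false positives, total classified.
#' @param threshold risk threshold `p_t`.
#' @param prevalence outcome prevalence used for standardization.
#' @return list `(net_benefit, snb)`.
#' @export
net_benefit_from_counts <- function(tp, fp, n, threshold, prevalence) {
  nb <- tp / n - (fp / n) * threshold / (1 - threshold)
  list(net_benefit = nb, snb = nb / prevalence)
}

#' Sensitivity, PPV and positive likelihood ratio at target FPRs
#'
#' For each target false-positive rate the threshold is placed at the
#' corresponding quantile of the non-event scores (nearest achievable rate
#' under ties; the realized FPR is reported). `LR+ = sensitivity / FPR`.
#' Participants censored before the horizon without an event are excluded.
#'
#' @param predicted risk scores.
#' @param times,events outcomes (or pass `events` as horizon-status binary
#'   with `times = NULL` for pre-classified outcomes).
#' @param fpr_grid target false-positive rates.
#' @param horizon years.
#' @return data.frame `(target_fpr, realized_fpr, threshold, sensitivity,
#'   ppv, lr_plus)`.
#' @export
metrics_at_fpr <- function(predicted, times, events,
                           fpr_grid = c(0.05, 0.10, 0.20), horizon = 10) {
  if (is.null(times)) {
    y <- as.logical(events); keep <- rep(TRUE, length(y))
  } else {
    hs <- horizon_status(times, events, horizon)
    y <- hs$event; keep <- hs$known
  }
  y <- y[keep]; p <- predicted[keep]
  neg <- p[!y]; pos <- p[y]
  out <- lapply(fpr_grid, function(f) {
    thr <- quantile(neg, 1 - f, type = 1)
    realized <- mean(neg >= thr)
    if (realized > f) { # ties pushed the rate above target: step one up
      thr2 <- min(neg[neg > thr], Inf)
      if (abs(mean(neg >= thr2) - f) < abs(realized - f)) {
        thr <- thr2; realized <- mean(neg >= thr)
      }
    }
    sens <- mean(pos >= thr)
    npos <- sum(p >= thr)
    ppv <- if (npos) sum(pos >= thr) / npos else NA_real_
    data.frame(target_fpr = f, realized_fpr = realized, threshold = thr,
               sensitivity = sens, ppv = ppv,
               lr_plus = if (realized > 0) sens / realized else Inf)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
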