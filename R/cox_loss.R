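# The adapted proportional-hazards loss: negative mean log partial
# likelihood over the eligible events of a batch, with risk sets formed
# within the batch among eligible rows and Breslow handling of ties.
# Ineligible rows (prevalent cases, wrong sex, medication exclusions)
# contribute neither as events nor as risk-set members.

#' Batch Cox partial-likelihood loss
#'
#' Computes `-(1/D) * sum over eligible events i of
#' (s_i - log sum over eligible j with t_j >= t_i of exp(s_j))`, where `D` is
#' the number of eligible in-batch events. On a full dataset this is exactly
#' the classical negative log partial likelihood divided by the event count
#' (Breslow ties); on a minibatch it is the same quantity restricted to the
#' batch. Adding a constant to all states leaves the value unchanged.
#'
#' @param states numeric vector of risk scores.
#' @param times follow-up times.
#' @param events logical/0-1 event indicators.
#' @param eligible logical eligibility mask (default: all eligible).
#' @return nonnegative scalar. When the batch holds no eligible event the
#'   value is 0 with attribute `n_events = 0` (a flagged zero contribution,
#'   not `NaN`); otherwise `n_events` carries the event count used.
#' @export
cox_ph_loss <- function(states, times, events, eligible = NULL) {
  res <- cox_loss_grad(states, times, events, eligible, want_grad = FALSE)
  structure(res$loss, n_events = res$n_events)
}

# internal: loss plus gradient wrt states (full-length vector, zeros at
# ineligible positions)
cox_loss_grad <- function(states, times, events, eligible = NULL,
                          want_grad = TRUE) {
  n <- length(states)
  if (length(times) != n || length(events) != n)
    stop("states, times and events must have equal length")
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  if (length(eligible) != n) stop("eligible mask has wrong length")
  idx <- which(eligible)
  s <- states[idx]; t <- times[idx]; e <- as.logical(events[idx])
  D <- sum(e)
  if (D == 0L)
    return(list(loss = 0, grad = if (want_grad) numeric(n) else NULL,
                n_events = 0L))
  smax <- max(s)
  w <- exp(s - smax)
  # risk-set mass S(t_i) = sum of w over eligible j with t_j >= t_i;
  # descending-time cumsum, ties share the tie group's full cumsum
  ord <- order(t, decreasing = TRUE)
  cs <- cumsum(w[ord])
  ties <- anyDuplicated(t) > 0L
  if (ties) {
    grp <- match(t[ord], t[ord]) # first position of each tied time
    cs <- ave(cs, grp, FUN = max)
  }
  S <- numeric(length(s))
  S[ord] <- cs
  loss <- -(sum(s[e] - smax - log(S[e]))) / D
  grad <- NULL
  if (want_grad) {
    # R_k = sum over events i with t_i <= t_k of 1/S(t_i)
    ord2 <- order(t)
    r <- ifelse(e, 1 / S, 0)
    cr <- cumsum(r[ord2])
    if (ties) {
      grp2 <- match(t[ord2], t[ord2])
      cr <- ave(cr, grp2, FUN = max)
    }
    R <- numeric(length(s))
    R[ord2] <- cr
    g <- -(as.numeric(e) - w * R) / D
    grad <- numeric(n)
    grad[idx] <- g
  }
  list(loss = loss, grad = grad, n_events = D)
}

#' Combine per-endpoint losses into the multitask training loss
#'
#' Each endpoint's loss is already an average over its eligible in-batch
#' events; the multitask loss is their sum over endpoints flagged valid, so
#' an endpoint's contribution does not depend on the event-count imbalance
#' within the batch. Endpoints without eligible in-batch events are invalid
#' and contribute zero.
#'
#' @param per_endpoint_losses numeric vector, one entry per endpoint.
#' @param valid_flags logical vector of the same length.
#' @return scalar total loss. Warns when every endpoint is invalid.
#' @export
multitask_loss <- function(per_endpoint_losses, valid_flags) {
  if (length(per_endpoint_losses) != length(valid_flags))
    stop("per_endpoint_losses and valid_flags must have equal length")
  if (!any(valid_flags)) {
    warning("no endpoint with eligible events in this batch; zero loss")
    return(0)
  }
  sum(per_endpoint_losses[valid_flags])
}
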