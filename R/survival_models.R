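# Cox proportional-hazards integration of metabolomic states with clinical
# predictor sets: per-fold fits, 10-year risks from the Breslow baseline,
# hazard ratios per s.d., partial effects and pooled test predictions.

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial-likelihood estimation with Breslow tie handling via
#' [survival::coxph()]. A deterministic retry ladder handles hard instances:
#' default Newton iterations, then a raised iteration cap, then a small ridge
#' penalty; failure after the ladder raises an error with diagnostics. The
#' Breslow baseline cumulative hazard (for covariates at zero) is stored with
#' the fit, as are the training means/s.d.s of the predictor columns.
#'
#' @param predictors numeric matrix (named columns) of predictor values.
#' @param times,events outcome vectors.
#' @param eligible logical mask; ineligible rows are dropped before fitting.
#' @param ridge optional ridge penalty applied from the start.
#' @return object of class `cph_fit`: coefficients with standard errors,
#'   baseline cumulative hazard step function, column statistics,
#'   convergence diagnostics.
#' @export
fit_cph <- function(predictors, times, events, eligible = NULL, ridge = 0) {
  predictors <- as.matrix(predictors)
  if (is.null(colnames(predictors)))
    stop("predictor columns must be named")
  n <- nrow(predictors)
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  keep <- eligible
  X <- predictors[keep, , drop = FALSE]
  t <- times[keep]; e <- as.numeric(events[keep])
  if (sum(e) < 1) stop("no events among eligible rows")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  df <- data.frame(X, check.names = FALSE)
  rhs <- paste(sprintf("`%s`", colnames(X)), collapse = " + ")
  if (ridge > 0)
    rhs <- sprintf("ridge(%s, theta = %g, scale = FALSE)",
                   paste(sprintf("`%s`", colnames(X)), collapse = ", "), ridge)
  df$.time <- t; df$.event <- e
  fml <- as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  ladder <- list(
    list(control = survival::coxph.control(), label = "default"),
    list(control = survival::coxph.control(iter.max = 100), label = "iter100"),
    list(control = survival::coxph.control(iter.max = 200), label = "ridge",
         ridge = 1e-4))
  fit <- NULL; used <- NULL
  for (rung in ladder) {
    f2 <- fml
    if (!is.null(rung$ridge) && ridge == 0) {
      rhs2 <- sprintf("ridge(%s, theta = %g, scale = FALSE)",
                      paste(sprintf("`%s`", colnames(X)), collapse = ", "),
                      rung$ridge)
      f2 <- as.formula(paste("survival::Surv(.time, .event) ~", rhs2))
    }
    res <- tryCatch(
      withCallingHandlers(
        survival::coxph(f2, data = df, ties = "breslow",
                        control = rung$control, x = FALSE, y = TRUE),
        warning = function(w) {
          if (grepl("convergence|infinite|out of range|loglik", conditionMessage(w),
                    ignore.case = TRUE)) invokeRestart("muffleWarning")
          else invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (!inherits(res, "error") &&
        all(is.finite(coef(res))) &&
        (is.null(res$info) || TRUE)) {
      conv_ok <- is.null(res$iter) || res$iter < rung$control$iter.max ||
        identical(rung$label, "ridge")
      if (conv_ok) { fit <- res; used <- rung$label; break }
      if (is.null(fit)) { fit <- res; used <- rung$label }
    }
  }
  if (is.null(fit))
    stop("Cox fit failed after retry ladder (columns: ",
         paste(colnames(X), collapse = ", "), ")")
  beta <- coef(fit)
  names(beta) <- colnames(X)
  se <- sqrt(diag(fit$var))[seq_along(beta)]
  names(se) <- colnames(X)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(
    coef = beta, se = se,
    baseline = list(time = bh$time, cumhaz = bh$hazard),
    col_means = colMeans(X), col_sds = sds,
    n = nrow(X), n_events = sum(e),
    ladder_rung = used, coxph = fit
  ), class = "cph_fit")
}

baseline_cumhaz_at <- function(fit, horizon) {
  bl <- fit$baseline
  if (horizon > max(bl$time))
    warning("horizon ", horizon, " beyond last event time ",
            signif(max(bl$time), 4), "; using the last baseline step")
  idx <- findInterval(horizon, bl$time)
  if (idx == 0) 0 else bl$cumhaz[idx]
}

linear_predictor <- function(fit, rows) {
  X <- as.matrix(rows[, names(fit$coef), drop = FALSE])
  as.numeric(X %*% fit$coef)
}

#' Absolute risk at a horizon from a Cox fit
#'
#' `risk = 1 - S0(horizon)^exp(lp)` with `S0` from the stored Breslow
#' baseline and `lp` the (uncentered) linear predictor.
#'
#' @param fit a `cph_fit`.
#' @param rows matrix/data.frame holding the fit's predictor columns.
#' @param horizon years (default 10).
#' @return risk vector in `[0, 1]`.
#' @export
predict_risk_at_horizon <- function(fit, rows, horizon = 10) {
  stopifnot(inherits(fit, "cph_fit"))
  H0 <- baseline_cumhaz_at(fit, horizon)
  lp <- linear_predictor(fit, rows)
  1 - exp(-H0 * exp(lp))
}

#' Hazard ratio per standard deviation of a predictor
#'
#' `HR = exp(beta * sigma)` with the 95% CI `exp((beta +- 1.96 se) * sigma)`,
#' where `sigma` is the training s.d. of the column stored in the fit.
#'
#' @param fit a `cph_fit`.
#' @param column predictor column name.
#' @return named numeric vector `c(hr, lo, hi)`.
#' @export
hr_per_sd <- function(fit, column) {
  stopifnot(inherits(fit, "cph_fit"))
  if (!column %in% names(fit$coef)) stop("no such column: ", column)
  b <- fit$coef[[column]]; s <- fit$se[[column]]
  sigma <- fit$col_sds[[column]]
  c(hr = exp(b * sigma),
    lo = exp((b - 1.96 * s) * sigma),
    hi = exp((b + 1.96 * s) * sigma))
}

#' Partial-effect survival trajectories over state quantiles
#'
#' Fixes all non-state predictors at central values (median for continuous,
#' mode for binary/indicator columns, computed on the fit's training rows)
#' and returns the baseline-derived survival curve for the state held at
#' each requested quantile.
#'
#' @param fit a `cph_fit` containing a `state_col` column.
#' @param train_rows rows the fit was trained on (for central values and
#'   state quantiles).
#' @param state_col name of the state column (default "met_state").
#' @param quantiles state quantiles in (0,1) (default 0.1/0.5/0.9).
#' @param horizon_grid time grid in years.
#' @return data.frame with columns `quantile`, `time`, `survival`.
#' @export
partial_effects <- function(fit, train_rows, state_col = "met_state",
                            quantiles = c(0.1, 0.5, 0.9),
                            horizon_grid = seq(0, 10, by = 0.5)) {
  stopifnot(inherits(fit, "cph_fit"))
  if (!state_col %in% names(fit$coef)) stop("no such column: ", state_col)
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must be inside (0, 1)")
  X <- as.matrix(train_rows[, names(fit$coef), drop = FALSE])
  central <- vapply(colnames(X), function(cc) {
    v <- X[, cc]
    if (all(v %in% c(0, 1))) as.numeric(names(which.max(table(v))))
    else median(v)
  }, 0)
  qs <- quantile(X[, state_col], quantiles)
  out <- do.call(rbind, lapply(seq_along(quantiles), function(k) {
    row <- central
    row[state_col] <- qs[k]
    lp <- sum(row * fit$coef)
    H0 <- vapply(horizon_grid, function(h) {
      idx <- findInterval(h, fit$baseline$time)
      if (idx == 0) 0 else fit$baseline$cumhaz[idx]
    }, 0)
    data.frame(quantile = quantiles[k], time = horizon_grid,
               survival = exp(-H0 * exp(lp)))
  }))
  rownames(out) <- NULL
  out
}

#' Pool per-fold test predictions
#'
#' Concatenates fold-level test predictions with fold provenance and enforces
#' that no participant appears twice (a duplicate across folds indicates
#' leakage in the partition plan and raises an error).
#'
#' @param fold_predictions list of data.frames, each with at least
#'   `participant_id` and a prediction column, plus a `fold` label column.
#' @return single data.frame of class `pooled_predictions`.
#' @export
aggregate_test_predictions <- function(fold_predictions) {
  pooled <- do.call(rbind, fold_predictions)
  dup <- pooled$participant_id[duplicated(pooled$participant_id)]
  if (length(dup))
    stop("participant(s) predicted in more than one test fold: ",
         paste(head(unique(dup), 5), collapse = ", "))
  rownames(pooled) <- NULL
  class(pooled) <- c("pooled_predictions", class(pooled))
  pooled
}
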