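# Predictor-set assembly, endpoint eligibility and leakage-free
# impute/standardize/encode preprocessing.

predictor_set_names <- function() {
  c("MET", "AgeSex", "ASCVD", "PANEL", "PANELnoLaboratory",
    "AgeSex+MET", "ASCVD+MET", "PANEL+MET")
}

#' The seven covariate sets of the model grid
#'
#' The full evaluation grid fits one Cox model per endpoint for each of:
#' the metabolomic state alone, the three clinical sets, and the three
#' clinical sets combined with the state. (`PANELnoLaboratory` exists in
#' addition for decision-curve comparisons and is not part of the grid.)
#'
#' @return character vector of the seven set names.
#' @export
model_grid_sets <- function() {
  c("MET", "AgeSex", "ASCVD", "PANEL", "AgeSex+MET", "ASCVD+MET", "PANEL+MET")
}

predictor_set_columns <- function(set_name) {
  agesex <- c("age", "sex")
  ascvd <- c(agesex, "smoking", "systolic_bp", "total_chol", "hdl_chol",
             "diabetes", "antihypertensives")
  panel <- c(ascvd, "alcohol_daily", "physical_activity", "bmi",
             "waist_hip_ratio", "glucose", "creatinine", "crp", "albumin")
  switch(set_name,
         "MET" = character(),
         "AgeSex" = agesex,
         "ASCVD" = ascvd,
         "PANEL" = panel,
         "PANELnoLaboratory" = setdiff(panel, laboratory_cols()),
         "AgeSex+MET" = agesex,
         "ASCVD+MET" = ascvd,
         "PANEL+MET" = panel,
         stop("unknown predictor set '", set_name, "'; valid options: ",
              paste(predictor_set_names(), collapse = ", ")))
}

#' Assemble a named predictor table for one covariate set
#'
#' `AgeSex` is age and sex; `ASCVD` adds the cardiovascular primary-prevention
#' panel (smoking, systolic blood pressure, total and HDL cholesterol,
#' diabetes and antihypertensive flags); `PANEL` adds lifestyle, physical
#' measurements and laboratory values; `PANELnoLaboratory` drops the
#' laboratory columns. MET-suffixed sets append exactly one column holding
#' the endpoint's scalar metabolomic state (already on a log-hazard-like
#' scale, so it is not re-standardized downstream).
#'
#' @param cohort cohort table.
#' @param set_name one of [predictor_set_names()].
#' @param states optional n x endpoints state matrix with endpoint columns.
#' @param endpoint endpoint name; required for MET-containing sets.
#' @return data.frame of predictor columns (sex as factor).
#' @export
assemble_predictor_set <- function(cohort, set_name, states = NULL,
                                   endpoint = NULL) {
  cols <- predictor_set_columns(set_name)
  needs_state <- set_name == "MET" || grepl("\\+MET$", set_name)
  out <- cohort[, cols, drop = FALSE]
  if (needs_state) {
    if (is.null(states) || is.null(endpoint))
      stop("set '", set_name, "' requires a state matrix and an endpoint")
    if (!endpoint %in% colnames(states))
      stop("no state column for endpoint '", endpoint, "'")
    if (nrow(states) != nrow(cohort))
      stop("state matrix and cohort have different numbers of rows")
    out[["met_state"]] <- states[, endpoint]
  }
  out
}

#' Endpoint-specific eligibility mask
#'
#' A participant is ineligible for an endpoint iff prevalent for that endpoint,
#' of the non-target sex for a sex-restricted endpoint, or on lipid-lowering
#' therapy for a cardiovascular endpoint. The mask depends only on the
#' prevalent flag, sex and medication columns and is idempotent.
#'
#' @param cohort cohort table.
#' @param spec an [endpoint_spec()] whose endpoint exists in the cohort.
#' @return logical vector, `TRUE` = eligible.
#' @export
apply_endpoint_exclusions <- function(cohort, spec) {
  stopifnot(inherits(spec, "endpoint_spec"))
  prev_col <- paste0(spec$name, "_prevalent")
  if (!prev_col %in% names(cohort))
    stop("unknown endpoint: ", spec$name)
  eligible <- !cohort[[prev_col]]
  if (spec$sex_restriction != "none")
    eligible <- eligible & (cohort$sex == spec$sex_restriction)
  if (isTRUE(spec$cardiovascular_flag))
    eligible <- eligible & (cohort$lipid_lowering == 0)
  eligible
}

#' Eligibility masks for every configured endpoint
#' @param cohort cohort table.
#' @param specs list of [endpoint_spec()] objects.
#' @return named list of logical vectors.
#' @export
eligibility_masks <- function(cohort, specs) {
  masks <- lapply(specs, function(s) apply_endpoint_exclusions(cohort, s))
  names(masks) <- vapply(specs, `[[`, "", "name")
  masks
}

#' Fit a leakage-free preprocessor on training rows
#'
#' Fits, in order: a chained-equation imputer over the continuous columns
#' with missingness (round-robin conditional models, iterated until the
#' relative change of the imputed values drops below `tol` or `max_sweeps`
#' is reached), per-column standardization statistics, and one-hot category
#' maps. Imputation runs on the raw scale; standardization follows. Nothing
#' about rows outside the training set enters any fitted statistic;
#' [transform_preprocessor()] only ever replays training-time models.
#'
#' @param data training rows (data.frame).
#' @param continuous_cols,categorical_cols,passthrough_cols column roles.
#'   Passthrough columns (e.g. an already scaled state column) are returned
#'   untouched.
#' @param learner conditional model for the imputer: `"regression"` (linear)
#'   or `"forest"` (random forest, requires the randomForest package).
#' @param max_sweeps,tol imputer stopping rule.
#' @return object of class `met_preprocessor`.
#' @export
fit_preprocessor <- function(data,
                             continuous_cols = NULL,
                             categorical_cols = NULL,
                             passthrough_cols = NULL,
                             learner = c("regression", "forest"),
                             max_sweeps = 10L, tol = 1e-3) {
  learner <- match.arg(learner)
  stopifnot(is.data.frame(data), nrow(data) > 0L)
  if (is.null(continuous_cols))
    continuous_cols <- names(data)[vapply(data, is.numeric, TRUE)]
  if (is.null(categorical_cols))
    categorical_cols <- setdiff(names(data)[vapply(data, function(x)
      is.factor(x) || is.character(x), TRUE)], passthrough_cols)
  continuous_cols <- setdiff(continuous_cols, passthrough_cols)

  X <- as.data.frame(data[, continuous_cols, drop = FALSE])
  has_na <- vapply(X, anyNA, TRUE)
  col_means <- vapply(X, function(x) mean(x, na.rm = TRUE), 0)

  # chained equations on the training rows
  imp_models <- list()
  if (any(has_na)) {
    filled <- X
    for (j in names(X)[has_na])
      filled[[j]][is.na(filled[[j]])] <- col_means[[j]]
    na_idx <- lapply(X, function(x) which(is.na(x)))
    for (sweep in seq_len(max_sweeps)) {
      delta <- 0; denom <- 0
      for (j in names(X)[has_na]) {
        obs <- !is.na(X[[j]])
        others <- setdiff(names(X), j)
        fit <- fit_conditional(filled[obs, others, drop = FALSE],
                               X[[j]][obs], learner)
        imp_models[[j]] <- fit
        if (length(na_idx[[j]])) {
          new_vals <- predict_conditional(
            fit, filled[na_idx[[j]], others, drop = FALSE], learner)
          old_vals <- filled[[j]][na_idx[[j]]]
          delta <- delta + sum((new_vals - old_vals)^2)
          denom <- denom + sum(old_vals^2) + 1e-12
          filled[[j]][na_idx[[j]]] <- new_vals
        }
      }
      if (sqrt(delta / denom) < tol) break
    }
    X <- filled
  }

  sds <- vapply(X, sd, 0)
  const <- names(sds)[sds == 0 | !is.finite(sds)]
  if (length(const))
    stop("constant continuous column(s): ", paste(const, collapse = ", "))
  means <- vapply(X, mean, 0)

  levels_map <- lapply(data[, categorical_cols, drop = FALSE],
                       function(x) levels(as.factor(x)))

  structure(list(
    continuous_cols = continuous_cols, categorical_cols = categorical_cols,
    passthrough_cols = passthrough_cols %||% character(),
    means = means, sds = sds, init_means = col_means,
    imp_models = imp_models, learner = learner,
    max_sweeps = max_sweeps, tol = tol,
    levels_map = levels_map,
    provenance = list(n_rows = nrow(data), fitted_at = "training")
  ), class = "met_preprocessor")
}

fit_conditional <- function(X, y, learner) {
  if (learner == "forest") {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("learner = 'forest' requires the randomForest package")
    randomForest::randomForest(X, y, ntree = 50)
  } else {
    df <- cbind(.y = y, X)
    lm(.y ~ ., data = df)
  }
}
predict_conditional <- function(fit, X, learner) {
  as.numeric(predict(fit, newdata = as.data.frame(X)))
}

#' Apply a fitted preprocessor to (possibly unseen) rows
#'
#' Imputes missing continuous values by replaying the training-time chained
#' models, standardizes with the training means and s.d.s, one-hot encodes
#' categoricals with the training level maps (a level unseen at fit time maps
#' to all zeros with a warning), and passes through passthrough columns.
#'
#' @param prep a `met_preprocessor`.
#' @param data rows to transform.
#' @return numeric matrix with named columns.
#' @export
transform_preprocessor <- function(prep, data) {
  stopifnot(inherits(prep, "met_preprocessor"))
  X <- as.data.frame(data[, prep$continuous_cols, drop = FALSE])
  if (anyNA(X)) {
    na_idx <- lapply(X, function(x) which(is.na(x)))
    for (j in names(X))
      X[[j]][na_idx[[j]]] <- prep$init_means[[j]]
    if (length(prep$imp_models)) {
      for (sweep in seq_len(prep$max_sweeps)) {
        delta <- 0; denom <- 0
        for (j in names(prep$imp_models)) {
          idx <- na_idx[[j]]
          if (!length(idx)) next
          others <- setdiff(names(X), j)
          new_vals <- predict_conditional(
            prep$imp_models[[j]], X[idx, others, drop = FALSE], prep$learner)
          delta <- delta + sum((new_vals - X[[j]][idx])^2)
          denom <- denom + sum(X[[j]][idx]^2) + 1e-12
          X[[j]][idx] <- new_vals
        }
        if (sqrt(delta / denom) < prep$tol) break
      }
    }
  }
  mats <- list()
  if (length(prep$continuous_cols)) {
    Xm <- as.matrix(X)
    Xm <- sweep(Xm, 2, prep$means[colnames(Xm)])
    Xm <- sweep(Xm, 2, prep$sds[colnames(Xm)], "/")
    mats <- c(mats, list(Xm))
  }
  for (cc in prep$categorical_cols) {
    lv <- prep$levels_map[[cc]]
    x <- as.character(data[[cc]])
    unseen <- !is.na(x) & !(x %in% lv)
    if (any(unseen))
      warning("column '", cc, "': ", sum(unseen),
              " value(s) with level unseen at fit time mapped to all zeros")
    # reference coding: first level dropped (all-zero row = reference level
    # or unseen); keeps the design full rank for Cox fitting
    enc <- matrix(0, nrow(data), length(lv) - 1L,
                  dimnames = list(NULL, paste0(cc, "_", lv[-1L])))
    for (k in seq_along(lv)[-1L])
      enc[, k - 1L] <- as.numeric(!is.na(x) & x == lv[k])
    mats <- c(mats, list(enc))
  }
  for (pc in prep$passthrough_cols)
    mats <- c(mats, list(matrix(as.numeric(data[[pc]]), ncol = 1,
                                dimnames = list(NULL, pc))))
  do.call(cbind, mats)
}

#' De-standardize continuous columns of a transformed matrix
#' @param prep a `met_preprocessor`.
#' @param mat matrix from [transform_preprocessor()].
#' @return matrix of the continuous columns on their original scale.
#' @export
inverse_standardize <- function(prep, mat) {
  cols <- prep$continuous_cols
  out <- sweep(mat[, cols, drop = FALSE], 2, prep$sds[cols], "*")
  sweep(out, 2, prep$means[cols], "+")
}
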