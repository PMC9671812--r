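local_tiny_cohort <- function(n = 600, seed = 2) {
  generate_cohort(tiny_cohort_config(n = n, seed = seed))
}

test_that("predictor sets have the documented compositions", {
  g <- local_tiny_cohort()
  agesex <- assemble_predictor_set(g$cohort, "AgeSex")
  expect_named(agesex, c("age", "sex"))
  ascvd <- assemble_predictor_set(g$cohort, "ASCVD")
  expect_true(all(c("age", "sex", "smoking", "systolic_bp", "total_chol",
                    "hdl_chol", "diabetes", "antihypertensives") %in%
                    names(ascvd)))
  panel <- assemble_predictor_set(g$cohort, "PANEL")
  expect_true(all(names(ascvd) %in% names(panel)))
  nolab <- assemble_predictor_set(g$cohort, "PANELnoLaboratory")
  expect_false(any(c("glucose", "creatinine", "crp", "albumin",
                     "total_chol", "hdl_chol") %in% names(nolab)))
  st <- matrix(rnorm(nrow(g$cohort) * 2), ncol = 2,
               dimnames = list(NULL, c("strong", "null_ep")))
  asmet <- assemble_predictor_set(g$cohort, "AgeSex+MET", st, "strong")
  expect_named(asmet, c("age", "sex", "met_state"))
  expect_equal(asmet$met_state, st[, "strong"])
  met <- assemble_predictor_set(g$cohort, "MET", st, "strong")
  expect_named(met, "met_state")
})

test_that("unknown or underspecified sets error clearly", {
  g <- local_tiny_cohort(n = 50)
  expect_error(assemble_predictor_set(g$cohort, "FOO"), "valid options")
  expect_error(assemble_predictor_set(g$cohort, "AgeSex+MET"),
               "requires a state matrix")
  st <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "other"))
  expect_error(assemble_predictor_set(g$cohort, "MET", st, "strong"),
               "no state column")
})

test_that("the model grid lists exactly the seven covariate sets", {
  expect_length(model_grid_sets(), 7)
  expect_setequal(model_grid_sets(),
                  c("MET", "AgeSex", "ASCVD", "PANEL",
                    "AgeSex+MET", "ASCVD+MET", "PANEL+MET"))
})

test_that("exclusions are endpoint-specific and rule-based", {
  g <- local_tiny_cohort(n = 800, seed = 4)
  co <- g$cohort
  specs <- tiny_cohort_config(n = 800, seed = 4)$endpoint_specs
  # "strong" is cardiovascular, "null_ep" is not
  m_strong <- apply_endpoint_exclusions(co, specs[[1]])
  m_null <- apply_endpoint_exclusions(co, specs[[2]])
  prevalent_a_only <- co$strong_prevalent & !co$null_ep_prevalent &
    co$lipid_lowering == 0
  expect_true(any(prevalent_a_only))
  expect_true(all(!m_strong[prevalent_a_only]))
  expect_true(all(m_null[prevalent_a_only]))
  lipid <- co$lipid_lowering == 1 & !co$strong_prevalent &
    !co$null_ep_prevalent
  expect_true(all(!m_strong[lipid]))
  expect_true(all(m_null[lipid]))
  # sex restriction
  spec_f <- endpoint_spec("strong", sex_restriction = "female")
  m_f <- apply_endpoint_exclusions(co, spec_f)
  expect_true(all(!m_f[co$sex == "male"]))
  # idempotent and exhaustive: every exclusion is explained by a rule
  expect_identical(m_strong, apply_endpoint_exclusions(co, specs[[1]]))
  excluded <- !m_strong
  explained <- co$strong_prevalent | co$lipid_lowering == 1
  expect_true(all(explained[excluded]))
  expect_error(apply_endpoint_exclusions(co, endpoint_spec("ghost")),
               "unknown endpoint")
})

test_that("complete data round-trips through standardize/encode", {
  set.seed(1)
  df <- data.frame(a = rnorm(200, 5, 2), b = runif(200),
                   sex = factor(sample(c("female", "male"), 200, TRUE)))
  prep <- fit_preprocessor(df, continuous_cols = c("a", "b"),
                           categorical_cols = "sex")
  X <- transform_preprocessor(prep, df)
  expect_equal(colnames(X), c("a", "b", "sex_male"))
  expect_equal(unname(colMeans(X[, 1:2])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(X[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  back <- inverse_standardize(prep, X)
  expect_equal(back[, "a"], df$a, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back[, "b"], df$b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("chained-equation imputation beats mean imputation on correlated data", {
  set.seed(42)
  n <- 5000
  rmse_gain <- replicate(3, {
    z <- rnorm(n)
    df <- data.frame(x1 = z + rnorm(n, sd = 0.4),
                     x2 = 2 * z + rnorm(n, sd = 0.4),
                     x3 = -z + rnorm(n, sd = 0.4))
    mask <- matrix(runif(n * 3) < 0.10, n, 3)
    df_na <- df
    df_na[mask] <- NA
    prep <- fit_preprocessor(df_na, continuous_cols = names(df))
    X <- transform_preprocessor(prep, df_na)
    imput <- inverse_standardize(prep, X)
    rmse_imp <- sqrt(mean((imput[mask] - as.matrix(df)[mask])^2))
    means <- colMeans(df_na, na.rm = TRUE)
    meanmat <- matrix(means, n, 3, byrow = TRUE)
    rmse_mean <- sqrt(mean((meanmat[mask] - as.matrix(df)[mask])^2))
    rmse_mean - rmse_imp
  })
  expect_true(all(rmse_gain > 0))
})

test_that("transform of held-out rows uses training statistics only", {
  set.seed(9)
  train <- data.frame(x = rnorm(500), y = rnorm(500))
  prep <- fit_preprocessor(train, continuous_cols = c("x", "y"))
  held <- data.frame(x = rnorm(500) + sd(train$x), y = rnorm(500))
  Xh <- transform_preprocessor(prep, held)
  expect_equal(mean(Xh[, "x"]), 1, tolerance = 0.15)
  # refitting on the identical training rows reproduces the preprocessor:
  # nothing about other rows in memory can leak in
  prep2 <- fit_preprocessor(train, continuous_cols = c("x", "y"))
  expect_equal(prep$means, prep2$means)
  expect_equal(prep$sds, prep2$sds)
})

test_that("degenerate preprocessing inputs are handled", {
  df <- data.frame(a = rep(1, 10), b = rnorm(10))
  expect_error(fit_preprocessor(df, continuous_cols = c("a", "b")),
               "constant continuous column")
  train <- data.frame(x = rnorm(50),
                      sex = factor(rep(c("female", "male"), 25)))
  prep <- fit_preprocessor(train, continuous_cols = "x",
                           categorical_cols = "sex")
  new <- data.frame(x = rnorm(3), sex = c("female", "male", "other"))
  expect_warning(X <- transform_preprocessor(prep, new), "unseen at fit")
  expect_equal(X[3, "sex_male"], 0, ignore_attr = TRUE)
})

test_that("passthrough columns are returned untouched", {
  df <- data.frame(x = rnorm(100), met_state = rnorm(100, 3, 2))
  prep <- fit_preprocessor(df, continuous_cols = "x",
                           passthrough_cols = "met_state")
  X <- transform_preprocessor(prep, df)
  expect_equal(X[, "met_state"], df$met_state, ignore_attr = TRUE)
})
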