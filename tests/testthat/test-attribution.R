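# wrap a built model as a trained model with identity normalization
as_trained <- function(model, n_markers, enames = NULL) {
  mcols <- sprintf("mkr_%03d", seq_len(n_markers))
  structure(list(
    model = model, config = model$config, history = NULL,
    selected_checkpoint = "test",
    endpoint_names = enames,
    normalization = list(means = setNames(numeric(n_markers), mcols),
                         sds = setNames(rep(1, n_markers), mcols),
                         markers = mcols)),
    class = "trained_state_model")
}

test_that("attributions of a linear model follow the closed form", {
  p <- 12
  cfg <- linear_state_model_config(2, n_markers = p, seed = 3)
  m <- build_state_model(cfg)
  trained <- as_trained(m, p, c("e1", "e2"))
  W <- m$final[[1]]$W # p x 2
  set.seed(4)
  X <- matrix(rnorm(30 * p), 30, p)
  B <- matrix(rnorm(15 * p), 15, p)
  phi <- compute_attributions(trained, X, B, endpoint = 1, n_steps = 4)
  expected <- (X - matrix(colMeans(B), 30, p, byrow = TRUE)) *
    matrix(W[, 1], 30, p, byrow = TRUE)
  expect_equal(unname(phi[, ]), unname(expected), tolerance = 1e-6,
               ignore_attr = TRUE)
  # endpoint by name resolves to the same slice
  phi2 <- compute_attributions(trained, X, B, endpoint = "e1", n_steps = 4)
  expect_equal(unname(phi2[, ]), unname(phi[, ]), ignore_attr = TRUE)
  # sample at the background mean has zero attributions
  phi0 <- compute_attributions(trained,
                               matrix(colMeans(B), 1, p), B, 1, n_steps = 4)
  expect_equal(max(abs(phi0)), 0, tolerance = 1e-10)
  expect_error(compute_attributions(trained, X[, 1:5], B, 1),
               "dimension mismatch")
})

test_that("additivity holds for the nonlinear network", {
  p <- 20
  cfg <- state_model_config(3, n_markers = p,
                            shared_widths = c(16L, 12L), shared_dropout = 0.2,
                            head_mlp_widths = c(8L, 4L), head_dropout = 0.3,
                            skip_widths = c(6L, 4L), post_merge_widths = 8L,
                            seed = 11)
  m <- build_state_model(cfg)
  # scale up the final layers so predictions are not vanishingly small
  m$final[[1]]$W <- m$final[[1]]$W * 40
  trained <- as_trained(m, p)
  set.seed(12)
  X <- matrix(rnorm(200 * p), 200, p)
  B <- matrix(rnorm(32 * p), 32, p)
  phi <- compute_attributions(trained, X, B, endpoint = 2, n_steps = 32)
  chk <- additivity_check(phi, tol = 0.05)
  expect_gte(chk$fraction_within, 0.99)
  preds <- attr(phi, "predictions")
  expect_gt(sd(preds), 0.01) # the check is not vacuous
})

test_that("global importance is the sum of absolute attributions", {
  phi <- matrix(c(-1, 2, 0, 0.5), 2, 2,
                dimnames = list(NULL, c("m1", "m2")))
  gi <- global_importance(phi)
  expect_equal(unname(gi), c(3, 0.5))
  expect_equal(unname(global_importance(matrix(0, 5, 3))), rep(0, 3))
  # brute-force double loop on a 10 x 5 x 2 set
  set.seed(13)
  tens <- list(a = matrix(rnorm(50), 10, 5), b = matrix(rnorm(50), 10, 5))
  gi2 <- global_importance(tens)
  brute <- matrix(0, 5, 2)
  for (e in 1:2) for (j in 1:5) for (i in 1:10)
    brute[j, e] <- brute[j, e] + abs(tens[[e]][i, j])
  expect_equal(unname(gi2), brute)
  expect_error(global_importance(list()), "empty")
})

test_that("percentile profiles aggregate and order correctly", {
  set.seed(14)
  n <- 400
  vals <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  # constant attributions -> flat profile
  phi_const <- matrix(2.5, n, 2, dimnames = list(NULL, c("a", "b")))
  prof <- percentile_profile(phi_const, vals, n_bins = 10)
  expect_true(all(prof$mean_attribution == 2.5))
  # bins partition the sample: weighted bin mean = overall mean
  phi <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  prof2 <- percentile_profile(phi, vals, n_bins = 10)
  for (mk in c("a", "b")) {
    sub <- prof2[prof2$marker == mk, ]
    expect_equal(mean(sub$mean_attribution), mean(phi[, mk]),
                 tolerance = 1e-10)
    # profiles are sorted by attribution, hence monotone in the mean
    expect_true(all(diff(sub$mean_attribution) >= 0))
  }
  # attribution monotone in the marker value -> value profile monotone too
  phi_m <- matrix(vals[, 1] * 3, n, 1, dimnames = list(NULL, "a"))
  prof3 <- percentile_profile(phi_m, vals[, 1, drop = FALSE], n_bins = 10)
  expect_true(all(diff(prof3$mean_value) > 0))
  expect_error(percentile_profile(phi[1:5, ], vals[1:5, ], n_bins = 10),
               "at least")
})

test_that("high-impact masks implement the percentile rule", {
  set.seed(15)
  phi <- matrix(rnorm(1e5), 1000, 100)
  mask <- high_impact_mask(phi)
  expect_equal(mean(mask), 0.02, tolerance = 0.003)
  # values strictly inside bounds computed from a wider reference: empty
  ref <- rnorm(1e4) * 10
  mask2 <- high_impact_mask(phi, reference = ref)
  expect_equal(sum(mask2), 0)
  # a distribution whose 1%/99% percentiles are -0.2/0.2 flags exactly
  # the values outside (-0.2, 0.2)
  x <- seq(-0.2, 0.2, length.out = 99)
  vals <- matrix(c(x, -0.5, 0.5), 1)
  mask3 <- high_impact_mask(vals, fixed_bounds = c(-0.2, 0.2))
  expect_equal(sum(mask3), 2)
  expect_true(all(vals[mask3] < -0.2 | vals[mask3] > 0.2))
  expect_error(high_impact_mask(matrix(1, 5, 5)), "degenerate")
})

test_that("attribution embedding is deterministic and separates clusters", {
  set.seed(16)
  phi <- rbind(matrix(rnorm(60 * 8, mean = 0), 60, 8),
               matrix(rnorm(60 * 8, mean = 8), 60, 8))
  emb1 <- embed_attributions(phi, seed = 5)
  expect_equal(dim(emb1), c(120L, 2L))
  emb2 <- embed_attributions(phi, seed = 5)
  expect_identical(emb1, emb2)
  # constructed separability: within-cluster spread below the
  # between-centroid distance
  c1 <- colMeans(emb1[1:60, ]); c2 <- colMeans(emb1[61:120, ])
  between <- sqrt(sum((c1 - c2)^2))
  within <- mean(c(sqrt(rowSums((emb1[1:60, ] -
                                   matrix(c1, 60, 2, byrow = TRUE))^2)),
                   sqrt(rowSums((emb1[61:120, ] -
                                   matrix(c2, 60, 2, byrow = TRUE))^2))))
  expect_gt(between, within)
  expect_error(embed_attributions(phi[1:10, ], seed = 1), "n_neighbors")
})
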