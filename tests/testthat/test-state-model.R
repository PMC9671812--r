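# closed-form parameter count from the configured widths, written
# independently of the builder: dense = in*out + out, batch norm = 2*out,
# heads replicated per endpoint
expected_param_count <- function(cfg) {
  dense <- function(i, o) i * o + o
  bn <- function(o) if (cfg$batchnorm) 2 * o else 0
  chain <- function(n_in, widths) {
    tot <- 0
    for (w in widths) {
      tot <- tot + dense(n_in, w) + bn(w)
      n_in <- w
    }
    tot
  }
  p <- cfg$n_markers
  E <- cfg$n_endpoints
  rep_dim <- cfg$shared_widths[length(cfg$shared_widths)]
  merge <- cfg$head_mlp_widths[length(cfg$head_mlp_widths)]
  post_out <- if (length(cfg$post_merge_widths))
    cfg$post_merge_widths[length(cfg$post_merge_widths)] else merge
  chain(p, cfg$shared_widths) +
    E * (chain(rep_dim, cfg$head_mlp_widths) + chain(p, cfg$skip_widths) +
           chain(merge, cfg$post_merge_widths) + dense(post_out, 1))
}

test_that("parameter count matches the closed-form hand computation", {
  cfg <- desk_state_model_config(8)
  expect_identical(count_parameters(build_state_model(cfg)),
                   as.integer(expected_param_count(cfg)))
  # the reference-scale architecture
  cfg_full <- state_model_config(24)
  expect_identical(count_parameters(build_state_model(cfg_full)),
                   as.integer(expected_param_count(cfg_full)))
})

test_that("configuration invariants are enforced", {
  expect_error(state_model_config(4, shared_widths = c(0L, 64L)), "positive")
  expect_error(state_model_config(4, shared_dropout = 1), "\\[0, 1\\)")
  expect_error(state_model_config(4, head_mlp_widths = c(32L, 16L),
                                  skip_widths = c(32L, 8L)),
               "equal widths")
  cfg <- state_model_config(24)
  expect_equal(cfg$shared_widths, c(256L, 256L, 512L))
  expect_equal(cfg$head_mlp_widths, c(256L, 128L, 32L))
  expect_equal(cfg$skip_widths, c(128L, 128L, 32L))
  expect_equal(cfg$post_merge_widths, c(128L, 128L))
  expect_equal(cfg$shared_dropout, 0.3)
  expect_equal(cfg$head_dropout, 0.6)
  expect_equal(cfg$batch_size, 1024L)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$lr_milestones, c(20L, 30L, 40L))
  expect_equal(cfg$max_epochs, 100L)
})

test_that("forward pass has the n x endpoints shape and is deterministic", {
  cfg <- state_model_config(5, n_markers = 30,
                            shared_widths = c(16L, 8L), shared_dropout = 0.2,
                            head_mlp_widths = c(8L, 4L), head_dropout = 0.4,
                            skip_widths = c(6L, 4L), post_merge_widths = 8L,
                            seed = 3)
  m <- build_state_model(cfg)
  X <- matrix(rnorm(40 * 30), 40, 30)
  X[2, ] <- X[1, ] # duplicated row
  s <- metstate:::model_predict_states(m, X)
  expect_equal(dim(s), c(40L, 5L))
  expect_true(all(is.finite(s)))
  expect_equal(s[1, ], s[2, ]) # identical inputs, identical states
  # inference twice gives the identical matrix (dropout off)
  expect_identical(s, metstate:::model_predict_states(m, X))
  # invariance to participant order
  perm <- sample(40)
  expect_equal(metstate:::model_predict_states(m, X[perm, ]), s[perm, ],
               tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(5)
  cfg <- state_model_config(2, n_markers = 7,
                            shared_widths = c(5L, 4L), shared_dropout = 0,
                            head_mlp_widths = c(4L, 3L), head_dropout = 0,
                            skip_widths = c(3L, 3L), post_merge_widths = 4L,
                            seed = 2)
  m <- build_state_model(cfg)
  n <- 12
  X <- matrix(rnorm(n * 7), n, 7)
  t <- rexp(n); e <- rbinom(n, 1, 0.7); e[1] <- 1
  loss_of <- function(model) {
    fw <- metstate:::model_forward(model, X, mode = "train")
    metstate:::cox_loss_grad(fw$states[, 1], t, e, want_grad = FALSE)$loss +
      metstate:::cox_loss_grad(fw$states[, 2], t, e, want_grad = FALSE)$loss
  }
  fw <- metstate:::model_forward(m, X, mode = "train")
  d1 <- metstate:::cox_loss_grad(fw$states[, 1], t, e)$grad
  d2 <- metstate:::cox_loss_grad(fw$states[, 2], t, e)$grad
  bw <- metstate:::model_backward(fw$model, fw$caches, cbind(d1, d2))
  eps <- 1e-6
  bump <- function(path, d) {
    mo <- m
    mo[[path[[1]]]][[path[[2]]]][[path[[3]]]][path[[4]]] <-
      mo[[path[[1]]]][[path[[2]]]][[path[[3]]]][path[[4]]] + d
    mo
  }
  cases <- list(
    list(path = list("trunk", 1L, "W", 3L), an = bw$grads$trunk[[1]]$W[3]),
    list(path = list("trunk", 2L, "gamma", 2L),
         an = bw$grads$trunk[[2]]$gamma[2]),
    list(path = list("mlp", 1L, "W", 5L), an = bw$grads$mlp[[1]]$W[5]),
    list(path = list("skip", 1L, "W", 2L), an = bw$grads$skip[[1]]$W[2]),
    list(path = list("post", 1L, "W", 7L), an = bw$grads$post[[1]]$W[7]),
    list(path = list("final", 1L, "W", 2L), an = bw$grads$final[[1]]$W[2])
  )
  for (cs in cases) {
    num <- (loss_of(bump(cs$path, eps)) - loss_of(bump(cs$path, -eps))) /
      (2 * eps)
    expect_equal(cs$an, num, tolerance = 1e-4)
  }
})

test_that("training respects the epoch budget and records history", {
  g <- generate_cohort(tiny_cohort_config(n = 900, seed = 6))
  plan <- make_partitions(g$cohort, seed = 1)
  specs <- tiny_cohort_config(n = 900, seed = 6)$endpoint_specs
  cfg <- desk_state_model_config(
    2, seed = 4,
    shared_widths = c(16L, 16L), head_mlp_widths = c(8L, 4L),
    skip_widths = c(6L, 4L), post_merge_widths = 8L,
    max_epochs = 6L, lr_milestones = c(3L, 5L), swa_start = 3L,
    batch_size = 256L)
  tr <- fit_fold_state_model(g$cohort, specs, plan$folds[[1]], cfg)
  expect_lte(tr$epochs_run, 6L)
  expect_lte(tr$epochs_run, cfg$max_epochs)
  expect_equal(nrow(tr$history), tr$epochs_run)
  expect_true(all(is.finite(tr$history$valid_loss)))
  # learning-rate schedule: gamma 0.1 applied at the milestones
  expect_equal(tr$history$lr[1], cfg$learning_rate)
  expect_equal(tr$history$lr[3], cfg$learning_rate * 0.1)
  expect_equal(tr$history$lr[5], cfg$learning_rate * 0.01)
  # states on new data: shape and finiteness
  st <- predict_states(tr, as.matrix(g$cohort[1:20, sprintf("mkr_%03d", 1:168)]))
  expect_equal(dim(st), c(20L, 2L))
  expect_true(all(is.finite(st)))
})

test_that("export/load round-trips states and normalization statistics", {
  g <- generate_cohort(tiny_cohort_config(n = 700, seed = 8))
  plan <- make_partitions(g$cohort, seed = 2)
  specs <- tiny_cohort_config(n = 700, seed = 8)$endpoint_specs
  cfg <- desk_state_model_config(
    2, seed = 9, shared_widths = c(12L, 12L), head_mlp_widths = c(6L, 4L),
    skip_widths = c(4L, 4L), post_merge_widths = 6L, max_epochs = 3L,
    lr_milestones = integer(), swa_start = 2L, batch_size = 256L)
  tr <- fit_fold_state_model(g$cohort, specs, plan$folds[[1]], cfg)
  path <- withr::local_tempfile(fileext = ".json")
  export_state_model(tr, path)
  back <- load_state_model(path)
  X <- as.matrix(g$cohort[1:50, sprintf("mkr_%03d", 1:168)])
  expect_equal(predict_states(back, X), predict_states(tr, X),
               tolerance = 1e-5)
  # the bundle carries the training-time marker normalization
  bundle <- jsonlite::read_json(path)
  expect_length(bundle$normalization$means, 168)
  expect_length(bundle$normalization$sds, 168)
  # wrong marker count is a shape error
  expect_error(predict_states(back, X[, 1:10]), "expects")
})

test_that("random hyperparameter search honors its contracts", {
  g <- generate_cohort(tiny_cohort_config(n = 600, seed = 10))
  plan <- make_partitions(g$cohort, seed = 3)
  specs <- tiny_cohort_config(n = 600, seed = 10)$endpoint_specs
  fold <- plan$folds[[1]]
  mcols <- sprintf("mkr_%03d", 1:168)
  M <- as.matrix(g$cohort[, mcols])
  rows_tr <- match(fold$train_ids, g$cohort$participant_id)
  rows_va <- match(fold$valid_ids, g$cohort$participant_id)
  norm <- list(means = colMeans(M[rows_tr, ]),
               sds = apply(M[rows_tr, ], 2, sd), markers = mcols)
  mk_split <- function(rows) list(
    x = metstate:::normalize_markers(M[rows, ], norm),
    time = sapply(specs, function(s) g$cohort[[paste0(s$name, "_time")]][rows]),
    event = sapply(specs, function(s) g$cohort[[paste0(s$name, "_event")]][rows]),
    eligible = sapply(specs, function(s)
      apply_endpoint_exclusions(g$cohort, s)[rows]))
  base <- desk_state_model_config(
    2, seed = 1, shared_widths = c(8L, 8L), head_mlp_widths = c(4L, 4L),
    skip_widths = c(4L, 4L), post_merge_widths = 4L, max_epochs = 2L,
    lr_milestones = integer(), swa_start = 1L, batch_size = 256L)
  space <- list(learning_rate = c(1e-3, 3e-3), batch_size = c(128L, 256L))
  tr1 <- mk_split(rows_tr); va1 <- mk_split(rows_va)
  expect_error(hyperparameter_search(list(), 2, 1, tr1, va1, base),
               "empty search space")
  res1 <- hyperparameter_search(space, 1, seed = 7, tr1, va1, base)
  expect_s3_class(res1$best_config, "state_model_config")
  res <- hyperparameter_search(space, 3, seed = 7, tr1, va1, base)
  res_again <- hyperparameter_search(space, 3, seed = 7, tr1, va1, base)
  expect_identical(res$trials$config, res_again$trials$config)
  expect_true(all(res$best_loss <= res$trials$valid_loss))
})
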