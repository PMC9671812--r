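# The multitask residual metabolomic state model: a shared trunk over the
# marker panel feeding per-endpoint residual heads, each head combining an
# MLP on the shared representation with a skip network on the raw markers,
# trained under the batch Cox partial-likelihood loss.

#' State model configuration
#'
#' Defaults follow the reference architecture: shared trunk of three
#' fully connected layers (256, 256, 512 nodes) with batch normalization,
#' dropout 0.3 and SiLU activations; per-endpoint heads made of a 256/128/32
#' MLP (dropout 0.6) on the shared representation plus a 128/128/32 skip
#' network on the raw markers, added elementwise and passed through a
#' 128/128 post-merge network before a single-output linear layer with
#' identity activation. Training: Adam, batch size 1024, learning rate 1e-3
#' with multistep decay (factor 0.1 at epochs 20/30/40), at most 100 epochs,
#' stochastic weight averaging and early stopping on the validation loss.
#'
#' @param n_endpoints number of endpoint heads (24 in the full analysis).
#' @param n_markers input dimension (default 168).
#' @param shared_widths,shared_dropout trunk layer widths and dropout rate.
#' @param head_mlp_widths,head_dropout head MLP widths and dropout rate
#'   (also applied in the skip and post-merge networks).
#' @param skip_widths skip-network widths; the terminal width must match the
#'   head MLP's terminal width (the two outputs are added).
#' @param post_merge_widths widths of the post-merge network.
#' @param batchnorm whether layers carry batch normalization.
#' @param batch_size,learning_rate,lr_gamma,lr_milestones,max_epochs Adam
#'   minibatch training schedule.
#' @param weight_averaging average weights of the epochs from `swa_start`
#'   onward and keep the averaged model if it validates better than the best
#'   single checkpoint.
#' @param swa_start first epoch entering the weight average (defaults to the
#'   first learning-rate step).
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return object of class `state_model_config`.
#' @export
state_model_config <- function(n_endpoints,
                               n_markers = 168L,
                               shared_widths = c(256L, 256L, 512L),
                               shared_dropout = 0.3,
                               head_mlp_widths = c(256L, 128L, 32L),
                               head_dropout = 0.6,
                               skip_widths = c(128L, 128L, 32L),
                               post_merge_widths = c(128L, 128L),
                               batchnorm = TRUE,
                               batch_size = 1024L,
                               learning_rate = 0.001,
                               lr_gamma = 0.1,
                               lr_milestones = c(20L, 30L, 40L),
                               max_epochs = 100L,
                               weight_averaging = TRUE,
                               swa_start = NULL,
                               early_stopping_patience = 10L,
                               seed = 1L) {
  stopifnot(n_endpoints >= 1L, n_markers >= 1L)
  widths <- c(shared_widths, head_mlp_widths, skip_widths, post_merge_widths)
  if (length(widths) && any(widths <= 0)) stop("all widths must be positive")
  for (d in c(shared_dropout, head_dropout))
    if (d < 0 || d >= 1) stop("dropout must be in [0, 1)")
  linear <- !length(widths)
  if (!linear) {
    if (!length(head_mlp_widths) || !length(skip_widths) ||
        tail1(head_mlp_widths) != tail1(skip_widths))
      stop("head MLP and skip network must end in equal widths (their ",
           "outputs are added)")
  }
  structure(list(
    n_endpoints = as.integer(n_endpoints), n_markers = as.integer(n_markers),
    shared_widths = as.integer(shared_widths), shared_dropout = shared_dropout,
    head_mlp_widths = as.integer(head_mlp_widths), head_dropout = head_dropout,
    skip_widths = as.integer(skip_widths),
    post_merge_widths = as.integer(post_merge_widths),
    batchnorm = batchnorm, batch_size = as.integer(batch_size),
    learning_rate = learning_rate, lr_gamma = lr_gamma,
    lr_milestones = as.integer(lr_milestones),
    max_epochs = as.integer(max_epochs),
    weight_averaging = weight_averaging,
    swa_start = as.integer(swa_start %||%
                             (if (length(lr_milestones)) lr_milestones[1]
                              else max(1L, max_epochs %/% 2L))),
    early_stopping_patience = as.integer(early_stopping_patience),
    linear = linear, seed = as.integer(seed)
  ), class = "state_model_config")
}

tail1 <- function(x) x[length(x)]

#' Desk-scale state model configuration
#'
#' A scaled-down profile of the same architecture for laptop-sized synthetic
#' cohorts: trunk 64/64, heads 32/16 with a 24/16 skip network and a single
#' 32-node post-merge layer, dropout 0.3 throughout, batch 512, at most 30
#' epochs with learning-rate steps at 15 and 22. Used by the smoke pipeline
#' and the recovery experiments.
#'
#' @inheritParams state_model_config
#' @param ... overrides passed through to [state_model_config()].
#' @return a `state_model_config`.
#' @export
desk_state_model_config <- function(n_endpoints, n_markers = 168L,
                                    seed = 1L, ...) {
  args <- list(
    n_endpoints = n_endpoints, n_markers = n_markers,
    shared_widths = c(64L, 64L), shared_dropout = 0.3,
    head_mlp_widths = c(32L, 16L), head_dropout = 0.3,
    skip_widths = c(24L, 16L), post_merge_widths = 32L,
    batch_size = 512L, lr_milestones = c(15L, 22L), max_epochs = 30L,
    swa_start = 15L, early_stopping_patience = 10L, seed = seed)
  do.call(state_model_config, utils::modifyList(args, list(...)))
}

#' Degenerate linear configuration
#'
#' No hidden layers, batch normalization or dropout: each endpoint head is a
#' single linear map from the markers (or covariates) to the state. Trained
#' to convergence on one endpoint this reduces to a classical Cox
#' proportional-hazards fit, which anchors the network loss to the classical
#' estimator.
#'
#' @inheritParams state_model_config
#' @param ... overrides passed through to [state_model_config()].
#' @return a `state_model_config`.
#' @export
linear_state_model_config <- function(n_endpoints, n_markers, seed = 1L, ...) {
  args <- list(
    n_endpoints = n_endpoints, n_markers = n_markers,
    shared_widths = integer(), shared_dropout = 0,
    head_mlp_widths = integer(), head_dropout = 0,
    skip_widths = integer(), post_merge_widths = integer(),
    batchnorm = FALSE, batch_size = 100000L, learning_rate = 0.05,
    lr_milestones = integer(), max_epochs = 400L, weight_averaging = FALSE,
    early_stopping_patience = 50L, seed = seed)
  do.call(state_model_config, utils::modifyList(args, list(...)))
}

#' Build an untrained state model
#'
#' The per-endpoint heads are stored feature-fused: layers that are
#' mathematically independent per endpoint (the head MLP, skip and post-merge
#' networks and the final linear map) are represented as block-diagonal dense
#' layers over endpoint-concatenated features, which keeps every endpoint's
#' parameters separate while letting the elementwise layers run across all
#' endpoints at once.
#'
#' @param config a [state_model_config()].
#' @return object of class `state_model` holding the trunk and fused head
#'   layer lists with randomly initialized weights.
#' @export
build_state_model <- function(config) {
  stopifnot(inherits(config, "state_model_config"))
  set.seed(config$seed)
  p <- config$n_markers
  E <- config$n_endpoints
  if (config$linear) {
    return(structure(list(
      trunk = NULL, mlp = NULL, skip = NULL, post = NULL,
      final = list(nn_dense(p, E, init_sd = 0.01)),
      config = config), class = "state_model"))
  }
  fused_mlp <- function(n_in, widths, dropout, shared_first) {
    layers <- list(); d <- n_in; first <- shared_first
    for (w in widths) {
      layers <- c(layers,
                  if (first) list(nn_dense(d, E * w, init_sd = sqrt(2 / d)))
                  else list(nn_bdense(d, w, E)))
      if (config$batchnorm) layers <- c(layers, list(nn_bn(E * w)))
      layers <- c(layers, list(nn_silu()))
      if (dropout > 0) layers <- c(layers, list(nn_dropout(dropout)))
      d <- w; first <- FALSE
    }
    layers
  }
  trunk <- nn_mlp(p, config$shared_widths, config$shared_dropout,
                  config$batchnorm)
  rep_dim <- tail1(config$shared_widths)
  merge_dim <- tail1(config$head_mlp_widths)
  post_out <- if (length(config$post_merge_widths))
    tail1(config$post_merge_widths) else merge_dim
  structure(list(
    trunk = trunk,
    mlp = fused_mlp(rep_dim, config$head_mlp_widths, config$head_dropout,
                    shared_first = TRUE),
    skip = fused_mlp(p, config$skip_widths, config$head_dropout,
                     shared_first = TRUE),
    post = fused_mlp(merge_dim, config$post_merge_widths,
                     config$head_dropout, shared_first = FALSE),
    final = list(nn_bdense(post_out, 1L, E, init_sd = 0.01)),
    config = config), class = "state_model")
}

model_parts <- function(model) {
  nm <- c("trunk", "mlp", "skip", "post", "final")
  nm[vapply(nm, function(x) length(model[[x]]) > 0, TRUE)]
}

#' Number of trainable parameters of a state model
#' @param model a `state_model` or `trained_state_model`.
#' @return integer parameter count (dense weights/biases and batch-norm
#'   scale/shift; running statistics are not trainable).
#' @export
count_parameters <- function(model) {
  if (inherits(model, "trained_state_model")) model <- model$model
  cnt <- function(layers) sum(vapply(layers, function(l)
    switch(l$type,
           dense = length(l$W) + length(l$b),
           bdense = length(l$W) + length(l$b),
           bn = length(l$gamma) + length(l$beta),
           0L), 0L))
  total <- 0L
  for (part in model_parts(model)) total <- total + cnt(model[[part]])
  as.integer(total)
}

# full multitask forward; mode in c("train", "infer", "stats")
model_forward <- function(model, X, mode = "infer") {
  caches <- list()
  if (model$config$linear) {
    ff <- seq_forward(model$final, X, mode)
    model$final <- ff$layers
    return(list(states = ff$out, caches = list(final = ff$caches),
                model = model))
  }
  tr <- seq_forward(model$trunk, X, mode)
  model$trunk <- tr$layers
  caches$trunk <- tr$caches
  fm <- seq_forward(model$mlp, tr$out, mode)
  model$mlp <- fm$layers; caches$mlp <- fm$caches
  fs <- seq_forward(model$skip, X, mode)
  model$skip <- fs$layers; caches$skip <- fs$caches
  merged <- fm$out + fs$out
  if (length(model$post)) {
    fp <- seq_forward(model$post, merged, mode)
    model$post <- fp$layers; caches$post <- fp$caches
    merged <- fp$out
  }
  ff <- seq_forward(model$final, merged, mode)
  model$final <- ff$layers; caches$final <- ff$caches
  list(states = ff$out, caches = caches, model = model)
}

# backward from per-endpoint state gradients (n x E); returns parameter
# gradients mirroring the model structure plus the input gradient
model_backward <- function(model, caches, dstates) {
  grads <- list()
  if (model$config$linear) {
    bb <- seq_backward(model$final, caches$final, dstates)
    return(list(grads = list(final = bb$grads), dX = bb$dX))
  }
  bf <- seq_backward(model$final, caches$final, dstates)
  grads$final <- bf$grads
  dmerged <- bf$dX
  if (length(model$post)) {
    bp <- seq_backward(model$post, caches$post, dmerged)
    grads$post <- bp$grads
    dmerged <- bp$dX
  }
  bm <- seq_backward(model$mlp, caches$mlp, dmerged)
  grads$mlp <- bm$grads
  bs <- seq_backward(model$skip, caches$skip, dmerged)
  grads$skip <- bs$grads
  bt <- seq_backward(model$trunk, caches$trunk, bm$dX)
  grads$trunk <- bt$grads
  list(grads = grads, dX = bs$dX + bt$dX)
}

model_predict_states <- function(model, X) {
  model_forward(model, X, mode = "infer")$states
}

# ---- training ---------------------------------------------------------------

model_adam_init <- function(model) {
  st <- list()
  for (part in model_parts(model)) st[[part]] <- adam_init(model[[part]])
  st
}

model_adam_step <- function(model, grads, state, lr, t) {
  for (part in model_parts(model)) {
    up <- adam_step_layers(model[[part]], grads[[part]], state[[part]], lr, t)
    model[[part]] <- up$layers
    state[[part]] <- up$state
  }
  list(model = model, state = state)
}

model_weights <- function(model) {
  w <- list()
  for (part in model_parts(model)) w[[part]] <- layers_weights(model[[part]])
  w
}
model_weights_add <- function(acc, w) {
  if (is.null(acc)) return(w)
  for (part in names(w)) acc[[part]] <- layers_axpy(acc[[part]], w[[part]])
  acc
}
model_set_weights <- function(model, w, scale = 1) {
  for (part in names(w))
    model[[part]] <- layers_set_weights(model[[part]], w[[part]], scale)
  model
}

multitask_batch_loss <- function(states, surv, rows) {
  E <- ncol(states)
  losses <- numeric(E); valid <- logical(E)
  dstates <- matrix(0, nrow(states), E)
  for (e in seq_len(E)) {
    cg <- cox_loss_grad(states[, e], surv$time[rows, e], surv$event[rows, e],
                        surv$eligible[rows, e])
    losses[e] <- cg$loss
    valid[e] <- cg$n_events > 0L
    dstates[, e] <- cg$grad
  }
  list(total = sum(losses[valid]), dstates = dstates, valid = valid)
}

eval_multitask_loss <- function(model, x, surv) {
  states <- model_predict_states(model, x)
  E <- ncol(states)
  total <- 0
  for (e in seq_len(E)) {
    l <- cox_loss_grad(states[, e], surv$time[, e], surv$event[, e],
                       surv$eligible[, e], want_grad = FALSE)
    if (l$n_events > 0L) total <- total + l$loss
  }
  total
}

#' Train a state model
#'
#' Minibatch Adam on the multitask Cox loss with the configured multistep
#' learning-rate decay, early stopping on the validation multitask loss and
#' optional stochastic weight averaging. The returned model is the best
#' validation checkpoint, or the weight-averaged model when it validates
#' better; batch-norm running statistics of the averaged model are refreshed
#' with one full pass over the training markers. Inference is deterministic
#' (dropout off, normalization in inference mode).
#'
#' @param model an untrained `state_model` from [build_state_model()].
#' @param train,valid lists with elements `x` (n x markers matrix, already
#'   normalized with training statistics), `time`, `event`, `eligible`
#'   (each n x endpoints matrices).
#' @param config the [state_model_config()] used to build the model.
#' @return object of class `trained_state_model` with the selected weights,
#'   the config echo, the per-epoch loss history and the selected
#'   checkpoint id.
#' @export
train_state_model <- function(model, train, valid, config = model$config) {
  stopifnot(inherits(model, "state_model"))
  if (length(intersect(rownames(train$x), rownames(valid$x))) > 0)
    stop("train and valid rows overlap")
  set.seed(config$seed)
  n <- nrow(train$x)
  adam <- model_adam_init(model)
  step <- 0L
  best_val <- Inf; best_w <- NULL; best_epoch <- NA_integer_
  patience_left <- config$early_stopping_patience
  swa_acc <- NULL; swa_n <- 0L
  history <- data.frame()
  epochs_run <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    epochs_run <- epoch
    lr <- config$learning_rate *
      config$lr_gamma^sum(epoch >= config$lr_milestones)
    perm <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      rows <- perm[(((b - 1L) * config$batch_size) + 1L):
                     min(b * config$batch_size, n)]
      fw <- model_forward(model, train$x[rows, , drop = FALSE], mode = "train")
      model <- fw$model
      bl <- multitask_batch_loss(fw$states, train, rows)
      if (!is.finite(bl$total))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", batch ", b)
      bw <- model_backward(model, fw$caches, bl$dstates)
      step <- step + 1L
      up <- model_adam_step(model, bw$grads, adam, lr, step)
      model <- up$model; adam <- up$state
      ep_loss <- ep_loss + bl$total
    }
    val_loss <- eval_multitask_loss(model, valid$x, valid)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / nb,
      valid_loss = val_loss))
    if (config$weight_averaging && epoch >= config$swa_start) {
      swa_acc <- model_weights_add(swa_acc, model_weights(model))
      swa_n <- swa_n + 1L
    }
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss
      best_w <- model_weights(model)
      best_epoch <- epoch
      patience_left <- config$early_stopping_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }
  selected <- sprintf("best_epoch_%d", best_epoch)
  final <- model_set_weights(model, best_w)
  # the best checkpoint's batch-norm running stats drifted after that epoch;
  # refresh them (and the SWA candidate's) with one full training pass
  final <- refresh_bn_stats(final, train$x)
  best_val <- eval_multitask_loss(final, valid$x, valid)
  if (config$weight_averaging && swa_n > 0L) {
    swa_model <- model_set_weights(model, swa_acc, scale = 1 / swa_n)
    swa_model <- refresh_bn_stats(swa_model, train$x)
    swa_val <- eval_multitask_loss(swa_model, valid$x, valid)
    if (swa_val < best_val) {
      final <- swa_model
      best_val <- swa_val
      selected <- sprintf("swa_epochs_%d_%d", config$swa_start, epochs_run)
    }
  }
  structure(list(
    model = final, config = config, history = history,
    best_valid_loss = best_val, selected_checkpoint = selected,
    epochs_run = epochs_run, normalization = NULL
  ), class = "trained_state_model")
}

refresh_bn_stats <- function(model, x) {
  if (model$config$linear || !model$config$batchnorm) return(model)
  model_forward(model, x, mode = "stats")$model
}

#' Fit the state model for one cross-validation fold
#'
#' Normalizes markers with the fold's training statistics (z-score per
#' marker), assembles per-endpoint outcome and eligibility matrices, builds
#' and trains the network, and stores the normalization statistics with the
#' trained model.
#'
#' @param cohort cohort table.
#' @param specs list of [endpoint_spec()] objects.
#' @param fold one fold of a [make_partitions()] plan.
#' @param config a [state_model_config()].
#' @return a `trained_state_model` with `normalization` (marker means/sds)
#'   and `fold_center` filled in.
#' @export
fit_fold_state_model <- function(cohort, specs, fold, config) {
  mcols <- marker_cols(attr(cohort, "n_markers"))
  rows_tr <- match(fold$train_ids, cohort$participant_id)
  rows_va <- match(fold$valid_ids, cohort$participant_id)
  M <- as.matrix(cohort[, mcols])
  mu <- colMeans(M[rows_tr, , drop = FALSE])
  sds <- apply(M[rows_tr, , drop = FALSE], 2, sd)
  norm <- list(means = mu, sds = sds, markers = mcols)
  surv_of <- function(rows) {
    list(x = normalize_markers(M[rows, , drop = FALSE], norm),
         time = sapply(specs, function(s) cohort[[paste0(s$name, "_time")]][rows]),
         event = sapply(specs, function(s) cohort[[paste0(s$name, "_event")]][rows]),
         eligible = sapply(specs, function(s)
           apply_endpoint_exclusions(cohort, s)[rows]))
  }
  model <- build_state_model(config)
  trained <- train_state_model(model, surv_of(rows_tr), surv_of(rows_va),
                               config)
  trained$normalization <- norm
  trained$fold_center <- fold$test_center_id
  trained
}

normalize_markers <- function(M, norm) {
  M <- sweep(M, 2, norm$means)
  sweep(M, 2, pmax(norm$sds, 1e-12), "/")
}

#' Metabolomic states for new participants
#'
#' Applies the stored marker normalization and a deterministic inference
#' forward pass.
#'
#' @param trained a `trained_state_model`.
#' @param markers n x markers numeric matrix of raw marker values (or a
#'   cohort table, from which the marker columns are taken).
#' @return n x endpoints state matrix (relative log-hazard scale).
#' @export
predict_states <- function(trained, markers) {
  stopifnot(inherits(trained, "trained_state_model"))
  if (is.data.frame(markers))
    markers <- as.matrix(markers[, trained$normalization$markers])
  if (ncol(markers) != trained$config$n_markers)
    stop("marker matrix has ", ncol(markers), " columns; the model expects ",
         trained$config$n_markers)
  if (!is.null(trained$normalization))
    markers <- normalize_markers(markers, trained$normalization)
  model_predict_states(trained$model, markers)
}

# ---- export / import --------------------------------------------------------

#' Export a trained state model as a portable JSON bundle
#'
#' Writes the full computation graph description (layer types, shapes,
#' weights, batch-norm running statistics), the marker normalization
#' statistics fitted at training and the config echo, so that a reloaded
#' artifact reproduces states on new data.
#'
#' @param trained a `trained_state_model`.
#' @param path output file (".json").
#' @return `path`, invisibly.
#' @export
export_state_model <- function(trained, path) {
  stopifnot(inherits(trained, "trained_state_model"))
  ser_layers <- function(layers) lapply(layers, function(l) {
    out <- l
    if (l$type %in% c("dense", "bdense"))
      out$W <- list(dim = dim(l$W) %||% c(length(l$W), 1L),
                    data = as.numeric(l$W))
    out
  })
  parts <- model_parts(trained$model)
  bundle <- list(
    format = "metstate-state-model-v1",
    config = unclass(trained$config),
    normalization = trained$normalization,
    endpoint_names = trained$endpoint_names,
    selected_checkpoint = trained$selected_checkpoint,
    parts = setNames(lapply(parts, function(p)
      ser_layers(trained$model[[p]])), parts)
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a state model exported with [export_state_model()]
#' @param path bundle path.
#' @return a `trained_state_model` (without training history).
#' @export
load_state_model <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
  if (!identical(bundle$format, "metstate-state-model-v1"))
    stop("not a metstate state-model bundle: ", path)
  deser_layers <- function(layers) lapply(layers, function(l) {
    l$type <- as.character(l$type)
    if (l$type %in% c("dense", "bdense")) {
      l$W <- array(as.numeric(unlist(l$W$data)), dim = unlist(l$W$dim))
      if (length(dim(l$W)) == 2L) l$W <- as.matrix(l$W)
      l$b <- as.numeric(unlist(l$b))
    } else if (l$type == "bn") {
      for (nm in c("gamma", "beta", "rmean", "rvar"))
        l[[nm]] <- as.numeric(unlist(l[[nm]]))
      l$momentum <- as.numeric(l$momentum); l$eps <- as.numeric(l$eps)
    } else if (l$type == "dropout") l$p <- as.numeric(l$p)
    l
  })
  cfg <- bundle$config
  config <- state_model_config(
    n_endpoints = cfg$n_endpoints, n_markers = cfg$n_markers,
    shared_widths = unlist(cfg$shared_widths) %||% integer(),
    shared_dropout = cfg$shared_dropout,
    head_mlp_widths = unlist(cfg$head_mlp_widths) %||% integer(),
    head_dropout = cfg$head_dropout,
    skip_widths = unlist(cfg$skip_widths) %||% integer(),
    post_merge_widths = unlist(cfg$post_merge_widths) %||% integer(),
    batchnorm = cfg$batchnorm, batch_size = cfg$batch_size,
    learning_rate = cfg$learning_rate, lr_gamma = cfg$lr_gamma,
    lr_milestones = unlist(cfg$lr_milestones) %||% integer(),
    max_epochs = cfg$max_epochs, weight_averaging = cfg$weight_averaging,
    swa_start = cfg$swa_start,
    early_stopping_patience = cfg$early_stopping_patience, seed = cfg$seed)
  model <- structure(c(
    list(trunk = NULL, mlp = NULL, skip = NULL, post = NULL, final = NULL),
    list(config = config)), class = "state_model")
  for (p in names(bundle$parts)) model[[p]] <- deser_layers(bundle$parts[[p]])
  norm <- bundle$normalization
  norm$means <- setNames(as.numeric(unlist(norm$means)),
                         unlist(norm$markers))
  norm$sds <- setNames(as.numeric(unlist(norm$sds)), unlist(norm$markers))
  norm$markers <- unlist(norm$markers)
  structure(list(model = model, config = config, history = NULL,
                 selected_checkpoint = bundle$selected_checkpoint,
                 endpoint_names = unlist(bundle$endpoint_names),
                 normalization = norm),
            class = "trained_state_model")
}

# ---- hyperparameter search --------------------------------------------------

#' Random hyperparameter search on one fold
#'
#' Uniform random draws from a declared space, each candidate trained on the
#' supplied training split and scored by validation multitask loss; the best
#' configuration is returned together with the full trial log.
#'
#' @param space named list; each element is a list/vector of candidate values
#'   for one [state_model_config()] argument.
#' @param budget number of trials.
#' @param seed RNG seed (same seed, same trial sequence).
#' @param train,valid data splits as in [train_state_model()].
#' @param base_config a `state_model_config` providing the fixed fields.
#' @return list with `best_config`, `best_loss` and a `trials` data.frame.
#' @export
hyperparameter_search <- function(space, budget, seed, train, valid,
                                  base_config) {
  if (!length(space)) stop("empty search space")
  stopifnot(budget >= 1L)
  set.seed(seed)
  draws <- lapply(seq_len(budget), function(i)
    lapply(space, function(vals) vals[[sample.int(length(vals), 1L)]]))
  trials <- data.frame(trial = seq_len(budget), valid_loss = NA_real_)
  trials$config <- I(draws)
  best <- NULL; best_loss <- Inf
  for (i in seq_len(budget)) {
    args <- unclass(base_config)
    args$linear <- NULL
    args[names(draws[[i]])] <- draws[[i]]
    cfg <- do.call(state_model_config, args)
    tr <- train_state_model(build_state_model(cfg), train, valid, cfg)
    trials$valid_loss[i] <- tr$best_valid_loss
    if (tr$best_valid_loss < best_loss) {
      best_loss <- tr$best_valid_loss
      best <- cfg
    }
  }
  list(best_config = best, best_loss = best_loss, trials = trials)
}
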