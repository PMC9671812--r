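# Per-sample metabolite attributions for each endpoint state.
#
# Backend: expected gradients — integrated gradients along the straight path
# from each background sample to the explained sample, averaged over the
# background set. The defining contract is local additivity: the attributions
# of a sample sum to the difference between its prediction and the mean
# background prediction. For a linear model the method is exact
# (phi_i = w_i * (x_i - mean background x_i)); for the smooth SiLU network the
# midpoint quadrature converges at O(steps^-2).

# gradient of one endpoint's state wrt the (normalized) marker inputs
model_input_gradient <- function(model, X, endpoint_idx) {
  fw <- model_forward(model, X, mode = "infer")
  E <- model$config$n_endpoints
  dstates <- matrix(0, nrow(X), E)
  dstates[, endpoint_idx] <- 1
  model_backward(model, fw$caches, dstates)$dX
}

#' Compute metabolite attributions for one endpoint
#'
#' @param trained a `trained_state_model`.
#' @param samples n x markers matrix of raw marker values to explain.
#' @param background m x markers matrix of raw background marker values
#'   (typically a random training subsample; default size 256 in the
#'   pipeline).
#' @param endpoint endpoint column index or name (when the trained model
#'   carries `endpoint_names`).
#' @param n_steps quadrature steps along each path (midpoint rule).
#' @param chunk_rows interpolated rows evaluated per block (memory control).
#' @return n x markers attribution matrix (state units) with attributes
#'   `predictions` (f(x) per sample), `background_mean_prediction`, and
#'   `endpoint`.
#' @export
compute_attributions <- function(trained, samples, background, endpoint,
                                 n_steps = 32L, chunk_rows = 8192L) {
  stopifnot(inherits(trained, "trained_state_model"))
  if (is.null(dim(background)) || nrow(background) == 0)
    stop("background must be a non-empty matrix")
  p <- trained$config$n_markers
  if (ncol(samples) != p || ncol(background) != p)
    stop("marker dimension mismatch: model expects ", p, " markers")
  eidx <- endpoint
  if (is.character(endpoint)) {
    enames <- trained$endpoint_names %||% stop("model carries no endpoint names")
    eidx <- match(endpoint, enames)
    if (is.na(eidx)) stop("unknown endpoint: ", endpoint)
  }
  norm <- trained$normalization
  Xs <- normalize_markers(as.matrix(samples), norm)
  Xb <- normalize_markers(as.matrix(background), norm)
  n <- nrow(Xs); m <- nrow(Xb)
  model <- trained$model

  preds <- as.numeric(model_predict_states(model, Xs)[, eidx])
  bg_preds <- as.numeric(model_predict_states(model, Xb)[, eidx])

  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  phi <- matrix(0, n, p)
  # grand loop over (sample, background, step) in row blocks
  per_sample <- m * n_steps
  samples_per_chunk <- max(1L, chunk_rows %/% per_sample)
  bg_rep <- Xb[rep(seq_len(m), times = n_steps), , drop = FALSE]
  alpha_rep <- rep(alphas, each = m)
  for (start in seq(1L, n, by = samples_per_chunk)) {
    sidx <- start:min(start + samples_per_chunk - 1L, n)
    blocks <- lapply(sidx, function(i) {
      diff <- matrix(Xs[i, ], per_sample, p, byrow = TRUE) - bg_rep
      list(pts = bg_rep + alpha_rep * diff, diff = diff)
    })
    pts <- do.call(rbind, lapply(blocks, `[[`, "pts"))
    g <- model_input_gradient(model, pts, eidx)
    for (k in seq_along(sidx)) {
      rows <- ((k - 1L) * per_sample + 1L):(k * per_sample)
      phi[sidx[k], ] <- colMeans(g[rows, , drop = FALSE] * blocks[[k]]$diff) *
        n_steps / n_steps # mean over m*steps equals mean_b mean_steps
    }
  }
  # attributions are wrt normalized inputs; they are already in state units
  colnames(phi) <- norm$markers
  attr(phi, "predictions") <- preds
  attr(phi, "background_mean_prediction") <- mean(bg_preds)
  attr(phi, "endpoint") <- endpoint
  phi
}

#' Check the additivity contract of an attribution matrix
#'
#' Relative residual `|sum(phi) - (f(x) - mean_b f)| / (|f(x) - mean_b f| + eps)`
#' per sample.
#'
#' @param phi attribution matrix from [compute_attributions()].
#' @param tol relative tolerance (default 0.05).
#' @param eps guard for near-zero prediction deviations.
#' @return list `(residuals, fraction_within)`.
#' @export
additivity_check <- function(phi, tol = 0.05, eps = 1e-3) {
  delta <- attr(phi, "predictions") - attr(phi, "background_mean_prediction")
  res <- abs(rowSums(phi) - delta) / (abs(delta) + eps)
  list(residuals = res, fraction_within = mean(res < tol))
}

#' Global metabolite importance
#'
#' Sum of absolute attributions per marker (and endpoint when given a list).
#'
#' @param attributions one attribution matrix, or a named list of matrices
#'   (one per endpoint).
#' @return named numeric vector, or a marker x endpoint matrix for a list.
#' @export
global_importance <- function(attributions) {
  if (is.list(attributions) && !is.matrix(attributions)) {
    if (!length(attributions)) stop("empty attribution set")
    cols <- lapply(attributions, function(a) colSums(abs(a)))
    do.call(cbind, cols)
  } else {
    if (!length(attributions)) stop("empty attribution tensor")
    colSums(abs(attributions))
  }
}

#' Percentile attribution profile for each marker
#'
#' Participants are ranked per marker by attribution value and aggregated in
#' equal-count percentile bins; each bin reports the mean attribution and the
#' mean raw marker value (used as the color dimension in profile plots).
#'
#' @param phi attribution matrix.
#' @param marker_values aligned matrix of raw marker values.
#' @param n_bins number of percentile bins (default 100).
#' @return data.frame `(marker, percentile, mean_attribution, mean_value)`.
#' @export
percentile_profile <- function(phi, marker_values, n_bins = 100L) {
  if (nrow(phi) < n_bins)
    stop("need at least n_bins participants (", n_bins, ")")
  if (!all(dim(phi) == dim(marker_values)))
    stop("marker values not aligned with attributions")
  out <- lapply(seq_len(ncol(phi)), function(j) {
    ord <- order(phi[, j])
    b <- score_bins(seq_along(ord), n_bins)
    data.frame(marker = colnames(phi)[j] %||% j,
               percentile = sort(unique(b)),
               mean_attribution = as.numeric(
                 tapply(phi[ord, j], b, mean)),
               mean_value = as.numeric(
                 tapply(marker_values[ord, j], b, mean)))
  })
  do.call(rbind, out)
}

#' High-impact attribution mask
#'
#' Flags attributions below the lower or above the upper empirical percentile
#' of the pooled per-endpoint attribution distribution (default 1%/99%). The
#' numeric interval is data-derived; a fixed interval (e.g. outside
#' (-0.2, 0.2)) can be supplied instead via `fixed_bounds`.
#'
#' @param phi attribution matrix.
#' @param bounds lower/upper percentile bounds in (0,1).
#' @param reference optional attribution values from which the percentiles
#'   are computed (defaults to `phi` itself).
#' @param fixed_bounds optional numeric `c(lo, hi)` overriding the percentile
#'   rule.
#' @return logical matrix of the same shape, with attribute `interval`.
#' @export
high_impact_mask <- function(phi, bounds = c(0.01, 0.99), reference = NULL,
                             fixed_bounds = NULL) {
  if (is.null(fixed_bounds)) {
    stopifnot(length(bounds) == 2L, bounds[1] > 0, bounds[2] < 1,
              bounds[1] < bounds[2])
    ref <- as.numeric(reference %||% phi)
    if (max(ref) == min(ref)) stop("degenerate attribution distribution")
    iv <- unname(quantile(ref, bounds))
  } else iv <- fixed_bounds
  mask <- phi < iv[1] | phi > iv[2]
  attr(mask, "interval") <- iv
  mask
}

#' 2-D embedding of attribution profiles
#'
#' UMAP of the per-participant attribution vectors for one endpoint,
#' deterministic for a fixed seed (single-threaded SGD).
#'
#' @param phi attribution matrix (needs at least `n_neighbors + 1` rows).
#' @param seed RNG seed.
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @return n x 2 coordinate matrix.
#' @export
embed_attributions <- function(phi, seed = 1L, n_neighbors = 15L) {
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("embed_attributions requires the uwot package")
  if (nrow(phi) <= n_neighbors)
    stop("need more rows than n_neighbors (", n_neighbors, ")")
  set.seed(seed)
  coords <- uwot::umap(as.matrix(phi), n_neighbors = n_neighbors,
                       n_threads = 1, n_sgd_threads = 1, batch = FALSE)
  colnames(coords) <- c("umap_1", "umap_2")
  coords
}
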