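# Training objective: weighted cross-entropy, prior-alignment similarity
# loss, and their lambda-combination.

#' Inverse-count class weights
#'
#' Weight of class k is `1 / count_k`; under-represented classes get larger
#' weights. No renormalization by default.
#'
#' @param class_counts Integer vector of per-class sample counts (all >= 1).
#' @param normalize If `TRUE`, rescale the weights to mean 1.
#' @return A `weight_vector`: list with `weights` and `class_counts`.
#' @export
class_weights <- function(class_counts, normalize = FALSE) {
  class_counts <- as.integer(class_counts)
  if (any(class_counts < 1))
    stop("class_weights: zero-count class present; drop the class before ",
         "computing weights")
  w <- 1 / class_counts
  if (normalize) w <- w / mean(w)
  structure(list(weights = w, class_counts = class_counts),
            class = "weight_vector")
}

#' Loss configuration
#'
#' @param lambda Non-negative weight of the similarity loss in the combined
#'   objective (default `5e-5`).
#' @param distance Distance of the similarity loss: `"L2"` (Euclidean norm,
#'   default) or `"L2sq"` (squared norm).
#' @param reduction `"mean"` (batch mean, default) or `"sum"` (the plain
#'   per-equation sum over the minibatch).
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda = 5e-5, distance = c("L2", "L2sq"),
                        reduction = c("mean", "sum")) {
  distance <- match.arg(distance)
  reduction <- match.arg(reduction)
  stopifnot(is.finite(lambda), lambda >= 0)
  structure(list(lambda = lambda, distance = distance, reduction = reduction),
            class = "loss_config")
}

as_weights <- function(w, K) {
  v <- if (inherits(w, "weight_vector")) w$weights else as.numeric(w)
  if (length(v) != K)
    stop("weights length ", length(v), " does not match K = ", K)
  if (any(v <= 0)) stop("class weights must be positive")
  v
}

#' Weighted cross-entropy loss
#'
#' `-sum_i w_{y_i} log p_i[y_i]`, optionally batch-averaged. `labels` may also
#' be an N x K matrix of soft targets (as produced by Mixup), in which case
#' the loss generalizes to `-sum_i sum_k w_k y_{ik} log p_{ik}`.
#'
#' @param probs_batch N x K matrix of class probabilities (rows sum to 1).
#' @param labels Integer vector in 0..K-1, or an N x K soft-target matrix.
#' @param w A [class_weights()] result or positive numeric vector of length K.
#' @param reduction `"mean"` or `"sum"`.
#' @param floor Clamp applied inside the log for numerical safety.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs_batch, labels, w,
                                   reduction = c("mean", "sum"),
                                   floor = 1e-12) {
  reduction <- match.arg(reduction)
  probs_batch <- rbind(probs_batch)
  K <- ncol(probs_batch)
  N <- nrow(probs_batch)
  wv <- as_weights(w, K)
  Y <- soft_targets(labels, N, K)
  if (any(probs_batch[Y > 0] < floor))
    warning("weighted_cross_entropy: probability below clamp floor at a ",
            "true label; clamping")
  lp <- log(pmax(probs_batch, floor))
  per_sample <- -rowSums(Y * sweep(lp, 2, wv, "*"))
  if (reduction == "mean") mean(per_sample) else sum(per_sample)
}

soft_targets <- function(labels, N, K) {
  if (is.matrix(labels)) {
    stopifnot(nrow(labels) == N, ncol(labels) == K)
    return(labels)
  }
  labels <- as.integer(labels)
  if (any(labels < 0 | labels >= K))
    stop("labels must lie in 0..K-1")
  Y <- matrix(0, N, K)
  Y[cbind(seq_len(N), labels + 1L)] <- 1
  Y
}

# Gradient of weighted cross-entropy wrt the logits, for softmax outputs.
# For soft targets y: d/dz = (sum_k w_k y_k) * p - w * y, per sample.
wce_logit_grad <- function(probs_batch, labels, w,
                           reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  probs_batch <- rbind(probs_batch)
  K <- ncol(probs_batch); N <- nrow(probs_batch)
  wv <- as_weights(w, K)
  Y <- soft_targets(labels, N, K)
  WY <- sweep(Y, 2, wv, "*")
  G <- probs_batch * rowSums(WY) - WY
  if (reduction == "mean") G / N else G
}

#' Prior-alignment similarity loss
#'
#' Sum over samples i and classes k of the distance between the learnt
#' attention map `M_{i,k}` and the class prior `SHAP_k`; the default distance
#' is the Euclidean (L2) norm over all voxels. Every class channel is coupled
#' to its class prior regardless of the sample's label.
#'
#' @param attention_batch List of N attention arrays (each K x D' x H' x W',
#'   or an `attention_stack`).
#' @param priors A [prior_set()] already resampled to the attention grid, or a
#'   list of K arrays on that grid.
#' @param config A [loss_config()]; uses `distance` and `reduction`.
#' @param labels Optional integer vector (0-based, length N): when given,
#'   only each sample's ground-truth class channel is aligned with its prior
#'   instead of summing over all K classes.
#' @return Scalar loss.
#' @export
similarity_loss <- function(attention_batch, priors, config = loss_config(),
                            labels = NULL) {
  pr <- prior_arrays(priors)
  K <- length(pr)
  total <- 0
  N <- length(attention_batch)
  if (!is.null(labels)) stopifnot(length(labels) == N)
  for (i in seq_len(N)) {
    M <- attention_maps(attention_batch[[i]])
    if (dim(M)[1] != K)
      stop("similarity_loss: attention has ", dim(M)[1],
           " channels but priors have ", K, " classes")
    ks <- if (is.null(labels)) seq_len(K) else labels[i] + 1L
    for (k in ks) {
      if (!all(dim(M)[2:4] == dim(pr[[k]])))
        stop("similarity_loss: attention grid (",
             paste(dim(M)[2:4], collapse = "x"),
             ") does not match prior grid (",
             paste(dim(pr[[k]]), collapse = "x"),
             "); resample the priors with resample_prior()")
      diff <- array(M[k, , , ], dim(M)[2:4]) - pr[[k]]
      nrm2 <- sum(diff * diff)
      total <- total + if (config$distance == "L2") sqrt(nrm2) else nrm2
    }
  }
  if (config$reduction == "mean") total / N else total
}

attention_maps <- function(x) {
  if (inherits(x, "attention_stack")) x$maps else x
}

prior_arrays <- function(priors) {
  if (inherits(priors, "prior_set")) priors$priors else priors
}

# Gradient of the similarity loss wrt one sample's attention maps:
# per (i,k) block (M - P)/||M - P|| for the L2 distance (0 at M == P),
# or 2 (M - P) for the squared distance.
sim_attention_grad <- function(M, priors, config = loss_config(), n_batch = 1,
                               label = NULL) {
  pr <- prior_arrays(priors)
  M <- attention_maps(M)
  G <- array(0, dim(M))
  ks <- if (is.null(label)) seq_along(pr) else label + 1L
  for (k in ks) {
    diff <- array(M[k, , , ], dim(M)[2:4]) - pr[[k]]
    if (config$distance == "L2") {
      nrm <- sqrt(sum(diff * diff))
      if (nrm > 0) G[k, , , ] <- diff / nrm
    } else {
      G[k, , , ] <- 2 * diff
    }
  }
  if (config$reduction == "mean") G / n_batch else G
}

#' Combined training loss
#'
#' `total = wce + lambda * sim`.
#'
#' @param wce Scalar weighted cross-entropy value.
#' @param sim Scalar similarity-loss value.
#' @param config A [loss_config()]; supplies `lambda`.
#' @return Scalar loss.
#' @export
total_loss <- function(wce, sim, config = loss_config()) {
  stopifnot(is.finite(wce), is.finite(sim))
  wce + config$lambda * sim
}
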