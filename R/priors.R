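# Class-wise saliency priors: per-voxel Shapley-value attribution of class
# logits (expected-gradients sampling approximation, with an exhaustive-subset
# oracle for tiny inputs), averaged over correctly predicted training samples
# per class, scaled to [-1, 1], and resampled to the attention grid.

#' Attribution settings
#'
#' @param n_samples Number of path samples of the expected-gradients
#'   approximation.
#' @param seed Seed of the sampling stream.
#' @return An `attribution_config` list.
#' @export
attribution_config <- function(n_samples = 32, seed = 1) {
  stopifnot(n_samples >= 1)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 backend = "expected_gradients"),
            class = "attribution_config")
}

# Model interface used by the attribution backend: logits and the gradient of
# one class logit with respect to the input volume.
model_logits <- function(model, x) UseMethod("model_logits")
model_input_grad <- function(model, x, class) UseMethod("model_input_grad")

#' @export
model_logits.dgsal_model <- function(model, x) forward_model(model, x)$logits

#' @export
model_input_grad.dgsal_model <- function(model, x, class) {
  fwd <- forward_model(model, x)
  K <- model$config$n_classes
  dlog <- numeric(K)
  dlog[class + 1L] <- 1
  backward_model(model, fwd, dlog, want_dinput = TRUE)$dinput
}

#' A single-linear-layer test model
#'
#' `logit = sum_v w_v x_v + b`, exposed through the same interface as the full
#' classifier so attribution backends can be validated against the closed-form
#' Shapley values of linear models.
#'
#' @param weights Numeric array/vector of per-voxel weights.
#' @param bias Scalar intercept.
#' @return A `linear_model` object.
#' @export
linear_model <- function(weights, bias = 0) {
  structure(list(w = weights, b = bias), class = "linear_model")
}

#' @export
model_logits.linear_model <- function(model, x) sum(model$w * x) + model$b

#' @export
model_input_grad.linear_model <- function(model, x, class) model$w

#' Shapley attribution of one sample
#'
#' Per-voxel Shapley-value attribution of the target-class logit relative to a
#' reference volume, by the expected-gradients sampling approximation:
#' `phi_v = (x_v - ref_v) * mean_s grad_v(ref + alpha_s (x - ref))` with the
#' path positions `alpha_s` drawn by jittered stratified sampling on
#' `(0, 1)`. Satisfies completeness approximately: the attributions
#' sum to `logit(x) - logit(ref)` up to Monte Carlo error, and exactly for
#' linear models.
#'
#' @param model A `dgsal_model` (or any object implementing the internal model
#'   interface, e.g. [linear_model()]).
#' @param sample A `volume_sample`, or a raw 3D array.
#' @param reference Baseline volume of the same dims (default all zeros).
#' @param target_class Class whose logit is attributed (0-based).
#' @param config An [attribution_config()].
#' @return A `saliency_volume`: list with `values` (3D array), `target_class`,
#'   `subject_id`.
#' @export
attribute_sample <- function(model, sample, reference = NULL, target_class = 0,
                             config = attribution_config()) {
  x <- if (inherits(sample, "volume_sample")) sample$volume else sample
  sid <- if (inherits(sample, "volume_sample")) sample$subject_id else ""
  if (is.null(reference)) reference <- array(0, dim(x))
  if (!all(dim(reference) == dim(x)))
    stop("attribute_sample: reference dims do not match sample dims")
  # jittered stratified path positions: one uniform draw per stratum keeps
  # the estimator unbiased while cutting Monte Carlo variance sharply
  n <- config$n_samples
  alphas <- with_seed(config$seed, (seq_len(n) - stats::runif(n)) / n)
  diff <- x - reference
  acc <- array(0, dim(x))
  for (a in alphas) {
    g <- model_input_grad(model, reference + a * diff, target_class)
    acc <- acc + g
  }
  attr_vals <- diff * (acc / length(alphas))
  nbad <- sum(!is.finite(attr_vals))
  if (nbad > 0)
    stop("attribute_sample: ", nbad, " non-finite attribution voxels")
  structure(list(values = attr_vals, target_class = as.integer(target_class),
                 subject_id = sid),
            class = "saliency_volume")
}

#' Exact Shapley values by exhaustive subset enumeration
#'
#' Independent oracle for tiny inputs (<= ~14 features): enumerates all 2^n
#' coalitions, where a coalition takes its member voxels from `x` and the rest
#' from `reference`.
#'
#' @param f Value function: takes a numeric vector, returns a scalar.
#' @param x Numeric vector of feature values.
#' @param reference Baseline vector of the same length.
#' @return Numeric vector of Shapley values, one per feature.
#' @export
shapley_exhaustive <- function(f, x, reference = rep(0, length(x))) {
  n <- length(x)
  if (n > 20) stop("shapley_exhaustive: too many features (", n, ")")
  n_sub <- 2^n
  vals <- numeric(n_sub)
  sizes <- integer(n_sub)
  for (m in 0:(n_sub - 1)) {
    members <- as.logical(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))))
    z <- ifelse(members, x, reference)
    vals[m + 1] <- f(z)
    sizes[m + 1] <- sum(members)
  }
  wgt <- function(s) factorial(s) * factorial(n - s - 1) / factorial(n)
  phi <- numeric(n)
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    for (m in 0:(n_sub - 1)) {
      if (bitwAnd(m, bit) == 0) {
        s <- sizes[m + 1]
        phi[v] <- phi[v] + wgt(s) * (vals[bitwOr(m, bit) + 1] - vals[m + 1])
      }
    }
  }
  phi
}

#' Per-class averaged saliency priors
#'
#' Runs inference over the dataset, keeps only correctly predicted samples
#' (argmax ties broken toward the lowest class index), attributes each kept
#' sample toward its true class, averages the attributions per class, and
#' scales each class prior to `[-1, 1]` by its maximum absolute value.
#'
#' @param model The trained stage-1 baseline (`dgsal_model`).
#' @param dataset Non-empty list of `volume_sample`s.
#' @param config An [attribution_config()].
#' @param reference Baseline volume (default zeros).
#' @param fallback_all If `TRUE`, a class with no correct predictions falls
#'   back to all samples of that class instead of failing.
#' @param scale_mode `"maxabs"` (default) or `"none"`.
#' @param source_model_id Identifier recorded in the output.
#' @return A `prior_set`: list with `priors` (K 3D arrays), `grid`,
#'   `scale_mode`, `n_samples_used` (length-K integer), `source_model_id`.
#' @export
build_class_priors <- function(model, dataset, config = attribution_config(),
                               reference = NULL, fallback_all = FALSE,
                               scale_mode = c("maxabs", "none"),
                               source_model_id = "baseline") {
  scale_mode <- match.arg(scale_mode)
  if (!length(dataset)) stop("build_class_priors: empty dataset")
  K <- model$config$n_classes
  labels <- vapply(dataset, function(s) s$label, 0L)
  preds <- vapply(dataset, function(s) {
    which.max(model_logits(model, s$volume)) - 1L
  }, 0L)
  keep <- preds == labels
  use_idx <- vector("list", K)
  for (k in 0:(K - 1)) {
    idx <- which(labels == k & keep)
    if (!length(idx)) {
      if (!fallback_all)
        stop("build_class_priors: class ", k, " has zero correct ",
             "predictions; use fallback_all = TRUE to average over all its ",
             "samples instead")
      idx <- which(labels == k)
      if (!length(idx))
        stop("build_class_priors: class ", k, " absent from dataset")
    }
    use_idx[[k + 1]] <- idx
  }
  dims <- dim(dataset[[1]]$volume)
  priors <- vector("list", K)
  n_used <- integer(K)
  for (k in 0:(K - 1)) {
    acc <- array(0, dims)
    idx <- use_idx[[k + 1]]
    for (j in seq_along(idx)) {
      s <- dataset[[idx[j]]]
      cfg_j <- config
      cfg_j$seed <- derive_seed(config$seed, "attr", idx[j])
      sal <- attribute_sample(model, s, reference, target_class = k,
                              config = cfg_j)
      acc <- acc + sal$values
    }
    pr <- acc / length(idx)
    if (scale_mode == "maxabs") pr <- scale_maxabs(pr)
    priors[[k + 1]] <- pr
    n_used[k + 1] <- length(idx)
  }
  prior_set(priors, scale_mode = scale_mode, n_samples_used = n_used,
            source_model_id = source_model_id)
}

scale_maxabs <- function(x) {
  m <- max(abs(x))
  if (m > 0) x / m else x
}

#' Container for class-wise saliency priors
#'
#' @param priors List of K 3D arrays on a common grid.
#' @param scale_mode `"maxabs"` or `"none"`.
#' @param n_samples_used Integer vector: samples averaged per class.
#' @param source_model_id Identifier of the model the priors came from.
#' @return A `prior_set` list.
#' @export
prior_set <- function(priors, scale_mode = "maxabs",
                      n_samples_used = rep(1L, length(priors)),
                      source_model_id = "") {
  stopifnot(length(priors) >= 1)
  grid <- dim(priors[[1]])
  for (p in priors) stopifnot(all(dim(p) == grid))
  structure(list(priors = priors, grid = as.integer(grid),
                 scale_mode = scale_mode,
                 n_samples_used = as.integer(n_samples_used),
                 source_model_id = source_model_id),
            class = "prior_set")
}

#' Resample a prior onto a target grid
#'
#' Trilinear interpolation; reconciles input-resolution priors with the
#' feature-resolution attention grid. Constant volumes map to the same
#' constant; an identity target is returned bit-identically.
#'
#' @param prior A 3D array.
#' @param target Target dims (`dim3` or length-3 vector).
#' @return A 3D array with dims `target`.
#' @export
resample_prior <- function(prior, target) resample_trilinear(prior, target)

#' Resample every prior of a set onto a target grid
#'
#' @param priors A `prior_set`.
#' @param target Target dims.
#' @return A `prior_set` on the target grid.
#' @export
resample_prior_set <- function(priors, target) {
  out <- priors
  out$priors <- lapply(priors$priors, resample_prior, target = target)
  out$grid <- as.integer(target)
  out
}

#' Persist / load a prior set as NIfTI volumes plus a JSON sidecar
#'
#' One `.nii.gz` per class (`prior_class<k>.nii.gz`) and `priors.json` with
#' the scale mode, per-class sample counts and source model id.
#'
#' @param priors A `prior_set`.
#' @param dir Output directory (created if missing).
#' @return `read_prior_set` returns the `prior_set`.
#' @export
write_prior_set <- function(priors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(priors$priors))
    write_volume(priors$priors[[k]],
                 file.path(dir, sprintf("prior_class%d.nii.gz", k - 1L)))
  meta <- list(scale_mode = priors$scale_mode,
               n_samples_used = priors$n_samples_used,
               source_model_id = priors$source_model_id,
               grid = priors$grid)
  jsonlite::write_json(meta, file.path(dir, "priors.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_prior_set
#' @export
read_prior_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "priors.json"),
                              simplifyVector = TRUE)
  K <- length(meta$n_samples_used)
  priors <- lapply(seq_len(K) - 1L, function(k) {
    read_volume(file.path(dir, sprintf("prior_class%d.nii.gz", k)))$volume
  })
  prior_set(priors, scale_mode = meta$scale_mode,
            n_samples_used = meta$n_samples_used,
            source_model_id = meta$source_model_id)
}
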