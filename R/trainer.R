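# Two-stage training orchestration: stratified cross-validation splits,
# augmentation, gradient-accumulated Adam updates, the Mixup comparison
# baseline, and baseline -> priors -> guided training.

#' Augmentation policy
#'
#' Transforms applied, in order and each with `per_transform_probability`, to
#' every training sample: gamma contrast adjustment, smooth multiplicative
#' bias field, random spatial crop followed by trilinear upsampling back to
#' the input grid, then deterministic min-max intensity scaling to `[0, 1]`.
#'
#' @param contrast_range Range of the gamma exponent.
#' @param bias_field_amplitude Amplitude of the random bias field.
#' @param bias_field_smoothness Gaussian length-scale of the bias field
#'   (voxels).
#' @param crop_fraction Side-length fraction of the random crop, in `(0, 1]`.
#' @param upsample_to Grid to upsample the crop to (`NULL` = original dims).
#' @param intensity_scale_to_unit Apply final min-max scaling (always
#'   deterministic, not gated by the probability).
#' @param per_transform_probability Probability each random transform fires.
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(contrast_range = c(0.8, 1.25),
                           bias_field_amplitude = 0.1,
                           bias_field_smoothness = 6,
                           crop_fraction = 0.9,
                           upsample_to = NULL,
                           intensity_scale_to_unit = TRUE,
                           per_transform_probability = 0.5) {
  stopifnot(crop_fraction > 0, crop_fraction <= 1,
            per_transform_probability >= 0, per_transform_probability <= 1)
  structure(list(contrast_range = contrast_range,
                 bias_field_amplitude = bias_field_amplitude,
                 bias_field_smoothness = bias_field_smoothness,
                 crop_fraction = crop_fraction,
                 upsample_to = upsample_to,
                 intensity_scale_to_unit = intensity_scale_to_unit,
                 per_transform_probability = per_transform_probability),
            class = "augment_policy")
}

#' Training configuration
#'
#' Defaults follow the study protocol: 60 epochs of 200 weight updates, a
#' micro-batch of 2 with gradient accumulation over 8 steps (effective batch
#' 16), 5-fold stratified cross-validation with a 3:1:1
#' train/validation/test split.
#'
#' @param epochs,steps_per_epoch Number of epochs and weight updates per
#'   epoch.
#' @param micro_batch Samples per forward/backward pass.
#' @param accumulation_steps Micro-batches averaged into one update.
#' @param learning_rate Adam learning rate.
#' @param lr_schedule `"constant"` (default) or `"step"`: step decay
#'   multiplies the rate by 0.3 after 60% and again after 85% of the epochs,
#'   which stabilizes late training on small cohorts.
#' @param k_folds Number of cross-validation folds.
#' @param split_ratio Train/validation/test ratio (normalized internally).
#' @param loss A [loss_config()].
#' @param augmentation An [augment_policy()] or `NULL` to disable.
#' @param seed Seed of the data-order and augmentation streams.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 60, steps_per_epoch = 200, micro_batch = 2,
                         accumulation_steps = 8, learning_rate = 1e-3,
                         lr_schedule = c("constant", "step"),
                         k_folds = 5, split_ratio = c(3, 1, 1),
                         loss = loss_config(), augmentation = NULL,
                         seed = 1) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(epochs >= 0, steps_per_epoch >= 1, micro_batch >= 1,
            accumulation_steps >= 1, learning_rate > 0, k_folds >= 2,
            length(split_ratio) == 3, all(split_ratio > 0))
  structure(list(epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 micro_batch = as.integer(micro_batch),
                 accumulation_steps = as.integer(accumulation_steps),
                 learning_rate = learning_rate,
                 lr_schedule = lr_schedule,
                 k_folds = as.integer(k_folds),
                 split_ratio = split_ratio / sum(split_ratio),
                 loss = loss, augmentation = augmentation,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified k-fold split with train/validation/test roles
#'
#' Subjects of each class are dealt round-robin into k folds after a seeded
#' shuffle, so per-fold class counts differ from exact proportionality by at
#' most one subject per class. For cross-validation run `f`, the test role is
#' fold `f`, validation the next fold (cyclically), and training the rest —
#' realizing the configured split ratio for `k = sum(ratio)` folds.
#'
#' @param labels Named integer vector: subject id -> class (0-based).
#' @param k Number of folds.
#' @param split_ratio Train/val/test ratio (default 3:1:1).
#' @param seed Seed of the shuffle.
#' @return A `fold_assignment`: list with `fold_of_subject` (named integer in
#'   0..k-1), `k`, and `n_val_folds`/`n_test_folds`.
#' @export
stratified_folds <- function(labels, k, split_ratio = c(3, 1, 1), seed = 1) {
  stopifnot(!is.null(names(labels)), k >= 2)
  r <- split_ratio / sum(split_ratio)
  n_test <- max(1L, round(k * r[3]))
  n_val <- max(1L, round(k * r[2]))
  if (n_test + n_val >= k)
    stop("stratified_folds: split ratio leaves no training folds for k = ", k)
  fold <- integer(length(labels))
  names(fold) <- names(labels)
  for (cl in sort(unique(labels))) {
    ids <- names(labels)[labels == cl]
    if (length(ids) < k)
      stop("stratified_folds: class ", cl, " has ", length(ids),
           " members, fewer than k = ", k)
    ids <- with_seed(derive_seed(seed, "fold", cl), sample(ids))
    fold[ids] <- (seq_along(ids) - 1L) %% k
  }
  structure(list(fold_of_subject = fold, k = as.integer(k),
                 n_val_folds = n_val, n_test_folds = n_test),
            class = "fold_assignment")
}

#' Subject roles for one cross-validation run
#'
#' @param assignment A [stratified_folds()] result.
#' @param fold Run index in 0..k-1.
#' @return List of subject-id character vectors `train`, `val`, `test`.
#' @export
fold_roles <- function(assignment, fold) {
  k <- assignment$k
  stopifnot(fold >= 0, fold < k)
  test_f <- (fold + seq_len(assignment$n_test_folds) - 1L) %% k
  val_f <- (fold + assignment$n_test_folds +
              seq_len(assignment$n_val_folds) - 1L) %% k
  fo <- assignment$fold_of_subject
  list(train = names(fo)[!(fo %in% c(test_f, val_f))],
       val = names(fo)[fo %in% val_f],
       test = names(fo)[fo %in% test_f])
}

#' Apply the augmentation policy to one sample
#'
#' @param sample A `volume_sample`.
#' @param policy An [augment_policy()].
#' @param seed Seed; output is a pure function of `(sample, policy, seed)`.
#' @return The augmented `volume_sample` (label, domain, metadata unchanged).
#' @export
augment <- function(sample, policy, seed) {
  x <- sample$volume
  d <- dim(x)
  rng <- with_seed(seed, list(u = stats::runif(3),
                              gamma = stats::runif(1, policy$contrast_range[1],
                                                   policy$contrast_range[2]),
                              bias_seed = sample.int(2^30, 1),
                              corner = stats::runif(3)))
  if (rng$u[1] < policy$per_transform_probability) {
    x <- pmax(x, 0)^rng$gamma
  }
  if (rng$u[2] < policy$per_transform_probability &&
      policy$bias_field_amplitude > 0) {
    bf <- with_seed(rng$bias_seed, array(stats::rnorm(prod(d)), d))
    bf <- gaussian_smooth3(bf, policy$bias_field_smoothness)
    bf <- bf / max(stats::sd(bf), 1e-12)
    x <- x * (1 + policy$bias_field_amplitude * bf)
  }
  if (rng$u[3] < policy$per_transform_probability && policy$crop_fraction < 1) {
    cd <- pmax(2L, as.integer(round(policy$crop_fraction * d)))
    if (any(cd < 2)) stop("augment: crop smaller than 2 voxels per axis")
    start <- 1L + as.integer(floor(rng$corner * (d - cd + 1 - 1e-9)))
    x <- x[start[1] + seq_len(cd[1]) - 1L, start[2] + seq_len(cd[2]) - 1L,
           start[3] + seq_len(cd[3]) - 1L, drop = FALSE]
    target <- if (is.null(policy$upsample_to)) d else as.integer(policy$upsample_to)
    x <- resample_trilinear(x, target)
  }
  if (policy$intensity_scale_to_unit) x <- minmax01(x)
  out <- sample
  out$volume <- x
  out
}

#' Mixup a batch of volumes and one-hot labels
#'
#' Each sample is convexly combined with a randomly chosen partner using
#' `lambda_mix ~ Beta(alpha, alpha)`, drawn per pair; labels are mixed with
#' the identical weight.
#'
#' @param volumes List of 3D arrays (length >= 2).
#' @param labels_onehot N x K matrix of one-hot (or soft) labels.
#' @param alpha Beta concentration (> 0); 0.2 in the study protocol.
#' @param seed Seed.
#' @param lambda_fix Optional fixed mixing weight overriding the Beta draw
#'   (used in tests).
#' @return List with mixed `volumes` and `labels`.
#' @export
mixup_batch <- function(volumes, labels_onehot, alpha = 0.2, seed = 1,
                        lambda_fix = NULL) {
  N <- length(volumes)
  if (N < 2) stop("mixup_batch: batch size must be >= 2")
  if (alpha <= 0) stop("mixup_batch: alpha must be > 0")
  drawn <- with_seed(seed, list(partner = sample.int(N),
                                lam = stats::rbeta(N, alpha, alpha)))
  lam <- if (is.null(lambda_fix)) drawn$lam else rep(lambda_fix, N)
  out_v <- vector("list", N)
  out_y <- labels_onehot
  for (i in seq_len(N)) {
    j <- drawn$partner[i]
    out_v[[i]] <- lam[i] * volumes[[i]] + (1 - lam[i]) * volumes[[j]]
    out_y[i, ] <- lam[i] * labels_onehot[i, ] + (1 - lam[i]) * labels_onehot[j, ]
  }
  list(volumes = out_v, labels = out_y)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mh / (sqrt(vh) + eps))
}

# Seeded shuffled cycling sampler over sample indices: reshuffles whenever the
# epoch of indices is exhausted, so "steps per epoch" is decoupled from the
# dataset size.
make_sampler <- function(n, seed) {
  env <- new.env(parent = emptyenv())
  env$order <- integer(0)
  env$pos <- 0L
  env$cycle <- 0L
  function(m) {
    out <- integer(0)
    while (length(out) < m) {
      if (env$pos >= length(env$order)) {
        env$cycle <- env$cycle + 1L
        env$order <- with_seed(derive_seed(seed, "shuffle", env$cycle),
                               sample.int(n))
        env$pos <- 0L
      }
      take <- min(m - length(out), length(env$order) - env$pos)
      out <- c(out, env$order[env$pos + seq_len(take)])
      env$pos <- env$pos + take
    }
    out
  }
}

val_macro_f1 <- function(model, val_data) {
  truth <- vapply(val_data, function(s) s$label, 0L)
  preds <- vapply(val_data, function(s)
    which.max(model_logits(model, s$volume)) - 1L, 0L)
  macro_f1(confusion(truth, preds, model$config$n_classes))
}

run_training <- function(data, config, mconfig, priors = NULL,
                         val_data = NULL, mixup_alpha = NULL) {
  if (!length(data)) stop("training requires a non-empty train split")
  model <- init_model(mconfig)
  K <- mconfig$n_classes
  labels <- vapply(data, function(s) s$label, 0L)
  counts <- tabulate(labels + 1L, nbins = K)
  if (any(counts == 0))
    stop("training split is missing class(es): ",
         paste(which(counts == 0) - 1L, collapse = ", "))
  w <- class_weights(counts)
  pr_feat <- NULL
  if (!is.null(priors)) {
    pr_feat <- resample_prior_set(priors, mconfig$feature_dims)
    if (length(pr_feat$priors) != K)
      stop("priors have ", length(pr_feat$priors), " classes, model has ", K)
  }
  theta <- params_flatten(model$params)
  opt <- adam_init(length(theta))
  sampler <- make_sampler(length(data), config$seed)
  n_updates <- config$epochs * config$steps_per_epoch
  log <- vector("list", n_updates)
  best <- list(params = model$params, f1 = -Inf)
  lcfg <- config$loss
  reduction <- lcfg$reduction
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate
    if (identical(config$lr_schedule, "step")) {
      if (epoch > 0.85 * config$epochs) lr <- lr * 0.09
      else if (epoch > 0.6 * config$epochs) lr <- lr * 0.3
    }
    for (su in seq_len(config$steps_per_epoch)) {
      step <- step + 1L
      acc_grad <- numeric(length(theta))
      wce_acc <- 0; sim_acc <- 0
      for (micro in seq_len(config$accumulation_steps)) {
        idx <- sampler(config$micro_batch)
        batch <- data[idx]
        if (!is.null(config$augmentation))
          batch <- lapply(seq_along(batch), function(b)
            augment(batch[[b]], config$augmentation,
                    derive_seed(config$seed, "aug", step, micro, b)))
        vols <- lapply(batch, function(s) s$volume)
        Y <- soft_targets(vapply(batch, function(s) s$label, 0L),
                          length(batch), K)
        if (!is.null(mixup_alpha)) {
          mx <- mixup_batch(vols, Y, alpha = mixup_alpha,
                            seed = derive_seed(config$seed, "mix", step, micro))
          vols <- mx$volumes
          Y <- mx$labels
        }
        fwds <- lapply(vols, function(v) forward_model(model, v))
        probs <- do.call(rbind, lapply(fwds, function(f) f$probs))
        wce <- weighted_cross_entropy(probs, Y, w, reduction = reduction)
        dlogits <- wce_logit_grad(probs, Y, w, reduction = reduction)
        sim <- 0
        g_micro <- numeric(length(theta))
        for (b in seq_along(fwds)) {
          dM <- NULL
          if (!is.null(pr_feat)) {
            Mb <- fwds[[b]]$attention
            sim_b <- similarity_loss(list(Mb), pr_feat,
                                     loss_config(distance = lcfg$distance,
                                                 reduction = "sum"))
            sim <- sim + sim_b
            gM <- sim_attention_grad(Mb, pr_feat,
                                     loss_config(distance = lcfg$distance,
                                                 reduction = "sum"))
            scale <- if (reduction == "mean") length(fwds) else 1
            dM <- lcfg$lambda * gM / scale
          }
          bk <- backward_model(model, fwds[[b]], dlogits[b, ], dM_extra = dM)
          g_micro <- g_micro + params_flatten(bk$grads)
        }
        if (reduction == "mean") sim <- sim / length(fwds)
        acc_grad <- acc_grad + g_micro
        wce_acc <- wce_acc + wce
        sim_acc <- sim_acc + sim
      }
      acc_grad <- acc_grad / config$accumulation_steps
      wce_step <- wce_acc / config$accumulation_steps
      sim_step <- sim_acc / config$accumulation_steps
      tot <- wce_step + lcfg$lambda * sim_step
      if (!is.finite(tot)) {
        warning("non-finite loss at step ", step,
                "; aborting with the last good checkpoint")
        log <- log[seq_len(step - 1L)]
        model$params <- if (is.finite(best$f1)) best$params else model$params
        return(structure(list(model = model,
                              log = do.call(rbind, log),
                              best_val_f1 = best$f1),
                         class = "train_result"))
      }
      st <- adam_step(opt, theta, acc_grad, lr)
      opt <- st$state
      theta <- st$theta
      model$params <- params_unflatten(theta, model$params)
      log[[step]] <- data.frame(step = step, epoch = epoch, wce = wce_step,
                                sim = if (is.null(pr_feat)) NA_real_ else sim_step,
                                total = tot, lr = lr)
    }
    if (!is.null(val_data) && length(val_data)) {
      f1 <- val_macro_f1(model, val_data)
      if (f1 > best$f1) best <- list(params = model$params, f1 = f1)
    }
  }
  if (!is.null(val_data) && length(val_data) && is.finite(best$f1))
    model$params <- best$params
  structure(list(model = model,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(step = integer(), epoch = integer(),
                              wce = numeric(), sim = numeric(),
                              total = numeric(), lr = numeric()),
                 best_val_f1 = best$f1),
            class = "train_result")
}

#' Train the stage-1 baseline model
#'
#' Optimizes the weighted cross-entropy objective with gradient-accumulated
#' Adam updates. Class weights are computed from the training split only.
#' When validation data is supplied, the returned parameters are the epoch
#' checkpoint with the best validation macro F1.
#'
#' @param data Training split: list of `volume_sample`s.
#' @param config A [train_config()].
#' @param model_config A [model_config()].
#' @param val_data Optional validation split.
#' @param mixup_alpha Optional Mixup concentration (enables the Mixup
#'   comparison baseline).
#' @return A `train_result`: list with `model`, per-step `log` data.frame
#'   (step, epoch, wce, sim, total, lr), and `best_val_f1`.
#' @export
train_baseline <- function(data, config, model_config, val_data = NULL,
                           mixup_alpha = NULL) {
  run_training(data, config, model_config, priors = NULL, val_data = val_data,
               mixup_alpha = mixup_alpha)
}

#' Train the stage-2 prior-guided model
#'
#' As [train_baseline()], but a freshly initialized model is optimized under
#' the combined objective: weighted cross-entropy plus `lambda` times the
#' similarity loss aligning every class-wise attention map with its
#' (feature-grid-resampled) saliency prior. Priors are frozen throughout. For
#' an initialization independent of the baseline's, give `model_config` a
#' different seed.
#'
#' @param data Training split.
#' @param priors A `prior_set` from [build_class_priors()].
#' @param config A [train_config()]; `config$loss$lambda` weights the
#'   similarity term.
#' @param model_config A [model_config()].
#' @param val_data Optional validation split.
#' @return A `train_result` (the `log` includes the `sim` component).
#' @export
train_guided <- function(data, priors, config, model_config, val_data = NULL) {
  run_training(data, config, model_config, priors = priors,
               val_data = val_data)
}
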