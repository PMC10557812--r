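make_labels <- function(counts) {
  lab <- rep(seq_along(counts) - 1L, counts)
  names(lab) <- sprintf("s%04d", seq_along(lab))
  lab
}

test_that("stratified folds deal classes evenly and deterministically", {
  lab <- make_labels(c(10, 10, 10))
  fa <- stratified_folds(lab, 5, seed = 3)
  for (f in 0:4) {
    test_ids <- names(fa$fold_of_subject)[fa$fold_of_subject == f]
    expect_equal(unname(table(lab[test_ids])), rep(2L, 3), ignore_attr = TRUE)
  }
  fa2 <- stratified_folds(lab, 5, seed = 3)
  expect_identical(fa$fold_of_subject, fa2$fold_of_subject)
  expect_error(stratified_folds(make_labels(c(3, 10)), 5, seed = 1),
               "fewer than k")
})

test_that("fold proportions track cohort-scale class imbalance within one subject", {
  counts <- c(2524, 1175, 948)
  lab <- make_labels(counts)
  fa <- stratified_folds(lab, 5, seed = 1)
  global <- counts / sum(counts)
  for (f in 0:4) {
    ids <- names(fa$fold_of_subject)[fa$fold_of_subject == f]
    fold_counts <- tabulate(lab[ids] + 1L, 3)
    # round-robin dealing keeps per-fold counts within 1 of exact proportion
    expect_true(all(abs(fold_counts - global * length(ids)) <= 1))
  }
})

test_that("fold roles partition subjects 3:1:1", {
  lab <- make_labels(c(10, 10, 10))
  fa <- stratified_folds(lab, 5, seed = 3)
  for (f in 0:4) {
    r <- fold_roles(fa, f)
    expect_setequal(c(r$train, r$val, r$test), names(lab))
    expect_length(r$test, 6)
    expect_length(r$val, 6)
    expect_length(r$train, 18)
    expect_length(intersect(r$train, r$test), 0)
    expect_length(intersect(r$val, r$test), 0)
  }
})

test_that("augmentation honors probabilities, geometry and determinism", {
  coh <- fixture_cohort()
  s <- coh$samples[[5]]
  # probability-0 policy with unit scaling only: output is min-max input
  p0 <- augment_policy(per_transform_probability = 0)
  a0 <- augment(s, p0, seed = 1)
  expect_equal(a0$volume, dgsal:::minmax01(s$volume))
  expect_identical(a0$label, s$label)
  expect_identical(a0$domain, s$domain)
  # identity crop keeps geometry
  p1 <- augment_policy(crop_fraction = 1, per_transform_probability = 1,
                       bias_field_amplitude = 0)
  a1 <- augment(s, p1, seed = 2)
  expect_identical(dim(a1$volume), dim(s$volume))
  # determinism
  p2 <- augment_policy(per_transform_probability = 1)
  expect_identical(augment(s, p2, seed = 7)$volume,
                   augment(s, p2, seed = 7)$volume)
  expect_false(identical(augment(s, p2, seed = 7)$volume,
                         augment(s, p2, seed = 8)$volume))
})

test_that("mixup endpoints, midpoint and validation", {
  vols <- list(array(0, c(4, 4, 4)), array(1, c(4, 4, 4)))
  Y <- diag(2)
  mx1 <- mixup_batch(vols, Y, alpha = 0.2, seed = 1, lambda_fix = 1)
  expect_equal(mx1$volumes[[1]], vols[[1]])
  expect_equal(mx1$labels, Y)
  mx5 <- mixup_batch(vols, Y, alpha = 0.2, seed = 3, lambda_fix = 0.5)
  for (i in 1:2) {
    partner_differs <- !identical(mx5$volumes[[i]], vols[[i]])
    if (partner_differs) {
      expect_equal(unique(as.vector(mx5$volumes[[i]])), 0.5)
      expect_equal(unname(mx5$labels[i, ]), c(0.5, 0.5))
    }
  }
  expect_error(mixup_batch(vols[1], Y[1, , drop = FALSE], alpha = 0.2),
               ">= 2")
  expect_error(mixup_batch(vols, Y, alpha = 0), "> 0")
})

test_that("zero-epoch training returns the initialized model unchanged", {
  coh <- fixture_cohort()
  mc <- model_config(3, fixture_dims(), encoder_widths = c(3, 4), seed = 4)
  tc <- train_config(epochs = 0, steps_per_epoch = 5, micro_batch = 2,
                     accumulation_steps = 1, learning_rate = 1e-3, seed = 1)
  res <- train_baseline(coh$samples, tc, mc)
  expect_equal(res$model$params, init_model(mc)$params)
  expect_identical(nrow(res$log), 0L)
})

test_that("gradient accumulation reproduces the full-batch update", {
  coh <- fixture_cohort()
  mc <- model_config(3, fixture_dims(), encoder_widths = c(3, 4), seed = 4)
  cfg <- function(mb, acc) train_config(
    epochs = 1, steps_per_epoch = 1, micro_batch = mb,
    accumulation_steps = acc, learning_rate = 1e-3, seed = 31)
  r_accum <- train_baseline(coh$samples, cfg(2, 8), mc)
  r_full <- train_baseline(coh$samples, cfg(16, 1), mc)
  th_a <- dgsal:::params_flatten(r_accum$model$params)
  th_f <- dgsal:::params_flatten(r_full$model$params)
  th_0 <- dgsal:::params_flatten(init_model(mc)$params)
  upd_a <- th_a - th_0
  upd_f <- th_f - th_0
  expect_lt(max(abs(upd_a - upd_f)) / max(abs(upd_f)), 1e-5)
  expect_equal(r_accum$log$wce, r_full$log$wce, tolerance = 1e-10)
})

test_that("training reduces the loss on a separable phantom", {
  coh <- fixture_cohort()
  mc <- model_config(3, fixture_dims(), encoder_widths = c(4, 8), seed = 2)
  tc <- train_config(epochs = 5, steps_per_epoch = 10, micro_batch = 2,
                     accumulation_steps = 2, learning_rate = 3e-3, seed = 5)
  res <- train_baseline(coh$samples, tc, mc)
  lg <- res$log
  expect_identical(nrow(lg), 50L)
  expect_lt(mean(lg$wce[lg$epoch == 5]), mean(lg$wce[lg$epoch == 1]))
  expect_true(all(is.na(lg$sim)))
})

test_that("guided training with lambda 0 retraces the baseline trajectory", {
  coh <- fixture_cohort()
  mc <- model_config(3, fixture_dims(), encoder_widths = c(3, 4), seed = 6)
  tc <- train_config(epochs = 2, steps_per_epoch = 4, micro_batch = 2,
                     accumulation_steps = 2, learning_rate = 2e-3,
                     loss = loss_config(lambda = 0), seed = 17)
  pri <- prior_set(lapply(1:3, function(k)
    random_volume(c(4, 4, 4), seed = k)))
  rb <- train_baseline(coh$samples, tc, mc)
  rg <- train_guided(coh$samples, pri, tc, mc)
  expect_equal(rb$model$params, rg$model$params, tolerance = 1e-14)
  expect_equal(rg$log$wce, rb$log$wce, tolerance = 1e-14)
  expect_true(all(is.finite(rg$log$sim)))
})

test_that("guided training logs and reduces the similarity component", {
  coh <- fixture_cohort()
  mc <- model_config(3, fixture_dims(), encoder_widths = c(3, 4), seed = 8)
  tc <- train_config(epochs = 4, steps_per_epoch = 8, micro_batch = 2,
                     accumulation_steps = 1, learning_rate = 3e-3,
                     loss = loss_config(lambda = 1, distance = "L2sq"),
                     seed = 23)
  pri <- prior_set(lapply(1:3, function(k)
    array(0.2 * (k - 2), c(4, 4, 4))))
  res <- train_guided(coh$samples, pri, tc, mc)
  lg <- res$log
  expect_true(all(is.finite(lg$sim)))
  expect_lt(mean(lg$sim[lg$epoch == 4]), mean(lg$sim[lg$epoch == 1]))
})

test_that("training with mixup runs and logs finite losses", {
  coh <- fixture_cohort()
  mc <- model_config(3, fixture_dims(), encoder_widths = c(3, 4), seed = 9)
  tc <- train_config(epochs = 1, steps_per_epoch = 4, micro_batch = 4,
                     accumulation_steps = 1, learning_rate = 1e-3, seed = 2)
  res <- train_baseline(coh$samples, tc, mc, mixup_alpha = 0.2)
  expect_true(all(is.finite(res$log$wce)))
})
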