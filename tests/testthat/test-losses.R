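test_that("class weights are exact reciprocals of the class counts", {
  w <- class_weights(c(2524, 1175, 948))
  expect_equal(w$weights, c(1 / 2524, 1 / 1175, 1 / 948), tolerance = 1e-15)
  expect_equal(class_weights(c(10, 10, 10))$weights, rep(0.1, 3))
  w2 <- class_weights(c(3, 1))
  expect_equal(w2$weights, c(1 / 3, 1))
  expect_equal(w2$weights[2] / w2$weights[1], 3)
  expect_error(class_weights(c(5, 0)), "drop the class")
  wn <- class_weights(c(2, 4), normalize = TRUE)
  expect_equal(mean(wn$weights), 1)
})

test_that("weighted cross-entropy matches hand-evaluated cases", {
  w <- c(1, 2, 3)
  # one-hot-correct rows contribute zero
  probs <- diag(3)[c(1, 3), ]
  expect_equal(weighted_cross_entropy(probs, c(0L, 2L), w, reduction = "sum"), 0)
  # uniform probabilities: contribution w_y * log 3
  u <- matrix(1 / 3, 1, 3)
  for (y in 0:2)
    expect_equal(weighted_cross_entropy(u, y, w, reduction = "sum"),
                 w[y + 1] * log(3), tolerance = 1e-12)
  # two-sample case evaluated by hand
  p2 <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
  expect_equal(weighted_cross_entropy(p2, c(0L, 1L), w, reduction = "sum"),
               -(1 * log(0.7) + 2 * log(0.8)), tolerance = 1e-12)
  expect_equal(weighted_cross_entropy(p2, c(0L, 1L), w, reduction = "mean"),
               -(1 * log(0.7) + 2 * log(0.8)) / 2, tolerance = 1e-12)
})

test_that("equal class counts reduce to scaled unweighted cross-entropy", {
  probs <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.25, 0.25, 0.5))
  y <- c(0L, 1L, 2L)
  w <- class_weights(c(7, 7, 7))
  unweighted <- -sum(log(probs[cbind(1:3, y + 1)]))
  expect_equal(weighted_cross_entropy(probs, y, w, reduction = "sum"),
               unweighted / 7, tolerance = 1e-12)
})

test_that("zero probability at the true label is clamped with a warning", {
  probs <- rbind(c(0, 0.5, 0.5))
  expect_warning(v <- weighted_cross_entropy(probs, 0L, c(1, 1, 1),
                                             reduction = "sum"), "clamp")
  expect_true(is.finite(v))
})

test_that("similarity loss matches its closed forms", {
  pr <- prior_set(lapply(1:3, function(k) random_volume(c(3, 3, 3), seed = k)))
  mk_att <- function(delta = 0) {
    M <- array(0, c(3, 3, 3, 3))
    for (k in 1:3) M[k, , , ] <- pr$priors[[k]] + delta
    M
  }
  cfg <- loss_config(reduction = "sum")
  expect_equal(similarity_loss(list(mk_att(), mk_att()), pr, cfg), 0)
  # single differing voxel of size delta -> |delta|
  M <- mk_att()
  M[2, 1, 3, 2] <- M[2, 1, 3, 2] + 0.37
  expect_equal(similarity_loss(list(M), pr, cfg), 0.37, tolerance = 1e-12)
  # constant offset c on a V-voxel grid: N * K * |c| * sqrt(V)
  V <- 27
  off <- -0.21
  batch <- list(mk_att(off), mk_att(off))
  expect_equal(similarity_loss(batch, pr, cfg), 2 * 3 * abs(off) * sqrt(V),
               tolerance = 1e-10)
  # batch-mean reduction divides by N
  expect_equal(similarity_loss(batch, pr, loss_config(reduction = "mean")),
               3 * abs(off) * sqrt(V), tolerance = 1e-10)
  # squared distance option
  expect_equal(similarity_loss(batch, pr, loss_config(distance = "L2sq",
                                                      reduction = "sum")),
               2 * 3 * off^2 * V, tolerance = 1e-10)
})

test_that("ground-truth-only mode aligns a single class channel per sample", {
  pr <- prior_set(lapply(1:3, function(k) random_volume(c(2, 2, 2), seed = k)))
  M <- array(random_volume(c(3, 2, 2, 2), seed = 50), c(3, 2, 2, 2))
  cfg <- loss_config(reduction = "sum")
  per_class <- vapply(0:2, function(y)
    similarity_loss(list(M), pr, cfg, labels = y), 0.0)
  expect_equal(sum(per_class), similarity_loss(list(M), pr, cfg),
               tolerance = 1e-12)
  # the truth-only gradient vanishes on the other channels
  g <- dgsal:::sim_attention_grad(M, pr, cfg, label = 1L)
  expect_true(all(g[1, , , ] == 0))
  expect_true(all(g[3, , , ] == 0))
  expect_gt(sum(abs(g[2, , , ])), 0)
})

test_that("similarity loss is non-negative and satisfies the triangle inequality", {
  cfg <- loss_config(reduction = "sum")
  for (rep in 1:20) {
    pr <- prior_set(list(random_volume(c(2, 2, 2), seed = 100 + rep)))
    A <- array(random_volume(c(2, 2, 2), seed = 200 + rep), c(1, 2, 2, 2))
    B <- array(random_volume(c(2, 2, 2), seed = 300 + rep), c(1, 2, 2, 2))
    dA <- similarity_loss(list(A), pr, cfg)
    dB <- similarity_loss(list(B), pr, cfg)
    dAB <- sqrt(sum((A - B)^2))
    expect_gte(dA, 0)
    expect_lte(dA, dAB + dB + 1e-12)   # per-term triangle inequality
  }
})

test_that("similarity gradient is the normalized difference", {
  pr <- prior_set(lapply(1:2, function(k) random_volume(c(2, 2, 2), seed = k)))
  M <- array(random_volume(c(2, 2, 2, 2), seed = 77), c(2, 2, 2, 2))
  cfg <- loss_config(reduction = "sum")
  g <- dgsal:::sim_attention_grad(M, pr, cfg)
  for (k in 1:2) {
    diff <- array(M[k, , , ], c(2, 2, 2)) - pr$priors[[k]]
    expect_equal(array(g[k, , , ], c(2, 2, 2)), diff / sqrt(sum(diff^2)),
                 tolerance = 1e-12)
  }
  # finite-difference check of one coordinate
  h <- 1e-6
  Mp <- M; Mp[1, 2, 1, 2] <- Mp[1, 2, 1, 2] + h
  Mm <- M; Mm[1, 2, 1, 2] <- Mm[1, 2, 1, 2] - h
  fd <- (similarity_loss(list(Mp), pr, cfg) -
           similarity_loss(list(Mm), pr, cfg)) / (2 * h)
  expect_lt(abs(fd - g[1, 2, 1, 2]) / abs(fd), 1e-4)
})

test_that("similarity loss demands a matching grid", {
  pr <- prior_set(list(random_volume(c(4, 4, 4))))
  M <- array(0, c(1, 2, 2, 2))
  expect_error(similarity_loss(list(M), pr), "resample_prior")
})

test_that("combined loss is wce + lambda * sim and monotone in sim", {
  expect_equal(total_loss(1.23, 999, loss_config(lambda = 0)), 1.23)
  expect_equal(total_loss(1, 2000, loss_config(lambda = 5e-5)), 1.1)
  expect_equal(total_loss(0, 0, loss_config()), 0)
  cfg <- loss_config(lambda = 0.7)
  expect_lt(total_loss(1, 2, cfg), total_loss(1, 3, cfg))
  expect_error(total_loss(Inf, 0, cfg))
})
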