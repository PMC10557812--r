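test_that("attribution of a sample identical to its reference is zero", {
  m <- tiny_model()
  x <- random_volume(c(8, 8, 8), seed = 1)
  sal <- attribute_sample(m, x, reference = x, target_class = 0,
                          config = attribution_config(n_samples = 4, seed = 1))
  expect_true(all(sal$values == 0))
})

test_that("linear models get exact closed-form Shapley attributions", {
  dims <- c(2, 2, 3)
  w <- array(dgsal:::with_seed(3, stats::rnorm(12)), dims)
  x <- random_volume(dims, seed = 4)
  ref <- random_volume(dims, seed = 5)
  lm <- linear_model(w, bias = 0.4)
  sal <- attribute_sample(lm, x, reference = ref, target_class = 0,
                          config = attribution_config(n_samples = 8, seed = 2))
  closed <- w * (x - ref)
  expect_equal(sal$values, closed, tolerance = 1e-12)
  # exhaustive-subset oracle on the same 12-voxel problem
  phi <- shapley_exhaustive(function(z) sum(w * z) + 0.4, as.vector(x),
                            as.vector(ref))
  expect_equal(as.vector(sal$values), phi, tolerance = 1e-10)
  # completeness: attributions sum to logit(x) - logit(ref)
  expect_equal(sum(sal$values), sum(w * x) - sum(w * ref), tolerance = 1e-10)
})

test_that("symmetric players receive equal exhaustive Shapley values", {
  # voxels 1 and 2 enter only through their sum; the value function is
  # nonlinear so symmetry is not an artifact of linearity
  f <- function(z) (z[1] + z[2])^2 + 3 * z[3]
  phi <- shapley_exhaustive(f, c(1, 1, 2), c(0, 0, 0))
  expect_equal(phi[1], phi[2], tolerance = 1e-12)
  expect_equal(sum(phi), f(c(1, 1, 2)) - f(c(0, 0, 0)), tolerance = 1e-12)
})

test_that("network attributions satisfy completeness within tolerance", {
  m <- tiny_model(dims = c(8, 8, 8), widths = c(3, 4), seed = 11)
  x <- random_volume(c(8, 8, 8), seed = 12)
  ref <- array(0, c(8, 8, 8))
  k <- 1L
  sal <- attribute_sample(m, x, reference = ref, target_class = k,
                          config = attribution_config(seed = 3))
  gap <- dgsal:::model_logits(m, x)[k + 1] - dgsal:::model_logits(m, ref)[k + 1]
  expect_lt(abs(sum(sal$values) - gap) / abs(gap), 0.02)
})

test_that("completeness residual spread shrinks as sample count doubles", {
  m <- tiny_model(dims = c(8, 8, 8), widths = c(3, 4), seed = 13)
  x <- random_volume(c(8, 8, 8), seed = 14)
  ref <- array(0, c(8, 8, 8))
  gap <- dgsal:::model_logits(m, x)[1] - dgsal:::model_logits(m, ref)[1]
  resid <- function(n, seed) {
    sal <- attribute_sample(m, x, reference = ref, target_class = 0,
                            config = attribution_config(n_samples = n,
                                                        seed = seed))
    sum(sal$values) - gap
  }
  r8 <- vapply(1:24, function(s) resid(8, 1000 + s), 0.0)
  r16 <- vapply(1:24, function(s) resid(16, 2000 + s), 0.0)
  expect_lt(stats::sd(r16), stats::sd(r8))
  expect_lt(stats::sd(r16) / stats::sd(r8), 0.95)
})

test_that("attribution is deterministic for a fixed seed", {
  m <- tiny_model()
  x <- random_volume(c(8, 8, 8), seed = 15)
  cfg <- attribution_config(n_samples = 4, seed = 9)
  s1 <- attribute_sample(m, x, target_class = 2, config = cfg)
  s2 <- attribute_sample(m, x, target_class = 2, config = cfg)
  expect_identical(s1$values, s2$values)
})

test_that("class priors average kept samples and maxabs-scale once", {
  atlas <- fixture_atlas()
  coh <- fixture_cohort()
  m <- tiny_model(dims = c(16, 16, 16), widths = c(3, 4), seed = 2)
  cfg <- attribution_config(n_samples = 4, seed = 5)
  pri <- build_class_priors(m, coh$samples, cfg, fallback_all = TRUE)
  expect_length(pri$priors, 3)
  expect_identical(pri$grid, c(16L, 16L, 16L))
  expect_true(all(pri$n_samples_used >= 1))
  for (p in pri$priors) expect_equal(max(abs(p)), 1, tolerance = 1e-12)
  # maxabs idempotence
  for (p in pri$priors)
    expect_equal(dgsal:::scale_maxabs(p), p, tolerance = 1e-15)
  # determinism
  pri2 <- build_class_priors(m, coh$samples, cfg, fallback_all = TRUE)
  expect_equal(pri$priors, pri2$priors, tolerance = 1e-15)
  # mean-of-attributions property, recomputed independently for one class
  labels <- vapply(coh$samples, function(s) s$label, 0L)
  preds <- vapply(coh$samples, function(s)
    which.max(dgsal:::model_logits(m, s$volume)) - 1L, 0L)
  k <- 0L
  idx <- which(labels == k & preds == labels)
  if (!length(idx)) idx <- which(labels == k)
  acc <- array(0, c(16, 16, 16))
  for (j in idx) {
    cj <- cfg
    cj$seed <- derive_seed(cfg$seed, "attr", j)
    acc <- acc + attribute_sample(m, coh$samples[[j]], target_class = k,
                                  config = cj)$values
  }
  expect_equal(pri$priors[[1]], dgsal:::scale_maxabs(acc / length(idx)),
               tolerance = 1e-12)
})

test_that("maxabs scaling maps an extreme of -2 to -1 and halves the rest", {
  p <- array(0.5, c(2, 2, 2))
  p[1, 1, 1] <- -2
  s <- dgsal:::scale_maxabs(p)
  expect_equal(s[1, 1, 1], -1)
  expect_equal(s[2, 2, 2], 0.25)
})

test_that("a class with no correct predictions errors without the fallback", {
  coh <- fixture_cohort()
  m <- tiny_model(dims = c(16, 16, 16), widths = c(3, 4), seed = 2)
  # force constant predictions: zero encoder output leads to logits bf * bm
  m$params$att$Wf[] <- 0; m$params$att$Wm[] <- 0
  m$params$att$bf <- c(1, 0, 0); m$params$att$bm <- c(1, 0, 0)
  expect_error(build_class_priors(m, coh$samples,
                                  attribution_config(n_samples = 2, seed = 1)),
               "zero correct")
})

test_that("trilinear prior resampling hits its closed-form cases", {
  # constants map to the same constant
  expect_equal(resample_prior(array(0.7, c(4, 4, 4)), c(7, 5, 3)),
               array(0.7, c(7, 5, 3)), tolerance = 1e-12)
  # identity resample is bit-identical
  p <- random_volume(c(5, 4, 3), seed = 6)
  expect_identical(resample_prior(p, c(5, 4, 3)), p)
  # 2^3 grid with a single hot corner onto 3^3: centre value is 1/8
  p2 <- array(0, c(2, 2, 2))
  p2[1, 1, 1] <- 1
  up <- resample_prior(p2, c(3, 3, 3))
  expect_equal(up[2, 2, 2], 0.125, tolerance = 1e-12)
  expect_equal(up[1, 1, 1], 1, tolerance = 1e-12)
})

test_that("prior sets persist as NIfTI plus JSON sidecar", {
  pr <- prior_set(lapply(1:3, function(k) random_volume(c(6, 5, 4), seed = k)),
                  n_samples_used = c(4L, 5L, 6L), source_model_id = "m0")
  dir <- withr::local_tempdir()
  write_prior_set(pr, dir)
  expect_true(file.exists(file.path(dir, "priors.json")))
  back <- read_prior_set(dir)
  expect_equal(back$priors, pr$priors, tolerance = 1e-7)
  expect_identical(back$n_samples_used, pr$n_samples_used)
  expect_identical(back$source_model_id, "m0")
})
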