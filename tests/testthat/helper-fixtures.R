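# Shared fixtures, generated in code. Kept deliberately small so the whole
# suite runs quickly on one CPU.

fixture_dims <- function() dim3(16, 16, 16)

fixture_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_atlas(fixture_dims(), 5, seed = 3)
    cache
  }
})

fixture_spec <- function(domains = list(domain_spec("src", noise_sigma = 0.02)),
                         n = 4, effect = 0.5, seed = 11, grade_noise = 0) {
  cohort_spec(fixture_dims(), 3,
              disease_regions = list("1" = c(1L, 2L), "2" = c(4L, 5L)),
              effect_size = effect, domains = domains,
              n_per_class_per_domain = n, seed = seed,
              grade_noise = grade_noise)
}

fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(fixture_spec(), fixture_atlas())
    cache
  }
})

tiny_model <- function(dims = c(8, 8, 8), widths = c(4, 6), K = 3, seed = 9) {
  init_model(model_config(K, dim3(dims[1], dims[2], dims[3]),
                          encoder_widths = widths, seed = seed))
}

random_volume <- function(dims, seed = 1) {
  dgsal:::with_seed(seed, array(stats::runif(prod(dims)), dims))
}

# Independent from-definition implementations of the evaluation metrics,
# used as oracles against the package implementations.
oracle_macro_f1 <- function(m) {
  K <- nrow(m)
  f1s <- vapply(seq_len(K), function(k) {
    tp <- m[k, k]
    prec_den <- sum(m[, k])
    rec_den <- sum(m[k, ])
    p <- if (prec_den > 0) tp / prec_den else 0
    r <- if (rec_den > 0) tp / rec_den else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, 0.0)
  mean(f1s)
}

oracle_mcc <- function(m) {
  s <- sum(m)
  c_ <- sum(diag(m))
  t_k <- colSums(m)
  p_k <- rowSums(m)
  den1 <- s^2 - sum(p_k^2)
  den2 <- s^2 - sum(t_k^2)
  if (den1 <= 0 || den2 <= 0) return(0)
  (c_ * s - sum(p_k * t_k)) / sqrt(den1 * den2)
}
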