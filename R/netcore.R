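# Classifier architecture: conv-pool encoder -> class-wise attention module
# -> global-average-pooling softmax classifier.
#
# Feature arrays are channel-first (C, D, H, W). Convolutions are stride-1,
# "same"-padded, implemented as im2col + matrix multiply with manual
# backpropagation; each encoder stage is conv(3x3x3) -> ReLU -> 2x2x2 average
# pool (stride 2), so every stage halves the spatial grid.

.conv_cache <- new.env(parent = emptyenv())

# Linear indices into the zero-padded input for the im2col patch matrix.
# Column order (ci fastest, then kz, ky, kx) matches the column-major
# flattening of a (C_out, C_in, k, k, k) weight array.
im2col_indices <- function(C, D, H, W, k) {
  p <- (k - 1L) %/% 2L
  key <- paste(C, D, H, W, k, sep = "_")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  Dp <- D + 2L * p; Hp <- H + 2L * p
  g <- expand.grid(z = seq_len(D), y = seq_len(H), x = seq_len(W))
  V <- nrow(g)
  idx <- matrix(0L, V, C * k^3)
  col <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) for (dz in 0:(k - 1L))
    for (ci in seq_len(C)) {
      col <- col + 1L
      idx[, col] <- ci + C * ((g$z + dz - 1L) + Dp * ((g$y + dy - 1L) +
        Hp * (g$x + dx - 1L)))
    }
  # reorder columns to (ci, dz, dy, dx) nesting: built above with ci fastest,
  # then dz, dy, dx — already the required order
  .conv_cache[[key]] <- list(idx = idx, p = p, V = V)
  .conv_cache[[key]]
}

pad3 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4] + 2 * p))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), p + seq_len(d[4])] <- x
  out
}

conv3d_forward <- function(x, W, b) {
  dx <- dim(x)                      # (C, D, H, W)
  dw <- dim(W)                      # (C_out, C_in, k, k, k)
  if (dx[1] != dw[2])
    stop("conv3d: input has ", dx[1], " channels but kernel expects ", dw[2])
  k <- dw[3]
  ic <- im2col_indices(dx[1], dx[2], dx[3], dx[4], k)
  xp <- pad3(x, ic$p)
  P <- matrix(as.vector(xp)[ic$idx], ic$V, dx[1] * k^3)
  Wm <- matrix(W, dw[1], dw[2] * k^3)
  Y <- P %*% t(Wm)
  Y <- sweep(Y, 2, b, "+")
  out <- aperm(array(Y, c(dx[2], dx[3], dx[4], dw[1])), c(4, 1, 2, 3))
  list(out = out, patches = P, in_dim = dx)
}

conv3d_backward <- function(dY, W, cache, want_dx = TRUE) {
  dw <- dim(W); k <- dw[3]
  dx_dim <- cache$in_dim
  V <- prod(dx_dim[2:4])
  dYm <- matrix(aperm(dY, c(2, 3, 4, 1)), V, dw[1])
  gW <- array(t(dYm) %*% cache$patches, dw)
  gb <- colSums(dYm)
  dX <- NULL
  if (want_dx) {
    Wm <- matrix(W, dw[1], dw[2] * k^3)
    dP <- dYm %*% Wm
    p <- (k - 1L) %/% 2L
    C <- dx_dim[1]; D <- dx_dim[2]; H <- dx_dim[3]; Wd <- dx_dim[4]
    pd <- c(C, D + 2L * p, H + 2L * p, Wd + 2L * p)
    dXp <- array(0, pd)
    sz <- seq_len(D); sy <- seq_len(H); sx <- seq_len(Wd)
    col <- 0L
    # scatter-accumulate each patch column back into its shifted slab
    for (ox in 0:(k - 1L)) for (oy in 0:(k - 1L)) for (oz in 0:(k - 1L))
      for (ci in seq_len(C)) {
        col <- col + 1L
        dXp[ci, oz + sz, oy + sy, ox + sx] <-
          dXp[ci, oz + sz, oy + sy, ox + sx, drop = FALSE] +
          array(dP[, col], c(1L, D, H, Wd))
      }
    dX <- if (p > 0)
      dXp[, p + sz, p + sy, p + sx, drop = FALSE]
    else dXp
    dim(dX) <- dx_dim
  }
  list(dW = gW, db = gb, dX = dX)
}

# 2x2x2 average pooling, stride 2; odd trailing slices are cropped first.
avgpool2_forward <- function(x) {
  d <- dim(x)
  dd <- (d[2:4] %/% 2L) * 2L
  xc <- x[, seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]), drop = FALSE]
  dim(xc) <- c(d[1], dd)
  od <- dd %/% 2L
  out <- array(0, c(d[1], od))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    out <- out + xc[, seq(1L + dz, dd[1], 2L), seq(1L + dy, dd[2], 2L),
                    seq(1L + dx, dd[3], 2L), drop = FALSE] / 8
  dim(out) <- c(d[1], od)
  list(out = out, in_dim = d, crop_dim = dd)
}

avgpool2_backward <- function(dY, cache) {
  d <- cache$in_dim; dd <- cache$crop_dim
  dX <- array(0, d)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    dX[, seq(1L + dz, dd[1], 2L), seq(1L + dy, dd[2], 2L),
       seq(1L + dx, dd[3], 2L)] <-
      dX[, seq(1L + dz, dd[1], 2L), seq(1L + dy, dd[2], 2L),
         seq(1L + dx, dd[3], 2L), drop = FALSE] + dY / 8
  dX
}

#' Model configuration
#'
#' @param n_classes Number of classes K (>= 2).
#' @param input_dims `dim3` input grid.
#' @param encoder_widths Channel counts of the encoder stages; each stage is
#'   conv(3^3) -> ReLU -> stride-2 average pool, so `length(encoder_widths)`
#'   halvings are applied to the spatial grid.
#' @param attention_kernel Odd kernel size of the two attention convolutions
#'   (default 1).
#' @param seed Seed of the parameter initialization stream.
#' @return A `model_config` list; `$feature_dims` gives the encoder output
#'   grid.
#' @export
model_config <- function(n_classes, input_dims, encoder_widths = c(8, 16),
                         attention_kernel = 1, seed = 1) {
  stopifnot(n_classes >= 2, length(encoder_widths) >= 1,
            attention_kernel %% 2 == 1, attention_kernel >= 1)
  input_dims <- as_dim3(input_dims)
  fd <- as.integer(input_dims)
  for (i in seq_along(encoder_widths)) fd <- fd %/% 2L
  if (any(fd < 1)) stop("model_config: too many encoder stages for input dims")
  if (utils::tail(encoder_widths, 1) < n_classes)
    stop("model_config: final encoder width must be >= n_classes")
  structure(list(n_classes = as.integer(n_classes),
                 input_dims = input_dims,
                 encoder_widths = as.integer(encoder_widths),
                 attention_kernel = as.integer(attention_kernel),
                 feature_dims = fd,
                 seed = as.integer(seed)),
            class = "model_config")
}

he_init <- function(dims, fan_in, seed) {
  with_seed(seed, array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims))
}

#' Initialize model parameters
#'
#' Seeded He-style initialization; biases start at zero.
#'
#' @param config A [model_config()].
#' @return A `dgsal_model`: list with `config` and `params`.
#' @export
init_model <- function(config) {
  widths <- config$encoder_widths
  k <- 3L
  enc <- list()
  c_in <- 1L
  for (i in seq_along(widths)) {
    c_out <- widths[i]
    enc[[i]] <- list(
      W = he_init(c(c_out, c_in, k, k, k), c_in * k^3,
                  derive_seed(config$seed, "enc", i)),
      b = numeric(c_out))
    c_in <- c_out
  }
  ka <- config$attention_kernel
  K <- config$n_classes
  att <- list(
    Wf = he_init(c(K, c_in, ka, ka, ka), c_in * ka^3,
                 derive_seed(config$seed, "att_f")),
    bf = numeric(K),
    # attention-map conv starts small so M grows from a near-neutral state
    # on the scale of the [-1,1] priors rather than fighting them
    Wm = 0.1 * he_init(c(K, c_in, ka, ka, ka), c_in * ka^3,
                       derive_seed(config$seed, "att_m")),
    bm = numeric(K))
  structure(list(config = config, params = list(enc = enc, att = att)),
            class = "dgsal_model")
}

as_channel_volume <- function(volume) {
  d <- dim(volume)
  if (length(d) == 3) {
    dim(volume) <- c(1L, d)
  }
  volume
}

#' Run the encoder feature extractor
#'
#' @param volume 3D input array matching `config$input_dims`.
#' @param config A [model_config()].
#' @param params Model parameter list (from a `dgsal_model`).
#' @return A `feature_stack`: list with `values` (C x D' x H' x W' array) and
#'   `spatial_dims`.
#' @export
extract_features <- function(volume, config, params) {
  fwd <- encoder_forward(volume, config, params)
  structure(list(values = fwd$out, spatial_dims = dim(fwd$out)[2:4]),
            class = "feature_stack")
}

encoder_forward <- function(volume, config, params) {
  d <- dim(volume)
  if (!identical(as.integer(d), as.integer(config$input_dims)))
    stop("extract_features: input dims (", paste(d, collapse = "x"),
         ") do not match config input_dims (",
         paste(config$input_dims, collapse = "x"), ")")
  x <- as_channel_volume(volume)
  stages <- list()
  for (i in seq_along(params$enc)) {
    cv <- conv3d_forward(x, params$enc[[i]]$W, params$enc[[i]]$b)
    a <- pmax(cv$out, 0)
    pl <- avgpool2_forward(a)
    stages[[i]] <- list(conv = cv, pre_act = cv$out, pool = pl)
    x <- pl$out
  }
  list(out = x, stages = stages)
}

#' Class-wise attention module
#'
#' Two parallel 3D convolutions map the feature stack to K channels each:
#' `F'` (modulation input) and the linear-activation attention maps `M`. The
#' module output is the element-wise product `F' * M`.
#'
#' @param features A `feature_stack` (or a raw C x D' x H' x W' array).
#' @param params Model parameter list.
#' @return List with `attention` (`attention_stack`: K x D' x H' x W' array
#'   under `$maps`), and `modulated` (`feature_stack` with K channels).
#' @export
attention_forward <- function(features, params) {
  f <- if (inherits(features, "feature_stack")) features$values else features
  cf <- conv3d_forward(f, params$att$Wf, params$att$bf)
  cm <- conv3d_forward(f, params$att$Wm, params$att$bm)
  mod <- cf$out * cm$out
  list(attention = structure(list(maps = cm$out), class = "attention_stack"),
       modulated = structure(list(values = mod, spatial_dims = dim(mod)[2:4]),
                             class = "feature_stack"),
       f_prime = cf$out,
       cache = list(cf = cf, cm = cm))
}

#' Global-average-pooling softmax classifier
#'
#' Logit k is the spatial mean of modulated channel k; probabilities are the
#' softmax of the logits. The spatial mean (not sum) makes logits independent
#' of the feature-grid resolution.
#'
#' @param modulated A `feature_stack` with exactly K channels (or raw array).
#' @param n_classes K; defaults to the channel count.
#' @return A `class_probabilities` list with `logits` and `probs`.
#' @export
classify <- function(modulated, n_classes = NULL) {
  m <- if (inherits(modulated, "feature_stack")) modulated$values else modulated
  d <- dim(m)
  K <- if (is.null(n_classes)) d[1] else as.integer(n_classes)
  if (d[1] != K)
    stop("classify: expected ", K, " channels, got ", d[1])
  logits <- rowMeans(matrix(m, d[1], prod(d[2:4])))
  structure(list(logits = logits, probs = softmax(logits)),
            class = "class_probabilities")
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Full forward pass with cache for backpropagation.
forward_model <- function(model, volume) {
  enc <- encoder_forward(volume, model$config, model$params)
  att <- attention_forward(enc$out, model$params)
  cls <- classify(att$modulated, model$config$n_classes)
  list(features = enc$out, attention = att$attention$maps,
       f_prime = att$f_prime, modulated = att$modulated$values,
       logits = cls$logits, probs = cls$probs,
       cache = list(enc = enc, att = att))
}

# Backpropagation. dlogits: length-K gradient of the loss wrt logits.
# dM_extra: optional (K, D', H', W') gradient injected directly on the
# attention maps (prior-alignment loss). Returns parameter gradients in the
# same structure as params, and optionally the input gradient.
backward_model <- function(model, fwd, dlogits, dM_extra = NULL,
                           want_dinput = FALSE) {
  params <- model$params
  dmod <- dim(fwd$modulated)
  V <- prod(dmod[2:4])
  dMod <- array(rep(dlogits / V, V), dmod)
  dFp <- dMod * fwd$attention
  dM <- dMod * fwd$f_prime
  if (!is.null(dM_extra)) dM <- dM + dM_extra
  att <- fwd$cache$att
  bf <- conv3d_backward(dFp, params$att$Wf, att$cache$cf, want_dx = TRUE)
  bm <- conv3d_backward(dM, params$att$Wm, att$cache$cm, want_dx = TRUE)
  dF <- bf$dX + bm$dX
  grads <- list(enc = vector("list", length(params$enc)),
                att = list(Wf = bf$dW, bf = bf$db, Wm = bm$dW, bm = bm$db))
  dx <- dF
  for (i in rev(seq_along(params$enc))) {
    st <- fwd$cache$enc$stages[[i]]
    dA <- avgpool2_backward(dx, st$pool)
    dPre <- dA * (st$pre_act > 0)
    want <- want_dinput || i > 1L
    cb <- conv3d_backward(dPre, params$enc[[i]]$W, st$conv, want_dx = want)
    grads$enc[[i]] <- list(W = cb$dW, b = cb$db)
    dx <- cb$dX
  }
  list(grads = grads, dinput = if (want_dinput) array(dx, dim(dx)[2:4]))
}

# Flatten parameters (or gradients of the same shape) to a numeric vector and
# back; used by the optimizer and by finite-difference checks.
params_flatten <- function(p) {
  unlist(list(enc = lapply(p$enc, function(s) list(W = as.vector(s$W), b = s$b)),
              att = lapply(p$att, as.vector)), use.names = FALSE)
}

params_unflatten <- function(vec, template) {
  pos <- 0L
  take <- function(x) {
    n <- length(x)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  enc <- lapply(template$enc, function(s) list(W = take(s$W), b = take(s$b)))
  att <- list(Wf = take(template$att$Wf), bf = take(template$att$bf),
              Wm = take(template$att$Wm), bm = take(template$att$bm))
  list(enc = enc, att = att)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full `model_config`, so a loaded model is
#' self-describing.
#'
#' @param model A `dgsal_model`.
#' @param path File path.
#' @return `load_model` returns the `dgsal_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "dgsal_checkpoint_v1",
               config = unclass(model$config),
               params = model$params), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "dgsal_checkpoint_v1"))
    stop("load_model: not a dgsal checkpoint: ", path)
  cfg <- ck$config
  cfg$input_dims <- as_dim3(cfg$input_dims)
  class(cfg) <- "model_config"
  structure(list(config = cfg, params = ck$params), class = "dgsal_model")
}

#' Predict class probabilities for one volume
#'
#' @param object A `dgsal_model`.
#' @param volume 3D array matching the model's input dims.
#' @param ... Unused.
#' @return A `class_probabilities` list.
#' @export
predict_volume <- function(object, volume, ...) {
  fwd <- forward_model(object, volume)
  structure(list(logits = fwd$logits, probs = fwd$probs),
            class = "class_probabilities")
}
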