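#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' One global seed fans out to per-stage / per-subject seed streams via an
#' integer hash, so every stage is independently reproducible. The result is
#' always a valid 32-bit R seed.
#'
#' @param seed Integer master seed.
#' @param ... Further integers or strings identifying the stream (stage name,
#'   subject index, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 48271 + as.numeric(p) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Three-dimensional grid size
#'
#' Validated (depth, height, width) voxel dimensions used throughout the
#' package; all volume arrays are indexed `[depth, height, width]`.
#'
#' @param depth,height,width Positive integer voxel counts, each at least 8
#'   unless `min_side` is lowered.
#' @param min_side Minimum allowed side length (default 8).
#' @param max_voxels Cap on the total voxel count.
#' @return An integer vector of length 3 with class `"dim3"`.
#' @export
dim3 <- function(depth, height, width, min_side = 8L, max_voxels = 2^27) {
  d <- as.integer(c(depth, height, width))
  if (any(is.na(d)) || any(d < min_side))
    stop("dim3: all sides must be integers >= ", min_side)
  if (prod(as.numeric(d)) > max_voxels)
    stop("dim3: total voxel count ", prod(as.numeric(d)),
         " exceeds cap ", max_voxels)
  structure(d, class = "dim3", names = c("depth", "height", "width"))
}

as_dim3 <- function(x, ...) {
  if (inherits(x, "dim3")) return(x)
  dim3(x[[1]], x[[2]], x[[3]], ...)
}

# Separable Gaussian smoothing of a 3D array; `sigma` in voxels. Used for the
# phantom's smooth anatomy and bias fields.
gaussian_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  conv1 <- function(v) {
    # reflect-pad 1D convolution along the first margin of a matrix
    n <- nrow(v)
    idx <- c(pmin(n, pmax(1, rev(seq_len(r) + 1))), seq_len(n),
             pmin(n, pmax(1, n - seq_len(r))))
    vp <- v[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(v))
    for (j in seq_along(k)) out <- out + k[j] * vp[(j - 1) + seq_len(n), , drop = FALSE]
    out
  }
  # smooth along each axis in turn by permuting that axis to the front
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- conv1(matrix(xp, dp[1], dp[2] * dp[3]))
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  x
}

# Min-max scale an array to [0,1]; constant arrays are returned unchanged.
minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) return(x)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Trilinear resampling of a 3D grid
#'
#' Cell-centred trilinear interpolation of `x` onto a `target` grid. Constant
#' volumes map to the same constant; an identity target returns the input
#' bit-identically.
#'
#' @param x A 3D numeric array.
#' @param target Target dimensions (`dim3` or length-3 integer vector).
#' @return A 3D numeric array with dimensions `target`.
#' @export
resample_trilinear <- function(x, target) {
  src <- dim(x)
  tgt <- as.integer(target)
  stopifnot(length(src) == 3, length(tgt) == 3, all(tgt >= 1))
  if (identical(as.integer(src), tgt)) return(x)
  coord <- function(n_t, n_s) {
    # voxel-centre mapping: target centre t maps to source coord
    s <- (seq_len(n_t) - 0.5) * (n_s / n_t) + 0.5
    pmin(pmax(s, 1), n_s)
  }
  cs <- lapply(1:3, function(i) coord(tgt[i], src[i]))
  lo <- lapply(seq_along(cs), function(i) {
    l <- floor(cs[[i]])
    as.integer(pmax(1L, pmin(l, max(1L, src[i] - 1L))))
  })
  fr <- lapply(seq_along(cs), function(i) cs[[i]] - lo[[i]])
  hi <- lapply(seq_along(lo), function(i) pmin(lo[[i]] + 1L, src[i]))
  out <- array(0, tgt)
  g <- expand.grid(d = seq_len(tgt[1]), h = seq_len(tgt[2]), w = seq_len(tgt[3]))
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    iz <- if (bz == 0) lo[[1]][g$d] else hi[[1]][g$d]
    iy <- if (by == 0) lo[[2]][g$h] else hi[[2]][g$h]
    ix <- if (bx == 0) lo[[3]][g$w] else hi[[3]][g$w]
    wz <- if (bz == 0) 1 - fr[[1]][g$d] else fr[[1]][g$d]
    wy <- if (by == 0) 1 - fr[[2]][g$h] else fr[[2]][g$h]
    wx <- if (bx == 0) 1 - fr[[3]][g$w] else fr[[3]][g$w]
    out <- out + array(wz * wy * wx * x[cbind(iz, iy, ix)], tgt)
  }
  out
}

# Nearest-neighbour resampling for integer label grids (atlas downsampling);
# preserves label identity.
resample_nearest <- function(x, target) {
  src <- dim(x)
  tgt <- as.integer(target)
  if (identical(as.integer(src), tgt)) return(x)
  idx <- lapply(1:3, function(i) {
    s <- (seq_len(tgt[i]) - 0.5) * (src[i] / tgt[i]) + 0.5
    as.integer(pmin(pmax(round(s), 1), src[i]))
  })
  g <- expand.grid(d = idx[[1]], h = idx[[2]], w = idx[[3]])
  array(x[cbind(g$d, g$h, g$w)], tgt)
}
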