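# Region-level validation of model attention against ordinal pathology
# grades: aggregate the disease-class attention map per atlas region,
# normalized by region volume, then Spearman rank correlation across
# subjects.

#' Region-level attention scores
#'
#' `score_r = mean over region-r voxels of attention[target_class]`. By
#' default the atlas is downsampled to the attention grid by nearest-neighbour
#' resampling (preserving label identity); alternatively the attention map is
#' upsampled trilinearly to the atlas grid.
#'
#' @param attention An `attention_stack` (or raw K x D x H x W array).
#' @param target_class Class whose map is aggregated (0-based; the disease
#'   class for pathology validation).
#' @param atlas An `atlas_volume`.
#' @param direction `"atlas_down"` (default) or `"attention_up"`.
#' @param absolute If `TRUE`, aggregate `|attention|` instead of signed
#'   values.
#' @param subject_id Recorded in the output.
#' @return A `region_score_table`: list with `subject_id`, `scores` (named
#'   numeric, one entry per region present after resampling), `target_class`,
#'   and `empty_regions` (ids lost to resampling, if any).
#' @export
region_attention_scores <- function(attention, target_class, atlas,
                                    direction = c("atlas_down", "attention_up"),
                                    absolute = FALSE, subject_id = "") {
  direction <- match.arg(direction)
  M <- attention_maps(attention)
  K <- dim(M)[1]
  if (target_class < 0 || target_class >= K)
    stop("region_attention_scores: target_class outside 0..", K - 1)
  amap <- array(M[target_class + 1L, , , ], dim(M)[2:4])
  if (absolute) amap <- abs(amap)
  if (direction == "atlas_down") {
    lab <- resample_nearest(atlas$labels, dim(amap))
  } else {
    amap <- resample_trilinear(amap, dim(atlas$labels))
    lab <- atlas$labels
  }
  region_ids <- as.integer(names(atlas$region_volumes))
  present <- region_ids[region_ids %in% lab]
  empty <- setdiff(region_ids, present)
  scores <- vapply(present, function(r) mean(amap[lab == r]), 0.0)
  names(scores) <- as.character(present)
  structure(list(subject_id = subject_id, scores = scores,
                 target_class = as.integer(target_class),
                 empty_regions = empty),
            class = "region_score_table")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average ranks).
#' Returns `NA` — reported as missing, never coerced to 0 — when either
#' vector is constant.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Rho in `[-1, 1]`, or `NA_real_` for a constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("spearman_rho: input lengths differ (", length(x), " vs ",
         length(y), ")")
  if (length(x) < 3) stop("spearman_rho: need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Correlate attention scores with pathology grades across subjects
#'
#' For every atlas region present in both tables with at least `min_n`
#' overlapping subjects, computes the Spearman correlation between the
#' region's attention score and its ordinal pathology grade across subjects.
#' Regions with constant grades (or scores) are reported with `rho = NA`;
#' regions below the subject threshold are omitted.
#'
#' @param scores List of `region_score_table`s (one per subject).
#' @param grades List of `pathology_grades` (one per subject).
#' @param stain Stain label recorded in the output (e.g. `"amyloid_beta"`,
#'   `"NFT"`, `"NP"`).
#' @param min_n Minimum overlapping subjects per region (default 3).
#' @return A `correlation_table` data.frame with columns `region_id`, `stain`,
#'   `rho`, `n`, `p_value` (t-approximation, reported but not used for any
#'   decision).
#' @export
correlate_with_pathology <- function(scores, grades, stain = "grade",
                                     min_n = 3) {
  sid_s <- vapply(scores, function(s) s$subject_id, "")
  sid_g <- vapply(grades, function(g) g$subject_id, "")
  common <- intersect(sid_s, sid_g)
  if (!length(common))
    stop("correlate_with_pathology: no overlapping subjects")
  s_by <- stats::setNames(scores, sid_s)[common]
  g_by <- stats::setNames(grades, sid_g)[common]
  region_ids <- Reduce(intersect, c(
    lapply(s_by, function(s) names(s$scores)),
    lapply(g_by, function(g) names(g$grades))))
  rows <- list()
  for (r in region_ids) {
    xv <- vapply(s_by, function(s) unname(s$scores[r]), 0.0)
    yv <- vapply(g_by, function(g) as.numeric(g$grades[r]), 0.0)
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < min_n) {
      message("correlate_with_pathology: region ", r, " has ", sum(ok),
              " subjects (< ", min_n, "); omitted")
      next
    }
    rho <- spearman_rho(xv[ok], yv[ok])
    n <- sum(ok)
    p <- if (is.na(rho) || abs(rho) >= 1) NA_real_ else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
    rows[[r]] <- data.frame(region_id = as.integer(r), stain = stain,
                            rho = rho, n = n, p_value = p)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = integer(), stain = character(), rho = numeric(),
               n = integer(), p_value = numeric())
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}
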