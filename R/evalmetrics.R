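# Accuracy, macro F1 and multiclass Matthews correlation coefficient from
# confusion matrices, with fold-wise aggregation.
#
# Convention: counts[p, t] is the number of samples of true class t predicted
# as class p (rows = predicted, columns = true), so column sums are the
# per-class true occurrences t_k and row sums the per-class prediction counts
# p_k.

#' Build a confusion matrix
#'
#' @param true_labels,predicted Integer vectors in 0..K-1, equal length >= 1.
#' @param K Number of classes.
#' @return A `confusion_matrix`: K x K integer matrix (rows = predicted,
#'   columns = true).
#' @export
confusion <- function(true_labels, predicted, K) {
  true_labels <- as.integer(true_labels)
  predicted <- as.integer(predicted)
  if (length(true_labels) != length(predicted))
    stop("confusion: label vectors differ in length")
  if (!length(true_labels)) stop("confusion: empty input")
  bad <- which(true_labels < 0 | true_labels >= K |
                 predicted < 0 | predicted >= K)
  if (length(bad))
    stop("confusion: out-of-range label at index ", bad[1])
  m <- matrix(0L, K, K)
  for (i in seq_along(true_labels))
    m[predicted[i] + 1L, true_labels[i] + 1L] <-
      m[predicted[i] + 1L, true_labels[i] + 1L] + 1L
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Accuracy from a confusion matrix
#'
#' @param m A K x K confusion matrix.
#' @return Fraction of correctly classified samples, `sum(diag) / sum`.
#' @export
accuracy <- function(m) {
  m <- unclass(m)
  sum(diag(m)) / sum(m)
}

#' Macro F1 score
#'
#' Unweighted mean over classes of the harmonic mean of per-class precision
#' and recall; a class with an empty denominator (never predicted and never
#' present, or zero precision + recall) contributes F1 = 0. Symmetric under
#' transposition of the confusion matrix.
#'
#' @param m A K x K confusion matrix (rows = predicted, columns = true).
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(m) {
  m <- unclass(m)
  K <- nrow(m)
  f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- m[k, k]
    col_sum <- sum(m[, k])   # true occurrences of k
    row_sum <- sum(m[k, ])   # predictions of k
    p <- if (col_sum > 0) tp / col_sum else 0
    r <- if (row_sum > 0) tp / row_sum else 0
    f1[k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  mean(f1)
}

#' Multiclass Matthews correlation coefficient
#'
#' `(c*s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))` with
#' `t_k` the true occurrences (column sums), `p_k` the prediction counts (row
#' sums), `c` the correct count and `s` the total. Returns 0 when either
#' factor under the square root vanishes (single-class predictions or truth).
#'
#' @param m A K x K confusion matrix (rows = predicted, columns = true).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(m) {
  m <- unclass(m)
  t_k <- colSums(m)
  p_k <- rowSums(m)
  c_ <- sum(diag(m))
  s <- sum(m)
  num <- c_ * s - sum(p_k * t_k)
  f1 <- s^2 - sum(p_k^2)
  f2 <- s^2 - sum(t_k^2)
  if (f1 <= 0 || f2 <= 0) return(0)
  num / sqrt(f1 * f2)
}

#' Evaluate a model across domains
#'
#' Runs inference per domain and reports accuracy, macro F1 and MCC per
#' domain, plus an unweighted mean row over the target domains.
#'
#' @param model A `dgsal_model`.
#' @param datasets Named list: domain -> list of `volume_sample`s.
#' @param fold Fold index recorded in the output rows.
#' @param target_domains Domains averaged into the `"target_mean"` row
#'   (default: all provided domains).
#' @return A data.frame with columns `domain`, `fold`, `n`, `accuracy`,
#'   `macro_f1`, `mcc`.
#' @export
evaluate_model <- function(model, datasets, fold = 0L,
                           target_domains = names(datasets)) {
  if (!length(datasets)) stop("evaluate_model: no datasets")
  K <- model$config$n_classes
  rows <- list()
  for (dom in names(datasets)) {
    ds <- datasets[[dom]]
    if (!length(ds)) {
      warning("evaluate_model: empty dataset for domain ", dom, "; skipped")
      next
    }
    truth <- vapply(ds, function(s) s$label, 0L)
    preds <- vapply(ds, function(s)
      which.max(model_logits(model, s$volume)) - 1L, 0L)
    m <- confusion(truth, preds, K)
    rows[[dom]] <- data.frame(domain = dom, fold = fold, n = length(ds),
                              accuracy = accuracy(m), macro_f1 = macro_f1(m),
                              mcc = mcc(m))
  }
  df <- do.call(rbind, rows)
  tgt <- df[df$domain %in% target_domains, , drop = FALSE]
  if (nrow(tgt)) {
    df <- rbind(df, data.frame(domain = "target_mean", fold = fold,
                               n = sum(tgt$n),
                               accuracy = mean(tgt$accuracy),
                               macro_f1 = mean(tgt$macro_f1),
                               mcc = mean(tgt$mcc)))
  }
  rownames(df) <- NULL
  df
}

#' Aggregate per-fold metric rows to mean and standard deviation
#'
#' Population (not sample) standard deviation over folds, matching mean +/- sd
#' reporting across cross-validation runs.
#'
#' @param rows A data.frame of per-fold rows as produced by
#'   [evaluate_model()], stacked over folds.
#' @return A data.frame with one row per domain and `<metric>_mean`,
#'   `<metric>_sd` columns.
#' @export
aggregate_folds <- function(rows) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  doms <- unique(rows$domain)
  out <- lapply(doms, function(dom) {
    d <- rows[rows$domain == dom, , drop = FALSE]
    data.frame(domain = dom, n_folds = nrow(d),
               accuracy_mean = mean(d$accuracy), accuracy_sd = pop_sd(d$accuracy),
               macro_f1_mean = mean(d$macro_f1), macro_f1_sd = pop_sd(d$macro_f1),
               mcc_mean = mean(d$mcc), mcc_sd = pop_sd(d$mcc))
  })
  do.call(rbind, out)
}
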