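#' Top-L/k long-range contact precision
#'
#' Ranks upper-triangle pairs with sequence separation `j - i >= min_sep`
#' by score (ties broken by lower `(i, j)` lexicographic order for
#' determinism), takes the top `floor(k)`, and reports the fraction whose
#' true distance is at or below the contact threshold.
#'
#' @param scores L x L contact score matrix (larger = more confident).
#' @param truth L x L true Cb-Cb distance map (A).
#' @param k number of pairs to take, e.g. `floor(L/5)`; values are floored.
#' @param min_sep minimum sequence separation; default 24 (long range).
#' @param contact_threshold true-contact cutoff; default 8 A.
#' @return Precision in [0, 1]; `NA` with a message when no eligible pairs
#'   exist.
#' @export
contact_precision <- function(scores, truth, k, min_sep = 24,
                              contact_threshold = 8) {
  L <- nrow(scores)
  pairs <- which(upper.tri(scores) & (col(scores) - row(scores)) >= min_sep)
  if (length(pairs) == 0 || floor(k) < 1) {
    message("contact_precision: no eligible long-range pairs (L = ", L, ")")
    return(NA_real_)
  }
  i <- row(scores)[pairs]; j <- col(scores)[pairs]
  ord <- order(-scores[pairs], i, j)
  top <- pairs[ord][seq_len(min(floor(k), length(pairs)))]
  mean(truth[top] <= contact_threshold)
}

.filtered_pairs <- function(pred, truth, filter_on, cutoff) {
  ut <- upper.tri(pred)
  keep <- if (filter_on == "predicted") pred < cutoff else truth < cutoff
  which(ut & keep)
}

#' Mean squared error over distance-filtered pairs
#'
#' MSE over upper-triangle pairs whose predicted (default) or true distance
#' is below the cutoff. Predicted-side filtering is the evaluation
#' convention; true-side filtering matches the training mask.
#'
#' @param pred,truth L x L distance maps (A).
#' @param filter_on `"predicted"` or `"true"`.
#' @param cutoff filter cutoff; default 16 A.
#' @return MSE in A^2, or `NA` when no pairs pass the filter.
#' @export
filtered_mse <- function(pred, truth, filter_on = c("predicted", "true"),
                         cutoff = 16) {
  filter_on <- match.arg(filter_on)
  idx <- .filtered_pairs(pred, truth, filter_on, cutoff)
  if (length(idx) == 0) {
    message("filtered_mse: empty filtered set")
    return(NA_real_)
  }
  mean((pred[idx] - truth[idx])^2)
}

#' Pearson correlation between predicted and true distances
#'
#' Sample correlation over the same filtered pair set as [filtered_mse()].
#'
#' @inheritParams filtered_mse
#' @return Correlation in [-1, 1], or `NA` on < 2 pairs / zero variance.
#' @export
distance_pearson <- function(pred, truth, filter_on = c("predicted", "true"),
                             cutoff = 16) {
  filter_on <- match.arg(filter_on)
  idx <- .filtered_pairs(pred, truth, filter_on, cutoff)
  if (length(idx) < 2) {
    message("distance_pearson: fewer than 2 filtered pairs")
    return(NA_real_)
  }
  x <- pred[idx]; y <- truth[idx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("distance_pearson: zero variance in filtered pairs")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Full evaluation report for one prediction
#'
#' Bundles top-L/5, top-L/2 and top-L long-range contact precision,
#' filtered MSE and Pearson correlation into one record.
#'
#' @param scores L x L contact scores (see [realdist_to_contact()] /
#'   [distogram_to_contact()]).
#' @param pred L x L predicted distance map.
#' @param truth L x L true distance map.
#' @param min_sep,contact_threshold,filter_on,cutoff see the individual
#'   metrics.
#' @return A one-row `data.frame` (class `evaluation_report`).
#' @export
evaluation_report <- function(scores, pred, truth, min_sep = 24,
                              contact_threshold = 8,
                              filter_on = "predicted", cutoff = 16) {
  L <- nrow(truth)
  idx <- .filtered_pairs(pred, truth, filter_on, cutoff)
  out <- data.frame(
    precision_topL5 = contact_precision(scores, truth, floor(L / 5), min_sep,
                                        contact_threshold),
    precision_topL2 = contact_precision(scores, truth, floor(L / 2), min_sep,
                                        contact_threshold),
    precision_topL = contact_precision(scores, truth, L, min_sep,
                                       contact_threshold),
    mse = filtered_mse(pred, truth, filter_on, cutoff),
    pearson = distance_pearson(pred, truth, filter_on, cutoff),
    n_pairs_evaluated = length(idx),
    min_sep = min_sep, contact_threshold = contact_threshold,
    filter_on = filter_on, cutoff = cutoff)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Aggregate per-target evaluation reports into a mean row
#' @param reports list of [evaluation_report()] rows.
#' @return One-row data.frame of column means over the numeric metrics.
#' @export
aggregate_reports <- function(reports) {
  df <- do.call(rbind, lapply(reports, as.data.frame))
  num <- c("precision_topL5", "precision_topL2", "precision_topL",
           "mse", "pearson")
  out <- as.data.frame(lapply(df[num], mean, na.rm = TRUE))
  out$n_targets <- nrow(df)
  out
}
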