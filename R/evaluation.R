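#' Recall, precision and F1 over certain predictions
#'
#' Computes `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)` and
#' `F1 = 2*recall*precision/(recall+precision)` with `"transmissible"` as
#' the positive class. Predictions labelled `"uncertain"` are excluded from
#' the confusion counts.
#'
#' @param predicted Character vector of predicted labels
#'   (`"transmissible"`, `"non-transmissible"`, `"uncertain"`).
#' @param truth Character vector of true labels, aligned with `predicted`.
#' @return List with `recall`, `precision`, `f1`, `tp`, `fp`, `fn`,
#'   `n_certain`. Zero-denominator metrics are `NA` with a warning.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must have the same length")
  }
  certain <- predicted != "uncertain"
  if (!any(certain)) stop("no certain predictions to evaluate")
  p <- predicted[certain]
  y <- truth[certain]
  tp <- sum(p == "transmissible" & y == "transmissible")
  fp <- sum(p == "transmissible" & y == "non-transmissible")
  fn <- sum(p == "non-transmissible" & y == "transmissible")
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positives among certain predictions; recall undefined")
    NA_real_
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no positive predictions; precision undefined")
    NA_real_
  }
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else NA_real_
  list(recall = recall, precision = precision, f1 = f1,
       tp = tp, fp = fp, fn = fn, n_certain = sum(certain))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' mid-rank tie handling: the probability that a random positive scores
#' above a random negative, ties counted half.
#'
#' @param scores Numeric scores.
#' @param truth Positive-class indicator: logical, 0/1, or labels with
#'   `"transmissible"` as the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth) == "transmissible"
  }
  pos <- as.logical(truth)
  if (anyNA(pos)) stop("'truth' contains missing values")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an AUC")
  }
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Threshold sweep over the uncertainty parameter
#'
#' For each threshold `t`, labels every score with [classify_score()],
#' reports the uncertain-prediction rate, recall/precision/F1 computed on
#' certain predictions only, and the AUC. The AUC is computed on all scores
#' regardless of `t`: discarding mid-range scores does not change the
#' ranking information, and reporting it on the full set keeps the sweep
#' rows comparable.
#'
#' @param scores Numeric vector of sequence scores.
#' @param truth True labels aligned with `scores`.
#' @param t_values Thresholds in `[0, 0.5)`.
#' @param group Optional group tag copied into the report.
#' @return A `data.frame` with one row per threshold: `group`,
#'   `threshold_t`, `uncertain_rate`, `recall`, `precision`, `f1`, `auc`,
#'   `n_pos`, `n_neg`, `n_certain`.
#' @export
threshold_sweep <- function(scores, truth, t_values = c(0, 0.1, 0.2),
                            group = NA_character_) {
  truth <- if (is.character(truth) || is.factor(truth)) {
    as.character(truth)
  } else {
    ifelse(as.logical(truth), "transmissible", "non-transmissible")
  }
  full_auc <- auc(scores, truth)
  rows <- lapply(t_values, function(t) {
    labels <- classify_score(scores, t)
    m <- confusion_metrics(labels, truth)
    data.frame(group = group, threshold_t = t,
               uncertain_rate = mean(labels == "uncertain"),
               recall = m$recall, precision = m$precision, f1 = m$f1,
               auc = full_auc,
               n_pos = sum(truth == "transmissible"),
               n_neg = sum(truth == "non-transmissible"),
               n_certain = m$n_certain,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Grouped threshold-sweep report
#'
#' Applies [threshold_sweep()] within each benchmark group (the length
#' strata A-D), producing one report row per group per threshold.
#'
#' @param predictions A `data.frame` with columns `sequence_id` and `score`
#'   (as from [predict_sequences()]).
#' @param truth A `data.frame` with columns `fragment_id` (or
#'   `sequence_id`), `label` and `group` (the benchmark manifest).
#' @param t_values Thresholds in `[0, 0.5)`.
#' @return A `data.frame`, rows ordered by group then threshold.
#' @export
evaluate_groups <- function(predictions, truth, t_values = c(0, 0.1, 0.2)) {
  id_col <- if (!is.null(truth$fragment_id)) "fragment_id" else "sequence_id"
  m <- match(predictions$sequence_id, truth[[id_col]])
  if (anyNA(m)) stop("predictions contain ids absent from the truth table")
  df <- data.frame(score = predictions$score,
                   label = truth$label[m],
                   group = truth$group[m], stringsAsFactors = FALSE)
  out <- lapply(split(df, df$group), function(d) {
    threshold_sweep(d$score, d$label, t_values, group = d$group[1L])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
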