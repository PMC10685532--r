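# Binary-classification evaluation protocol: expert star ratings are
# collapsed to binary ground truth (ratings 3-5 positive, 1-2 negative),
# the corpus is split 90:10 (the held-out 10% is scored), and performance
# is reported as a confusion matrix, precision / recall / specificity /
# accuracy / F-measure, and rank-based AUC — per feedback section.

#' Map a 1..5 satisfaction rating to a binary label
#'
#' Ratings 3, 4 and 5 are positive; 1 and 2 are negative.
#'
#' @param rating Integer vector with values in 1..5.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
rating_to_label <- function(rating) {
  if (any(is.na(rating)) || any(rating %% 1 != 0) ||
      any(rating < 1 | rating > 5))
    stop_range("rating must be an integer in 1..5")
  ifelse(rating >= 3, "positive", "negative")
}

#' Train/test split of comment ids
#'
#' Splits ids into disjoint, exhaustive train and test sets with
#' `|test| = round((1 - ratio) * n)`. When labels are supplied the split is
#' stratified: each stratum contributes to the test set in proportion to
#' its size, fractional seats resolved by largest remainder. Reproducible
#' for a fixed seed.
#'
#' @param ids Vector of ids (length >= 2).
#' @param ratio Training fraction in (0, 1); default 0.9.
#' @param seed RNG seed.
#' @param labels Optional vector of labels, parallel to `ids`.
#' @return A list with `train` and `test` id vectors.
#' @export
split_corpus <- function(ids, ratio = 0.9, seed = 1L, labels = NULL) {
  n <- length(ids)
  if (n < 2L) stop_length("need at least 2 ids to split")
  if (ratio <= 0 || ratio >= 1) stop_range("ratio must be in (0, 1)")
  n_test <- round((1 - ratio) * n)
  set.seed(seed)
  if (is.null(labels)) {
    test_idx <- sample.int(n, n_test)
  } else {
    if (length(labels) != n) stop_length("labels must be parallel to ids")
    strata <- split(seq_len(n), labels)
    sizes <- lengths(strata)
    exact <- n_test * sizes / n
    take <- floor(exact)
    rem <- exact - take
    short <- n_test - sum(take)
    if (short > 0) {
      bump <- order(-rem)[seq_len(short)]
      take[bump] <- take[bump] + 1L
    }
    test_idx <- unlist(mapply(function(idx, m) {
      if (m > 0L) idx[sample.int(length(idx), m)] else integer()
    }, strata, take, SIMPLIFY = FALSE), use.names = FALSE)
  }
  list(train = ids[setdiff(seq_len(n), test_idx)],
       test = ids[sort(test_idx)])
}

#' Binary confusion matrix
#'
#' Counts follow the usual cell definitions: TP = truly positive and
#' predicted positive, FP = truly negative predicted positive, FN = truly
#' positive predicted negative, TN = truly negative predicted negative.
#'
#' @param truth,predicted Character vectors of `"positive"` / `"negative"`,
#'   equal length.
#' @return A list of class `confusion` with integer fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_length("truth and predicted must have the same length")
  ok <- c("positive", "negative")
  if (!all(truth %in% ok) || !all(predicted %in% ok))
    stop_label("labels must be 'positive' or 'negative'")
  structure(list(
    tp = sum(truth == "positive" & predicted == "positive"),
    fp = sum(truth == "negative" & predicted == "positive"),
    fn = sum(truth == "positive" & predicted == "negative"),
    tn = sum(truth == "negative" & predicted == "negative")
  ), class = "confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/(TP+TN+FP+FN)` and F-measure
#' `2*Precision*Recall/(Precision+Recall)`. Any metric with a zero
#' denominator is reported as `NA` (an explicit undefined marker), never an
#' error.
#'
#' @param cm A `confusion` object (or list with `tp`, `fp`, `fn`, `tn`).
#' @return A list of class `metrics_report` with fields `precision`,
#'   `recall`, `specificity`, `accuracy`, `f_measure` (and `auc`, `NA`
#'   until filled in by the caller).
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0L) stop_length("empty confusion matrix")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(precision = precision,
                 recall = recall,
                 specificity = safe_div(tn, tn + fp),
                 accuracy = (tp + tn) / total,
                 f_measure = f,
                 auc = NA_real_),
            class = "metrics_report")
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counted one half. Invariant under strictly monotone
#' transformations of the scores.
#'
#' @param scores Numeric vector.
#' @param truth Character vector of `"positive"` / `"negative"`; both
#'   classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop_length("scores and truth must have the same length")
  pos <- truth == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop_label("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-section evaluation report
#'
#' Evaluates lexicon predictions against rating-derived ground truth within
#' each feedback section and lays the result out as a metrics-by-section
#' table. Neutral-scored comments are excluded from the binary metrics by
#' default (`neutral = "drop"`); alternatively they can be forced to the
#' majority ground-truth class (`neutral = "majority"`). Sections with only
#' one ground-truth class are omitted with a warning.
#'
#' @param scores A data.frame with columns `comment_id`, `section`, `score`,
#'   `label` (predicted) and `rating` (1..5 ground truth).
#' @param neutral How to treat neutral predictions: `"drop"` or
#'   `"majority"`.
#' @return A data.frame with one row per metric (precision, recall,
#'   specificity, accuracy, f_measure, auc) and one column per section.
#' @export
evaluate_sections <- function(scores, neutral = c("drop", "majority")) {
  neutral <- match.arg(neutral)
  stopifnot(all(c("section", "score", "label", "rating") %in% names(scores)))
  metric_names <- c("precision", "recall", "specificity", "accuracy",
                    "f_measure", "auc")
  out <- data.frame(metric = metric_names, stringsAsFactors = FALSE)
  for (sec in unique(scores$section)) {
    d <- scores[scores$section == sec, , drop = FALSE]
    truth <- rating_to_label(d$rating)
    pred <- d$label
    if (neutral == "drop") {
      keep <- pred != "neutral"
      d <- d[keep, , drop = FALSE]
      truth <- truth[keep]
      pred <- pred[keep]
    } else {
      majority <- names(which.max(table(truth)))
      pred[pred == "neutral"] <- majority
    }
    if (!nrow(d) || length(unique(truth)) < 2L) {
      warning("section '", sec, "' lacks both classes and was omitted",
              call. = FALSE)
      next
    }
    m <- compute_metrics(confusion(truth, pred))
    m$auc <- auc_score(d$score, truth)
    out[[sec]] <- unlist(m[metric_names], use.names = FALSE)
  }
  out
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion> tp=", x$tp, " fp=", x$fp, " fn=", x$fn, " tn=", x$tn,
      "\n", sep = "")
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (m in c("precision", "recall", "specificity", "accuracy",
              "f_measure", "auc")) {
    cat("  ", format(m, width = 12), format(x[[m]], digits = 4), "\n")
  }
  invisible(x)
}
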