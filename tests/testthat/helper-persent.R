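# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: they recompute expected values from first
# principles so agreement is informative.

demo_lexicon <- function() {
  read_lexicon(system.file("extdata", "demo_lexicon.tsv", package = "persent"))
}

# brute-force sentence scorer: look up every token directly in the entry
# table, flip negated signs, then take max positive / min negative and the
# larger absolute value (tie -> 0)
oracle_sentence <- function(stems, negated, entries) {
  vals <- integer()
  for (i in seq_along(stems)) {
    if (stems[i] %in% names(entries)) {
      v <- entries[[stems[i]]]
      if (negated[i]) v <- -v
      vals <- c(vals, v)
    }
  }
  mp <- 0L
  mn <- 0L
  for (v in vals) {
    if (v > mp) mp <- v
    if (v < mn) mn <- v
  }
  pol <- if (mp > -mn) mp else if (-mn > mp) mn else 0L
  list(max_pos = mp, min_neg = mn, polarity = pol)
}

# confusion-matrix metrics straight from the defining formulas
oracle_metrics <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  p <- div(tp, tp + fp)
  r <- div(tp, tp + fn)
  list(precision = p,
       recall = r,
       specificity = div(tn, tn + fp),
       accuracy = (tp + tn) / (tp + fp + fn + tn),
       f_measure = if (is.na(p) || is.na(r) || p + r == 0) NA_real_
                   else 2 * p * r / (p + r))
}

# AUC by exhaustive enumeration of positive-negative pairs, ties = 1/2
oracle_auc <- function(scores, truth) {
  pos <- which(truth == "positive")
  neg <- which(truth == "negative")
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}

# ground-truth-aligned classification accuracy of a scored corpus
label_accuracy <- function(scores, truth_docs) {
  truth <- truth_docs$label[match(scores$comment_id, truth_docs$id)]
  mean(scores$label == truth)
}

# greedy one-to-one matching of planted to recovered topics by cosine
# similarity of topic-word rows over the shared vocabulary
match_topics <- function(phi_true, phi_fit) {
  shared <- intersect(colnames(phi_true), colnames(phi_fit))
  k <- nrow(phi_true)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  M <- outer(seq_len(k), seq_len(nrow(phi_fit)),
             Vectorize(function(i, j) cos(phi_true[i, shared],
                                          phi_fit[j, shared])))
  map <- integer(k)
  for (s in seq_len(k)) {
    idx <- which(M == max(M), arr.ind = TRUE)[1, ]
    map[idx[1]] <- idx[2]
    M[idx[1], ] <- -Inf
    M[, idx[2]] <- -Inf
  }
  map
}
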