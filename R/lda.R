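# Topic modeling by latent Dirichlet allocation.
#
# Comments are short, so the model is fitted by collapsed Gibbs sampling
# with smoothed count-based point estimates averaged over the post-burn-in
# sweeps. Defaults follow the common Griffiths-Steyvers settings
# (alpha = 50/k, beta = 0.01). The number of topics is chosen by UMass
# coherence, which rewards topics whose top words co-occur in documents —
# an automatic stand-in for the manual topic review a domain expert would
# perform.

#' Fit LDA by collapsed Gibbs sampling
#'
#' @param corpus A list of `normalized_doc` objects (stems are modeled), or
#'   a list of character vectors of tokens.
#' @param k Number of topics (>= 1).
#' @param alpha Document-topic concentration; default `50 / k`.
#' @param beta Topic-word concentration; default `0.01`.
#' @param n_iter Total Gibbs sweeps; default 1000.
#' @param burn_in Sweeps discarded before estimation; default `n_iter / 2`.
#' @param seed RNG seed; fixing it makes the fit bit-reproducible.
#' @return An object of class `lda_model`: `phi` (k x V topic-word
#'   probabilities, columns named by term), `theta` (D x k document-topic
#'   probabilities, rows named by document), `assignments` (per-token topic
#'   ids in 1..k), `log_likelihood` (per-sweep trace), `vocab`, `doc_ids`
#'   and the sampler settings.
#' @export
fit_lda <- function(corpus, k, alpha = 50 / k, beta = 0.01,
                    n_iter = 1000L, burn_in = n_iter %/% 2L, seed = 1L) {
  if (!length(corpus)) stop_corpus("corpus is empty")
  stopifnot(k >= 1L, alpha > 0, beta > 0, n_iter >= 1L, burn_in < n_iter)
  tokens <- lapply(corpus, function(d) {
    if (inherits(d, "normalized_doc")) d$tokens$stem else as.character(d)
  })
  if (any(!lengths(tokens)))
    stop_corpus("every document must contain at least one token")
  doc_ids <- names(corpus)
  if (is.null(doc_ids)) doc_ids <- as.character(seq_along(corpus))
  vocab <- sort(enc2utf8(unique(unlist(tokens, use.names = FALSE))),
                method = "radix")
  if (!length(vocab)) stop_corpus("degenerate vocabulary (V = 0)")

  doc_id <- rep.int(seq_along(tokens), lengths(tokens)) - 1L
  word_id <- match(unlist(tokens, use.names = FALSE), vocab) - 1L

  set.seed(seed)
  fit <- lda_gibbs_cpp(doc_id, word_id, length(tokens), length(vocab),
                       as.integer(k), alpha, beta,
                       as.integer(n_iter), as.integer(burn_in))
  phi <- fit$phi
  colnames(phi) <- vocab
  theta <- fit$theta
  rownames(theta) <- doc_ids
  structure(list(phi = phi, theta = theta,
                 assignments = fit$assignments + 1L,
                 log_likelihood = as.numeric(fit$log_likelihood),
                 vocab = vocab, doc_ids = doc_ids,
                 k = as.integer(k), alpha = alpha, beta = beta,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = seed),
            class = "lda_model")
}

#' Top words of a topic
#'
#' @param model An `lda_model`.
#' @param topic Topic index in `1..k`.
#' @param n Number of terms (truncated to the vocabulary size).
#' @return Character vector of the `n` highest-probability terms, ties
#'   broken lexicographically.
#' @export
top_words <- function(model, topic, n = 10L) {
  stopifnot(inherits(model, "lda_model"))
  if (topic < 1L || topic > model$k) stop_index("topic index out of range")
  p <- model$phi[topic, ]
  ord <- order(-p, enc2utf8(names(p)), method = "radix")
  names(p)[ord][seq_len(min(n, length(p)))]
}

#' Dominant topic of each document
#'
#' @param model An `lda_model`.
#' @param doc Document index (or vector of indices); defaults to all.
#' @return Integer vector of topic indices (argmax of the theta row, ties
#'   resolved to the lowest index), named by document id.
#' @export
dominant_topic <- function(model, doc = seq_len(nrow(model$theta))) {
  stopifnot(inherits(model, "lda_model"))
  if (any(doc < 1L | doc > nrow(model$theta)))
    stop_index("document index out of range")
  out <- apply(model$theta[doc, , drop = FALSE], 1L, which.max)
  stats::setNames(as.integer(out), model$doc_ids[doc])
}

#' UMass topic coherence
#'
#' For each topic, sums `log((D(w_i, w_j) + 1) / D(w_j))` over all ordered
#' pairs of its `top_n` words, where `D(w)` counts documents containing `w`
#' and `D(w_i, w_j)` documents containing both. Higher (closer to 0) is
#' better; words that never co-occur drive the score strongly negative.
#'
#' @param model An `lda_model`.
#' @param corpus The corpus the model was fitted on (same formats as
#'   [fit_lda()]).
#' @param top_n Number of top words per topic (default 10).
#' @return Numeric vector of per-topic coherence values.
#' @export
topic_coherence <- function(model, corpus, top_n = 10L) {
  stopifnot(inherits(model, "lda_model"))
  tokens <- lapply(corpus, function(d) {
    if (inherits(d, "normalized_doc")) d$tokens$stem else as.character(d)
  })
  doc_sets <- lapply(tokens, unique)
  vapply(seq_len(model$k), function(t) {
    words <- top_words(model, t, top_n)
    if (length(words) < 2L) return(0)
    present <- vapply(doc_sets, function(s) words %in% s,
                      logical(length(words)))
    if (is.null(dim(present))) present <- matrix(present, nrow = length(words))
    dw <- rowSums(present)
    total <- 0
    for (i in 2:length(words)) {
      for (j in 1:(i - 1)) {
        dij <- sum(present[i, ] & present[j, ])
        # D(w_j) = 0 cannot happen for a word present in phi's vocabulary,
        # but guard against a user-supplied foreign corpus
        if (dw[j] > 0) total <- total + log((dij + 1) / dw[j])
      }
    }
    total
  }, numeric(1))
}

#' Choose the number of topics by mean coherence
#'
#' Fits one model per candidate `k` (each from the same seed so the sweep is
#' reproducible), computes the mean UMass coherence over topics, and returns
#' the `k` maximizing it; exact ties go to the smaller `k`. The full per-k
#' table is returned so the candidate models can also be reviewed manually.
#'
#' @param corpus Corpus in a [fit_lda()]-accepted format.
#' @param k_values Non-empty vector of candidate topic counts.
#' @param top_n Words per topic used for coherence (default 10).
#' @param seed Seed reused for every fit.
#' @param ... Further arguments passed to [fit_lda()] (`n_iter`, ...).
#' @return A list with `k` (the chosen count), `table` (data.frame of
#'   `k` and `mean_coherence`), and `models` (the fitted models, named by k).
#' @export
select_k <- function(corpus, k_values, top_n = 10L, seed = 1L, ...) {
  if (!length(k_values)) stop_config("k_values must be non-empty")
  k_values <- sort(unique(as.integer(k_values)))
  models <- list()
  coh <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    m <- fit_lda(corpus, k = k_values[i], seed = seed, ...)
    models[[as.character(k_values[i])]] <- m
    coh[i] <- mean(topic_coherence(m, corpus, top_n))
  }
  best <- k_values[which.max(coh)]   # ties -> first, i.e. smallest k
  list(k = best,
       table = data.frame(k = k_values, mean_coherence = coh),
       models = models)
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> k=", x$k, ", D=", nrow(x$theta), ", V=", length(x$vocab),
      ", ", x$n_iter, " sweeps (burn-in ", x$burn_in, ")\n", sep = "")
  for (t in seq_len(x$k)) {
    cat("  topic ", t, ": ", paste(top_words(x, t, 8L), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}
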