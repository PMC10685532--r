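# End-to-end pipeline: read comments -> normalize -> score -> topics ->
# per-topic sentiment -> evaluation -> term frequencies, with every
# artifact written to open text formats (JSON-lines for per-comment
# records, CSV for tabular reports) plus a manifest recording seeds and
# configuration for reproducibility.

#' Read a comment CSV
#'
#' Expected header: `id,section,text,rating,age`; `rating` and `age` may be
#' blank. Malformed rows (empty text, rating outside 1..5, unknown section)
#' are rejected with their row numbers.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A data.frame with columns `id` (character), `section`, `text`,
#'   `rating` (integer or NA), `age` (integer or NA).
#' @export
read_comments <- function(path) {
  if (!file.exists(path)) stop_format(paste0("comments file not found: ", path))
  df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  if (!nrow(df)) stop_format("comments file has no rows")
  need <- c("id", "section", "text")
  if (!all(need %in% names(df)))
    stop_format("comments CSV must have columns id, section, text")
  if (!"rating" %in% names(df)) df$rating <- ""
  if (!"age" %in% names(df)) df$age <- ""
  sections <- c("healthcare_services", "general_services", "life_expectancy")
  bad <- which(!nzchar(trimws(df$text)) | !(df$section %in% sections))
  rating <- suppressWarnings(as.integer(df$rating))
  bad_rating <- which(nzchar(df$rating) &
                        (is.na(rating) | rating < 1L | rating > 5L))
  bad <- sort(unique(c(bad, bad_rating)))
  if (length(bad))
    stop_format(paste0("malformed comment row(s): ",
                       paste(bad, collapse = ", ")))
  data.frame(id = df$id, section = df$section, text = df$text,
             rating = rating,
             age = suppressWarnings(as.integer(df$age)),
             stringsAsFactors = FALSE)
}

write_jsonl <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

# write via a temporary file in the same directory, then rename: a crashed
# run never leaves a half-written artifact behind
atomically <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full opinion-mining pipeline
#'
#' Executes normalize -> score -> topic model -> per-topic sentiment ->
#' evaluation -> term frequency in order and writes six artifacts to
#' `out_dir`: `normalized.jsonl`, `scores.jsonl`, `topics.json`,
#' `topic_sentiment.csv`, `metrics.json`, `frequency.csv`, plus
#' `manifest.json` recording seeds and configuration. If no comment
#' carries a rating the evaluation stage is skipped with a message and
#' `metrics.json` is omitted.
#'
#' @param comments Comment data.frame (see [read_comments()]).
#' @param lexicon A `sentiment_lexicon`.
#' @param out_dir Output directory (created if needed).
#' @param rules A `norm_rules`.
#' @param k Number of topics, or a vector of candidates to sweep with
#'   [select_k()].
#' @param seed Seed for the topic model and evaluation split.
#' @param n_iter Gibbs sweeps for the topic model.
#' @param neutral_band Neutral zone half-width for classification.
#' @param split_ratio Training fraction for the evaluation split; the
#'   held-out fraction is what the metrics are computed on.
#' @param top_n_terms Terms in the frequency report.
#' @return Invisibly, a list with the in-memory results (`docs`, `scores`,
#'   `model`, `topic_table`, `metrics`, `frequencies`, `paths`).
#' @export
run_pipeline <- function(comments, lexicon, out_dir,
                         rules = default_rules(), k = 6L, seed = 42L,
                         n_iter = 1000L, neutral_band = 0,
                         split_ratio = 0.9, top_n_terms = 20L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  docs <- normalize_corpus(comments, rules, lexicon = lexicon)
  paths$normalized <- atomically(file.path(out_dir, "normalized.jsonl"), function(p)
    write_jsonl(lapply(docs, function(d) {
      list(comment_id = d$comment_id, section = d$section,
           sentences = lapply(split(d$tokens, d$tokens$sentence), function(s)
             list(surface = s$surface, stem = s$stem, negated = s$negated)))
    }), p))

  scores <- score_corpus(docs, lexicon, neutral_band)
  doc_pols <- lapply(docs, function(d)
    score_document(d, lexicon, neutral_band)$sentence_polarities)
  paths$scores <- atomically(file.path(out_dir, "scores.jsonl"), function(p)
    write_jsonl(lapply(seq_len(nrow(scores)), function(i)
      list(comment_id = scores$comment_id[i], section = scores$section[i],
           score = scores$score[i], label = scores$label[i],
           sentence_polarities = doc_pols[[scores$comment_id[i]]])), p))

  if (length(k) > 1L) {
    sweep <- select_k(docs, k_values = k, seed = seed, n_iter = n_iter)
    model <- sweep$models[[as.character(sweep$k)]]
    k_table <- sweep$table
  } else {
    model <- fit_lda(docs, k = k, seed = seed, n_iter = n_iter)
    k_table <- NULL
  }
  dom <- dominant_topic(model)
  coh <- topic_coherence(model, docs)
  paths$topics <- atomically(file.path(out_dir, "topics.json"), function(p)
    jsonlite::write_json(list(
      k = model$k, seed = seed,
      top_words = lapply(seq_len(model$k), function(t) top_words(model, t, 10L)),
      coherence = coh,
      k_sweep = k_table,
      dominant_topic = as.list(dom),
      theta = apply(model$theta, 1L, function(r) round(r, 6), simplify = FALSE)
    ), p, auto_unbox = TRUE, digits = NA))

  topic_table <- topic_sentiment(scores, dom, model$k)
  paths$topic_sentiment <- atomically(file.path(out_dir, "topic_sentiment.csv"),
    function(p) utils::write.csv(topic_table, p, row.names = FALSE,
                                 fileEncoding = "UTF-8"))

  metrics <- NULL
  if (any(!is.na(comments$rating))) {
    rated <- comments[!is.na(comments$rating), ]
    eval_scores <- merge(scores, rated[, c("id", "rating")],
                         by.x = "comment_id", by.y = "id")
    truth <- rating_to_label(eval_scores$rating)
    split <- split_corpus(eval_scores$comment_id, ratio = split_ratio,
                          seed = seed, labels = truth)
    test <- eval_scores[eval_scores$comment_id %in% split$test, ]
    metrics <- evaluate_sections(test)
    paths$metrics <- atomically(file.path(out_dir, "metrics.json"), function(p)
      jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA,
                           na = "null"))
  } else {
    message("no ratings present; evaluation stage skipped")
  }

  freqs <- term_frequency_report(docs, top_n_terms)
  paths$frequency <- atomically(file.path(out_dir, "frequency.csv"), function(p)
    utils::write.csv(freqs, p, row.names = FALSE, fileEncoding = "UTF-8"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("persent")),
    n_comments = nrow(comments), n_documents = length(docs),
    k = model$k, seed = seed, n_iter = n_iter,
    neutral_band = neutral_band, split_ratio = split_ratio,
    artifacts = lapply(paths, basename)
  )
  paths$manifest <- atomically(file.path(out_dir, "manifest.json"), function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE))

  invisible(list(docs = docs, scores = scores, model = model,
                 topic_table = topic_table, metrics = metrics,
                 frequencies = freqs, paths = paths))
}
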