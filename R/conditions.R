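# Typed error conditions used across the package. Every user-facing failure
# carries a condition class so callers (and tests) can dispatch on it rather
# than matching message strings.

persent_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "persent_error")))
}

stop_format <- function(msg) persent_error(msg, "persent_format_error")
stop_range <- function(msg) persent_error(msg, "persent_range_error")
stop_duplicate <- function(msg) persent_error(msg, "persent_duplicate_error")
stop_empty_document <- function(msg) persent_error(msg, "persent_empty_document")
stop_weight <- function(msg) persent_error(msg, "persent_weight_error")
stop_length <- function(msg) persent_error(msg, "persent_length_error")
stop_index <- function(msg) persent_error(msg, "persent_index_error")
stop_config <- function(msg) persent_error(msg, "persent_config_error")
stop_corpus <- function(msg) persent_error(msg, "persent_corpus_error")
stop_label <- function(msg) persent_error(msg, "persent_label_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
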