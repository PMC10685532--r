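# Sentiment lexicon: term -> integer strength in -5..+5 (zero forbidden),
# plus the negation shifter particles and their protected exceptions.
# Strength conventions follow the SentiStrength family of lexicons: the
# magnitude encodes how strongly a term carries sentiment, the sign its
# direction, and absence from the lexicon means neutral.

#' Construct a sentiment lexicon
#'
#' @param entries Named integer vector: names are (stemmed) terms, values
#'   strengths in `{-5..-1, 1..5}`. Zero is forbidden so that "absent from
#'   the lexicon" is the only way a term can be neutral.
#' @param shifters Negation particles; a word starting with one of these is
#'   a candidate negation (defaults "ضد", "نا", "ن").
#' @param protected_words Words that begin with a shifter but are not
#'   negations (e.g. "نان", bread).
#' @return An object of class `sentiment_lexicon`.
#' @export
sentiment_lexicon <- function(entries,
                              shifters = c("ضد", "نا", "ن"),
                              protected_words = character()) {
  entries <- as.integer(round(entries)) |> stats::setNames(names(entries))
  if (length(entries)) {
    if (is.null(names(entries)) || any(!nzchar(names(entries))))
      stop_format("every lexicon entry must be a named term")
    if (anyDuplicated(names(entries)))
      stop_duplicate("duplicate term in lexicon")
    bad <- entries == 0L | abs(entries) > 5L | is.na(entries)
    if (any(bad))
      stop_range(paste0("lexicon strength must be in -5..-1 or 1..5; offending term(s): ",
                        paste(names(entries)[bad], collapse = ", ")))
  }
  if (!length(shifters)) stop_format("shifters must be non-empty")
  lex <- list(entries = entries,
              shifters = as.character(shifters),
              protected_words = as.character(protected_words))
  class(lex) <- "sentiment_lexicon"
  lex
}

#' Load a sentiment lexicon from a TSV file
#'
#' Expected format: UTF-8, a header line `term<TAB>strength`, then one
#' entry per line. Strengths must be non-zero integers in -5..5 and terms
#' must be unique.
#'
#' @param path Path to the TSV file.
#' @param shifters,protected_words Passed to [sentiment_lexicon()].
#' @return A `sentiment_lexicon`.
#' @export
read_lexicon <- function(path, shifters = c("ضد", "نا", "ن"),
                         protected_words = character()) {
  if (!file.exists(path)) stop_format(paste0("lexicon file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_format("lexicon file is empty (no header)")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) != 2L || header[1] != "term" || header[2] != "strength")
    stop_format("lexicon header must be 'term<TAB>strength'")
  body <- lines[-1]
  if (!length(body))
    return(sentiment_lexicon(stats::setNames(integer(), character()),
                             shifters, protected_words))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L))
    stop_format(paste0("lexicon line(s) with bad column count: ",
                       paste(which(nfield != 2L) + 1L, collapse = ", ")))
  terms <- vapply(parts, `[[`, character(1), 1L)
  raw <- vapply(parts, `[[`, character(1), 2L)
  strengths <- suppressWarnings(as.integer(raw))
  if (any(is.na(strengths)) || any(as.numeric(raw) != strengths))
    stop_format("lexicon strengths must be integers")
  if (any(strengths == 0L | abs(strengths) > 5L))
    stop_range("lexicon strength out of range (must be in -5..-1 or 1..5)")
  if (anyDuplicated(terms))
    stop_duplicate(paste0("duplicate lexicon term(s): ",
                          paste(unique(terms[duplicated(terms)]), collapse = ", ")))
  sentiment_lexicon(stats::setNames(strengths, terms), shifters, protected_words)
}

#' Write a sentiment lexicon to a TSV file
#'
#' Terms are written in sorted order so output is deterministic;
#' `read_lexicon(write_lexicon(L))` reproduces `L`'s entries exactly.
#'
#' @param lexicon A `sentiment_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  terms <- sort(enc2utf8(names(lexicon$entries)), method = "radix")
  lines <- c("term\tstrength",
             if (length(terms)) paste0(terms, "\t", lexicon$entries[terms]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Detect rule-based negation on surface tokens
#'
#' A token is negated when it starts with a shifter particle, is not itself
#' a lexicon term or a protected word, and the shifter-stripped remainder
#' is known — i.e. the remainder (or its stem) is a lexicon term, or it
#' appears in the supplied vocabulary. The known-remainder guard prevents
#' false shifts on words that merely begin with a shifter (person names,
#' "نظافت", ...). Longer shifters are tried first, and a
#' half-space after the particle is absorbed.
#'
#' @param tokens Character vector of normalized surface tokens.
#' @param lexicon A `sentiment_lexicon`.
#' @param vocabulary Optional character vector of additional known words.
#' @param rules Optional `norm_rules` used to stem the remainder before the
#'   lexicon check.
#' @return A data.frame with columns `base` (shifter-stripped surface) and
#'   `negated` (logical), one row per input token, order preserved.
#' @export
detect_negation <- function(tokens, lexicon, vocabulary = NULL,
                            rules = default_rules()) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  n <- length(tokens)
  base <- tokens
  negated <- rep(FALSE, n)
  if (!n) return(data.frame(base = character(), negated = logical()))
  terms <- names(lexicon$entries)
  known <- function(x) {
    x %in% terms || x %in% vocabulary ||
      stem_tokens(x, rules) %in% terms
  }
  shifters <- lexicon$shifters[order(-nchar(lexicon$shifters))]
  for (i in seq_len(n)) {
    tok <- tokens[[i]]
    if (tok %in% lexicon$protected_words || tok %in% terms) next
    for (sh in shifters) {
      if (!startsWith(tok, sh)) next
      rest <- substring(tok, nchar(sh) + 1L)
      rest <- sub("^\u200c", "", rest)   # absorb half-space after particle
      if (nzchar(rest) && known(rest)) {
        base[[i]] <- rest
        negated[[i]] <- TRUE
        break
      }
    }
  }
  data.frame(base = base, negated = negated, stringsAsFactors = FALSE)
}

#' Look up term strengths with negation handling
#'
#' Returns the lexicon strength for each stem, with the sign inverted where
#' the token was negated; terms absent from the lexicon yield `NA`
#' (neutral-absent). Sign inversion is the standard shifter semantics for
#' strength lexicons: "not good" is as negative as "good" is positive.
#'
#' @param lexicon A `sentiment_lexicon`.
#' @param stems Character vector of stems.
#' @param negated Logical vector, same length (default all `FALSE`).
#' @return Integer vector of signed strengths, `NA` where neutral-absent.
#' @export
lookup_strength <- function(lexicon, stems, negated = rep(FALSE, length(stems))) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"),
            length(stems) == length(negated))
  s <- unname(lexicon$entries[stems])
  ifelse(negated & !is.na(s), -s, s)
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  e <- x$entries
  cat("<sentiment_lexicon> ", length(e), " terms (",
      sum(e > 0), " positive, ", sum(e < 0), " negative), shifters: ",
      paste(x$shifters, collapse = " "), "\n", sep = "")
  invisible(x)
}
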