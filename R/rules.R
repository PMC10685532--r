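# Normalization rule sets.
#
# Persian orthography admits many surface variants for the same word: Arabic
# code points for ی and ک, optional half-space (ZWNJ, U+200C) inside words,
# kashida elongation (U+0640), detached suffixes, spaced prefixes, and
# APLL-divergent spellings. A rule set bundles everything the normalizer
# needs to map these variants onto one canonical form.

#' Zero-width non-joiner (half-space) used inside Persian words
#' @keywords internal
ZWNJ <- "\u200c"

#' Kashida (tatweel) elongation character
#' @keywords internal
KASHIDA <- "\u0640"

#' Build the default Persian normalization rule set
#'
#' The rule set drives every normalization step: a character map unifying
#' Arabic code points with their Persian counterparts (plus an explicit
#' whole-word list restoring initial "آ"), a spelling-variant map for
#' APLL-divergent and compound spellings, suffix and prefix inventories for
#' affix standardization, a stopword list, negation shifter particles with
#' their protected exceptions, and the punctuation/elongation character sets.
#'
#' The "آ" restoration is deliberately list-driven: a blanket rule
#' rewriting every word-initial "ا" would corrupt the many valid words
#' that begin with plain alef, so only words enumerated in the character map
#' are touched.
#'
#' @param stopwords Character vector of stopwords; defaults to the bundled
#'   Persian list (`inst/extdata/stopwords_fa.txt`).
#' @return An object of class `norm_rules`.
#' @export
default_rules <- function(stopwords = NULL) {
  if (is.null(stopwords)) {
    path <- system.file("extdata", "stopwords_fa.txt", package = "persent")
    stopwords <- if (nzchar(path)) read_utf8_lines(path) else character()
  }
  char_map <- c(
    # Arabic -> Persian code points (single characters)
    "ي" = "ی",  # ARABIC YEH -> FARSI YEH
    "ى" = "ی",  # ALEF MAKSURA -> FARSI YEH
    "ك" = "ک",  # ARABIC KAF -> KEHEH
    "أ" = "ا",  # ALEF WITH HAMZA ABOVE -> ALEF
    "إ" = "ا",  # ALEF WITH HAMZA BELOW -> ALEF
    "ٱ" = "ا",  # ALEF WASLA -> ALEF
    "ؤ" = "و",  # WAW WITH HAMZA -> WAW
    "ة" = "ه",  # TEH MARBUTA -> HEH
    # whole-word restorations of initial long alef
    "اب" = "آب",
    "اباد" = "آباد",
    "ارام" = "آرام",
    "ارامش" = "آرامش",
    "اقا" = "آقا",
    "اینده" = "آینده"
  )
  spelling_variants <- c(
    "اطاق" = "اتاق",          # اطاق -> اتاق
    "بلیط" = "بلیت",          # بلیط -> بلیت
    "طهران" = "تهران", # طهران -> تهران
    "اطو" = "اتو",                      # اطو -> اتو
    # compound words written apart -> unified form
    "پیر مرد" = "پیرمرد",
    "شیمی درمانی" =
      "شیمی‌درمانی"
  )
  suffixes <- c("ترین", "تر",
                "هایم", "هایش",
                "هایت", "هایی",
                "های", "ها")
  prefixes <- c("نمی", "درمی",
                "برمی", "می", "بی")
  shifters <- c("ضد", "نا", "ن")
  protected_words <- c(
    "نان",                      # bread
    "نام",                      # name
    "ناهار",          # lunch
    "نامه",                # letter
    "ناراحت",    # upset (a sentiment term itself)
    "نگران",          # worried
    "ضدعفونی" # disinfected
  )
  punctuation <- c(".", "،", "؛", "؟", "!", "?", ",", ";",
                   ":", "(", ")", "[", "]", "{", "}", "«", "»",
                   "\"", "'", "…", "۔")
  rules <- list(
    char_map = char_map,
    spelling_variants = spelling_variants,
    suffixes = suffixes,
    prefixes = prefixes,
    stopwords = unique(stopwords),
    shifters = shifters,
    protected_words = protected_words,
    elongation_chars = KASHIDA,
    punctuation = punctuation
  )
  class(rules) <- "norm_rules"
  validate_rules(rules)
  rules
}

#' Validate a normalization rule set
#'
#' Checks the structural invariants that make rule application idempotent:
#' no character-map value contains a character-map key, and no
#' spelling-variant value is itself a variant key.
#'
#' @param rules A `norm_rules` object.
#' @return The rules, invisibly, if valid; otherwise an error is raised.
#' @export
validate_rules <- function(rules) {
  cm <- rules$char_map
  single <- names(cm)[nchar(names(cm)) == 1L]
  for (v in unname(cm)) {
    if (any(vapply(single, function(k) grepl(k, v, fixed = TRUE), logical(1))))
      stop_format("char_map value contains a char_map key; map not idempotent")
  }
  sv <- rules$spelling_variants
  if (any(unname(sv) %in% names(sv)))
    stop_format("spelling_variants value is itself a variant key")
  if (!length(rules$shifters)) stop_format("shifters must be non-empty")
  invisible(rules)
}

#' Read a normalization rule set from JSON
#'
#' The serialized form is a single JSON document with keys `char_map`,
#' `spelling_variants`, `suffixes`, `prefixes`, `stopwords` (or
#' `stopwords_file`, a path relative to the JSON file), `shifters`,
#' `protected_words`, `elongation_chars` and `punctuation`.
#'
#' @param path Path to a UTF-8 JSON file.
#' @return A `norm_rules` object.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop_format(paste0("rules file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$stopwords_file)) {
    sw_path <- file.path(dirname(path), obj$stopwords_file)
    obj$stopwords <- read_utf8_lines(sw_path)
    obj$stopwords_file <- NULL
  }
  rules <- list(
    char_map = unlist(obj$char_map) %||% character(),
    spelling_variants = unlist(obj$spelling_variants) %||% character(),
    suffixes = as.character(obj$suffixes %||% character()),
    prefixes = as.character(obj$prefixes %||% character()),
    stopwords = as.character(obj$stopwords %||% character()),
    shifters = as.character(obj$shifters %||% c("ضد", "نا", "ن")),
    protected_words = as.character(obj$protected_words %||% character()),
    elongation_chars = as.character(obj$elongation_chars %||% KASHIDA),
    punctuation = as.character(obj$punctuation %||% character())
  )
  class(rules) <- "norm_rules"
  validate_rules(rules)
  rules
}

#' Write a normalization rule set to JSON
#'
#' Round-trips through [read_rules()].
#'
#' @param rules A `norm_rules` object.
#' @param path Output path.
#' @export
write_rules <- function(rules, path) {
  obj <- list(
    char_map = as.list(rules$char_map),
    spelling_variants = as.list(rules$spelling_variants),
    suffixes = rules$suffixes,
    prefixes = rules$prefixes,
    stopwords = rules$stopwords,
    shifters = rules$shifters,
    protected_words = rules$protected_words,
    elongation_chars = rules$elongation_chars,
    punctuation = rules$punctuation
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# Read a UTF-8 text file, one entry per line, dropping blanks and comments.
read_utf8_lines <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @export
print.norm_rules <- function(x, ...) {
  cat("<norm_rules>\n")
  cat("  char_map entries:     ", length(x$char_map), "\n")
  cat("  spelling variants:    ", length(x$spelling_variants), "\n")
  cat("  suffixes / prefixes:  ", length(x$suffixes), "/", length(x$prefixes), "\n")
  cat("  stopwords:            ", length(x$stopwords), "\n")
  cat("  shifters:             ", paste(x$shifters, collapse = " "), "\n")
  invisible(x)
}
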