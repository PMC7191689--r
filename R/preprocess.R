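# Text normalization for clinical sentence pairs: lowercasing, tokenization,
# Arabic-numeral expansion, light rule-based lemmatization, stopword removal.

.ones <- c("one", "two", "three", "four", "five", "six", "seven", "eight", "nine")
.teens <- c("ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
            "sixteen", "seventeen", "eighteen", "nineteen")
.tens <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy", "eighty", "ninety")
.scales <- c("", "thousand", "million", "billion", "trillion")

# words for 0..999; returns character vector of tokens
.words3 <- function(v) {
  out <- character(0)
  h <- v %/% 100L
  r <- v %% 100L
  if (h > 0L) out <- c(out, .ones[h], "hundred")
  if (r >= 20L) {
    out <- c(out, .tens[r %/% 10L - 1L])
    if (r %% 10L > 0L) out <- c(out, .ones[r %% 10L])
  } else if (r >= 10L) {
    out <- c(out, .teens[r - 9L])
  } else if (r > 0L) {
    out <- c(out, .ones[r])
  }
  out
}

#' Convert a digit string to English cardinal word tokens
#'
#' Expands a maximal run of decimal digits into lowercase English number
#' words, one word per token, with no hyphens and no "and"
#' (`"24"` becomes `c("twenty", "four")`, `"105"` becomes
#' `c("one", "hundred", "five")`). Leading zeros are ignored except for the
#' all-zero string, which maps to `"zero"`. Digit strings longer than 15
#' characters are read out digit by digit.
#'
#' @param numeral A string consisting only of decimal digits.
#' @return Character vector of lowercase word tokens.
#' @examples
#' number_to_words("24")
#' number_to_words("0")
#' @export
number_to_words <- function(numeral) {
  if (!is.character(numeral) || length(numeral) != 1L || !grepl("^[0-9]+$", numeral))
    stop("number_to_words() expects a single string of decimal digits, got ",
         deparse(numeral), call. = FALSE)
  s <- sub("^0+", "", numeral)
  if (s == "") return("zero")
  if (nchar(s) > 15L) {
    digit_words <- c("zero", .ones)
    return(digit_words[as.integer(strsplit(s, "")[[1]]) + 1L])
  }
  n <- nchar(s)
  n_groups <- ceiling(n / 3)
  padded <- formatC(s, width = 3L * n_groups, flag = "0")
  out <- character(0)
  for (g in seq_len(n_groups)) {
    grp <- as.integer(substr(padded, 3L * g - 2L, 3L * g))
    if (grp == 0L) next
    scale <- .scales[n_groups - g + 1L]
    out <- c(out, .words3(grp), if (nzchar(scale)) scale)
  }
  out
}

#' Default stopword list
#'
#' A deliberately small English function-word list applied after
#' lemmatization. It is chosen so that clinically meaningful function-like
#' words survive: `within`, `without`, `every`, negations (`no`, `not`,
#' `never`) and number words are never removed.
#'
#' @return Character vector of stopword tokens.
#' @export
sts_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "nor", "so", "if", "then", "than",
    "that", "this", "these", "those", "of", "to", "for", "on", "in", "at",
    "by", "with", "from", "as", "into", "onto", "upon", "over", "under",
    "again", "further", "once", "here", "there", "when", "where", "why",
    "how", "is", "am", "are", "was", "were", "be", "been", "being", "do",
    "does", "did", "have", "has", "had", "having", "he", "him", "his", "she",
    "her", "hers", "it", "its", "they", "them", "their", "theirs", "i", "me",
    "my", "we", "us", "our", "ours", "you", "your", "yours", "will", "would",
    "shall", "should", "can", "could", "may", "might", "must", "up", "down",
    "out", "off", "own", "same", "such", "too", "very", "s", "t", "just",
    "also", "during", "while", "because", "until", "against", "between",
    "through", "after", "before", "above", "below", "both", "each", "which",
    "who", "whom", "what")
}

# tokens the lemmatizer must never alter (false plural/past shapes)
.lemma_keep <- c("denies", "series", "species", "diabetes", "pancreas",
                 "lens", "lupus", "herpes", "scabies", "measles", "pus",
                 "plus", "minus", "thus", "perhaps", "always", "sometimes",
                 "spent", "left", "need", "indeed", "used", "yes", "hundred",
                 "sing", "thing", "nothing", "something", "anything",
                 "everything", "morning", "evening", "bring", "during",
                 "wheezing")

.lemma_irregular <- c(children = "child", men = "man", women = "woman",
                      feet = "foot", teeth = "tooth", mice = "mouse",
                      criteria = "criterion", data = "data")

.double_cons <- c("bb", "dd", "gg", "mm", "nn", "pp", "rr", "tt")

# collapse a doubled final consonant left by -ing/-ed stripping
.undouble <- function(w) {
  n <- nchar(w)
  if (n >= 3L && substr(w, n - 1L, n) %in% .double_cons)
    substr(w, 1L, n - 1L) else w
}

#' Lemmatize a token
#'
#' Light rule-based English lemmatizer covering regular noun plurals and the
#' common verbal suffixes `-ing`/`-ed`. It is heuristic by design: rules are
#' guarded by minimum stem lengths and a keep-list, and tokens on the
#' stopword list pass through unchanged (they are function words, removed in
#' a later step if filtering is enabled). Silent-e restoration is not
#' attempted, so e.g. "prescribed" lemmatizes to "prescrib"; this mirrors the
#' aggressive stemming style visible in clinical STS preprocessing output.
#'
#' @param token Lowercase token.
#' @param stopwords Tokens passed through unchanged.
#' @return The lemmatized token.
#' @export
lemmatize_token <- function(token, stopwords = sts_stopwords()) {
  w <- token
  if (w %in% stopwords || w %in% .lemma_keep) return(w)
  if (w %in% names(.lemma_irregular)) return(unname(.lemma_irregular[w]))
  if (grepl("[0-9]", w)) return(w)   # mixed alphanumerics untouched
  n <- nchar(w)
  # noun plurals
  if (n >= 5L && endsWith(w, "sses")) return(substr(w, 1L, n - 2L))
  if (n >= 5L && endsWith(w, "ies"))  return(paste0(substr(w, 1L, n - 3L), "y"))
  if (n >= 5L && (endsWith(w, "xes") || endsWith(w, "ches") ||
                  endsWith(w, "shes") || endsWith(w, "zes")))
    return(substr(w, 1L, n - 2L))
  if (n >= 4L && endsWith(w, "s") &&
      !endsWith(w, "ss") && !endsWith(w, "us") && !endsWith(w, "is"))
    return(substr(w, 1L, n - 1L))
  # verbal -ing / -ed
  if (n >= 6L && endsWith(w, "ing")) return(.undouble(substr(w, 1L, n - 3L)))
  if (n >= 5L && endsWith(w, "ied")) return(paste0(substr(w, 1L, n - 3L), "y"))
  if (n >= 5L && endsWith(w, "ed") && !endsWith(w, "eed"))
    return(.undouble(substr(w, 1L, n - 2L)))
  w
}

#' Normalize a raw sentence into tokens
#'
#' The normalization pipeline: lowercase; split into maximal alphanumeric
#' runs (punctuation dropped); expand each pure-digit token into English
#' number words via [number_to_words()] (mixed alphanumerics such as
#' `"brca1"` are left untouched); lemmatize each token; finally drop
#' stopwords. If stopword removal would empty the sentence entirely, the
#' lemmatized tokens are retained instead so downstream features stay
#' defined.
#'
#' @param text Raw sentence (non-empty string).
#' @param stopwords Stopword set; `character(0)` disables removal.
#' @param lemmatize Apply the rule lemmatizer (default `TRUE`).
#' @return Character vector of normalized tokens.
#' @examples
#' normalize("Apply 1 patch every 24 hours")
#' @export
normalize <- function(text, stopwords = sts_stopwords(), lemmatize = TRUE) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("normalize() expects a single non-empty string", call. = FALSE)
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  # expand pure-digit tokens
  out <- character(0)
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) out <- c(out, number_to_words(tk))
    else out <- c(out, tk)
  }
  if (lemmatize)
    out <- vapply(out, lemmatize_token, character(1), stopwords = stopwords,
                  USE.NAMES = FALSE)
  if (length(stopwords)) {
    kept <- out[!(out %in% stopwords)]
    if (length(kept)) out <- kept
  }
  out
}

#' Tokenize every pair in a corpus
#'
#' Applies [normalize()] to both sentences of each pair.
#'
#' @param corpus An `sts_corpus` (see [read_pairs()]).
#' @param ... Passed to [normalize()].
#' @return A list of `TokenizedPair` lists with fields `pair_id`, `tokens1`,
#'   `tokens2` and `gold` (may be `NA`).
#' @export
tokenize_corpus <- function(corpus, ...) {
  stopifnot(inherits(corpus, "sts_corpus"))
  lapply(seq_len(nrow(corpus)), function(i) {
    list(pair_id = corpus$pair_id[i],
         tokens1 = normalize(corpus$s1[i], ...),
         tokens2 = normalize(corpus$s2[i], ...),
         gold = corpus$gold[i])
  })
}
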