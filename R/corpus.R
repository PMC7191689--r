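# Sentence-pair corpora: TSV read/write and stratified train/dev splitting.
# A corpus is a data.frame (class "sts_corpus") with columns
# pair_id, s1, s2, gold and a "provenance" attribute.

#' Construct a sentence-pair corpus
#'
#' @param s1,s2 Character vectors of raw sentences.
#' @param gold Optional numeric gold similarity scores in `[0, 5]` (`NA`
#'   allowed for unscored pairs).
#' @param pair_id Optional unique identifiers; generated when missing.
#' @param provenance Source label, e.g. a file path or `"synthetic"`.
#' @return An `sts_corpus` data.frame.
#' @export
sts_corpus <- function(s1, s2, gold = NULL, pair_id = NULL,
                       provenance = "memory") {
  n <- length(s1)
  if (length(s2) != n) stop("s1 and s2 must have equal length", call. = FALSE)
  if (is.null(gold)) gold <- rep(NA_real_, n)
  if (is.null(pair_id)) pair_id <- sprintf("pair-%05d", seq_len(n))
  if (anyDuplicated(pair_id)) stop("pair_ids must be unique", call. = FALSE)
  if (any(!nzchar(trimws(s1))) || any(!nzchar(trimws(s2))))
    stop("sentences must be non-empty", call. = FALSE)
  bad <- which(!is.na(gold) & (gold < 0 | gold > 5))
  if (length(bad))
    stop("gold score outside [0,5] for pair(s): ",
         paste(pair_id[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(pair_id = as.character(pair_id), s1 = as.character(s1),
                    s2 = as.character(s2), gold = as.numeric(gold),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("sts_corpus", "data.frame")
  out
}

#' @export
print.sts_corpus <- function(x, ...) {
  cat(sprintf("<sts_corpus> %d pairs (%d scored), provenance: %s\n",
              nrow(x), sum(!is.na(x$gold)), attr(x, "provenance")))
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read a sentence-pair corpus from a TSV file
#'
#' Expects UTF-8 tab-separated lines with no header: `sentence1<TAB>sentence2`
#' and, when `has_scores`, a third column holding a gold similarity score in
#' `[0, 5]`.
#'
#' @param path Path to the TSV file.
#' @param has_scores Whether a third score column is present (default `TRUE`).
#' @return An `sts_corpus`; line order is preserved and pair ids are
#'   generated from line numbers.
#' @export
read_pairs <- function(path, has_scores = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty corpus file: ", path, call. = FALSE)
  want <- if (has_scores) 3L else 2L
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != want)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected %d tab-separated fields, found %d",
                 bad[1], path, want, nf[bad[1]]), call. = FALSE)
  s1 <- vapply(parts, `[[`, character(1), 1L)
  s2 <- vapply(parts, `[[`, character(1), 2L)
  gold <- NULL
  if (has_scores) {
    raw <- vapply(parts, `[[`, character(1), 3L)
    gold <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(gold))
    if (length(bad))
      stop(sprintf("line %d in %s: unparseable score %s", bad[1], path,
                   dQuote(raw[bad[1]])), call. = FALSE)
    bad <- which(gold < 0 | gold > 5)
    if (length(bad))
      stop(sprintf("line %d in %s: score %s outside [0,5]", bad[1], path,
                   format(gold[bad[1]])), call. = FALSE)
  }
  sts_corpus(s1, s2, gold, pair_id = sprintf("pair-%05d", seq_along(s1)),
             provenance = path)
}

#' Write a corpus to TSV
#'
#' Inverse of [read_pairs()]: writes `s1<TAB>s2[<TAB>score]` lines. Scores
#' are written with [format()] using up to 15 significant digits; an
#' unscored corpus (all `gold` `NA`) is written as two columns.
#'
#' @param corpus An `sts_corpus`.
#' @param path Output path.
#' @param scores Include the score column; default: include iff any score
#'   present.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(corpus, path, scores = any(!is.na(corpus$gold))) {
  stopifnot(inherits(corpus, "sts_corpus"))
  lines <- if (scores) {
    paste(corpus$s1, corpus$s2,
          vapply(corpus$gold, function(g) format(g, digits = 15), character(1)),
          sep = "\t")
  } else paste(corpus$s1, corpus$s2, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# interval index 1..5 for a gold score, half-open bins with closed top bin
score_interval <- function(gold) {
  pmin(pmax(floor(gold), 0), 4) + 1L
}

#' Stratified train/dev split by score interval
#'
#' Strata are the five unit score intervals `[0,1), [1,2), [2,3), [3,4),
#' [4,5]`. Within each stratum, `round(dev_fraction * stratum size)` pairs
#' are sampled into the dev set; the split is deterministic given `seed`.
#'
#' @param corpus A fully scored `sts_corpus`.
#' @param dev_fraction Fraction of each stratum assigned to dev (default
#'   0.2).
#' @param seed Integer seed controlling the within-stratum sampling.
#' @return A list with elements `train` and `dev`, both `sts_corpus`.
#' @export
stratified_split <- function(corpus, dev_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(corpus, "sts_corpus"))
  if (any(is.na(corpus$gold)))
    stop("stratified_split() requires every pair to be scored", call. = FALSE)
  if (!is.numeric(dev_fraction) || dev_fraction <= 0 || dev_fraction >= 1)
    stop("dev_fraction must lie in (0,1)", call. = FALSE)
  iv <- score_interval(corpus$gold)
  dev_idx <- integer(0)
  with_seed(seed, {
    for (k in 1:5) {
      members <- which(iv == k)
      n_dev <- round(dev_fraction * length(members))
      if (n_dev > 0L)
        dev_idx <- c(dev_idx, sample(members, n_dev))
    }
  })
  dev_idx <- sort(dev_idx)
  if (!length(dev_idx))
    warning("dev_fraction too small: dev set is empty")
  train <- corpus[setdiff(seq_len(nrow(corpus)), dev_idx), , drop = FALSE]
  dev <- corpus[dev_idx, , drop = FALSE]
  attr(train, "provenance") <- attr(corpus, "provenance")
  attr(dev, "provenance") <- attr(corpus, "provenance")
  class(train) <- class(dev) <- c("sts_corpus", "data.frame")
  list(train = train, dev = dev)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
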