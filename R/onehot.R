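# Handcrafted ("one-hot") sentence-pair features: lengths, mean token IDF,
# distinct n-gram overlap for n = 1..3, and eight distance/kernel
# similarities between averaged word-embedding vectors.

#' Fit an inverse-document-frequency model
#'
#' Every sentence (not pair) counts as one document; each distinct token in
#' a sentence increments its document frequency by one. At query time
#' `idf(w) = ln(N / (1 + df(w)))`, a smoothed form that keeps tokens unseen
#' in training finite (`ln N`).
#'
#' @param tokenized A non-empty list of `TokenizedPair` (see
#'   [tokenize_corpus()]).
#' @return An `sts_idf` model with fields `doc_count` and `df`.
#' @export
fit_idf <- function(tokenized) {
  if (!length(tokenized)) stop("fit_idf() needs a non-empty collection", call. = FALSE)
  df <- new.env(parent = emptyenv())
  n_docs <- 0L
  for (tp in tokenized) {
    for (toks in list(tp$tokens1, tp$tokens2)) {
      n_docs <- n_docs + 1L
      for (tk in unique(toks))
        assign(tk, (get0(tk, envir = df, inherits = FALSE) %||% 0L) + 1L, envir = df)
    }
  }
  structure(list(doc_count = n_docs, df = df), class = "sts_idf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse document frequency of a token
#'
#' @param idf An `sts_idf` model from [fit_idf()].
#' @param token Token string (vectorized).
#' @return `ln(N / (1 + df(token)))`.
#' @export
idf_value <- function(idf, token) {
  stopifnot(inherits(idf, "sts_idf"))
  vapply(token, function(tk)
    log(idf$doc_count / (1 + (get0(tk, envir = idf$df, inherits = FALSE) %||% 0L))),
    numeric(1), USE.NAMES = FALSE)
}

# distinct n-grams of a token vector as strings
ngram_set <- function(tokens, n) {
  m <- length(tokens)
  if (m < n) return(character(0))
  if (n == 1L) return(unique(tokens))
  idx <- seq_len(m - n + 1L)
  grams <- tokens[idx]
  for (k in seq_len(n - 1L)) grams <- paste(grams, tokens[idx + k], sep = "␟")
  unique(grams)
}

#' Dice-style n-gram overlap of two token lists
#'
#' `NGO = 2 |G1 ∩ G2| / (|G1| + |G2|)` where `Gi` is the *set* of
#' distinct n-grams of sentence i. Sentences shorter than `n` contribute an
#' empty set; when both sets are empty the overlap is 0 by convention.
#'
#' @param tokens1,tokens2 Non-empty token vectors.
#' @param n N-gram order, one of 1, 2, 3.
#' @return A real in `[0, 1]`.
#' @export
ngram_overlap <- function(tokens1, tokens2, n) {
  if (!is.numeric(n) || length(n) != 1L || !(n %in% 1:3))
    stop("n must be 1, 2 or 3", call. = FALSE)
  if (!length(tokens1) || !length(tokens2))
    stop("ngram_overlap() requires non-empty token lists", call. = FALSE)
  g1 <- ngram_set(tokens1, n)
  g2 <- ngram_set(tokens2, n)
  denom <- length(g1) + length(g2)
  if (denom == 0L) return(0)
  2 * length(intersect(g1, g2)) / denom
}

#' Eight embedding-space similarities of a sentence pair
#'
#' Each sentence is represented by the mean of its tokens' embedding
#' vectors; the function returns (in order) cosine similarity, Manhattan,
#' Euclidean and Chebyshev distances, and the polynomial
#' `(gamma * <v1,v2> + coef0)^degree`, RBF `exp(-gamma ||v1-v2||^2)`,
#' Laplacian `exp(-gamma ||v1-v2||_1)` and sigmoid
#' `tanh(gamma * <v1,v2> + coef0)` kernels. Cosine is defined as 0 when
#' either averaged vector is all-zero (possible under the `"zero"` OOV
#' policy).
#'
#' @param tokens1,tokens2 Token vectors.
#' @param emb An `sts_embeddings` table.
#' @param gamma Kernel scale; default `1 / emb$dimension`.
#' @param coef0 Kernel offset (default 1).
#' @param degree Polynomial degree (default 3).
#' @return Named numeric vector of length 8.
#' @export
pair_similarities <- function(tokens1, tokens2, emb, gamma = NULL,
                              coef0 = 1, degree = 3) {
  v1 <- sentence_vector(emb, tokens1)
  v2 <- sentence_vector(emb, tokens2)
  vector_similarities(v1, v2, gamma = gamma %||% (1 / emb$dimension),
                      coef0 = coef0, degree = degree)
}

# closed-form similarities on two plain vectors (also used by tests' oracle
# fixtures to hand-build expected feature rows)
vector_similarities <- function(v1, v2, gamma, coef0 = 1, degree = 3) {
  d <- v1 - v2
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  cosine <- if (n1 == 0 || n2 == 0) 0 else sum(v1 * v2) / (n1 * n2)
  manhattan <- sum(abs(d))
  euclidean <- sqrt(sum(d^2))
  chebyshev <- if (length(d)) max(abs(d)) else 0
  dot <- sum(v1 * v2)
  c(cosine = cosine, manhattan = manhattan, euclidean = euclidean,
    chebyshev = chebyshev,
    polynomial = (gamma * dot + coef0)^degree,
    rbf = exp(-gamma * sum(d^2)),
    laplacian = exp(-gamma * manhattan),
    sigmoid = tanh(gamma * dot + coef0))
}

#' Names of the one-hot feature slots
#' @return Character vector of length 17.
#' @export
onehot_feature_names <- function() {
  c("len1", "len2", "len_diff", "idf1", "idf2", "idf_diff",
    "ngo1", "ngo2", "ngo3",
    "cosine", "manhattan", "euclidean", "chebyshev",
    "polynomial", "rbf", "laplacian", "sigmoid")
}

#' Build the one-hot feature vector of a tokenized pair
#'
#' Fixed 17-slot layout: token counts of both sentences and their absolute
#' difference; mean token IDF of both sentences and its absolute
#' difference; unigram/bigram/trigram overlap ([ngram_overlap()]); and the
#' eight similarities of [pair_similarities()]. The per-sentence IDF
#' aggregate is the mean of token IDFs by default (`aggregate = "sum"`
#' switches to the sum).
#'
#' @param pair A `TokenizedPair`.
#' @param idf An `sts_idf` model.
#' @param emb An `sts_embeddings` table.
#' @param aggregate `"mean"` (default) or `"sum"` token-IDF aggregation.
#' @param gamma,coef0,degree Kernel settings, see [pair_similarities()].
#' @return Named numeric vector of length 17, all entries finite.
#' @export
build_onehot <- function(pair, idf, emb, aggregate = c("mean", "sum"),
                         gamma = NULL, coef0 = 1, degree = 3) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else sum
  t1 <- pair$tokens1; t2 <- pair$tokens2
  if (!length(t1) || !length(t2))
    stop("build_onehot() requires non-empty token lists (pair ",
         pair$pair_id, ")", call. = FALSE)
  i1 <- agg(idf_value(idf, t1))
  i2 <- agg(idf_value(idf, t2))
  out <- c(len1 = length(t1), len2 = length(t2),
           len_diff = abs(length(t1) - length(t2)),
           idf1 = i1, idf2 = i2, idf_diff = abs(i1 - i2),
           ngo1 = ngram_overlap(t1, t2, 1L),
           ngo2 = ngram_overlap(t1, t2, 2L),
           ngo3 = ngram_overlap(t1, t2, 3L),
           pair_similarities(t1, t2, emb, gamma = gamma, coef0 = coef0,
                             degree = degree))
  if (any(!is.finite(out)))
    stop("non-finite one-hot feature for pair ", pair$pair_id, call. = FALSE)
  out
}

#' Featurize a whole corpus
#'
#' @param tokenized List of `TokenizedPair`.
#' @param idf,emb,... Passed to [build_onehot()].
#' @return Numeric matrix, one row per pair, columns named by
#'   [onehot_feature_names()].
#' @export
featurize_corpus <- function(tokenized, idf, emb, ...) {
  rows <- lapply(tokenized, build_onehot, idf = idf, emb = emb, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(tokenized, `[[`, character(1), "pair_id")
  out
}
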