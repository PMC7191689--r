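# Word-embedding tables in word2vec text/binary layout, with deterministic
# fallbacks for out-of-vocabulary tokens. Used by the handcrafted
# kernel-similarity features (sentences are averaged token vectors).

new_embedding_table <- function(dimension, vectors = list(),
                                oov_policy = c("zero", "random-fixed-seed"),
                                source = "memory") {
  oov_policy <- match.arg(oov_policy)
  env <- new.env(parent = emptyenv())
  for (tok in names(vectors)) {
    v <- vectors[[tok]]
    if (length(v) != dimension)
      stop(sprintf("vector for %s has length %d, expected %d",
                   dQuote(tok), length(v), dimension), call. = FALSE)
    assign(tok, as.numeric(v), envir = env)
  }
  structure(list(dimension = as.integer(dimension), vectors = env,
                 oov_policy = oov_policy, source = source,
                 oov_cache = new.env(parent = emptyenv())),
            class = "sts_embeddings")
}

#' @export
print.sts_embeddings <- function(x, ...) {
  cat(sprintf("<sts_embeddings> dim %d, %d stored vectors, oov policy %s (%s)\n",
              x$dimension, length(ls(x$vectors)), x$oov_policy, x$source))
  invisible(x)
}

#' Load a word2vec embedding table
#'
#' Reads the word2vec text layout (header line `"<count> <dim>"`, then one
#' `token v1 ... v_dim` line per word) or the binary layout (same header,
#' then `token<space>` followed by `dim` little-endian float32 values per
#' word).
#'
#' @param path Path to the embedding file.
#' @param format `"auto"` (sniff), `"text"` or `"binary"`.
#' @param oov_policy How lookups of unstored tokens resolve: `"zero"`
#'   (default; a zero vector) or `"random-fixed-seed"` (a deterministic
#'   standard-normal vector seeded by a hash of the token, identical across
#'   sessions).
#' @return An `sts_embeddings` table.
#' @export
load_embeddings <- function(path, format = c("auto", "text", "binary"),
                            oov_policy = "zero") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("embedding file not found: ", path, call. = FALSE)
  if (format == "auto") {
    # binary payloads contain float32 bytes that are rarely all printable
    bytes <- readBin(path, "raw", n = min(file.size(path), 4096))
    body <- bytes[-seq_len(which(bytes == as.raw(10))[1])]
    format <- if (length(body) && any(body > as.raw(127) | (body < as.raw(9) & body > as.raw(0))))
      "binary" else "text"
  }
  if (format == "text") .load_emb_text(path, oov_policy) else .load_emb_binary(path, oov_policy)
}

.load_emb_text <- function(path, oov_policy) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("bad word2vec text header: ", dQuote(lines[1]), call. = FALSE)
  dim <- as.integer(hdr[2])
  vecs <- list()
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != dim + 1L)
      stop(sprintf("embedding row for %s has %d values, expected %d",
                   dQuote(parts[1]), length(parts) - 1L, dim), call. = FALSE)
    vecs[[parts[1]]] <- as.numeric(parts[-1])
  }
  new_embedding_table(dim, vecs, oov_policy, source = path)
}

.load_emb_binary <- function(path, oov_policy) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_until <- function(stop_chars) {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (!length(b) || rawToChar(b) %in% stop_chars) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  hdr <- strsplit(trimws(read_until("\n")), "\\s+")[[1]]
  if (length(hdr) != 2L) stop("bad word2vec binary header", call. = FALSE)
  count <- as.integer(hdr[1]); dim <- as.integer(hdr[2])
  vecs <- vector("list", count)
  toks <- character(count)
  for (i in seq_len(count)) {
    tok <- read_until(" ")
    tok <- sub("^\n", "", tok)   # some writers put \n before the next token
    v <- readBin(con, "numeric", n = dim, size = 4L, endian = "little")
    if (length(v) != dim)
      stop("truncated binary embedding file at entry ", i, call. = FALSE)
    toks[i] <- tok
    vecs[[i]] <- v
  }
  names(vecs) <- toks
  new_embedding_table(dim, vecs, oov_policy, source = path)
}

#' Random-fallback embedding table
#'
#' An empty table whose every lookup resolves through the
#' `"random-fixed-seed"` policy: each token receives a deterministic
#' standard-normal vector seeded by a hash of its characters. Useful when no
#' pretrained embedding file is available; similarities computed from it are
#' still deterministic and reproducible.
#'
#' @param dimension Vector dimension (default 50).
#' @return An `sts_embeddings` table.
#' @export
random_embeddings <- function(dimension = 50L) {
  new_embedding_table(dimension, list(), oov_policy = "random-fixed-seed",
                      source = "random")
}

# deterministic 31-bit hash of a token (polynomial rolling hash)
token_hash <- function(token) {
  h <- 0
  for (b in utf8ToInt(token)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Look up a token's embedding vector
#'
#' Stored tokens return their vector; unstored tokens resolve per the
#' table's OOV policy (see [load_embeddings()]). Under
#' `"random-fixed-seed"` repeated lookups of the same token return the
#' identical vector.
#'
#' @param emb An `sts_embeddings` table.
#' @param token Token string.
#' @return Numeric vector of length `emb$dimension`.
#' @export
embedding_lookup <- function(emb, token) {
  stopifnot(inherits(emb, "sts_embeddings"))
  v <- get0(token, envir = emb$vectors, inherits = FALSE)
  if (!is.null(v)) return(v)
  if (emb$oov_policy == "zero") return(numeric(emb$dimension))
  v <- get0(token, envir = emb$oov_cache, inherits = FALSE)
  if (is.null(v)) {
    v <- with_seed(token_hash(token), stats::rnorm(emb$dimension))
    assign(token, v, envir = emb$oov_cache)
  }
  v
}

# mean of token vectors for one sentence (matrix row-mean; OOV per policy)
sentence_vector <- function(emb, tokens) {
  if (!length(tokens)) return(numeric(emb$dimension))
  m <- vapply(tokens, function(tk) embedding_lookup(emb, tk),
              numeric(emb$dimension))
  if (emb$dimension == 1L) return(mean(as.numeric(m)))
  rowMeans(matrix(m, nrow = emb$dimension))
}

#' Write an embedding table in word2vec text format
#'
#' @param emb An `sts_embeddings` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  toks <- sort(ls(emb$vectors))
  lines <- c(paste(length(toks), emb$dimension),
             vapply(toks, function(tk)
               paste(tk, paste(format(get(tk, envir = emb$vectors),
                                      digits = 8, trim = TRUE,
                                      scientific = FALSE), collapse = " ")),
               character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
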