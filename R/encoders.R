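# Distributed sentence-pair encoders. All three share a trainable token
# embedding and are expressed as autograd graphs (R/autograd.R) so the same
# code path serves forward encoding and training.
#
#   cnn  — Siamese convolution (shared weights), ReLU, average pooling over
#          positions; pair vector = [tower(s1), tower(s2)]
#   lstm — Siamese bidirectional LSTM; pair vector = final forward state and
#          position-1 backward state of each sentence, concatenated
#   transformer — pre-LN transformer over "[CLS] s1 [SEP] s2 [SEP]" with
#          segment + position embeddings; pair vector = final CLS row

PAD_ID <- 1L; UNK_ID <- 2L; CLS_ID <- 3L; SEP_ID <- 4L

#' Encoder configuration
#'
#' @param kind `"cnn"`, `"lstm"` or `"transformer"`.
#' @param embedding_dim Token embedding width for cnn/lstm (default 50; the
#'   transformer embeds straight at `hidden_dim`).
#' @param hidden_dim LSTM state size / transformer model width (default 64).
#' @param filters Convolution filters per width (default 64).
#' @param filter_widths Convolution window sizes (default 1:3).
#' @param depth Transformer layers (default 2; 0 = embeddings only).
#' @param heads Transformer attention heads (default 2).
#' @param max_len Maximum serialized pair length for the transformer
#'   (default 64; the second sentence is truncated first).
#' @return An `sts_encoder_config` list, including the derived pair-vector
#'   dimension `d_D`.
#' @export
encoder_config <- function(kind = c("cnn", "lstm", "transformer"),
                           embedding_dim = 50L, hidden_dim = 64L,
                           filters = 64L, filter_widths = 1:3,
                           depth = 2L, heads = 2L, max_len = 64L) {
  kind <- match.arg(kind)
  stopifnot(embedding_dim > 0, hidden_dim > 0, filters > 0, depth >= 0,
            heads > 0, max_len >= 8, all(filter_widths >= 1))
  if (kind == "transformer" && hidden_dim %% heads != 0)
    stop("hidden_dim must be divisible by heads", call. = FALSE)
  d_D <- switch(kind,
                cnn = 2L * filters * length(filter_widths),
                lstm = 4L * hidden_dim,
                transformer = hidden_dim)
  structure(list(kind = kind, embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 filters = as.integer(filters),
                 filter_widths = as.integer(filter_widths),
                 depth = as.integer(depth), heads = as.integer(heads),
                 max_len = as.integer(max_len), d_D = as.integer(d_D)),
            class = "sts_encoder_config")
}

# glorot-uniform init (uses the caller's RNG stream)
ginit <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Build a token vocabulary from tokenized pairs
#'
#' Reserves `<pad>`, `<unk>`, `<cls>`, `<sep>` at indices 1-4.
#'
#' @param tokenized List of `TokenizedPair`.
#' @return Character vector; names are not set, use [tokens_to_ids()].
#' @export
build_vocab <- function(tokenized) {
  toks <- sort(unique(unlist(lapply(tokenized, function(tp)
    c(tp$tokens1, tp$tokens2)))))
  c("<pad>", "<unk>", "<cls>", "<sep>", toks)
}

#' Map tokens to vocabulary ids (unknown tokens to `<unk>`)
#' @param tokens Character vector.
#' @param vocab Vocabulary from [build_vocab()].
#' @return Integer vector.
#' @export
tokens_to_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- UNK_ID
  ids
}

#' Initialize encoder parameters
#'
#' Parameters are drawn from the current RNG stream (seed at the call
#' site). The token embedding may optionally be warm-started from a
#' pretrained [load_embeddings()] table; rows for tokens absent from the
#' table fall back to random initialization, and the `<pad>` row is zero.
#'
#' @param cfg An [encoder_config()].
#' @param vocab Vocabulary from [build_vocab()].
#' @param emb Optional `sts_embeddings` used to initialize token rows (its
#'   dimension must match the embedding width).
#' @return An `sts_encoder` object: `list(cfg, vocab, params)`.
#' @export
encoder_init <- function(cfg, vocab, emb = NULL) {
  stopifnot(inherits(cfg, "sts_encoder_config"))
  V <- length(vocab)
  e <- if (cfg$kind == "transformer") cfg$hidden_dim else cfg$embedding_dim
  p <- list(emb = matrix(stats::rnorm(V * e, sd = 0.1), V, e))
  if (!is.null(emb)) {
    if (emb$dimension != e)
      stop("pretrained embedding dimension ", emb$dimension,
           " does not match encoder embedding width ", e, call. = FALSE)
    for (i in seq_along(vocab)) {
      v <- get0(vocab[i], envir = emb$vectors, inherits = FALSE)
      if (!is.null(v)) p$emb[i, ] <- v
    }
  }
  p$emb[PAD_ID, ] <- 0
  if (cfg$kind == "cnn") {
    for (wi in seq_along(cfg$filter_widths)) {
      w <- cfg$filter_widths[wi]
      p[[paste0("Wc", wi)]] <- ginit(w * e, cfg$filters)
      p[[paste0("bc", wi)]] <- matrix(0, 1L, cfg$filters)
    }
  } else if (cfg$kind == "lstm") {
    H <- cfg$hidden_dim
    for (dir in c("f", "b")) {
      p[[paste0(dir, "_Wx")]] <- ginit(e, 4L * H)
      p[[paste0(dir, "_Wh")]] <- ginit(H, 4L * H)
      b <- matrix(0, 1L, 4L * H)
      b[1, H + seq_len(H)] <- 1   # forget-gate bias
      p[[paste0(dir, "_b")]] <- b
    }
  } else {
    w <- cfg$hidden_dim
    p$seg <- matrix(stats::rnorm(2L * w, sd = 0.1), 2L, w)
    p$pos <- matrix(stats::rnorm(cfg$max_len * w, sd = 0.1), cfg$max_len, w)
    for (l in seq_len(cfg$depth)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1_g")]] <- matrix(1, 1L, w)
      p[[paste0(pre, "ln1_b")]] <- matrix(0, 1L, w)
      p[[paste0(pre, "Wq")]] <- ginit(w, w)
      p[[paste0(pre, "Wk")]] <- ginit(w, w)
      p[[paste0(pre, "Wv")]] <- ginit(w, w)
      p[[paste0(pre, "Wo")]] <- ginit(w, w)
      p[[paste0(pre, "ln2_g")]] <- matrix(1, 1L, w)
      p[[paste0(pre, "ln2_b")]] <- matrix(0, 1L, w)
      p[[paste0(pre, "W1")]] <- ginit(w, 4L * w)
      p[[paste0(pre, "b1")]] <- matrix(0, 1L, 4L * w)
      p[[paste0(pre, "W2")]] <- ginit(4L * w, w)
      p[[paste0(pre, "b2")]] <- matrix(0, 1L, w)
    }
    if (cfg$depth > 0L) {
      p$lnf_g <- matrix(1, 1L, w)
      p$lnf_b <- matrix(0, 1L, w)
    }
  }
  structure(list(cfg = cfg, vocab = vocab, params = p), class = "sts_encoder")
}

# --- graph builders -------------------------------------------------------
# `lv` is a named list of tape nodes (or plain matrices for frozen forward
# passes) mirroring the parameter list.

# window component o (0-based) of every position of sentence v, pad beyond
shift_ids <- function(v, o) {
  l <- length(v)
  if (o == 0L) return(v)
  if (l <= o) return(rep(PAD_ID, l))
  c(v[(o + 1L):l], rep(PAD_ID, o))
}

# per-sentence tower: one output row per sentence
cnn_towers <- function(tp, lv, sents, cfg) {
  lens <- lengths(sents)
  nS <- length(sents)
  group <- rep(seq_len(nS), times = lens)
  pooled <- vector("list", length(cfg$filter_widths))
  for (wi in seq_along(cfg$filter_widths)) {
    w <- cfg$filter_widths[wi]
    cols <- lapply(0:(w - 1L), function(o)
      ag_rows(tp, lv$emb, unlist(lapply(sents, shift_ids, o = o))))
    Xw <- if (length(cols) == 1L) cols[[1]] else ag_cbind(tp, cols)
    H <- ag_relu(tp, ag_add(tp, ag_matmul(tp, Xw, lv[[paste0("Wc", wi)]]),
                            lv[[paste0("bc", wi)]]))
    pooled[[wi]] <- ag_group_mean(tp, H, group, nS)
  }
  if (length(pooled) == 1L) pooled[[1]] else ag_cbind(tp, pooled)
}

cnn_graph <- function(tp, lv, sents, cfg) {
  B <- length(sents) %/% 2L
  tower <- cnn_towers(tp, lv, sents, cfg)
  ag_cbind(tp, list(ag_rows(tp, tower, seq_len(B)),
                    ag_rows(tp, tower, B + seq_len(B))))
}

lstm_dir_graph <- function(tp, lv, ids_mat, mask, cfg, dir) {
  nS <- nrow(ids_mat); L <- ncol(ids_mat); H <- cfg$hidden_dim
  Wx <- lv[[paste0(dir, "_Wx")]]; Wh <- lv[[paste0(dir, "_Wh")]]
  b <- lv[[paste0(dir, "_b")]]
  h <- matrix(0, nS, H); cc <- matrix(0, nS, H)
  for (t in seq_len(L)) {
    x <- ag_rows(tp, lv$emb, ids_mat[, t])
    z <- ag_add(tp, ag_add(tp, ag_matmul(tp, x, Wx), ag_matmul(tp, h, Wh)), b)
    ig <- ag_sigmoid(tp, ag_cols(tp, z, seq_len(H)))
    fg <- ag_sigmoid(tp, ag_cols(tp, z, H + seq_len(H)))
    og <- ag_sigmoid(tp, ag_cols(tp, z, 2L * H + seq_len(H)))
    gg <- ag_tanh(tp, ag_cols(tp, z, 3L * H + seq_len(H)))
    c_new <- ag_add(tp, ag_mul(tp, fg, cc), ag_mul(tp, ig, gg))
    h_new <- ag_mul(tp, og, ag_tanh(tp, c_new))
    M <- matrix(mask[, t], nS, H)
    h <- ag_add(tp, ag_mul(tp, h_new, M), ag_mul(tp, h, 1 - M))
    cc <- ag_add(tp, ag_mul(tp, c_new, M), ag_mul(tp, cc, 1 - M))
  }
  h
}

# per-sentence [forward final state, backward position-1 state]
lstm_towers <- function(tp, lv, sents, cfg) {
  lens <- lengths(sents)
  nS <- length(sents)
  L <- max(lens)
  fwd_ids <- t(vapply(sents, function(v) c(v, rep(PAD_ID, L - length(v))),
                      integer(L)))
  bwd_ids <- t(vapply(sents, function(v) c(rev(v), rep(PAD_ID, L - length(v))),
                      integer(L)))
  mask <- outer(lens, seq_len(L), ">=") * 1
  if (L == 1L) { fwd_ids <- matrix(fwd_ids, ncol = 1L); bwd_ids <- matrix(bwd_ids, ncol = 1L) }
  hf <- lstm_dir_graph(tp, lv, fwd_ids, mask, cfg, "f")
  hb <- lstm_dir_graph(tp, lv, bwd_ids, mask, cfg, "b")
  ag_cbind(tp, list(hf, hb))
}

lstm_graph <- function(tp, lv, sents, cfg) {
  B <- length(sents) %/% 2L
  tower <- lstm_towers(tp, lv, sents, cfg)
  ag_cbind(tp, list(ag_rows(tp, tower, seq_len(B)),
                    ag_rows(tp, tower, B + seq_len(B))))
}

# serialize one pair as [CLS] s1 [SEP] s2 [SEP] with segment ids
serialize_pair <- function(ids1, ids2, max_len) {
  budget <- max_len - 3L
  if (length(ids1) + length(ids2) > budget) {
    over <- length(ids1) + length(ids2) - budget
    cut2 <- min(over, max(length(ids2) - 1L, 0L))
    if (cut2 > 0L) ids2 <- ids2[seq_len(length(ids2) - cut2)]
    over <- over - cut2
    if (over > 0L) ids1 <- ids1[seq_len(max(length(ids1) - over, 1L))]
  }
  list(ids = c(CLS_ID, ids1, SEP_ID, ids2, SEP_ID),
       seg = c(rep(1L, length(ids1) + 2L), rep(2L, length(ids2) + 1L)))
}

affine_ln <- function(tp, h, g, b) {
  ag_add(tp, ag_mul(tp, ag_layernorm(tp, h), g), b)
}

transformer_graph <- function(tp, lv, pair_ids, cfg) {
  B <- length(pair_ids)
  ser <- lapply(pair_ids, function(pr)
    serialize_pair(pr$ids1, pr$ids2, cfg$max_len))
  lens <- vapply(ser, function(s) length(s$ids), integer(1))
  Lp <- max(lens)
  flat_ids <- unlist(lapply(ser, function(s) c(s$ids, rep(PAD_ID, Lp - length(s$ids)))))
  flat_seg <- unlist(lapply(ser, function(s) c(s$seg, rep(1L, Lp - length(s$seg)))))
  flat_pos <- rep(seq_len(Lp), times = B)
  h <- ag_add(tp, ag_add(tp, ag_rows(tp, lv$emb, flat_ids),
                         ag_rows(tp, lv$seg, flat_seg)),
              ag_rows(tp, lv$pos, flat_pos))
  dk <- cfg$hidden_dim %/% cfg$heads
  head_cols <- lapply(seq_len(cfg$heads), function(hh) (hh - 1L) * dk + seq_len(dk))
  for (l in seq_len(cfg$depth)) {
    pre <- paste0("l", l, "_")
    a_in <- affine_ln(tp, h, lv[[paste0(pre, "ln1_g")]], lv[[paste0(pre, "ln1_b")]])
    Q <- ag_matmul(tp, a_in, lv[[paste0(pre, "Wq")]])
    K <- ag_matmul(tp, a_in, lv[[paste0(pre, "Wk")]])
    Vv <- ag_matmul(tp, a_in, lv[[paste0(pre, "Wv")]])
    ctx_rows <- vector("list", B)
    for (bq in seq_len(B)) {
      ridx <- (bq - 1L) * Lp + seq_len(Lp)
      shift <- matrix(rep(ifelse(seq_len(Lp) <= lens[bq], 0, -1e9),
                          each = Lp), Lp, Lp)
      per_head <- vector("list", cfg$heads)
      for (hh in seq_len(cfg$heads)) {
        Qb <- ag_cols(tp, ag_rows(tp, Q, ridx), head_cols[[hh]])
        Kb <- ag_cols(tp, ag_rows(tp, K, ridx), head_cols[[hh]])
        Vb <- ag_cols(tp, ag_rows(tp, Vv, ridx), head_cols[[hh]])
        sc <- ag_scale(tp, ag_matmul(tp, Qb, ag_transpose(tp, Kb)), 1 / sqrt(dk))
        pr <- ag_softmax_rows(tp, sc, shift)
        per_head[[hh]] <- ag_matmul(tp, pr, Vb)
      }
      ctx_rows[[bq]] <- if (cfg$heads == 1L) per_head[[1]] else ag_cbind(tp, per_head)
    }
    ctx <- if (B == 1L) ctx_rows[[1]] else ag_rbind(tp, ctx_rows)
    h <- ag_add(tp, h, ag_matmul(tp, ctx, lv[[paste0(pre, "Wo")]]))
    f_in <- affine_ln(tp, h, lv[[paste0(pre, "ln2_g")]], lv[[paste0(pre, "ln2_b")]])
    f1 <- ag_relu(tp, ag_add(tp, ag_matmul(tp, f_in, lv[[paste0(pre, "W1")]]),
                             lv[[paste0(pre, "b1")]]))
    f2 <- ag_add(tp, ag_matmul(tp, f1, lv[[paste0(pre, "W2")]]),
                 lv[[paste0(pre, "b2")]])
    h <- ag_add(tp, h, f2)
  }
  if (cfg$depth > 0L) h <- affine_ln(tp, h, lv$lnf_g, lv$lnf_b)
  ag_rows(tp, h, (seq_len(B) - 1L) * Lp + 1L)
}

# dispatch: returns the (B x d_D) pair-representation node
encoder_graph <- function(tp, lv, batch, cfg) {
  if (cfg$kind == "transformer") {
    transformer_graph(tp, lv, batch, cfg)
  } else {
    sents <- c(lapply(batch, `[[`, "ids1"), lapply(batch, `[[`, "ids2"))
    if (cfg$kind == "cnn") cnn_graph(tp, lv, sents, cfg)
    else lstm_graph(tp, lv, sents, cfg)
  }
}

# --- user-facing encoding -------------------------------------------------

encode_with <- function(pair, encoder) {
  stopifnot(inherits(encoder, "sts_encoder"))
  ids1 <- tokens_to_ids(pair$tokens1, encoder$vocab)
  ids2 <- tokens_to_ids(pair$tokens2, encoder$vocab)
  cfg <- encoder$cfg
  vals <- if (cfg$kind == "transformer") {
    tp <- ag_tape()
    as.numeric(transformer_graph(tp, encoder$params,
                                 list(list(ids1 = ids1, ids2 = ids2)), cfg)$val)
  } else {
    # evaluate each tower on a one-sentence batch: the shared map
    # sentence -> vector is then bitwise independent of batch position,
    # so swapping s1/s2 swaps the blocks exactly
    towers <- if (cfg$kind == "cnn") cnn_towers else lstm_towers
    unlist(lapply(list(ids1, ids2), function(s) {
      tp <- ag_tape()
      as.numeric(towers(tp, encoder$params, list(s), cfg)$val)
    }))
  }
  structure(list(values = vals, encoder_tag = cfg$kind),
            class = "sts_pair_repr")
}

#' Encode a pair with a Siamese convolutional encoder
#'
#' Per sentence: trainable token embeddings, convolutions of each configured
#' width, ReLU, then average pooling over token positions; the two towers
#' share all weights and the pair representation is the concatenation
#' `[tower(s1), tower(s2)]`. Windows extending past the sentence end are
#' padded with the `<pad>` embedding, so one-token sentences are valid.
#'
#' @param pair A `TokenizedPair`.
#' @param params An `sts_encoder` with `kind = "cnn"` (see
#'   [encoder_init()]).
#' @return An `sts_pair_repr` with fields `values` and `encoder_tag`.
#' @export
encode_cnn <- function(pair, params) {
  stopifnot(params$cfg$kind == "cnn")
  encode_with(pair, params)
}

#' Encode a pair with a Siamese bidirectional LSTM
#'
#' Runs shared-weight forward and backward LSTM passes over each sentence;
#' the pair representation concatenates the final forward state and the
#' position-1 backward state of each sentence:
#' `[h_fwd_m(s1), h_bwd_1(s1), h_fwd_n(s2), h_bwd_1(s2)]`.
#'
#' @inheritParams encode_cnn
#' @export
encode_lstm <- function(pair, params) {
  stopifnot(params$cfg$kind == "lstm")
  encode_with(pair, params)
}

#' Encode a pair with a transformer over the serialized pair
#'
#' The pair is serialized as `[CLS] s1 [SEP] s2 [SEP]` with segment ids and
#' learned position embeddings, run through `depth` pre-LN transformer
#' layers, and represented by the final-layer hidden vector at the `[CLS]`
#' position. With `depth = 0` the representation is the raw `[CLS]`
#' embedding (token + segment + position). Pairs longer than `max_len` are
#' truncated, second sentence first.
#'
#' @inheritParams encode_cnn
#' @param weights Optional pretrained bundle directory (see
#'   [load_encoder_bundle()]); when supplied its parameters replace those in
#'   `params`.
#' @export
encode_transformer <- function(pair, params, weights = NULL) {
  if (!is.null(weights)) params <- load_encoder_bundle(weights)
  stopifnot(params$cfg$kind == "transformer")
  encode_with(pair, params)
}

# --- pretrained bundle I/O ------------------------------------------------

#' Save an encoder as a plain-text bundle
#'
#' Writes `config.json`, `vocab.txt` (one token per line, order defines the
#' ids) and `weights.json` (each tensor as `{dim, data}`) into `dir`.
#'
#' @param encoder An `sts_encoder`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_encoder_bundle <- function(encoder, dir) {
  stopifnot(inherits(encoder, "sts_encoder"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(encoder$cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(encoder$vocab, file.path(dir, "vocab.txt"), useBytes = TRUE)
  jsonlite::write_json(lapply(encoder$params, serialize_matrix),
                       file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' Load an encoder bundle saved by [save_encoder_bundle()]
#' @param dir Bundle directory.
#' @return An `sts_encoder`.
#' @export
load_encoder_bundle <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- encoder_config(kind = cfgl$kind, embedding_dim = cfgl$embedding_dim,
                        hidden_dim = cfgl$hidden_dim, filters = cfgl$filters,
                        filter_widths = cfgl$filter_widths, depth = cfgl$depth,
                        heads = cfgl$heads, max_len = cfgl$max_len)
  vocab <- readLines(file.path(dir, "vocab.txt"), encoding = "UTF-8")
  raw <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  params <- lapply(raw, deserialize_matrix)
  structure(list(cfg = cfg, vocab = vocab, params = params),
            class = "sts_encoder")
}

serialize_matrix <- function(m) list(dim = dim(m), data = as.numeric(m))
deserialize_matrix <- function(x) matrix(unlist(x$data), unlist(x$dim)[1], unlist(x$dim)[2])
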