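ns <- asNamespace("stsfuse")

swap_pair <- function(tp) make_tokpair(tp$tokens2, tp$tokens1, tp$gold, tp$pair_id)

test_that("encoder output dimensions follow the configuration", {
  expect_equal(encoder_config("cnn", filters = 16, filter_widths = 1:3)$d_D, 96L)
  expect_equal(encoder_config("lstm", hidden_dim = 24)$d_D, 96L)
  expect_equal(encoder_config("transformer", hidden_dim = 32)$d_D, 32L)
  expect_error(encoder_config("transformer", hidden_dim = 30, heads = 4),
               "divisible")
  enc <- random_encoder("cnn", filters = 8)
  tp <- make_tokpair(c("fever", "cough"), c("edema", "rash", "pain"))
  expect_length(encode_cnn(tp, enc)$values, 48L)
})

test_that("cnn and lstm towers are Siamese: swapping sentences swaps blocks", {
  co <- generate_corpus(synth_config(n_pairs = 6, seed = 13))
  toks <- tokenize_corpus(co)
  enc_c <- random_encoder("cnn", filters = 8)
  enc_l <- random_encoder("lstm", hidden_dim = 8, seed = 43)
  for (tp in toks[1:4]) {
    dc <- encode_cnn(tp, enc_c)$values
    dcs <- encode_cnn(swap_pair(tp), enc_c)$values
    h <- length(dc) / 2
    expect_identical(dc, c(dcs[(h + 1):(2 * h)], dcs[1:h]))
    dl <- encode_lstm(tp, enc_l)$values
    dls <- encode_lstm(swap_pair(tp), enc_l)$values
    q <- length(dl) / 2
    expect_identical(dl, c(dls[(q + 1):(2 * q)], dls[1:q]))
  }
  # identical sentences: the two halves coincide (shared weights)
  same <- make_tokpair(c("fever", "cough"), c("fever", "cough"))
  dc <- encode_cnn(same, enc_c)$values
  expect_identical(dc[1:(length(dc) / 2)], dc[(length(dc) / 2 + 1):length(dc)])
  dl <- encode_lstm(same, enc_l)$values
  expect_identical(dl[1:(length(dl) / 2)], dl[(length(dl) / 2 + 1):length(dl)])
})

test_that("width-1 identity convolution reduces to mean pooled embeddings", {
  vocab <- c("<pad>", "<unk>", "<cls>", "<sep>", "fever", "cough", "rash")
  e <- 4L
  set.seed(3)
  enc <- encoder_init(encoder_config("cnn", embedding_dim = e, filters = e,
                                     filter_widths = 1L), vocab)
  enc$params$emb <- matrix(abs(rnorm(length(vocab) * e)) + 0.1, ncol = e)
  enc$params$Wc1 <- diag(e)
  enc$params$bc1 <- matrix(0, 1, e)
  tp <- make_tokpair(c("fever", "cough"), "rash")
  d <- encode_cnn(tp, enc)$values
  ids <- tokens_to_ids(c("fever", "cough"), vocab)
  expect_equal(d[1:e], colMeans(enc$params$emb[ids, , drop = FALSE]))
  expect_equal(d[(e + 1):(2 * e)], enc$params$emb[tokens_to_ids("rash", vocab), ])
})

test_that("one-token sentences are valid for every encoder", {
  tp <- make_tokpair("fever", "rash")
  expect_true(all(is.finite(encode_cnn(tp, random_encoder("cnn", filters = 4))$values)))
  expect_true(all(is.finite(encode_lstm(tp, random_encoder("lstm", hidden_dim = 4))$values)))
  expect_true(all(is.finite(encode_transformer(
    tp, random_encoder("transformer", hidden_dim = 8, depth = 1, heads = 2))$values)))
})

test_that("zeroed recurrent weights give all-zero lstm states", {
  enc <- random_encoder("lstm", hidden_dim = 6)
  for (nm in grep("^(f|b)_", names(enc$params), value = TRUE))
    enc$params[[nm]] <- enc$params[[nm]] * 0
  d <- encode_lstm(make_tokpair(c("fever", "cough", "rash"), "pain"), enc)
  expect_equal(d$values, rep(0, 24))
})

test_that("depth-0 transformer returns the raw [CLS] embedding", {
  enc <- random_encoder("transformer", hidden_dim = 8, depth = 0, heads = 2)
  d <- encode_transformer(make_tokpair(c("fever", "cough"), "rash"), enc)
  expected <- enc$params$emb[ns$CLS_ID, ] + enc$params$seg[1, ] + enc$params$pos[1, ]
  expect_equal(d$values, unname(expected))
})

test_that("transformer encoding is deterministic and truncates long pairs", {
  enc <- random_encoder("transformer", hidden_dim = 8, depth = 1, heads = 2,
                        max_len = 12)
  tp <- make_tokpair(rep(c("fever", "cough"), 6), rep("rash", 10))
  d1 <- encode_transformer(tp, enc)
  d2 <- encode_transformer(tp, enc)
  expect_identical(d1$values, d2$values)
  # serialization respects max_len, cutting sentence 2 first
  ser <- ns$serialize_pair(rep(5L, 12L), rep(6L, 10L), 12L)
  expect_lte(length(ser$ids), 12L)
  expect_equal(sum(ser$ids == 6L), 1L)   # sentence 2 cut down before s1
  expect_equal(ser$ids[1], ns$CLS_ID)
  expect_equal(sum(ser$ids == ns$SEP_ID), 2L)
})

test_that("gradient flows to every parameter of every encoder", {
  co <- generate_corpus(synth_config(n_pairs = 2, seed = 19))
  toks <- tokenize_corpus(co)
  vocab <- build_vocab(toks)
  batch <- lapply(toks, function(tp)
    list(ids1 = tokens_to_ids(tp$tokens1, vocab),
         ids2 = tokens_to_ids(tp$tokens2, vocab)))
  for (kind in c("cnn", "lstm", "transformer")) {
    set.seed(23)
    cfg <- encoder_config(kind, embedding_dim = 6, hidden_dim = 8,
                          filters = 4, depth = 1, heads = 2)
    enc <- encoder_init(cfg, vocab)
    tp <- ns$ag_tape()
    lv <- lapply(enc$params, ns$ag_leaf, tp = tp)
    D <- ns$encoder_graph(tp, lv, batch, cfg)
    loss <- ns$ag_mse(tp, ns$ag_tanh(tp, D), matrix(0.4, 2, cfg$d_D))
    grads <- ns$ag_backward(tp, loss)
    for (nm in names(lv)) {
      g <- grads[[lv[[nm]]$id]]
      expect_false(is.null(g), label = paste(kind, nm, "gradient reached"))
      expect_true(all(is.finite(g)), label = paste(kind, nm, "finite"))
      expect_gt(max(abs(g)), 0, label = paste(kind, nm, "nonzero"))
    }
  }
})

test_that("encoder bundles round-trip through the plain-text format", {
  enc <- random_encoder("transformer", hidden_dim = 8, depth = 1, heads = 2)
  dir <- tempfile()
  save_encoder_bundle(enc, dir)
  back <- load_encoder_bundle(dir)
  tp <- make_tokpair(c("fever", "cough"), "rash")
  expect_equal(encode_transformer(tp, enc)$values,
               encode_transformer(tp, back)$values)
  # the weights argument of encode_transformer loads a bundle directly
  expect_equal(encode_transformer(tp, enc, weights = dir)$values,
               encode_transformer(tp, enc)$values)
})
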