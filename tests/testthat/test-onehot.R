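test_that("idf matches the smoothed formula on hand-computed cases", {
  # 2 pairs = 4 sentences; "common" in all 4, "rare" in 1, "absent" in 0
  toks <- list(make_tokpair(c("common", "rare"), c("common", "x"), id = "a"),
               make_tokpair(c("common", "y"), c("common", "z"), id = "b"))
  idf <- fit_idf(toks)
  expect_equal(idf$doc_count, 4L)
  expect_equal(idf_value(idf, "common"), log(4 / 5))
  expect_equal(idf_value(idf, "rare"), log(4 / 2))
  expect_equal(idf_value(idf, "absent"), log(4 / 1))
  # single sentence-pair, token present in both sentences
  one <- fit_idf(list(make_tokpair("w", "w")))
  expect_equal(idf_value(one, "w"), log(2 / 3))
  expect_error(fit_idf(list()), "non-empty")
})

test_that("idf counts each sentence once regardless of token repetition", {
  toks <- list(make_tokpair(c("dup", "dup", "dup"), c("other"), id = "a"))
  idf <- fit_idf(toks)
  expect_equal(idf_value(idf, "dup"), log(2 / 2))
})

test_that("idf is monotone non-increasing in document frequency", {
  co <- generate_corpus(synth_config(n_pairs = 40, seed = 5))
  toks <- tokenize_corpus(co)
  idf <- fit_idf(toks)
  all_tokens <- unique(unlist(lapply(toks, function(tp) c(tp$tokens1, tp$tokens2))))
  df <- vapply(all_tokens, function(tk)
    sum(vapply(toks, function(tp)
      (tk %in% tp$tokens1) + (tk %in% tp$tokens2), numeric(1))), numeric(1))
  iv <- idf_value(idf, all_tokens)
  ord <- order(df)
  expect_true(all(diff(iv[ord]) <= 1e-12))
})

test_that("ngram_overlap matches hand cases and the brute-force oracle", {
  expect_equal(ngram_overlap(c("a", "b", "c"), c("b", "c", "d"), 1), 2 * 2 / 6)
  expect_equal(ngram_overlap(c("a", "b"), c("a", "b"), 1), 1)
  expect_equal(ngram_overlap(c("a", "b", "c"), c("a", "b", "c"), 3), 1)
  expect_equal(ngram_overlap(c("a", "b"), c("c", "d"), 1), 0)
  # shorter than n on both sides: both sets empty, 0 by convention
  expect_equal(ngram_overlap("a", "b", 3), 0)
  expect_equal(ngram_overlap("a", c("a", "b", "c"), 3), 0)
  # distinct-set semantics: repeated n-grams count once
  expect_equal(ngram_overlap(c("a", "a", "a"), c("a", "b"), 1), 2 * 1 / 3)
  expect_error(ngram_overlap(c("a"), c("b"), 4), "1, 2 or 3")
  expect_error(ngram_overlap(character(0), "b", 1), "non-empty")
  set.seed(31)
  vocab <- letters[1:8]
  for (rep in 1:60) {
    t1 <- sample(vocab, sample(1:10, 1), replace = TRUE)
    t2 <- sample(vocab, sample(1:10, 1), replace = TRUE)
    for (n in 1:3)
      expect_identical(ngram_overlap(t1, t2, n), oracle_ngo(t1, t2, n))
  }
})

test_that("pair similarities match closed forms on hand-built vectors", {
  emb <- load_embeddings(write_emb_text(list(e1 = c(1, 0), e2 = c(0, 1))),
                         oov_policy = "zero")
  s <- pair_similarities("e1", "e2", emb, gamma = 0.5, coef0 = 1, degree = 3)
  expect_equal(unname(s["polynomial"]), (0.5 * 0 + 1)^3)
  expect_equal(unname(s["rbf"]), exp(-0.5 * 2))
  expect_equal(unname(s["laplacian"]), exp(-0.5 * 2))
  expect_equal(unname(s["cosine"]), 0)
  expect_equal(unname(s["manhattan"]), 2)
  expect_equal(unname(s["euclidean"]), sqrt(2))
  expect_equal(unname(s["chebyshev"]), 1)
  expect_equal(unname(s["sigmoid"]), tanh(1))
  # identical non-zero vectors: zero-distance limits
  sii <- pair_similarities("e1", "e1", emb, gamma = 0.5)
  expect_equal(unname(sii[c("cosine", "rbf", "laplacian")]), c(1, 1, 1))
  expect_equal(unname(sii[c("manhattan", "euclidean", "chebyshev")]), c(0, 0, 0))
  # all-OOV sentence under zero policy: cosine 0 by convention
  szero <- pair_similarities("unseen", "e1", emb)
  expect_equal(unname(szero["cosine"]), 0)
})

test_that("averaged-embedding sentence vectors feed the similarities", {
  emb <- load_embeddings(write_emb_text(list(a = c(2, 0), b = c(0, 2),
                                             c = c(4, 4))), oov_policy = "zero")
  # mean(a,b) = (1,1); mean(c) = (4,4) -> cosine 1
  s <- pair_similarities(c("a", "b"), "c", emb, gamma = 0.5)
  expect_equal(unname(s["cosine"]), 1)
  expect_equal(unname(s["manhattan"]), 6)
})

test_that("build_onehot has the fixed 17-slot layout with finite values", {
  co <- tiny_corpus()
  toks <- tokenize_corpus(co)
  idf <- fit_idf(toks)
  emb <- random_embeddings(8)
  fv <- build_onehot(toks[[2]], idf, emb)
  expect_length(fv, 17L)
  expect_identical(names(fv), onehot_feature_names())
  expect_true(all(is.finite(fv)))
  expect_true(all(fv[c("ngo1", "ngo2", "ngo3")] >= 0 &
                  fv[c("ngo1", "ngo2", "ngo3")] <= 1))
  # identity pair: overlaps 1, distances 0, absolute differences 0
  fid <- build_onehot(toks[[1]], idf, emb)
  expect_equal(unname(fid[c("ngo1", "ngo2", "ngo3")]), c(1, 1, 1))
  expect_equal(unname(fid[c("manhattan", "euclidean", "chebyshev")]), c(0, 0, 0))
  expect_equal(unname(fid[c("len_diff", "idf_diff")]), c(0, 0))
  expect_equal(unname(fid["cosine"]), 1)
})

test_that("swapping sentences permutes per-sentence slots and fixes the rest", {
  co <- generate_corpus(synth_config(n_pairs = 8, seed = 17))
  toks <- tokenize_corpus(co)
  idf <- fit_idf(toks)
  emb <- random_embeddings(8)
  for (tp in toks) {
    sw <- make_tokpair(tp$tokens2, tp$tokens1, id = tp$pair_id)
    a <- build_onehot(tp, idf, emb)
    b <- build_onehot(sw, idf, emb)
    expect_equal(unname(a[c("len1", "len2", "idf1", "idf2")]),
                 unname(b[c("len2", "len1", "idf2", "idf1")]))
    sym <- c("len_diff", "idf_diff", "ngo1", "ngo2", "ngo3",
             "cosine", "manhattan", "euclidean", "chebyshev",
             "polynomial", "rbf", "laplacian", "sigmoid")
    expect_equal(a[sym], b[sym])
  }
})

test_that("sum aggregation is exposed and differs from mean", {
  toks <- tokenize_corpus(tiny_corpus())
  idf <- fit_idf(toks)
  emb <- random_embeddings(4)
  fm <- build_onehot(toks[[2]], idf, emb, aggregate = "mean")
  fs <- build_onehot(toks[[2]], idf, emb, aggregate = "sum")
  expect_equal(unname(fs["idf1"]), unname(fm["idf1"]) * fm[["len1"]])
})

test_that("featurize_corpus stacks rows with pair ids", {
  toks <- tokenize_corpus(tiny_corpus())
  X <- featurize_corpus(toks, fit_idf(toks), random_embeddings(4))
  expect_equal(dim(X), c(6L, 17L))
  expect_identical(rownames(X), tiny_corpus()$pair_id)
})
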