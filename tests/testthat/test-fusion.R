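random_fusion_setup <- function(d = 4L, d_D = 6L, F_ = 5L) {
  par <- fusion_init(d, d_D, F_)
  par$b_d <- rnorm(d); par$b_o <- rnorm(d); par$b_f <- rnorm(d)
  par$head_b <- rnorm(1)
  list(par = par, D = rnorm(d_D), O = rnorm(F_))
}

test_that("gate saturation and the symmetric gate behave as closed forms say", {
  set.seed(51)
  s <- random_fusion_setup()
  # huge gate bias, zero gate weights: gate ~ 1, R ~ D_norm
  s$par$W_f <- s$par$W_f * 0
  s$par$b_f <- rep(50, 4)
  fz <- fuse(s$D, s$O, s$par)
  expect_true(all(fz$gate > 1 - 1e-10))
  expect_equal(fz$r, fz$d_norm, tolerance = 1e-9)
  # zero gate parameters: gate exactly 1/2, R the midpoint
  s$par$b_f <- rep(0, 4)
  fh <- fuse(s$D, s$O, s$par)
  expect_identical(fh$gate, rep(0.5, 4))
  expect_equal(fh$r, (fh$d_norm + fh$o_norm) / 2)
})

test_that("fuse matches a hand-evaluated d = 2 case", {
  par <- list(W_d = matrix(c(1, 0, 0, -1), 2, 2), b_d = c(0.1, -0.2),
              W_o = matrix(c(0.5, 0.5, -0.5, 0.25), 2, 2), b_o = c(0, 0.3),
              W_f = matrix(c(1, -1, 0.5, 0, -0.5, 1, 0.2, -0.2), 2, 4),
              b_f = c(0.05, -0.05), head_w = c(1, -2), head_b = 0.5)
  D <- c(0.4, -0.6); O <- c(1.2, -0.8)
  d_norm <- tanh(c(1 * 0.4 + 0 * -0.6 + 0.1, 0 * 0.4 + (-1) * -0.6 - 0.2))
  o_norm <- tanh(c(0.5 * 1.2 + (-0.5) * -0.8 + 0,
                   0.5 * 1.2 + 0.25 * -0.8 + 0.3))
  z <- as.numeric(par$W_f %*% c(d_norm, o_norm)) + par$b_f
  gate <- 1 / (1 + exp(-z))
  r <- gate * d_norm + (1 - gate) * o_norm
  got <- fuse(D, O, par)
  expect_equal(got$d_norm, d_norm, tolerance = 1e-10)
  expect_equal(got$o_norm, o_norm, tolerance = 1e-10)
  expect_equal(got$gate, gate, tolerance = 1e-10)
  expect_equal(got$r, r, tolerance = 1e-10)
  expect_equal(predict_score(got, par),
               5 / (1 + exp(-(sum(c(1, -2) * r) + 0.5))), tolerance = 1e-10)
})

test_that("fuse matches the scalar-loop oracle with valid gate/range invariants", {
  set.seed(52)
  for (rep in 1:20) {
    s <- random_fusion_setup(d = sample(2:6, 1), d_D = sample(3:8, 1),
                             F_ = sample(3:8, 1))
    got <- fuse(s$D, s$O, s$par)
    want <- oracle_fuse(s$D, s$O, s$par)
    expect_equal(got$d_norm, want$d_norm, tolerance = 1e-8)
    expect_equal(got$gate, want$gate, tolerance = 1e-8)
    expect_equal(got$r, want$r, tolerance = 1e-8)
    expect_true(all(got$gate > 0 & got$gate < 1))
    expect_true(all(got$r >= pmin(got$d_norm, got$o_norm) - 1e-12 &
                    got$r <= pmax(got$d_norm, got$o_norm) + 1e-12))
    expect_true(all(abs(got$r) < 1))
  }
})

test_that("concat returns [D_norm, O_norm] sharing the fuse projections", {
  set.seed(53)
  s <- random_fusion_setup()
  cc <- concat_repr(s$D, s$O, s$par)
  fz <- fuse(s$D, s$O, s$par)
  expect_length(cc, 8L)
  expect_true(all(cc > -1 & cc < 1))
  expect_equal(cc[1:4], fz$d_norm)
  expect_equal(cc[5:8], fz$o_norm)
})

test_that("the bounded head maps zero to 2.5 and saturates at 5", {
  par <- list(head_w = rep(0, 3), head_b = 0)
  expect_equal(predict_score(c(1, 2, 3), par), 2.5)
  par$head_b <- 100
  expect_gt(predict_score(c(1, 2, 3), par), 5 - 1e-10)
  expect_lte(predict_score(c(1, 2, 3), par), 5)  # saturates to 5 in doubles
  par$head_b <- 20
  expect_lt(predict_score(c(1, 2, 3), par), 5)
})

test_that("fuse rejects non-finite parameters with a diagnostic", {
  set.seed(54)
  s <- random_fusion_setup()
  s$par$W_d[1, 1] <- NaN
  expect_error(fuse(s$D, s$O, s$par), "non-finite")
})

test_that("training is deterministic given the seed", {
  co <- generate_corpus(synth_config(n_pairs = 80, seed = 6))
  sp <- stratified_split(co, 0.25, seed = 2)
  cfg <- sts_config(mode = "onehot_only", epochs = 8, seed = 99)
  m1 <- sts_train(sp$train, sp$dev, cfg)
  m2 <- sts_train(sp$train, sp$dev, cfg)
  expect_identical(m1$best_dev_pearson, m2$best_dev_pearson)
  expect_identical(m1$params, m2$params)
  m3 <- sts_train(sp$train, sp$dev, sts_config(mode = "onehot_only",
                                               epochs = 8, seed = 100))
  expect_false(identical(m1$params$Wo, m3$params$Wo))
})

test_that("a single-pair corpus is overfit to near-zero loss", {
  co <- sts_corpus("patient report severe chest pain",
                   "patient denies any chest pain", gold = 2.0)
  m <- sts_train(co, dev = NULL,
                 sts_config(mode = "onehot_only", epochs = 150, lr = 5e-3,
                            seed = 3, batch_size = 1))
  expect_lt(tail(m$log$train_loss, 1), 1e-2)
  expect_lt(tail(m$log$train_loss, 1), m$log$train_loss[1] / 100)
  # steady decrease at the epoch-window scale (Adam jitters near zero)
  expect_lt(mean(tail(m$log$train_loss, 20)), mean(head(m$log$train_loss, 20)) / 10)
})

test_that("without a dev corpus the full epoch budget is used", {
  co <- generate_corpus(synth_config(n_pairs = 20, seed = 8))
  m <- sts_train(co, dev = NULL, sts_config(mode = "onehot_only", epochs = 5,
                                            seed = 1))
  expect_equal(nrow(m$log), 5L)
  expect_true(all(is.na(m$log$dev_pearson)))
  expect_equal(m$best_epoch, 5L)
})

test_that("trained fusion parameters round-trip into the math layout", {
  co <- generate_corpus(synth_config(n_pairs = 40, seed = 9))
  sp <- stratified_split(co, 0.25, seed = 1)
  m <- sts_train(sp$train, sp$dev,
                 sts_config(mode = "gated", encoder = "cnn", epochs = 2,
                            seed = 2, d = 8, filters = 4))
  par <- fusion_params(m)
  expect_equal(dim(par$W_d), c(8L, m$enc_cfg$d_D))
  expect_equal(dim(par$W_f), c(8L, 16L))
  # the exported parameters reproduce the model head on a fused vector
  toks <- tokenize_corpus(sp$dev)[[1]]
  D <- encode_cnn(toks, structure(list(cfg = m$enc_cfg, vocab = m$vocab,
                                       params = m$params),
                                  class = "sts_encoder"))
  X <- build_onehot(toks, m$idf, random_embeddings(m$config$feature_emb_dim))
  O <- (X - m$feature_mu) / m$feature_sd
  sc <- predict_score(fuse(D, O, par), par)
  pd <- predict(m, sp$dev[1, ])
  expect_equal(sc, pd, tolerance = 1e-8)
})

test_that("checkpoints round-trip through JSON with identical predictions", {
  co <- generate_corpus(synth_config(n_pairs = 50, seed = 10))
  sp <- stratified_split(co, 0.2, seed = 3)
  m <- sts_train(sp$train, sp$dev,
                 sts_config(mode = "gated", encoder = "cnn", epochs = 2,
                            seed = 4, d = 8, filters = 4))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(predict(back, sp$dev), predict(m, sp$dev), tolerance = 1e-12)
  expect_error(load_model(write_tsv_corpus(c("{}"))), "checkpoint")
})
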