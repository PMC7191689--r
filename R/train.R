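# End-to-end training of the similarity regressor: minibatch Adam on mean
# squared error, early stopping on dev Pearson, best-dev checkpointing.

#' Model/run configuration
#'
#' Collects every tunable of the pipeline. The representation `mode` is one
#' of `"onehot_only"` (handcrafted features only), `"encoder_only"`
#' (distributed representation only), `"concat"` (concatenated normalized
#' representations) and `"gated"` (sigmoid-gate fusion). Defaults follow
#' desk-scale conventions: common dimension 64, Adam at learning rate 1e-3,
#' batches of 32, early-stopping patience 10 epochs on dev Pearson.
#'
#' @param mode Representation mode (see above).
#' @param encoder Encoder kind for modes that use one.
#' @param d Common-space dimension after projection (default 64).
#' @param head `"sigmoid"` (default; predictions bounded in (0,5) by
#'   `5 * sigmoid`) or `"linear"` (unbounded head, clipped to `[0,5]` at
#'   prediction time).
#' @param lr,batch_size,epochs,patience Optimization settings.
#' @param seed Master seed: drives parameter initialization and batch
#'   shuffling.
#' @param embeddings Optional path to a word2vec file used for the kernel
#'   similarity features (and to warm-start cnn/lstm token embeddings);
#'   `NULL` uses deterministic random fallback embeddings.
#' @param feature_emb_dim Dimension of the fallback feature embeddings
#'   (default 50).
#' @param aggregate,gamma,coef0,degree One-hot feature settings, see
#'   [build_onehot()].
#' @param stopwords Stopword set for [normalize()].
#' @param ... Encoder hyperparameters forwarded to [encoder_config()].
#' @return An `sts_config` list.
#' @export
sts_config <- function(mode = c("gated", "concat", "onehot_only", "encoder_only"),
                       encoder = c("cnn", "lstm", "transformer"),
                       d = 64L, head = c("sigmoid", "linear"),
                       lr = 1e-3, batch_size = 32L, epochs = 60L,
                       patience = 10L, seed = 1L, embeddings = NULL,
                       feature_emb_dim = 50L,
                       aggregate = "mean", gamma = NULL, coef0 = 1,
                       degree = 3, stopwords = sts_stopwords(), ...) {
  mode <- match.arg(mode)
  encoder <- match.arg(encoder)
  structure(list(mode = mode, encoder = encoder, d = as.integer(d),
                 head = match.arg(head), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed), embeddings = embeddings,
                 feature_emb_dim = as.integer(feature_emb_dim),
                 aggregate = aggregate, gamma = gamma, coef0 = coef0,
                 degree = degree, stopwords = stopwords,
                 enc_args = list(...)),
            class = "sts_config")
}

uses_encoder <- function(mode) mode %in% c("encoder_only", "concat", "gated")

# feature-embedding table per config
feature_embeddings <- function(config) {
  if (is.null(config$embeddings)) random_embeddings(config$feature_emb_dim)
  else load_embeddings(config$embeddings)
}

# standardized feature matrix (train stats)
standardize <- function(X, mu, sd_) sweep(sweep(X, 2L, mu), 2L, sd_, "/")

# build the prediction node for one batch; `lv` holds nodes (training) or
# plain matrices (inference)
model_graph <- function(tp, lv, batch_ids, O_std, mode, enc_cfg, head) {
  O_norm <- ag_tanh(tp, ag_add(tp, ag_matmul(tp, O_std, lv$Wo), lv$bo))
  r <- if (mode == "onehot_only") {
    O_norm
  } else {
    D <- encoder_graph(tp, lv, batch_ids, enc_cfg)
    D_norm <- ag_tanh(tp, ag_add(tp, ag_matmul(tp, D, lv$Wd), lv$bd))
    switch(mode,
           encoder_only = D_norm,
           concat = ag_cbind(tp, list(D_norm, O_norm)),
           gated = {
             DO <- ag_cbind(tp, list(D_norm, O_norm))
             f <- ag_sigmoid(tp, ag_add(tp, ag_matmul(tp, DO, lv$Wf), lv$bf))
             ag_add(tp, ag_mul(tp, f, D_norm),
                    ag_mul(tp, ag_sub(tp, 1, f), O_norm))
           })
  }
  z <- ag_add(tp, ag_matmul(tp, r, lv$hw), lv$hb)
  if (head == "sigmoid") ag_scale(tp, ag_sigmoid(tp, z), 5) else z
}

init_model_params <- function(config, enc_cfg, vocab, n_features, emb) {
  d <- config$d
  p <- list()
  if (uses_encoder(config$mode)) {
    enc <- encoder_init(enc_cfg, vocab,
                        emb = if (enc_cfg$kind %in% c("cnn", "lstm") &&
                                  !is.null(config$embeddings)) emb)
    p <- enc$params
    p$Wd <- ginit(enc_cfg$d_D, d); p$bd <- matrix(0, 1L, d)
  }
  p$Wo <- ginit(n_features, d); p$bo <- matrix(0, 1L, d)
  if (config$mode == "gated") {
    p$Wf <- ginit(2L * d, d); p$bf <- matrix(0, 1L, d)
  }
  head_dim <- if (config$mode == "concat") 2L * d else d
  p$hw <- ginit(head_dim, 1L); p$hb <- matrix(0, 1L, 1L)
  p
}

predict_matrix <- function(params, batch_ids, O_std, mode, enc_cfg, head,
                           chunk = 256L) {
  n <- nrow(O_std)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    tp <- ag_tape()
    node <- model_graph(tp, params, batch_ids[idx], O_std[idx, , drop = FALSE],
                        mode, enc_cfg, head)
    out[idx] <- as.numeric(node$val)
  }
  if (head == "linear") out <- pmin(pmax(out, 0), 5)
  out
}

#' Train a similarity model
#'
#' Preprocesses the corpora, fits the IDF model and feature standardization
#' on the training split only, builds the vocabulary, and minimizes mean
#' squared error between predicted and gold scores with minibatch Adam.
#' After every epoch the dev Pearson correlation is computed; training
#' stops when it has not improved for `patience` epochs and the best-dev
#' parameters are returned. Without a dev corpus the full `epochs` budget
#' is used and the final parameters are kept. Fully deterministic given
#' `config$seed`.
#'
#' @param train A scored `sts_corpus`.
#' @param dev Optional scored `sts_corpus` for early stopping/model
#'   selection.
#' @param config An [sts_config()].
#' @param quiet Suppress per-epoch messages (default `TRUE`).
#' @return An `sts_model`: parameters, config, vocabulary, IDF model,
#'   feature scaling, and a training `log` data.frame with columns
#'   `epoch`, `train_loss`, `dev_pearson`.
#' @export
sts_train <- function(train, dev = NULL, config = sts_config(), quiet = TRUE) {
  stopifnot(inherits(train, "sts_corpus"))
  if (any(is.na(train$gold))) stop("training corpus must be fully scored", call. = FALSE)
  if (!is.null(dev) && nrow(dev) == 0L) dev <- NULL
  if (!is.null(dev) && any(is.na(dev$gold)))
    stop("dev corpus must be fully scored", call. = FALSE)

  tok_tr <- tokenize_corpus(train, stopwords = config$stopwords)
  tok_dv <- if (!is.null(dev)) tokenize_corpus(dev, stopwords = config$stopwords)
  idf <- fit_idf(tok_tr)
  emb <- feature_embeddings(config)
  X_tr <- featurize_corpus(tok_tr, idf, emb, aggregate = config$aggregate,
                           gamma = config$gamma, coef0 = config$coef0,
                           degree = config$degree)
  mu <- colMeans(X_tr)
  sd_ <- apply(X_tr, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  O_tr <- standardize(X_tr, mu, sd_)
  O_dv <- if (!is.null(dev))
    standardize(featurize_corpus(tok_dv, idf, emb, aggregate = config$aggregate,
                                 gamma = config$gamma, coef0 = config$coef0,
                                 degree = config$degree), mu, sd_)

  vocab <- build_vocab(tok_tr)
  enc_cfg <- do.call(encoder_config,
                     c(list(kind = config$encoder), config$enc_args))
  ids_of <- function(toks) lapply(toks, function(tp)
    list(ids1 = tokens_to_ids(tp$tokens1, vocab),
         ids2 = tokens_to_ids(tp$tokens2, vocab)))
  ids_tr <- ids_of(tok_tr)
  ids_dv <- if (!is.null(dev)) ids_of(tok_dv)
  y_tr <- train$gold
  y_dv <- if (!is.null(dev)) dev$gold

  n <- nrow(train)
  log_rows <- list()
  model_env <- new.env(parent = emptyenv())

  with_seed(config$seed, {
    params <- init_model_params(config, enc_cfg, vocab, ncol(X_tr), emb)
    state <- adam_state(params)
    best <- list(pearson = -Inf, params = params, epoch = 0L)
    no_improve <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        tp <- ag_tape()
        lv <- lapply(params, ag_leaf, tp = tp)
        pred <- model_graph(tp, lv, ids_tr[idx], O_tr[idx, , drop = FALSE],
                            config$mode, enc_cfg, config$head)
        loss <- ag_mse(tp, pred, matrix(y_tr[idx], ncol = 1L))
        if (!is.finite(loss$val))
          stop(sprintf("NaN/Inf loss at epoch %d (batch starting %d); mode=%s encoder=%s lr=%g",
                       epoch, s, config$mode, config$encoder, config$lr),
               call. = FALSE)
        grads_by_id <- ag_backward(tp, loss)
        grads <- lapply(lv, function(leaf) grads_by_id[[leaf$id]])
        upd <- adam_step(params, grads, state, lr = config$lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss$val; n_batches <- n_batches + 1L
      }
      dev_r <- NA_real_
      if (!is.null(dev)) {
        pd <- predict_matrix(params, ids_dv, O_dv, config$mode, enc_cfg,
                             config$head)
        dev_r <- pearson(pd, y_dv)
        if (!is.na(dev_r) && dev_r > best$pearson + 1e-6) {
          best <- list(pearson = dev_r, params = params, epoch = epoch)
          no_improve <- 0L
        } else no_improve <- no_improve + 1L
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch,
                                      train_loss = ep_loss / n_batches,
                                      dev_pearson = dev_r)
      if (!quiet)
        message(sprintf("epoch %3d  loss %.4f  dev pearson %s", epoch,
                        ep_loss / n_batches,
                        if (is.na(dev_r)) "-" else sprintf("%.4f", dev_r)))
      if (!is.null(dev) && no_improve >= config$patience) break
    }
    model_env$params <- if (!is.null(dev) && is.finite(best$pearson))
      best$params else params
    model_env$best_epoch <- if (!is.null(dev)) best$epoch else config$epochs
    model_env$best_dev_pearson <- if (!is.null(dev)) best$pearson else NA_real_
  })

  structure(list(params = model_env$params, config = config,
                 enc_cfg = enc_cfg, vocab = vocab, idf = idf,
                 feature_mu = mu, feature_sd = sd_,
                 feature_names = colnames(X_tr),
                 best_epoch = model_env$best_epoch,
                 best_dev_pearson = model_env$best_dev_pearson,
                 log = do.call(rbind, log_rows)),
            class = "sts_model")
}

#' @export
print.sts_model <- function(x, ...) {
  cat(sprintf("<sts_model> mode=%s encoder=%s d=%d | best epoch %d, dev pearson %s\n",
              x$config$mode,
              if (uses_encoder(x$config$mode)) x$config$encoder else "-",
              x$config$d, x$best_epoch,
              if (is.na(x$best_dev_pearson)) "-" else sprintf("%.4f", x$best_dev_pearson)))
  invisible(x)
}

#' Predict similarity scores for a corpus
#'
#' @param object An `sts_model`.
#' @param corpus An `sts_corpus` (scores, if present, are ignored).
#' @param ... Unused.
#' @return Numeric vector of predicted scores in `[0, 5]`, one per pair.
#' @export
predict.sts_model <- function(object, corpus, ...) {
  stopifnot(inherits(corpus, "sts_corpus"))
  cfg <- object$config
  toks <- tokenize_corpus(corpus, stopwords = cfg$stopwords)
  emb <- feature_embeddings(cfg)
  X <- featurize_corpus(toks, object$idf, emb, aggregate = cfg$aggregate,
                        gamma = cfg$gamma, coef0 = cfg$coef0,
                        degree = cfg$degree)
  O <- standardize(X, object$feature_mu, object$feature_sd)
  ids <- lapply(toks, function(tp)
    list(ids1 = tokens_to_ids(tp$tokens1, object$vocab),
         ids2 = tokens_to_ids(tp$tokens2, object$vocab)))
  predict_matrix(object$params, ids, O, cfg$mode, object$enc_cfg, cfg$head)
}

#' Extract user-facing fusion parameters from a trained model
#'
#' Transposes the internal (input-by-output) training layout into the math
#' layout used by [fuse()], [concat_repr()] and [predict_score()]. Only
#' available for models that carry the corresponding tensors.
#'
#' @param model An `sts_model`.
#' @return An `sts_fusion_params` list (entries for tensors the mode does
#'   not use are `NULL`).
#' @export
fusion_params <- function(model) {
  p <- model$params
  structure(list(W_d = if (!is.null(p$Wd)) t(p$Wd),
                 b_d = if (!is.null(p$bd)) as.numeric(p$bd),
                 W_o = t(p$Wo), b_o = as.numeric(p$bo),
                 W_f = if (!is.null(p$Wf)) t(p$Wf),
                 b_f = if (!is.null(p$bf)) as.numeric(p$bf),
                 head_w = as.numeric(p$hw), head_b = as.numeric(p$hb)),
            class = "sts_fusion_params")
}

# --- checkpoint I/O -------------------------------------------------------

#' Save a trained model as a JSON checkpoint
#'
#' Single plain-text archive holding every parameter tensor, the config
#' snapshot, vocabulary, IDF counts, feature names and scaling.
#'
#' @param model An `sts_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  df_tokens <- ls(model$idf$df)
  obj <- list(
    package = "stsfuse", format = 1L,
    config = model$config[setdiff(names(model$config), "stopwords")],
    stopwords = model$config$stopwords,
    enc_cfg = unclass(model$enc_cfg),
    vocab = model$vocab,
    idf = list(doc_count = model$idf$doc_count, tokens = df_tokens,
               df = vapply(df_tokens, function(tk) get(tk, envir = model$idf$df),
                           numeric(1))),
    feature_mu = model$feature_mu, feature_sd = model$feature_sd,
    feature_names = model$feature_names,
    best_epoch = model$best_epoch, best_dev_pearson = model$best_dev_pearson,
    params = lapply(model$params, serialize_matrix))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return An `sts_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$package, "stsfuse"))
    stop("not a stsfuse checkpoint: ", path, call. = FALSE)
  cfg <- obj$config
  config <- do.call(sts_config, c(
    list(mode = cfg$mode, encoder = cfg$encoder, d = cfg$d, head = cfg$head,
         lr = cfg$lr, batch_size = cfg$batch_size, epochs = cfg$epochs,
         patience = cfg$patience, seed = cfg$seed,
         embeddings = cfg$embeddings, feature_emb_dim = cfg$feature_emb_dim,
         aggregate = cfg$aggregate, gamma = cfg$gamma, coef0 = cfg$coef0,
         degree = cfg$degree, stopwords = obj$stopwords),
    as.list(cfg$enc_args)))
  ec <- obj$enc_cfg
  enc_cfg <- encoder_config(kind = ec$kind, embedding_dim = ec$embedding_dim,
                            hidden_dim = ec$hidden_dim, filters = ec$filters,
                            filter_widths = ec$filter_widths, depth = ec$depth,
                            heads = ec$heads, max_len = ec$max_len)
  df <- new.env(parent = emptyenv())
  for (i in seq_along(obj$idf$tokens))
    assign(obj$idf$tokens[i], obj$idf$df[[i]], envir = df)
  mu <- as.numeric(obj$feature_mu); sd_ <- as.numeric(obj$feature_sd)
  names(mu) <- names(sd_) <- obj$feature_names
  structure(list(params = lapply(obj$params, deserialize_matrix),
                 config = config, enc_cfg = enc_cfg, vocab = obj$vocab,
                 idf = structure(list(doc_count = obj$idf$doc_count, df = df),
                                 class = "sts_idf"),
                 feature_mu = mu, feature_sd = sd_,
                 feature_names = obj$feature_names,
                 best_epoch = obj$best_epoch,
                 best_dev_pearson = obj$best_dev_pearson, log = NULL),
            class = "sts_model")
}
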