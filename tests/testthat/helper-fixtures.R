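# Fixtures are built in code; independent oracles live here so every test
# compares the implementation against a second, dumber route.

make_tokpair <- function(t1, t2, gold = NA_real_, id = "p1") {
  list(pair_id = id, tokens1 = t1, tokens2 = t2, gold = gold)
}

tiny_corpus <- function() {
  sts_corpus(
    s1 = c("nurse visit ten minute", "patient report chest pain",
           "blood pressure stable today", "order chest x ray",
           "discharge patient home", "fever and cough noted"),
    s2 = c("nurse visit ten minute", "patient denies chest pain",
           "blood pressure remains stable", "order abdominal scan",
           "patient discharged to home", "no fever reported"),
    gold = c(5, 3.2, 4.1, 1.5, 3.8, 0.6),
    provenance = "tiny")
}

write_tsv_corpus <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

# word2vec text fixture
write_emb_text <- function(vecs, path = tempfile(fileext = ".txt")) {
  dim <- length(vecs[[1]])
  lines <- c(paste(length(vecs), dim),
             vapply(names(vecs), function(tk)
               paste(tk, paste(format(vecs[[tk]], digits = 8), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  path
}

# word2vec binary fixture (header, then "token " + dim float32s)
write_emb_binary <- function(vecs, path = tempfile(fileext = ".bin")) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(length(vecs), " ", length(vecs[[1]]), "\n")), con)
  for (tk in names(vecs)) {
    writeBin(charToRaw(paste0(tk, " ")), con)
    writeBin(as.numeric(vecs[[tk]]), con, size = 4L, endian = "little")
  }
  path
}

# --- independent oracles --------------------------------------------------

# brute-force distinct n-gram overlap: materialize n-gram string sets by
# explicit loops, then apply the Dice-style formula
oracle_ngo <- function(t1, t2, n) {
  grams <- function(tok) {
    if (length(tok) < n) return(character(0))
    out <- character(0)
    for (i in 1:(length(tok) - n + 1))
      out <- c(out, paste(tok[i:(i + n - 1)], collapse = "\x01"))
    unique(out)
  }
  g1 <- grams(t1); g2 <- grams(t2)
  if (length(g1) + length(g2) == 0) return(0)
  inter <- 0
  for (g in g1) if (g %in% g2) inter <- inter + 1
  2 * inter / (length(g1) + length(g2))
}

# closed-form similarities computed with scalar loops
oracle_similarities <- function(v1, v2, gamma, coef0 = 1, degree = 3) {
  dot <- 0; l1 <- 0; l2sq <- 0; n1 <- 0; n2 <- 0; cheb <- 0
  for (i in seq_along(v1)) {
    dot <- dot + v1[i] * v2[i]
    l1 <- l1 + abs(v1[i] - v2[i])
    l2sq <- l2sq + (v1[i] - v2[i])^2
    n1 <- n1 + v1[i]^2; n2 <- n2 + v2[i]^2
    cheb <- max(cheb, abs(v1[i] - v2[i]))
  }
  c(cosine = if (n1 == 0 || n2 == 0) 0 else dot / (sqrt(n1) * sqrt(n2)),
    manhattan = l1, euclidean = sqrt(l2sq), chebyshev = cheb,
    polynomial = (gamma * dot + coef0)^degree,
    rbf = exp(-gamma * l2sq), laplacian = exp(-gamma * l1),
    sigmoid = tanh(gamma * dot + coef0))
}

# scalar-loop re-implementation of the fusion equations
oracle_fuse <- function(D, O, par) {
  d <- length(par$b_d)
  d_norm <- numeric(d); o_norm <- numeric(d)
  for (i in 1:d) {
    acc <- par$b_d[i]
    for (j in seq_along(D)) acc <- acc + par$W_d[i, j] * D[j]
    d_norm[i] <- tanh(acc)
    acc <- par$b_o[i]
    for (j in seq_along(O)) acc <- acc + par$W_o[i, j] * O[j]
    o_norm[i] <- tanh(acc)
  }
  cat_in <- c(d_norm, o_norm)
  gate <- numeric(d); r <- numeric(d)
  for (i in 1:d) {
    acc <- par$b_f[i]
    for (j in seq_along(cat_in)) acc <- acc + par$W_f[i, j] * cat_in[j]
    gate[i] <- 1 / (1 + exp(-acc))
    r[i] <- gate[i] * d_norm[i] + (1 - gate[i]) * o_norm[i]
  }
  list(d_norm = d_norm, o_norm = o_norm, gate = gate, r = r)
}

# per-bin evaluation by explicit loops
oracle_interval_report <- function(pred, gold) {
  lo <- 0:4; hi <- 1:5
  out <- data.frame(count = integer(5), pearson = NA_real_, mse = NA_real_)
  for (k in 1:5) {
    sel <- if (k < 5) gold >= lo[k] & gold < hi[k] else gold >= 4 & gold <= 5
    out$count[k] <- sum(sel)
    if (sum(sel) >= 2 && sd(pred[sel]) > 0 && sd(gold[sel]) > 0)
      out$pearson[k] <- cor(pred[sel], gold[sel])
    if (sum(sel) >= 1) out$mse[k] <- mean((pred[sel] - gold[sel])^2)
  }
  out
}

# random fitted encoder over a small vocabulary
random_encoder <- function(kind, seed = 42, ...) {
  co <- generate_corpus(synth_config(n_pairs = 12, seed = 3))
  vocab <- build_vocab(tokenize_corpus(co))
  set.seed(seed)
  encoder_init(encoder_config(kind, ...), vocab)
}
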