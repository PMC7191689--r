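---
title: "Gated fusion of handcrafted and neural representations for clinical sentence similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated fusion of handcrafted and neural representations for clinical sentence similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsfuse)
```

## The problem

Clinical notes are riddled with copied and templated text. Semantic textual
similarity (STS) systems score how close two text snippets are in meaning on
a 0–5 scale (0 = unrelated, 5 = semantically equivalent), which supports
deduplication and aggregation of electronic health records. STS is a
regression problem, and the interesting modeling question is how the
sentence *pair* is represented.

Two families dominate. Handcrafted ("one-hot") features — lexical overlap,
inverse document frequency, distances between averaged word embeddings —
are sparse but extremely reliable on clearly-dissimilar pairs. Dense
("distributed") vectors from neural encoders capture soft semantics but are
data-hungry and over-generous on unrelated sentences. This package
implements both, plus a *learned gate* that blends them componentwise, and
lets you run the full ablation grid (each representation alone, their
concatenation, and the gated fusion).

## The model

**One-hot representation `O`** (17 slots): token counts of both sentences
and their absolute difference; mean token IDF of both sentences and its
absolute difference; distinct n-gram overlap for n = 1, 2, 3,

$$NGO(s_1,s_2) = \frac{2\,|G_1 \cap G_2|}{|G_1| + |G_2|},$$

with `G_i` the *set* of distinct n-grams of sentence *i*; and eight
similarities between averaged word-embedding vectors — cosine, Manhattan,
Euclidean, Chebyshev, and the polynomial, RBF, Laplacian and sigmoid
kernels.

**Distributed representation `D`**, one of:

* *Siamese CNN*: shared-weight convolution towers (widths 1–3, ReLU,
  average pooling over positions), `D = [tower(s1), tower(s2)]`;
* *Siamese BiLSTM*: shared-weight bidirectional LSTM towers,
  `D = [h→_m(s1), h←_1(s1), h→_n(s2), h←_1(s2)]`;
* *transformer*: a pre-LN stack over `[CLS] s1 [SEP] s2 [SEP]` with segment
  and position embeddings, `D` = the final CLS vector.

**Fusion gate.** Both representations are projected into a common space
with `tanh`, and a sigmoid gate vector decides, per component, which source
to trust:

$$D_{norm} = \tanh(W_d D + b_d),\quad O_{norm} = \tanh(W_o O + b_o),$$
$$f = \sigma(W_f [D_{norm}, O_{norm}] + b_f),\quad
R = f \odot D_{norm} + (1-f) \odot O_{norm}.$$

`R` is an elementwise convex combination, so each component stays between
the corresponding components of the two normalized inputs. The
concatenation baseline instead feeds `[D_norm, O_norm]` to the head. The
regression head is `score = 5\,\sigma(w^\top r + b)`, bounding predictions
to the valid range (an unbounded linear head with clipping is available via
`head = "linear"`).

## Parameters that matter

| parameter | default | why |
|---|---|---|
| common dimension `d` | 64 | unstated upstream; large enough for 17 features + encoder output, small enough for desk-scale CPU training |
| IDF | `ln(N/(1+df))`, mean over tokens | smoothing keeps unseen tokens finite; mean (not sum) decouples IDF from length, which has its own slots |
| kernel settings | `gamma = 1/dim`, `coef0 = 1`, `degree = 3` | the conventional defaults of kernel libraries; configurable |
| CNN | widths 1–3, 64 filters, ReLU before pooling | unstated upstream; standard sentence-CNN shape |
| transformer | depth 2, width 64, 2 heads | a from-scratch desk-scale stand-in for a clinically pre-trained model, which is out of scope (restricted corpora); externally trained weights can be loaded from a plain-text bundle |
| optimizer | Adam, lr 1e-3, batch 32, MSE loss, patience 10 on dev Pearson | unstated upstream; declared defaults, all exposed in `sts_config()` |
| stopword list | small function-word list | chosen so the published preprocessing example reproduces *exactly*: `within`, `without`, `every`, negations and number words are never removed, while `a/and/on/for/up/to` are |

One deliberate preprocessing choice: the lemmatizer is a light rule system
(regular plurals, `-ing`/`-ed` with a keep-list). It reproduces the printed
example forms (`instructions → instruction`, `spent → spent`,
`denies → denies`) but does not attempt silent-e restoration
(`prescribed → prescrib`); clinical STS pipelines routinely use stemmers
with the same behavior, and both sentences of a pair pass through the same
map, which is what the overlap features see.

## What the synthetic generator emulates — and what it does not

The reference corpus for clinical STS is access-restricted, so the package
ships a generator (`generate_corpus()`) instead of data. It emulates the
*shape* of such a corpus: short clinical-style sentences; a configurable
distribution of pairs over the five unit score intervals (default
0.30/0.15/0.15/0.20/0.20 — skewed towards dissimilar pairs with a second
mode of near-duplicates, the copy-paste signature); and a gold score that
is a monotone function of lexical overlap. Sentence 2 is derived from
sentence 1 by keeping a target fraction of tokens and
substituting/deleting/inserting the rest from a disjoint vocabulary, with
deletions and insertions count-balanced so the realized unigram overlap
equals `kept/L` exactly; gold is `clip(5·NGO₁ + N(0, noise_sd), 0, 5)`
computed from the *realized* overlap.

This means a green end-to-end test establishes that the implementation can
*recover a planted overlap signal* and that the representation hierarchy
(fusion ≥ concatenation ≥ single representations) holds when the signal is
learnable. It does **not** establish clinical validity: real gold scores
reflect meaning beyond lexical overlap (negation, paraphrase, abbreviation),
real vocabulary statistics are Zipfian, and the generator's sentences have
no grammar. Published correlations on the restricted benchmark are
therefore out of reach by design, and no test claims them.

## Numerical choices and degenerate inputs

* Cosine similarity is defined as 0 when either averaged vector is all-zero
  (possible under the `zero` OOV policy).
* Both n-gram sets empty (both sentences shorter than `n`) gives overlap 0.
* Score intervals are half-open with a closed top bin,
  `[0,1) … [3,4) [4,5]`, so every score has exactly one bin; per-bin
  Pearson is flagged undefined (`NA`) below two pairs or for constant
  inputs rather than propagating `NaN`.
* If stopword removal would empty a sentence, the lemmatized tokens are
  kept so length/IDF features stay defined.
* One-hot features are standardized by training-set mean/sd before the
  network (stored in the checkpoint); features with zero variance get unit
  scale.
* Training is deterministic given the master seed, which drives parameter
  initialization, batch shuffling and the generator. Early stopping
  returns the best-dev-Pearson checkpoint; with no dev set a fixed epoch
  budget is used.
* The Siamese property is exact, not approximate: each tower is evaluated
  as a one-sentence batch at encoding time, so the sentence-to-vector map
  is bitwise independent of which side the sentence is on.

## Design decisions that were genuinely open

* **Gate arity.** The gate is a vector (one coefficient per common-space
  component), not a scalar: the gate map takes the length-2d concatenation
  to length d, matching the elementwise products in the fusion equation.
* **Interval statistics.** Per-interval cells of the evaluation report are
  within-interval Pearson correlations (mirroring the overall column), with
  per-interval MSE reported alongside; upstream presentations leave the
  statistic ambiguous.
* **Train/dev split.** Stratified by score interval at 80/20 (the upstream
  ratio is unstated), sampling `round(fraction · stratum)` per stratum.
* **Pool-then-convolve ambiguity** resolved as convolution → nonlinearity →
  average pooling.
* **Output head.** No regression head is specified upstream; the bounded
  `5·sigmoid` head is the default because MSE against targets in `[0,5]`
  otherwise rewards out-of-range excursions early in training.

## Known limitations

Pure-R training: fine for the shipped model sizes (minutes on one CPU for
2000 pairs), not for large corpora or deep transformers. The rule
lemmatizer is heuristic outside its keep-lists. The transformer default is
trained from scratch per run; it stands in for, and does not approximate,
large pre-trained clinical language models.

## A worked run

```{r, eval = FALSE}
corpus <- generate_corpus(synth_config(n_pairs = 2500, noise_sd = 0.2, seed = 7))
split <- stratified_split(corpus, dev_fraction = 0.2, seed = 7)
model <- sts_train(split$train, split$dev,
                   sts_config(mode = "gated", encoder = "cnn", seed = 1))
report <- interval_report(predict(model, split$dev), split$dev$gold)
print(report)
```

The same pipeline is scriptable through the CLI (`sts_cli()`), and
`scripts/acceptance.R` re-runs the four-way ablation from scratch at a
given seed.
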