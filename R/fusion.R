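# Gated fusion of a distributed pair representation D and a handcrafted
# feature vector O, plus the concatenation baseline and the bounded
# regression head:
#
#   D_norm = tanh(W_d D + b_d)
#   O_norm = tanh(W_o O + b_o)
#   f      = sigmoid(W_f [D_norm, O_norm] + b_f)
#   R      = f * D_norm + (1 - f) * O_norm        (elementwise)
#
# The gate f is a vector (one coefficient per component of the common
# space), so R is an elementwise convex combination of the two normalized
# representations.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize fusion parameters
#'
#' Weights use glorot-uniform initialization from the current RNG stream;
#' biases start at zero. Matrices are stored in the "math" layout
#' `W %*% x` (output rows, input columns).
#'
#' @param d Common-space dimension.
#' @param d_D Dimension of the distributed representation.
#' @param n_features Length of the one-hot feature vector.
#' @param head_dim Regression-head input size (`d` for gated/single modes,
#'   `2 * d` for concatenation).
#' @return An `sts_fusion_params` list with `W_d`, `b_d`, `W_o`, `b_o`,
#'   `W_f`, `b_f`, `head_w`, `head_b`.
#' @export
fusion_init <- function(d, d_D, n_features, head_dim = d) {
  structure(list(W_d = ginit(d, d_D), b_d = numeric(d),
                 W_o = ginit(d, n_features), b_o = numeric(d),
                 W_f = ginit(d, 2L * d), b_f = numeric(d),
                 head_w = as.numeric(ginit(head_dim, 1L)), head_b = 0),
            class = "sts_fusion_params")
}

as_repr_vector <- function(D) {
  if (inherits(D, "sts_pair_repr")) D$values else as.numeric(D)
}

#' Fuse distributed and one-hot representations with a sigmoid gate
#'
#' Projects both inputs into a common `d`-dimensional space with `tanh`
#' activations, computes the vector gate
#' `f = sigmoid(W_f [D_norm, O_norm] + b_f)`, and blends
#' `R = f * D_norm + (1 - f) * O_norm` elementwise. Every gate component
#' lies in (0, 1), so each component of `R` lies between the corresponding
#' components of `D_norm` and `O_norm`.
#'
#' @param D Distributed representation (`sts_pair_repr` or numeric vector).
#' @param O One-hot feature vector (numeric).
#' @param params An [fusion_init()] parameter set.
#' @return An `sts_fused` list: `d_norm`, `o_norm`, `gate`, `r`.
#' @export
fuse <- function(D, O, params) {
  Dv <- as_repr_vector(D); Ov <- as.numeric(O)
  d_norm <- tanh(as.numeric(params$W_d %*% Dv) + params$b_d)
  o_norm <- tanh(as.numeric(params$W_o %*% Ov) + params$b_o)
  gate <- sigmoid(as.numeric(params$W_f %*% c(d_norm, o_norm)) + params$b_f)
  r <- gate * d_norm + (1 - gate) * o_norm
  if (any(!is.finite(r)))
    stop("non-finite fused representation; parameter summary: ",
         paste(names(params), vapply(params, function(p) format(max(abs(p))),
                                     character(1)), sep = "=", collapse = " "),
         call. = FALSE)
  structure(list(d_norm = d_norm, o_norm = o_norm, gate = gate, r = r),
            class = "sts_fused")
}

#' Concatenate the normalized representations (baseline)
#'
#' Returns `[D_norm, O_norm]` (length `2d`), using the same projections as
#' [fuse()]; this is the representation of the concatenation baseline.
#'
#' @inheritParams fuse
#' @return Numeric vector of length `2d`.
#' @export
concat_repr <- function(D, O, params) {
  Dv <- as_repr_vector(D); Ov <- as.numeric(O)
  c(tanh(as.numeric(params$W_d %*% Dv) + params$b_d),
    tanh(as.numeric(params$W_o %*% Ov) + params$b_o))
}

#' Map a fused (or concatenated) representation to a similarity score
#'
#' `score = 5 * sigmoid(head_w . r + head_b)`, strictly inside (0, 5) for
#' finite inputs.
#'
#' @param r Numeric vector (or `sts_fused`, whose `r` field is used).
#' @param params Parameter set with `head_w`, `head_b`.
#' @return A real score in (0, 5).
#' @export
predict_score <- function(r, params) {
  rv <- if (inherits(r, "sts_fused")) r$r else as.numeric(r)
  5 * sigmoid(sum(params$head_w * rv) + params$head_b)
}
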