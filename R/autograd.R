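# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records operations in creation order; ag_backward() replays it in
# reverse, accumulating gradients. Operands may be tape nodes or plain
# matrices (treated as constants, no gradient). All values are base-R
# matrices; this is deliberately dependency-free and sized for the small
# models this package trains. Gradients are verified against central finite
# differences in the test suite.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$ops <- list()
  tp
}

is_node <- function(x) inherits(x, "agnode")

nval <- function(x) if (is_node(x)) x$val else x
nid <- function(x) if (is_node(x)) x$id else NA_integer_

# record a node; parents is a list of operands (nodes or constants),
# backward(g) returns a list of gradients aligned with parents (NULL for
# constant slots)
ag_record <- function(tp, val, parents, backward) {
  # force all promises BEFORE taking an id: nested op calls must finish
  # recording first or creation order stops being topological
  force(val); force(parents); force(backward)
  tp$n <- tp$n + 1L
  id <- tp$n
  tp$ops[[id]] <- list(parents = vapply(parents, nid, integer(1)),
                       backward = backward)
  structure(list(id = id, val = val), class = "agnode")
}

#' @noRd
ag_leaf <- function(tp, val) {
  ag_record(tp, as.matrix(val), list(), NULL)
}

ag_matmul <- function(tp, a, b) {
  A <- nval(a); B <- nval(b)
  ag_record(tp, A %*% B, list(a, b), function(g)
    list(if (is_node(a)) g %*% t(B), if (is_node(b)) t(A) %*% g))
}

# a + b; b may be a 1-row matrix broadcast over a's rows, or a scalar
ag_add <- function(tp, a, b) {
  A <- nval(a); B <- nval(b)
  bias <- is.matrix(B) && nrow(B) == 1L && is.matrix(A) && nrow(A) > 1L
  val <- if (bias) sweep(A, 2L, as.numeric(B), "+") else A + if (is.matrix(B)) B else B
  ag_record(tp, val, list(a, b), function(g)
    list(if (is_node(a)) g,
         if (is_node(b)) {
           if (bias) matrix(colSums(g), nrow = 1L)
           else if (is.matrix(B)) g else sum(g)
         }))
}

ag_sub <- function(tp, a, b) {
  ag_record(tp, nval(a) - nval(b), list(a, b), function(g)
    list(if (is_node(a)) g, if (is_node(b)) -g))
}

# elementwise product; one operand may be a 1-row matrix (column broadcast)
ag_mul <- function(tp, a, b) {
  A <- nval(a); B <- nval(b)
  brow_b <- is.matrix(B) && nrow(B) == 1L && is.matrix(A) && nrow(A) > 1L
  val <- if (brow_b) sweep(A, 2L, as.numeric(B), "*") else A * B
  ag_record(tp, val, list(a, b), function(g)
    list(if (is_node(a)) { if (brow_b) sweep(g, 2L, as.numeric(B), "*") else g * B },
         if (is_node(b)) { if (brow_b) matrix(colSums(g * A), nrow = 1L) else g * A }))
}

ag_scale <- function(tp, a, k) {
  ag_record(tp, nval(a) * k, list(a), function(g) list(g * k))
}

ag_tanh <- function(tp, a) {
  val <- tanh(nval(a))
  ag_record(tp, val, list(a), function(g) list(g * (1 - val^2)))
}

ag_sigmoid <- function(tp, a) {
  val <- 1 / (1 + exp(-nval(a)))
  ag_record(tp, val, list(a), function(g) list(g * val * (1 - val)))
}

ag_relu <- function(tp, a) {
  A <- nval(a)
  val <- pmax(A, 0)
  ag_record(tp, val, list(a), function(g) list(g * (A > 0)))
}

ag_cbind <- function(tp, nodes) {
  vals <- lapply(nodes, nval)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_record(tp, do.call(cbind, vals), nodes, function(g)
    lapply(seq_along(nodes), function(k)
      if (is_node(nodes[[k]])) g[, starts[k]:ends[k], drop = FALSE]))
}

ag_rbind <- function(tp, nodes) {
  vals <- lapply(nodes, nval)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ag_record(tp, do.call(rbind, vals), nodes, function(g)
    lapply(seq_along(nodes), function(k)
      if (is_node(nodes[[k]])) g[starts[k]:ends[k], , drop = FALSE]))
}

ag_cols <- function(tp, a, idx) {
  A <- nval(a)
  ag_record(tp, A[, idx, drop = FALSE], list(a), function(g) {
    gp <- matrix(0, nrow(A), ncol(A))
    gp[, idx] <- gp[, idx] + g
    list(gp)
  })
}

# gather rows (with repetition); backward scatter-adds
ag_rows <- function(tp, a, idx) {
  A <- nval(a)
  ag_record(tp, A[idx, , drop = FALSE], list(a), function(g) {
    gp <- matrix(0, nrow(A), ncol(A))
    rs <- rowsum(g, group = idx)
    gp[as.integer(rownames(rs)), ] <- rs
    list(gp)
  })
}

# mean over row groups: output row k = mean of a's rows with group == k.
# Summation order within a group is fixed by row order, so identical groups
# produce bitwise-identical results wherever they sit in the batch.
ag_group_mean <- function(tp, a, group, n_groups) {
  A <- nval(a)
  counts <- tabulate(group, nbins = n_groups)
  val <- rowsum(A, group = group, reorder = TRUE) / counts
  ag_record(tp, val, list(a), function(g)
    list((g / counts)[group, , drop = FALSE]))
}

ag_transpose <- function(tp, a) {
  ag_record(tp, t(nval(a)), list(a), function(g) list(t(g)))
}

# row-wise softmax; `shift` is an optional constant matrix added to the
# logits first (e.g. -1e9 at masked attention positions)
ag_softmax_rows <- function(tp, a, shift = NULL) {
  A <- nval(a)
  if (!is.null(shift)) A <- A + shift
  A <- A - apply(A, 1L, max)
  e <- exp(A)
  val <- e / rowSums(e)
  ag_record(tp, val, list(a), function(g)
    list(val * (g - rowSums(g * val))))
}

# row-wise layer normalization (population variance), no affine part
ag_layernorm <- function(tp, a, eps = 1e-5) {
  A <- nval(a)
  k <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  sig <- sqrt(rowMeans(xc^2) + eps)
  y <- xc / sig
  ag_record(tp, y, list(a), function(g) {
    gm <- rowMeans(g)
    gy <- rowMeans(g * y)
    list((g - gm - y * gy) / sig)
  })
}

# scalar node: mean squared error against a constant target matrix
ag_mse <- function(tp, pred, target) {
  P <- nval(pred)
  n <- length(P)
  val <- matrix(mean((P - target)^2), 1L, 1L)
  ag_record(tp, val, list(pred), function(g)
    list(as.numeric(g) * 2 * (P - target) / n))
}

# backpropagate from scalar node `root`; returns list of gradients indexed
# by node id (NULL where no gradient flowed)
ag_backward <- function(tp, root) {
  grads <- vector("list", tp$n)
  grads[[root$id]] <- matrix(1, nrow(root$val), ncol(root$val))
  for (i in seq(root$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    op <- tp$ops[[i]]
    if (is.null(op$backward)) next
    pg <- op$backward(g)
    for (k in seq_along(op$parents)) {
      pid <- op$parents[k]
      if (is.na(pid) || is.null(pg[[k]])) next
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[k]] else grads[[pid]] + pg[[k]]
    }
  }
  grads
}

# --- Adam optimizer -------------------------------------------------------

adam_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
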