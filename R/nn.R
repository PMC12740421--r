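# Minimal dense-network machinery: He-initialized layers, ReLU MLPs with
# hand-written backprop, and an Adam optimizer over nested parameter lists.
# Everything operates on plain numeric matrices (rows = batch) and draws
# initial weights from the caller's RNG stream, so whole training runs are
# reproducible from a single set.seed().

nn_dense_init <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

relu <- function(x) pmax(x, 0)

# layers: list of list(W, b); hidden activations ReLU, output linear.
mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L),
         function(i) nn_dense_init(sizes[i], sizes[i + 1L]))
}

mlp_forward <- function(X, layers) {
  L <- length(layers)
  cache <- vector("list", L)
  A <- X
  for (i in seq_len(L)) {
    Z <- sweep(A %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    if (i < L) {
      H <- relu(Z)
      cache[[i]] <- list(A = A, mask = Z > 0)
      A <- H
    } else {
      cache[[i]] <- list(A = A)
      A <- Z
    }
  }
  list(out = A, cache = cache)
}

# dOut: gradient at the (linear) output. Returns per-layer grads and dX.
mlp_backward <- function(dOut, layers, cache) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dOut
  for (i in rev(seq_len(L))) {
    A <- cache[[i]]$A
    grads[[i]] <- list(W = crossprod(A, delta), b = colSums(delta))
    dA <- tcrossprod(delta, layers[[i]]$W)  # delta %*% t(W)
    if (i > 1L) dA <- dA * cache[[i - 1L]]$mask
    delta <- dA
  }
  list(grads = grads, dX = delta)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Row-wise L2 normalization with its backward pass. eps >= 0 makes a
# zero-norm row an error (user-facing contract); eps < 0 clamps the norm
# instead (training-internal use, where a dead row must not abort a run).
l2_normalize_rows <- function(Z, eps = 0) {
  r <- sqrt(rowSums(Z^2))
  if (eps >= 0) {
    if (any(r <= eps)) stop("cannot L2-normalize a zero-norm row", call. = FALSE)
  } else {
    r <- pmax(r, 1e-12)
  }
  list(E = Z / r, r = r)
}

l2_normalize_backward <- function(dE, E, r) {
  (dE - E * rowSums(dE * E)) / r
}

# ---- Adam over nested lists of numeric arrays ---------------------------

map_params <- function(f, ...) {
  dots <- list(...)
  x <- dots[[1L]]
  if (is.list(x)) {
    out <- lapply(seq_along(x), function(i) {
      do.call(map_params, c(list(f), lapply(dots, `[[`, i)))
    })
    names(out) <- names(x)
    out
  } else {
    do.call(f, dots)
  }
}

zeros_like <- function(params) map_params(function(p) p * 0, params)

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

sum_params <- function(a, b) map_params(`+`, a, b)
scale_params <- function(a, s) map_params(function(p) p * s, a)
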