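# Dynamic gating fusion: a small MLP on the patient's encoded clinical
# vector emits three logits that are softmax-normalized into per-patient
# weights over the CT-image, lung-function and environment embeddings; the
# fused representation is their convex combination.

#' Initialize gating-network parameters
#'
#' A two-layer perceptron `u = W2 ReLU(W1 x + b1) + b2` mapping the encoded
#' clinical vector to 3 modality logits.
#'
#' @param input_dim Length of the encoded clinical vector.
#' @param hidden Hidden node count `h` (default 128).
#' @return Parameter list with class `gating_params`.
#' @export
gating_params <- function(input_dim, hidden = 128L) {
  if (hidden < 1L) stop("`hidden` must be >= 1", call. = FALSE)
  p <- mlp_init(c(input_dim, as.integer(hidden), 3L))
  class(p) <- "gating_params"
  p
}

#' Per-patient modality weights
#'
#' Softmax of the gating MLP's logits: for each patient a positive 3-vector
#' over (CT, lung function, environment) summing to 1.
#'
#' @param clinical Encoded clinical matrix (rows = patients) or vector.
#' @param params A [gating_params()] object (or any 2-layer MLP parameter
#'   list with 3 output units).
#' @return Matrix with columns `ct`, `lung_function`, `environment`, rows on
#'   the 3-simplex.
#' @examples
#' gp <- gating_params(4, hidden = 8)
#' w <- gating_weights(matrix(rnorm(8), 2), gp)
#' rowSums(w)  # 1 1
#' @export
gating_weights <- function(clinical, params) {
  if (is.vector(clinical)) clinical <- matrix(clinical, nrow = 1L)
  if (ncol(clinical) != nrow(params[[1L]]$W))
    stop("clinical vector length ", ncol(clinical),
         " does not match gate input dimension ", nrow(params[[1L]]$W),
         call. = FALSE)
  W <- softmax_rows(mlp_forward(clinical, params)$out)
  colnames(W) <- c("ct", "lung_function", "environment")
  W
}

#' Weighted fusion of aligned modality embeddings
#'
#' `f = w_ct * f_ct + w_lf * f_lf + w_env * f_env`, a per-patient convex
#' combination of the three aligned d-dimensional features.
#'
#' @param f_ct,f_lf,f_env Equal-dimension embedding matrices (rows =
#'   patients).
#' @param w Weight matrix from [gating_weights()] (or any rows on the
#'   3-simplex).
#' @return Fused embedding matrix.
#' @export
fuse_features <- function(f_ct, f_lf, f_env, w) {
  if (is.vector(f_ct)) {
    f_ct <- matrix(f_ct, 1L); f_lf <- matrix(f_lf, 1L); f_env <- matrix(f_env, 1L)
  }
  if (is.vector(w)) w <- matrix(w, 1L)
  if (!all(dim(f_ct) == dim(f_lf)) || !all(dim(f_ct) == dim(f_env)))
    stop("modality embeddings must have identical dimensions", call. = FALSE)
  if (nrow(w) != nrow(f_ct) || ncol(w) != 3L)
    stop("`w` must be an n x 3 weight matrix", call. = FALSE)
  w[, 1L] * f_ct + w[, 2L] * f_lf + w[, 3L] * f_env
}

#' Classification head
#'
#' Linear head over the fused embedding: in binary mode a sigmoid risk
#' probability; in stage mode a softmax simplex over the given classes.
#'
#' @param fused Fused embedding matrix.
#' @param head List with `W` (d x k) and `b` (k); `k = 1` gives binary mode.
#' @return For `k = 1`, a vector of probabilities in `[0, 1]`; otherwise a
#'   matrix of class probabilities with rows summing to 1.
#' @export
classify <- function(fused, head) {
  if (is.vector(fused)) fused <- matrix(fused, 1L)
  logits <- sweep(fused %*% head$W, 2, head$b, "+")
  if (ncol(logits) == 1L) {
    as.vector(1 / (1 + exp(-logits)))
  } else {
    softmax_rows(logits)
  }
}

#' Joint objective breakdown
#'
#' `L_total = L_cls + lambda1 * L_contrast + lambda2 * L_WGAN`, retaining the
#' components for logging. Default weights: `lambda1 = 0.5`,
#' `lambda2 = 0.2`.
#'
#' @param l_cls,l_contrast,l_wgan Finite scalar loss components
#'   (classification cross-entropy, contrastive, adversarial).
#' @param lambda1,lambda2 Component weights.
#' @return A one-row tibble with columns `l_cls`, `l_contrast`, `l_wgan`,
#'   `lambda1`, `lambda2`, `l_total`.
#' @examples
#' total_loss(1, 2, 5)$l_total  # 1 + 0.5*2 + 0.2*5 = 3
#' @export
total_loss <- function(l_cls, l_contrast, l_wgan, lambda1 = 0.5, lambda2 = 0.2) {
  for (nm in c("l_cls", "l_contrast", "l_wgan")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a finite scalar", call. = FALSE)
  }
  tibble::tibble(l_cls = l_cls, l_contrast = l_contrast, l_wgan = l_wgan,
                 lambda1 = lambda1, lambda2 = lambda2,
                 l_total = l_cls + lambda1 * l_contrast + lambda2 * l_wgan)
}
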