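# Dual-tower cross-modal alignment: a convolutional image tower and an MLP
# tabular tower are projected into one shared d-dimensional space, rows are
# L2-normalized, and matched image/tabular pairs are pulled together by a
# temperature-scaled symmetric contrastive objective over the batch cosine
# similarity matrix.

# "same" 3x3 convolution via zero padding and shifted adds.
conv2d_same <- function(M, k) {
  h <- nrow(M); w <- ncol(M)
  P <- matrix(0, h + 2L, w + 2L)
  P[2:(h + 1L), 2:(w + 1L)] <- M
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    kv <- k[dy + 1L, dx + 1L]
    if (kv != 0) out <- out + kv * P[(1L + dy):(h + dy), (1L + dx):(w + dx)]
  }
  out
}

avg_pool2 <- function(M) {
  h <- 2L * (nrow(M) %/% 2L); w <- 2L * (ncol(M) %/% 2L)
  M <- M[seq_len(h), seq_len(w), drop = FALSE]
  0.25 * (M[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
          M[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
          M[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
          M[seq(2, h, 2), seq(2, w, 2), drop = FALSE])
}

#' Build a convolutional image tower
#'
#' Constructs the fixed (seeded) convolutional feature extractor used as the
#' image branch. Each block applies 3x3 convolutions, ReLU, and 2x2 average
#' pooling; the final feature vector concatenates per-channel global mean and
#' max. Filters are He-initialized from `seed` and then frozen — the
#' trainable part of the image branch is the dense head and shared-space
#' projection learned during training (see [train_mmdf()]'s `fine_tune`
#' policy).
#'
#' @param preset `"tiny"` (3 blocks, 8/16/32 channels; the default, sized for
#'   CPU-scale runs) or `"deep"` (4 blocks, 16/32/64/128 channels, a
#'   ResNet-style deeper extractor).
#' @param seed Integer seed for filter initialization; part of the model
#'   checkpoint so features are reproducible.
#' @return An object of class `image_tower`.
#' @export
image_tower <- function(preset = c("tiny", "deep"), seed = 42L) {
  preset <- match.arg(preset)
  channels <- switch(preset, tiny = c(8L, 16L, 32L), deep = c(16L, 32L, 64L, 128L))
  set.seed(as.integer(seed))
  in_ch <- 1L
  blocks <- list()
  for (b in seq_along(channels)) {
    out_ch <- channels[b]
    fan_in <- 9L * in_ch
    filt <- array(stats::rnorm(3 * 3 * in_ch * out_ch, 0, sqrt(2 / fan_in)),
                  dim = c(3L, 3L, in_ch, out_ch))
    blocks[[b]] <- list(filters = filt, bias = rep(0, out_ch))
    in_ch <- out_ch
  }
  tower <- list(preset = preset, seed = as.integer(seed), blocks = blocks,
                n_features = 2L * channels[length(channels)])
  class(tower) <- "image_tower"
  tower
}

tower_forward_one <- function(img, tower) {
  maps <- list(img)
  for (blk in tower$blocks) {
    out_ch <- dim(blk$filters)[4]
    in_ch <- dim(blk$filters)[3]
    nxt <- vector("list", out_ch)
    for (o in seq_len(out_ch)) {
      acc <- matrix(blk$bias[o], nrow(maps[[1]]), ncol(maps[[1]]))
      for (i in seq_len(in_ch)) {
        acc <- acc + conv2d_same(maps[[i]], blk$filters[, , i, o])
      }
      nxt[[o]] <- avg_pool2(relu(acc))
    }
    maps <- nxt
  }
  c(vapply(maps, mean, numeric(1)), vapply(maps, max, numeric(1)))
}

#' Extract image features for a batch
#'
#' Runs each raster through the frozen convolutional tower after the standard
#' preprocessing chain (histogram equalization then training-moment
#' standardization, if `mu`/`sigma` are supplied).
#'
#' @param images List of numeric matrices in `[0, 1]`.
#' @param tower An [image_tower()].
#' @param mu,sigma Optional scalar training-set pixel moments for
#'   [standardize_image()]; if `NULL`, rasters are used as equalized.
#' @param equalize_levels Gray-level count for [histogram_equalize()].
#' @return Numeric matrix, one row of tower features per image.
#' @export
extract_image_features <- function(images, tower, mu = NULL, sigma = NULL,
                                   equalize_levels = 256L) {
  feats <- t(vapply(images, function(img) {
    img <- histogram_equalize(img, levels = equalize_levels)
    if (!is.null(mu)) img <- standardize_image(img, mu, sigma)
    tower_forward_one(img, tower)
  }, numeric(tower$n_features)))
  feats
}

#' Project features into the shared space and L2-normalize
#'
#' Multiplies a feature matrix by a projection matrix and normalizes each row
#' to unit Euclidean length, the form required for cosine-similarity
#' contrastive alignment. A zero-norm projected row is an error.
#'
#' @param features Numeric matrix, rows = batch.
#' @param projection Projection matrix (feature width x shared dimension).
#' @return Matrix of unit-norm row embeddings.
#' @examples
#' project_normalize(matrix(c(3, 4), 1), diag(2))  # -> (0.6, 0.8)
#' @export
project_normalize <- function(features, projection) {
  if (ncol(features) != nrow(projection))
    stop("feature width ", ncol(features), " does not match projection rows ",
         nrow(projection), call. = FALSE)
  l2_normalize_rows(features %*% projection)$E
}

#' Batch cosine similarity matrix
#'
#' For matched batches of unit-norm image and tabular embeddings, returns the
#' N x N matrix `S[i, j] = cos(image_i, tabular_j)`; matched patient pairs sit
#' on the diagonal.
#'
#' @param image_emb,tab_emb Equal-size matrices of unit-norm rows.
#' @return N x N numeric matrix with entries in `[-1, 1]`.
#' @export
similarity_matrix <- function(image_emb, tab_emb) {
  if (!all(dim(image_emb) == dim(tab_emb)))
    stop("embedding batches must have identical dimensions", call. = FALSE)
  tcrossprod(image_emb, tab_emb)
}

#' Symmetric temperature-scaled contrastive loss
#'
#' The InfoNCE objective over a batch similarity matrix: the image-direction
#' term is the mean cross-entropy of each row's softmax (at temperature
#' `temperature`) against its diagonal positive, the tabular-direction term
#' the same over columns, and the loss is their average. Lower temperature
#' sharpens the softmax, so with a dominant diagonal the loss decreases as
#' the temperature does.
#'
#' @param S Square similarity matrix (cosines of matched batches).
#' @param temperature Positive softmax temperature (default 0.05).
#' @return Non-negative scalar loss.
#' @examples
#' contrastive_loss(matrix(0.5, 4, 4))  # uniform similarities -> log(4)
#' @export
contrastive_loss <- function(S, temperature = 0.05) {
  check_contrastive_args(S, temperature)
  L <- S / temperature
  n <- nrow(S)
  lse_rows <- apply(L, 1, function(z) {
    m <- max(z); m + log(sum(exp(z - m)))
  })
  lse_cols <- apply(L, 2, function(z) {
    m <- max(z); m + log(sum(exp(z - m)))
  })
  loss_img <- mean(lse_rows - diag(L))
  loss_tab <- mean(lse_cols - diag(L))
  (loss_img + loss_tab) / 2
}

check_contrastive_args <- function(S, temperature) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("`S` must be a square similarity matrix", call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0)
    stop("`temperature` must be a single positive number", call. = FALSE)
  invisible(TRUE)
}

# Gradient of contrastive_loss with respect to S.
contrastive_grad <- function(S, temperature = 0.05) {
  check_contrastive_args(S, temperature)
  n <- nrow(S)
  L <- S / temperature
  Pr <- softmax_rows(L)
  Pc <- t(softmax_rows(t(L)))
  ((Pr - diag(n)) + (Pc - diag(n))) / (2 * n * temperature)
}
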