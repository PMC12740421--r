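# Conditional WGAN-GP for environmental exposure synthesis. The generator
# maps (clinical condition, Gaussian noise) to the environmental vector; the
# critic scores (condition, environment) pairs. Training alternates several
# critic updates per generator update and regularizes the critic with the
# gradient penalty, which drives the norm of the critic's gradient at points
# interpolated between real and generated samples toward 1.

#' Configure the conditional WGAN-GP
#'
#' @param env_dim Number of environmental variables generated (default 2:
#'   PM2.5 and exposure years, generated jointly).
#' @param cond_dim Length of the encoded clinical condition vector.
#' @param noise_dim Gaussian noise input length.
#' @param hidden_g Hidden widths of the generator MLP.
#' @param hidden_d Hidden width of the (single-hidden-layer) critic MLP.
#' @param phi_gp Gradient-penalty coefficient (> 0; default 10).
#' @param n_critic Critic updates per generator update (>= 1; default 5).
#' @param lr Adam learning rate; Adam runs with betas (0, 0.9), the standard
#'   WGAN-GP setting.
#' @return An object of class `cgan_spec`.
#' @export
cgan_spec <- function(env_dim = 2L, cond_dim = 9L, noise_dim = 8L,
                      hidden_g = c(64L, 64L), hidden_d = 64L,
                      phi_gp = 10, n_critic = 5L, lr = 1e-3) {
  if (phi_gp <= 0) stop("`phi_gp` must be > 0", call. = FALSE)
  if (n_critic < 1L) stop("`n_critic` must be >= 1", call. = FALSE)
  structure(list(env_dim = as.integer(env_dim), cond_dim = as.integer(cond_dim),
                 noise_dim = as.integer(noise_dim), hidden_g = hidden_g,
                 hidden_d = as.integer(hidden_d), phi_gp = phi_gp,
                 n_critic = as.integer(n_critic), lr = lr),
            class = "cgan_spec")
}

cgan_init <- function(spec) {
  list(
    spec = spec,
    G = mlp_init(c(spec$cond_dim + spec$noise_dim, spec$hidden_g, spec$env_dim)),
    D = mlp_init(c(spec$cond_dim + spec$env_dim, spec$hidden_d, 1L))
  )
}

#' Build a linear critic
#'
#' Constructs a critic whose score is exactly `D(c, x) = w . x + b`,
#' independent of the condition, realized inside the standard ReLU
#' architecture via paired mirrored hidden units (`relu(u) - relu(-u) = u`).
#' Useful for analytic checks: with `||w|| = 1` the gradient penalty is
#' exactly zero; with `w = 0` the critic is constant and the penalty is 1.
#'
#' @param w Weight vector over the environmental variables.
#' @param cond_dim Condition length (ignored by the score).
#' @param b Scalar bias.
#' @return A critic parameter list usable with [gradient_penalty()] and
#'   [critic_loss()].
#' @export
linear_critic <- function(w, cond_dim = 0L, b = 0) {
  env_dim <- length(w)
  in_dim <- cond_dim + env_dim
  W1 <- matrix(0, in_dim, 2L)
  if (env_dim > 0) {
    W1[cond_dim + seq_len(env_dim), 1L] <- w
    W1[cond_dim + seq_len(env_dim), 2L] <- -w
  }
  list(list(W = W1, b = c(1e-9, 1e-9)),            # tiny bias keeps units active at 0
       list(W = matrix(c(1, -1), 2L, 1L), b = b))
}

critic_score <- function(D, condition, x) {
  mlp_forward(cbind(condition, x), D)$out[, 1L]
}

# Gradient of the critic score with respect to its environmental input,
# per sample. Single-hidden-layer ReLU critic: grad = W1x (m * w2).
critic_input_grad <- function(D, condition, x) {
  env_dim <- ncol(x)
  in_dim <- nrow(D[[1L]]$W)
  cond_dim <- in_dim - env_dim
  V <- cbind(condition, x)
  Z <- sweep(V %*% D[[1L]]$W, 2, D[[1L]]$b, "+")
  Mk <- (Z > 0) * 1
  W1x <- D[[1L]]$W[cond_dim + seq_len(env_dim), , drop = FALSE]
  w2 <- D[[2L]]$W[, 1L]
  # each row i: W1x %*% (m_i * w2)
  (Mk * matrix(w2, nrow(x), length(w2), byrow = TRUE)) %*% t(W1x)
}

#' WGAN gradient penalty
#'
#' Draws per-sample interpolates `xhat = eps * x_real + (1 - eps) * x_gen`
#' with `eps ~ U(0, 1)`, evaluates the norm of the critic's gradient with
#' respect to `xhat`, and returns `mean((||grad|| - 1)^2)` over the batch.
#'
#' @param critic Critic parameter list (e.g. from [linear_critic()] or a
#'   trained model's `$D`).
#' @param x_real,x_gen Real and generated environmental batches (matrices,
#'   equal dimensions).
#' @param condition Matching condition batch.
#' @param seed Seed for the interpolation draw.
#' @return Non-negative scalar penalty.
#' @examples
#' x <- matrix(rnorm(10), 5); cnd <- matrix(0, 5, 0)
#' gradient_penalty(linear_critic(c(0.6, 0.8)), x, x + 1, cnd)  # ~0
#' @export
gradient_penalty <- function(critic, x_real, x_gen, condition, seed = NULL) {
  if (nrow(x_real) == 0L) stop("empty batch", call. = FALSE)
  if (!all(dim(x_real) == dim(x_gen)))
    stop("real and generated batches must conform", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  eps <- stats::runif(nrow(x_real))
  xhat <- eps * x_real + (1 - eps) * x_gen
  g <- critic_input_grad(critic, condition, xhat)
  mean((sqrt(rowSums(g^2)) - 1)^2)
}

# Penalty plus its gradient with respect to the critic parameters
# (single-hidden-layer analytic form; mask derivative vanishes a.e.).
gradient_penalty_with_grads <- function(D, condition, xhat) {
  n <- nrow(xhat); env_dim <- ncol(xhat)
  in_dim <- nrow(D[[1L]]$W)
  cond_dim <- in_dim - env_dim
  V <- cbind(condition, xhat)
  Z <- sweep(V %*% D[[1L]]$W, 2, D[[1L]]$b, "+")
  Mk <- (Z > 0) * 1
  W1x <- D[[1L]]$W[cond_dim + seq_len(env_dim), , drop = FALSE]
  w2 <- D[[2L]]$W[, 1L]
  G <- (Mk * matrix(w2, n, length(w2), byrow = TRUE)) %*% t(W1x)  # n x env_dim
  r <- sqrt(rowSums(G^2))
  pen <- mean((r - 1)^2)
  s <- ifelse(r > 1e-12, 2 * (r - 1) / r, 0) / n
  dW2 <- colSums(Mk * (G %*% W1x) * s)                 # n x H -> H
  dW1x <- t(G * s) %*% (Mk * matrix(w2, n, length(w2), byrow = TRUE))
  dW1 <- matrix(0, in_dim, ncol(D[[1L]]$W))
  dW1[cond_dim + seq_len(env_dim), ] <- dW1x
  grads <- list(list(W = dW1, b = rep(0, ncol(dW1))),
                list(W = matrix(dW2, ncol = 1L), b = 0))
  list(penalty = pen, grads = grads)
}

#' Critic and generator objectives
#'
#' `critic_loss()` is the minimization-form critic objective
#' `mean(D(x_gen)) - mean(D(x_real)) + phi_gp * GP`; `generator_loss()` is
#' `-mean(D(x_gen))`. Both require finite inputs.
#'
#' @inheritParams gradient_penalty
#' @param phi_gp Gradient-penalty coefficient.
#' @return Scalar loss.
#' @export
critic_loss <- function(critic, x_real, x_gen, condition, phi_gp = 10,
                        seed = NULL) {
  if (any(!is.finite(x_real)) || any(!is.finite(x_gen)))
    stop("non-finite values in critic inputs", call. = FALSE)
  gap <- mean(critic_score(critic, condition, x_gen)) -
    mean(critic_score(critic, condition, x_real))
  gp <- if (phi_gp > 0) {
    gradient_penalty(critic, x_real, x_gen, condition, seed = seed)
  } else 0
  gap + phi_gp * gp
}

#' @rdname critic_loss
#' @export
generator_loss <- function(critic, x_gen, condition) {
  if (any(!is.finite(x_gen)))
    stop("non-finite values in generated batch", call. = FALSE)
  -mean(critic_score(critic, condition, x_gen))
}

# Core alternating-optimization loop on an already-encoded, already-scaled
# (x, condition) matrix pair. Returns trained parameters and a loss trace.
train_wgan_gp <- function(x, condition, spec, iters = 300L, batch = 64L,
                          seed = 1L, trace_every = 10L, ema_decay = 0.995) {
  n <- nrow(x)
  if (n < 1L) stop("no observed environmental data to train on", call. = FALSE)
  if (n == 1L) warning("training a conditional GAN on a single record", call. = FALSE)
  set.seed(as.integer(seed))
  gan <- cgan_init(spec)
  stG <- adam_init(gan$G); stD <- adam_init(gan$D)
  G_ema <- gan$G  # slow exponential average of generator weights; damps the
                  # adversarial oscillation of the raw iterates
  batch <- min(batch, n)
  trace <- list()

  sample_noise <- function(m) matrix(stats::rnorm(m * spec$noise_dim), m)
  gen_forward <- function(cnd, z) mlp_forward(cbind(cnd, z), gan$G)

  for (it in seq_len(iters)) {
    for (k in seq_len(spec$n_critic)) {
      idx <- sample.int(n, batch, replace = batch > n)
      xr <- x[idx, , drop = FALSE]
      cnd <- condition[idx, , drop = FALSE]
      xg <- gen_forward(cnd, sample_noise(batch))$out
      # Wasserstein gap gradient
      fw_g <- mlp_forward(cbind(cnd, xg), gan$D)
      fw_r <- mlp_forward(cbind(cnd, xr), gan$D)
      gr_g <- mlp_backward(matrix(1 / batch, batch, 1L), gan$D, fw_g$cache)$grads
      gr_r <- mlp_backward(matrix(-1 / batch, batch, 1L), gan$D, fw_r$cache)$grads
      eps <- stats::runif(batch)
      xhat <- eps * xr + (1 - eps) * xg
      gp <- gradient_penalty_with_grads(gan$D, cnd, xhat)
      gD <- sum_params(sum_params(gr_g, gr_r), scale_params(gp$grads, spec$phi_gp))
      up <- adam_step(gan$D, gD, stD, lr = spec$lr, beta1 = 0, beta2 = 0.9)
      gan$D <- up$params; stD <- up$state
    }
    idx <- sample.int(n, batch, replace = batch > n)
    cnd <- condition[idx, , drop = FALSE]
    fwG <- gen_forward(cnd, sample_noise(batch))
    dX <- -critic_input_grad(gan$D, cnd, fwG$out) / batch
    gG <- mlp_backward(dX, gan$G, fwG$cache)$grads
    up <- adam_step(gan$G, gG, stG, lr = spec$lr, beta1 = 0, beta2 = 0.9)
    gan$G <- up$params; stG <- up$state
    G_ema <- map_params(function(e, g) ema_decay * e + (1 - ema_decay) * g,
                        G_ema, gan$G)

    if (it %% trace_every == 0L || it == iters) {
      xg <- gen_forward(cnd, sample_noise(batch))$out
      xr <- x[idx, , drop = FALSE]
      trace[[length(trace) + 1L]] <- tibble::tibble(
        iter = it,
        critic_loss = critic_loss(gan$D, xr, xg, cnd, spec$phi_gp),
        generator_loss = generator_loss(gan$D, xg, cnd)
      )
    }
  }
  gan$trace <- dplyr::bind_rows(trace)
  gan$G_ema <- G_ema
  gan
}

#' Train the conditional WGAN-GP on a cohort's observed environment
#'
#' Encodes the clinical condition with a [tabular_schema()] fitted on the
#' observed records, standardizes the environmental variables (PM2.5,
#' exposure years) by their observed moments, and runs the alternating
#' WGAN-GP loop. Deterministic given `seed`.
#'
#' @param cohort A cohort tibble; records with `env_missing = TRUE` are
#'   excluded from training.
#' @param spec A [cgan_spec()]; its `cond_dim` is overridden by the encoded
#'   condition width.
#' @param iters Generator iterations (each preceded by `n_critic` critic
#'   updates).
#' @param batch Minibatch size.
#' @param seed Integer seed.
#' @param schema Optional pre-fitted [tabular_schema()] for the condition.
#' @return An object of class `cgan_model` holding generator/critic
#'   parameters, the condition schema, environmental scaling moments and a
#'   per-iteration loss trace.
#' @export
train_cgan <- function(cohort, spec = cgan_spec(), iters = 300L, batch = 64L,
                       seed = 1L, schema = NULL) {
  obs <- cohort[!cohort$env_missing & !is.na(cohort$pm25), , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no observed environmental data in cohort", call. = FALSE)
  if (is.null(schema)) schema <- tabular_schema(obs)
  cnd <- encode_tabular(obs, schema)
  x_raw <- cbind(pm25 = obs$pm25, exposure_years = obs$exposure_years)
  mu <- colMeans(x_raw)
  sdv <- apply(x_raw, 2, stats::sd)
  sdv[!is.finite(sdv)] <- 1  # single-record training set has no spread
  sdv <- pmax(sdv, 1e-8)
  x <- sweep(sweep(x_raw, 2, mu), 2, sdv, "/")
  spec$cond_dim <- ncol(cnd)
  spec$env_dim <- ncol(x)
  gan <- train_wgan_gp(x, cnd, spec, iters = iters, batch = batch, seed = seed)
  model <- list(spec = spec, G = gan$G, G_ema = gan$G_ema, D = gan$D,
                trace = gan$trace,
                schema = schema, env_mu = mu, env_sd = sdv,
                env_names = colnames(x_raw))
  class(model) <- "cgan_model"
  model
}

#' Draw environmental samples from a trained generator
#'
#' @param model A [train_cgan()] fit.
#' @param data Data frame of records supplying the clinical condition.
#' @param n_draws Draws per record.
#' @param seed Integer seed.
#' @return A list of matrices (one per draw), each `nrow(data)` x env-dim on
#'   the natural scale, clamped to `[0, Inf)`.
#' @export
cgan_generate <- function(model, data, n_draws = 1L, seed = 1L) {
  cnd <- encode_tabular(data, model$schema)
  set.seed(as.integer(seed))
  G <- if (!is.null(model$G_ema)) model$G_ema else model$G
  lapply(seq_len(n_draws), function(k) {
    z <- matrix(stats::rnorm(nrow(cnd) * model$spec$noise_dim), nrow(cnd))
    xs <- mlp_forward(cbind(cnd, z), G)$out
    x <- sweep(sweep(xs, 2, model$env_sd, "*"), 2, model$env_mu, "+")
    x <- pmax(x, 0)
    colnames(x) <- model$env_names
    x
  })
}

#' Impute masked environmental exposure
#'
#' Fills `pm25` / `exposure_years` for records flagged `env_missing` with
#' generator draws conditioned on each record's clinical vector; values are
#' clamped to the physical range `[0, Inf)`. Observed records are never
#' modified. With `n_draws > 1` all draws are retained (multiple imputation)
#' in the `imputation_draws` attribute, a tibble of one row per
#' (record, draw); the filled columns carry the across-draw mean.
#'
#' @param cohort A cohort tibble.
#' @param model A trained [train_cgan()] model.
#' @param n_draws Number of imputation draws per masked record.
#' @param seed Integer seed.
#' @return The cohort with masked environmental cells filled.
#' @export
impute_environment <- function(cohort, model, n_draws = 1L, seed = 1L) {
  stopifnot(inherits(model, "cgan_model"))
  masked <- which(cohort$env_missing | is.na(cohort$pm25))
  if (length(masked) == 0L) return(cohort)
  need <- c(names(model$schema$continuous), names(model$schema$categorical))
  if (!all(need %in% names(cohort)))
    stop("cohort does not match the checkpoint's condition schema", call. = FALSE)
  draws <- cgan_generate(model, cohort[masked, , drop = FALSE],
                         n_draws = n_draws, seed = seed)
  avg <- Reduce(`+`, draws) / length(draws)
  cohort$pm25[masked] <- avg[, "pm25"]
  cohort$exposure_years[masked] <- avg[, "exposure_years"]
  if (n_draws > 1L) {
    attr(cohort, "imputation_draws") <- dplyr::bind_rows(lapply(
      seq_along(draws), function(k) {
        tibble::tibble(id = cohort$id[masked], draw = k,
                       pm25 = draws[[k]][, "pm25"],
                       exposure_years = draws[[k]][, "exposure_years"])
      }))
  }
  cohort
}

#' Energy distance between two samples
#'
#' The (squared) energy distance
#' `2 E||X - Y|| - E||X - X'|| - E||Y - Y'||`, a nonparametric discrepancy
#' used to track how closely generated environmental samples match held-out
#' real ones.
#'
#' @param x,y Numeric matrices with the same number of columns.
#' @return Non-negative scalar.
#' @export
energy_distance <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  dxy <- pairwise_mean_dist(x, y)
  dxx <- pairwise_mean_dist(x, x)
  dyy <- pairwise_mean_dist(y, y)
  2 * dxy - dxx - dyy
}

pairwise_mean_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  mean(sqrt(pmax(d2, 0)))
}
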