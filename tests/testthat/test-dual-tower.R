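test_that("projection + normalization yields unit rows preserving direction", {
  expect_equal(project_normalize(matrix(c(3, 4), 1), diag(2)),
               matrix(c(0.6, 0.8), 1))
  u <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(project_normalize(u, diag(2)), u)
  set.seed(1)
  X <- matrix(stats::rnorm(4 * 6), 4, 6)
  P <- matrix(stats::rnorm(6 * 3), 6, 3)
  E <- project_normalize(X, P)
  expect_equal(unname(sqrt(rowSums(E^2))), rep(1, 4), tolerance = 1e-6)
  # direction matches the unprojected product
  Z <- X %*% P
  expect_equal(E * sqrt(rowSums(Z^2)), Z, tolerance = 1e-9)
  expect_error(project_normalize(matrix(0, 1, 2), diag(2)), "zero-norm")
  expect_error(project_normalize(matrix(1, 1, 3), diag(2)), "projection")
})

test_that("similarity matrix holds pairwise cosines with matches on the diagonal", {
  e1 <- c(1, 0); e2 <- c(0, 1)
  A <- rbind(e1, e2)
  expect_equal(unname(diag(similarity_matrix(A, A))), c(1, 1))
  expect_equal(similarity_matrix(matrix(e1, 1), matrix(e2, 1))[1, 1], 0)
  # hand-computed 2x2 case
  B <- rbind((e1 + e2) / sqrt(2), e2)
  S <- similarity_matrix(A, B)
  expect_equal(unname(S), rbind(c(1 / sqrt(2), 0), c(1 / sqrt(2), 1)),
               tolerance = 1e-12)
  expect_error(similarity_matrix(A, matrix(e1, 1)), "identical dimensions")
})

test_that("contrastive loss matches closed forms", {
  # all-equal similarities: both softmaxes uniform -> log N
  expect_equal(contrastive_loss(matrix(0.3, 4, 4), 0.05), log(4))
  expect_equal(contrastive_loss(matrix(-0.7, 6, 6), 1), log(6))
  # identity similarity at T = 0.05: diagonal logit exceeds others by 20,
  # so the loss is log(1 + (n-1) e^-20), numerically ~6.2e-9
  n <- 4
  want <- log1p((n - 1) * exp(-20))
  # the loss path computes log(1 + x) at x ~ 6e-9 without log1p, so agreement
  # is to absolute ~1e-15, i.e. relative ~1e-7
  expect_equal(contrastive_loss(diag(n), 0.05), want, tolerance = 1e-5)
  # single pair: no negatives, loss 0
  expect_equal(contrastive_loss(matrix(1, 1, 1), 0.05), 0)
  expect_error(contrastive_loss(matrix(1, 2, 3)), "square")
  expect_error(contrastive_loss(diag(2), temperature = 0), "temperature")
})

test_that("contrastive loss is permutation-invariant and temperature-monotone", {
  set.seed(11)
  S <- diag(5) * 0.8 + matrix(stats::runif(25, -0.1, 0.1), 5)
  perm <- sample(5)
  expect_equal(contrastive_loss(S[perm, perm], 0.05),
               contrastive_loss(S, 0.05), tolerance = 1e-12)
  # with a dominant diagonal, loss is non-increasing as T decreases
  temps <- c(1, 0.5, 0.2, 0.1, 0.05)
  losses <- vapply(temps, function(tt) contrastive_loss(S, tt), numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("analytic contrastive gradient matches finite differences", {
  set.seed(2)
  S <- matrix(stats::runif(25, -1, 1), 5, 5)
  g <- lungfuse:::contrastive_grad(S, 0.1)
  eps <- 1e-6
  for (k in sample(25, 8)) {
    Sp <- S; Sp[k] <- Sp[k] + eps
    Sm <- S; Sm[k] <- Sm[k] - eps
    num <- (contrastive_loss(Sp, 0.1) - contrastive_loss(Sm, 0.1)) / (2 * eps)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("image tower output contract holds for both presets", {
  set.seed(5)
  imgs <- lapply(1:3, function(i) matrix(stats::runif(32 * 32), 32, 32))
  for (preset in c("tiny", "deep")) {
    tw <- image_tower(preset, seed = 9L)
    F1 <- extract_image_features(imgs, tw, equalize_levels = 32)
    expect_equal(dim(F1), c(3L, tw$n_features))
    expect_true(all(is.finite(F1)))
    # deterministic given the tower seed
    tw2 <- image_tower(preset, seed = 9L)
    expect_identical(extract_image_features(imgs, tw2, equalize_levels = 32),
                     F1)
  }
})

test_that("contrastive training aligns matched pairs above the off-diagonal", {
  # frozen random features for two modalities of the same underlying signal;
  # only the projections learn
  set.seed(21)
  n <- 16; p <- 10; d <- 6
  latent <- matrix(stats::rnorm(n * 4), n, 4)
  Xi <- cbind(latent, matrix(stats::rnorm(n * (p - 4)), n)) %*%
    matrix(stats::rnorm(p * p), p)
  Xt <- cbind(latent, matrix(stats::rnorm(n * (p - 4)), n)) %*%
    matrix(stats::rnorm(p * p), p)
  Wi <- matrix(stats::rnorm(p * d, 0, 0.3), p, d)
  Wt <- matrix(stats::rnorm(p * d, 0, 0.3), p, d)
  sim_stats <- function(Wi, Wt) {
    S <- similarity_matrix(project_normalize(Xi, Wi),
                           project_normalize(Xt, Wt))
    c(diag = mean(diag(S)), off = mean(S[row(S) != col(S)]),
      loss = contrastive_loss(S, 0.1))
  }
  before <- sim_stats(Wi, Wt)
  params <- list(Wi = Wi, Wt = Wt)
  st <- lungfuse:::adam_init(params)
  losses <- numeric(60)
  for (it in 1:60) {
    ni <- lungfuse:::l2_normalize_rows(Xi %*% params$Wi)
    nt <- lungfuse:::l2_normalize_rows(Xt %*% params$Wt)
    S <- tcrossprod(ni$E, nt$E)
    losses[it] <- contrastive_loss(S, 0.1)
    dS <- lungfuse:::contrastive_grad(S, 0.1)
    dEi <- dS %*% nt$E
    dEt <- crossprod(dS, ni$E)
    g <- list(
      Wi = crossprod(Xi, lungfuse:::l2_normalize_backward(dEi, ni$E, ni$r)),
      Wt = crossprod(Xt, lungfuse:::l2_normalize_backward(dEt, nt$E, nt$r)))
    up <- lungfuse:::adam_step(params, g, st, lr = 0.01)
    params <- up$params; st <- up$state
  }
  after <- sim_stats(params$Wi, params$Wt)
  # loss strictly decreases over training on the fixed batch
  expect_lt(losses[60], losses[1])
  expect_true(all(diff(losses) < 1e-3))  # essentially monotone descent
  # alignment: matched pairs dominate and improve on the pre-training value
  expect_gt(after[["diag"]], after[["off"]])
  expect_gt(after[["diag"]], before[["diag"]])
})
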