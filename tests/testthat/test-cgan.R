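test_that("gradient penalty matches analytic values for linear critics", {
  set.seed(1)
  x <- matrix(stats::rnorm(10), 5, 2)
  xg <- x + matrix(stats::rnorm(10), 5, 2)
  cnd <- matrix(stats::rnorm(15), 5, 3)
  # unit-slope critic: ||grad|| = 1 everywhere -> penalty 0
  expect_equal(gradient_penalty(linear_critic(c(0.6, 0.8), cond_dim = 3),
                                x, xg, cnd, seed = 2), 0, tolerance = 1e-24)
  # constant critic: ||grad|| = 0 -> penalty (0 - 1)^2 = 1
  expect_equal(gradient_penalty(linear_critic(c(0, 0), cond_dim = 3),
                                x, xg, cnd, seed = 2), 1)
  # D = 2 x1: ||grad|| = 2 -> penalty 1
  expect_equal(gradient_penalty(linear_critic(c(2, 0), cond_dim = 3),
                                x, xg, cnd, seed = 2), 1, tolerance = 1e-12)
  expect_error(gradient_penalty(linear_critic(c(1, 0)), x[0, , drop = FALSE],
                                xg[0, , drop = FALSE], cnd[0, , drop = FALSE]),
               "empty batch")
})

test_that("penalty-zero certificate holds for any unit-norm linear critic", {
  set.seed(3)
  for (rep in 1:10) {
    k <- sample(1:4, 1)
    w <- stats::rnorm(k); w <- w / sqrt(sum(w^2))
    cd <- sample(0:3, 1)
    n <- sample(1:6, 1)
    x <- matrix(stats::rnorm(n * k), n, k)
    xg <- matrix(stats::rnorm(n * k), n, k)
    cnd <- matrix(stats::rnorm(n * cd), n, cd)
    expect_equal(gradient_penalty(linear_critic(w, cond_dim = cd), x, xg, cnd),
                 0, tolerance = 1e-20)
  }
})

test_that("critic and generator objectives follow the adversarial form", {
  set.seed(4)
  x <- matrix(stats::rnorm(12), 6, 2)
  cnd <- matrix(stats::rnorm(12), 6, 2)
  unit <- linear_critic(c(1, 0), cond_dim = 2)
  # generator output identical to real batch, unit-slope critic: gap 0, GP 0
  expect_equal(critic_loss(unit, x, x, cnd, phi_gp = 10), 0, tolerance = 1e-20)
  # constant critic: both expectations equal, loss = phi_gp * 1
  const <- linear_critic(c(0, 0), cond_dim = 2)
  expect_equal(critic_loss(const, x, x + 1, cnd, phi_gp = 10), 10)
  # phi_gp = 0 reduces to the plain Wasserstein surrogate
  xg <- x + 2
  gap <- mean(lungfuse:::critic_score(unit, cnd, xg)) -
    mean(lungfuse:::critic_score(unit, cnd, x))
  expect_equal(critic_loss(unit, x, xg, cnd, phi_gp = 0), gap)
  expect_equal(generator_loss(unit, xg, cnd),
               -mean(lungfuse:::critic_score(unit, cnd, xg)))
  expect_error(critic_loss(unit, x, xg * NA, cnd), "non-finite")
  expect_error(generator_loss(unit, xg * Inf, cnd), "non-finite")
})

test_that("gradient-penalty parameter gradients match finite differences", {
  set.seed(5)
  D <- lungfuse:::mlp_init(c(5, 8, 1))
  xh <- matrix(stats::rnorm(12), 6, 2)
  cnd <- matrix(stats::rnorm(18), 6, 3)
  an <- lungfuse:::gradient_penalty_with_grads(D, cnd, xh)
  eps <- 1e-6
  for (k in 1:4) {
    i <- sample(4:5, 1); j <- sample(1:8, 1)
    Dp <- D; Dp[[1]]$W[i, j] <- Dp[[1]]$W[i, j] + eps
    Dm <- D; Dm[[1]]$W[i, j] <- Dm[[1]]$W[i, j] - eps
    num <- (lungfuse:::gradient_penalty_with_grads(Dp, cnd, xh)$penalty -
            lungfuse:::gradient_penalty_with_grads(Dm, cnd, xh)$penalty) /
      (2 * eps)
    expect_equal(an$grads[[1]]$W[i, j], num, tolerance = 1e-5)
  }
})

test_that("cgan training is deterministic and flags degenerate data", {
  coh <- tiny_cohort(seed = 31L)
  g1 <- train_cgan(coh, cgan_spec(), iters = 5L, batch = 16L, seed = 2L)
  g2 <- train_cgan(coh, cgan_spec(), iters = 5L, batch = 16L, seed = 2L)
  expect_identical(g1$G, g2$G)
  expect_identical(g1$D, g2$D)
  # single observed record trains with a warning, empty errors
  one <- coh[1, ]
  expect_warning(train_cgan(one, cgan_spec(), iters = 2L, seed = 1L,
                            schema = tabular_schema(coh)),
                 "single record")
  none <- mask_environment(coh, 1)
  expect_error(train_cgan(none, cgan_spec(), iters = 2L),
               "no observed environmental data")
})

test_that("imputation fills only masked cells and keeps draws", {
  coh <- tiny_cohort(seed = 32L)
  masked <- mask_environment(coh, 0.3, seed = 3L)
  gan <- train_cgan(masked, cgan_spec(), iters = 40L, batch = 16L, seed = 4L)
  # no masked records: bit-identical return
  expect_identical(impute_environment(coh, gan), coh)
  imp <- impute_environment(masked, gan, n_draws = 5L, seed = 6L)
  miss <- masked$env_missing
  expect_false(any(is.na(imp$pm25)))
  expect_true(all(imp$pm25[miss] >= 0))
  expect_true(all(imp$exposure_years[miss] >= 0))
  # observed cells untouched bitwise
  expect_identical(imp$pm25[!miss], coh$pm25[!miss])
  expect_identical(imp$exposure_years[!miss], coh$exposure_years[!miss])
  draws <- attr(imp, "imputation_draws")
  expect_equal(nrow(draws), 5L * sum(miss))
  expect_true(all(is.finite(draws$pm25)))
  expect_true(all(draws$pm25 >= 0))
  # schema mismatch is an explicit error
  broken <- dplyr::rename(masked, years_smoked = smoking_years)
  expect_error(impute_environment(broken, gan), "schema")
})

test_that("generated samples approach the real conditional law over training", {
  # 2-component conditional Gaussian: env | smoker ~ N(30 + 10 smoker, 2^2)
  set.seed(9)
  n <- 400
  smoker <- stats::rbinom(n, 1, 0.5)
  x <- matrix(30 + 10 * smoker + stats::rnorm(n, 0, 2), ncol = 1)
  cnd <- matrix(smoker, ncol = 1)
  mu <- mean(x); sdv <- stats::sd(x)
  xs <- (x - mu) / sdv
  spec <- cgan_spec(env_dim = 1, cond_dim = 1, noise_dim = 4)
  hold_n <- 200
  hold_smoker <- stats::rbinom(hold_n, 1, 0.5)
  hold <- matrix((30 + 10 * hold_smoker + stats::rnorm(hold_n, 0, 2) - mu) / sdv,
                 ncol = 1)
  gen_from <- function(G, cvec) {
    z <- matrix(stats::rnorm(length(cvec) * 4), length(cvec))
    lungfuse:::mlp_forward(cbind(matrix(cvec, ncol = 1), z), G)$out
  }
  set.seed(10)
  init <- lungfuse:::cgan_init(spec)
  ed_init <- energy_distance(gen_from(init$G, hold_smoker), hold)
  gan <- lungfuse:::train_wgan_gp(xs, cnd, spec, iters = 500L, batch = 64L,
                                  seed = 11L)
  set.seed(12)
  ed_end <- energy_distance(gen_from(gan$G_ema, hold_smoker), hold)
  expect_lt(ed_end, ed_init)
  # and the trend is visible mid-run too
  set.seed(12)
  ed_mid <- energy_distance(gen_from(gan$G, hold_smoker), hold)
  expect_lt(min(ed_mid, ed_end), ed_init)
})
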