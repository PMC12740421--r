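make_train_cohort <- function(seed = 61L, n = 30L) {
  coh <- generate_cohort(cohort_spec(n_copd = n, n_control = n, seed = seed))
  mask_environment(coh, 0.2, seed = seed + 1L)
}

test_that("training is deterministic and its trace obeys the joint objective", {
  coh <- make_train_cohort()
  cfg <- tiny_config(epochs = 3L)
  ip <- tiny_image_params()
  m1 <- train_mmdf(coh, cfg, img_params = ip)
  m2 <- train_mmdf(coh, cfg, img_params = ip)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$trace, m2$trace)
  # per-epoch total equals L_cls + lambda1 L_contrast + lambda2 L_WGAN
  tr <- m1$trace
  expect_equal(tr$l_total,
               tr$l_cls + cfg$lambda_contrast * tr$l_contrast +
                 cfg$lambda_wgan * tr$l_wgan,
               tolerance = 1e-12)
  expect_equal(nrow(tr), 3L)
})

test_that("training learns on a separable cohort and predictions are valid", {
  coh <- generate_cohort(cohort_spec(n_copd = 40, n_control = 40, seed = 62L))
  cfg <- tiny_config(epochs = 12L, gate_warmup = 4L)
  m <- train_mmdf(coh, cfg, img_params = tiny_image_params())
  # learning progress: final training AUC above the first epoch's
  expect_gt(m$trace$auc_train[nrow(m$trace)], m$trace$auc_train[1])
  pr <- predict(m, coh)
  expect_equal(nrow(pr), nrow(coh))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_equal(pr$w_ct + pr$w_lung_function + pr$w_environment,
               rep(1, nrow(coh)), tolerance = 1e-6)
  # tidiers expose the trace and a one-row summary
  expect_equal(nrow(tidy(m)), 12L)
  gl <- glance(m)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_train + gl$n_val + gl$n_test, nrow(coh))
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("config invariants are enforced", {
  expect_error(mmdf_config(batch_size = 0), "batch_size")
  expect_error(mmdf_config(split = c(train = 0.5, val = 0.2, test = 0.2)),
               "split")
  expect_error(mmdf_config(temperature = -1), "temperature")
  expect_error(mmdf_config(force_weights = c(0.5, 0.5)), "force_weights")
  coh <- make_train_cohort()
  one_class <- coh[coh$label == "COPD", ]
  expect_error(train_mmdf(one_class, tiny_config()), "both classes")
})

test_that("ablation runner reuses the split and knows its component names", {
  coh <- make_train_cohort(seed = 63L)
  cfg <- tiny_config(epochs = 3L)
  ip <- tiny_image_params()
  expect_error(run_ablation(coh, cfg, disable = "dropout"), "unknown component")
  # empty disable set reproduces the full model row
  ab0 <- run_ablation(coh, cfg, split = "test", img_params = ip)
  m <- train_mmdf(coh, cfg, img_params = ip)
  full_row <- evaluate_mmdf(m, coh, "test")
  expect_equal(ab0$auc, full_row$auc)
  expect_equal(nrow(ab0), 1L)
  # disabling all three still runs and reports a row
  ab <- run_ablation(coh, cfg,
                     disable = list(c("contrastive", "cgan", "gating")),
                     split = "test", img_params = ip)
  expect_equal(nrow(ab), 2L)
  expect_true(all(is.finite(ab$auc)))
})

test_that("subgroup weight report sums to one per group and drops empty groups", {
  coh <- make_train_cohort(seed = 64L)
  m <- train_mmdf(coh, tiny_config(epochs = 3L),
                  img_params = tiny_image_params())
  rep_s <- subgroup_weight_report(m, coh, "smoking")
  expect_true(all(c("smoker", "nonsmoker") %in% rep_s$group))
  sums <- rep_s$w_ct_mean + rep_s$w_lung_function_mean +
    rep_s$w_environment_mean
  expect_equal(sums, rep(1, nrow(rep_s)), tolerance = 1e-6)
  expect_equal(sum(rep_s$n), nrow(coh))
  # pm25 threshold grouping splits the default cohort into two non-empty groups
  coh_full <- generate_cohort(cohort_spec(n_copd = 40, n_control = 40,
                                          seed = 65L))
  m2 <- train_mmdf(coh_full, tiny_config(epochs = 2L),
                   img_params = tiny_image_params())
  rep_p <- subgroup_weight_report(m2, coh_full, "pm25")
  expect_equal(nrow(rep_p), 2L)
  expect_true(all(rep_p$n > 0))
  # single-group cohort yields a single row that still sums to 1
  allsm <- coh
  allsm$smoker <- TRUE
  rep_1 <- subgroup_weight_report(m, allsm, "smoking")
  expect_equal(nrow(rep_1), 1L)
  expect_equal(rep_1$w_ct_mean + rep_1$w_lung_function_mean +
                 rep_1$w_environment_mean, 1, tolerance = 1e-6)
})

test_that("cross-validation folds cover the cohort disjointly", {
  coh <- generate_cohort(cohort_spec(n_copd = 24, n_control = 24, seed = 66L))
  cv <- train_mmdf_cv(coh, tiny_config(epochs = 2L), folds = 3L)
  expect_equal(nrow(cv), 3L)
  expect_equal(sum(cv$n), nrow(coh))
  expect_true(all(is.finite(cv$auc)))
})

test_that("modality forcing pins the fusion weights", {
  coh <- make_train_cohort(seed = 67L)
  cfg <- tiny_config(epochs = 2L, force_weights = c(1, 0, 0))
  m <- train_mmdf(coh, cfg, img_params = tiny_image_params())
  pr <- predict(m, coh)
  expect_true(all(pr$w_ct == 1))
  expect_true(all(pr$w_environment == 0))
})
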