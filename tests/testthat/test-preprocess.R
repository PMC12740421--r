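# Brute-force oracle for discrete equalization: per-pixel evaluation of the
# rounded cumulative-histogram brightness transform.
he_oracle <- function(img_levels, levels) {
  counts <- tabulate(as.vector(img_levels) + 1L, nbins = levels)
  out <- img_levels
  for (i in seq_along(img_levels)) {
    p <- img_levels[i]
    cum <- sum(counts[seq_len(p + 1L)])
    out[i] <- round((levels - 1) * cum / length(img_levels))
  }
  out
}

test_that("equalization matches the per-pixel cumulative-sum oracle", {
  # 4x4 image over levels {0,1,2,3} with counts (8,4,4,0)
  lv <- matrix(c(rep(0L, 8), rep(1L, 4), rep(2L, 4)), 4, 4)
  got <- histogram_equalize(lv / 3, levels = 4, range = c(0, 1))
  want <- he_oracle(lv, 4L) / 3
  expect_equal(got, want, tolerance = 1e-12)
  # same oracle on random images at several level counts
  set.seed(42)
  for (L in c(4L, 16L, 64L)) {
    lv <- matrix(sample(0:(L - 1), 100, replace = TRUE,
                        prob = (L:1)^2), 10, 10)
    got <- histogram_equalize(lv / (L - 1), levels = L, range = c(0, 1))
    expect_equal(got * (L - 1), he_oracle(lv, L), tolerance = 1e-9)
  }
})

test_that("equalization degenerate and fixed-point cases behave", {
  flat <- matrix(0.37, 5, 5)
  eq <- histogram_equalize(flat, levels = 16)
  expect_equal(length(unique(as.vector(eq))), 1L)  # single output level
  # exactly uniform histogram stays an identity ramp up to quantization
  lv <- matrix(rep(0:7, each = 2), 4, 4)
  eq <- histogram_equalize(lv / 7, levels = 8) * 7
  expect_true(all(abs(eq - lv) <= 1))
  expect_error(histogram_equalize(matrix(1, 2, 2), levels = 1), "levels")
  expect_error(histogram_equalize(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("equalization is monotone and idempotent in histogram", {
  set.seed(7)
  for (rep in 1:5) {
    img <- matrix(stats::runif(256)^2, 16, 16)
    eq1 <- histogram_equalize(img, levels = 32)
    # monotone: pixel order preserved
    o <- order(img)
    expect_true(all(diff(eq1[o]) >= -1e-12))
    # idempotent: second pass leaves the histogram unchanged
    eq2 <- histogram_equalize(eq1, levels = 32)
    expect_equal(tabulate(round(eq1 * 31) + 1L, 32),
                 tabulate(round(eq2 * 31) + 1L, 32))
  }
})

test_that("image standardization is exact and invertible", {
  img <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(standardize_image(img, 1.5, 0.5),
               matrix(c(-3, -1, 1, 3), 2, 2))
  expect_equal(standardize_image(matrix(2.5, 3, 3), 2.5, 1.1),
               matrix(0, 3, 3))
  expect_equal(standardize_image(matrix(2.5 + 1.1, 1, 1), 2.5, 1.1),
               matrix(1, 1, 1))
  expect_error(standardize_image(img, 0, 0), "sigma")
  # invertible
  z <- standardize_image(img, 1.2, 0.7)
  expect_equal(z * 0.7 + 1.2, img, tolerance = 1e-12)
})

test_that("tabular encoding Z-scores with training moments and one-hots levels", {
  coh <- tiny_cohort(seed = 3L)
  schema <- tabular_schema(coh)
  X <- encode_tabular(coh, schema)
  # training set encodes to mean 0, sd 1 per continuous column
  expect_lt(max(abs(colMeans(X[, c("age", "smoking_years", "fev1_fvc")]))),
            1e-10)
  expect_equal(unname(apply(X[, c("age", "smoking_years", "fev1_fvc")], 2,
                            stats::sd)),
               rep(1, 3), tolerance = 1e-10)
  # hand values: x = mu -> 0, x = mu + 2 sd -> 2
  mu <- schema$continuous$age$mean; s <- schema$continuous$age$sd
  rec <- coh[1, ]
  rec$age <- mu
  expect_equal(encode_tabular(rec, schema)[, "age"], c(age = 0))
  rec$age <- mu + 2 * s
  expect_equal(encode_tabular(rec, schema)[, "age"], c(age = 2))
  # one-hot definition for binary sex (levels sorted lexicographically)
  rec$sex <- factor("male", levels = levels(coh$sex))
  expect_equal(unname(encode_tabular(rec, schema)[, c("sex.female", "sex.male")]),
               c(0, 1))
  # unseen level is an explicit error
  rec2 <- coh[1, ]
  levels(rec2$sex) <- c(levels(coh$sex), "other")
  rec2$sex[1] <- "other"
  expect_error(encode_tabular(rec2, schema), "unseen level")
})

test_that("schema persists to JSON and back", {
  coh <- tiny_cohort(seed = 4L)
  schema <- tabular_schema(coh)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_schema(schema, tmp)
  back <- read_schema(tmp)
  expect_equal(back$continuous$fev1_fvc$mean, schema$continuous$fev1_fvc$mean)
  expect_equal(back$categorical$sex, schema$categorical$sex)
  expect_equal(encode_tabular(coh, back), encode_tabular(coh, schema),
               tolerance = 1e-12)
})
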