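test_that("near-constancy filter uses a strict modal-frequency threshold", {
  X <- cbind(c(rep(1, 9), 2),          # mode freq 0.9 > 0.8 -> removed
             c(rep(1, 8), 2, 3),       # mode freq 0.8, not > 0.8 -> kept
             1:10)                     # all distinct -> kept
  tab <- tiny_table(X, rnorm(10))
  out <- filter_near_constant(tab)
  expect_setequal(descriptors(out), c("x2", "x3"))
  rep <- selection_history(out)
  expect_equal(rep$n_before, 3L)
  expect_equal(rep$n_after, 2L)
  expect_equal(rep$removed[[1]], "x1")
  expect_error(filter_near_constant(tab[0, ]), "empty")
})

test_that("target-correlation filter keeps |r| >= threshold including negatives", {
  withr::local_seed(7)
  y <- rnorm(200)
  X <- cbind(y, -y, rnorm(200))        # r = 1, r = -1, independent noise
  tab <- tiny_table(X, y)
  expect_lt(abs(brute_cor(X[, 3], y)), 0.7)   # the noise column really is weak
  out <- filter_target_correlation(tab)
  expect_setequal(descriptors(out), c("x1", "x2"))
})

test_that("cross-correlation filter keeps the better target-correlate of a duplicate pair", {
  withr::local_seed(11)
  y <- rnorm(100)
  a <- y + rnorm(100, sd = 0.1)
  b <- a + rnorm(100, sd = 0.02)       # near-duplicate of a
  noisier <- ifelse(abs(brute_cor(a, y)) >= abs(brute_cor(b, y)), "x2", "x1")
  tab <- tiny_table(cbind(a, b), y)
  out <- filter_cross_correlation(tab)
  expect_length(descriptors(out), 1)
  expect_false(noisier %in% descriptors(out))
})

test_that("cross-correlation filter keeps orthogonal columns and collapses identical triples", {
  withr::local_seed(3)
  X <- qr.Q(qr(matrix(rnorm(100 * 3), 100, 3)))   # orthogonal columns
  y <- X[, 1] + 0.5 * X[, 2] + 0.25 * X[, 3]
  expect_length(descriptors(filter_cross_correlation(tiny_table(X, y))), 3)

  z <- rnorm(50)
  tab3 <- tiny_table(cbind(z, z, z), z)
  expect_length(descriptors(filter_cross_correlation(tab3)), 1)
})

test_that("stepwise MLR selects the true predictor and drops noise", {
  withr::local_seed(5)
  x1 <- rnorm(100)
  x2 <- rnorm(100)
  y <- 2 * x1 + rnorm(100, sd = 0.01)
  # exhaustive-subset oracle on the 2 candidates: {x1} must beat {}, {x2},
  # and {x1,x2} must not improve enough to justify x2 at p < 0.05
  rss <- function(vars) {
    f <- lm(y ~ ., data = as.data.frame(cbind(y = y,
                                              cbind(x1, x2)[, vars, drop = FALSE])))
    sum(residuals(f)^2)
  }
  expect_lt(rss("x1"), rss("x2"))
  tab <- tiny_table(cbind(x1, x2), y)
  out <- stepwise_mlr(tab)
  expect_identical(descriptors(out), "x1")
  expect_lt(attr(out, "training_mse"), 0.001)
})

test_that("stepwise MLR boundary cases: exact fit and zero candidates", {
  withr::local_seed(6)
  x1 <- rnorm(50); x2 <- rnorm(50)
  y <- 1 + x1 - 2 * x2
  # suppress the optimizer's essentially-perfect-fit warnings
  out <- suppressWarnings(stepwise_mlr(tiny_table(cbind(x1, x2), y)))
  expect_setequal(descriptors(out), c("x1", "x2"))
  expect_lt(attr(out, "training_mse"), 1e-20)

  empty <- tiny_table(matrix(numeric(0), 10, 0), rnorm(10))
  out0 <- stepwise_mlr(empty)
  expect_length(descriptors(out0), 0)
  expect_equal(unname(coef(attr(out0, "model"))[1]),
               mean(activity_values(empty)))
})

test_that("PCA representative selection picks one descriptor per correlated block", {
  withr::local_seed(8)
  base1 <- rnorm(100); base2 <- rnorm(100)
  X <- cbind(base1, base1 + rnorm(100, sd = 0.05), base1 + rnorm(100, sd = 0.05),
             base2, base2 + rnorm(100, sd = 0.05), base2 + rnorm(100, sd = 0.05))
  tab <- tiny_table(X, rnorm(100))
  out <- pca_reduce(tab, n_components = 2)
  kept <- descriptors(out)
  expect_length(kept, 2)
  # oracle: eigen-decomposition loadings say one representative per block
  expect_length(intersect(kept, c("x1", "x2", "x3")), 1)
  expect_length(intersect(kept, c("x4", "x5", "x6")), 1)

  # identity case: as many components as descriptors returns everything
  ortho <- tiny_table(qr.Q(qr(matrix(rnorm(300), 100, 3))), rnorm(100))
  expect_length(descriptors(pca_reduce(ortho, 3)), 3)
  expect_error(pca_reduce(ortho, 4), "exceeds")
})

test_that("the pipeline is the composition of its steps and monotone", {
  withr::local_seed(9)
  n <- 120
  a <- rnorm(n); b <- rnorm(n)
  y <- 0.8 * a + 0.6 * b
  X <- cbind(a + rnorm(n, sd = 0.05),           # strong correlate of y
             b + rnorm(n, sd = 0.05),           # second independent correlate
             rnorm(n),                          # pure noise
             c(rep(0, 110), rnorm(10)),         # near-constant
             a + rnorm(n, sd = 0.02))           # duplicate of column 1
  tab <- tiny_table(X, y)
  piped <- tab |> filter_near_constant() |>
    filter_target_correlation(min_abs_r = 0.5) |>
    filter_cross_correlation() |> stepwise_mlr() |> pca_reduce(2)
  hist <- selection_history(piped)
  expect_true(all(hist$n_after <= hist$n_before))
  expect_equal(hist$n_before[-1], hist$n_after[-nrow(hist)])
  whole <- select_features(tab, min_abs_r = 0.5, n_components = 2)
  expect_identical(descriptors(whole), descriptors(piped))
})

test_that("module Pearson r matches the brute-force two-pass formula", {
  withr::local_seed(10)
  for (i in 1:5) {
    X <- matrix(rnorm(60), 20, 3)
    y <- rnorm(20)
    tab <- tiny_table(X, y)
    r_mod <- xcsfqsar:::target_correlations(tab)
    r_brute <- apply(X, 2, brute_cor, b = y)
    expect_equal(unname(r_mod), unname(r_brute), tolerance = 1e-12)
  }
})
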