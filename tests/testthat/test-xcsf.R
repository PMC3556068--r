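test_that("hyperellipsoid matching follows the quadratic-form rule", {
  expect_true(xcsf_matches(c(0.5, 0.5), c(0.2, 0.2), c(0.5, 0.6)))
  expect_false(xcsf_matches(c(0.5, 0.5), c(0.2, 0.2), c(0.9, 0.5)))
  expect_true(xcsf_matches(c(0.3, 0.7), c(1e-9, 1e-9), c(0.3, 0.7)))
  expect_error(xcsf_matches(c(0.5, 0.5), c(0.2, 0.2), 0.5), "dimension")
})

test_that("classifier and system predictions are the stated linear/weighted forms", {
  expect_equal(classifier_prediction(c(0.5, 2), s = 0.25, x0 = 1), 1)
  expect_equal(classifier_prediction(c(0, 0, 0), s = c(3, 4)), 0)
  expect_equal(classifier_prediction(c(0.1, 0), s = 7, x0 = 10), 1)

  expect_equal(system_prediction(c(2, 6), c(3, 1)), 3)
  expect_equal(system_prediction(5, 0.2), 5)
  expect_equal(system_prediction(c(1, 3), c(0.4, 0.4)), 2)
  # numerosity-weighted: a num-2 member counts twice
  expect_equal(system_prediction(c(2, 6), c(1, 1), num = c(3, 1)), 3)
  expect_error(system_prediction(numeric(0), numeric(0)), "covering")
})

test_that("delta-rule update is the normalized gradient step", {
  w <- update_weights_delta(c(0, 0), s = 1, P = 4, eta = 0.2, x0 = 1)
  expect_equal(w, c(0.4, 0.4))
  # fixed point: P equal to the prediction leaves w unchanged
  w2 <- update_weights_delta(c(1, 2), s = 0.5, P = 2, eta = 0.2)
  expect_equal(w2, c(1, 2))
  # eta = 1 gives full NLMS correction: prediction equals P after one step
  w3 <- update_weights_delta(c(0.3, -1, 0.4), s = c(0.2, 0.7), P = 2.5, eta = 1)
  expect_equal(classifier_prediction(w3, c(0.2, 0.7)), 2.5)
})

test_that("RLS recovers exact linear coefficients and keeps V positive-definite", {
  withr::local_seed(1)
  d <- 3
  true_w <- c(1.5, -2, 0.5, 3)
  w <- numeric(d + 1)
  V <- diag(1e9, d + 1)
  pts <- matrix(runif(8 * d), 8, d)
  for (i in seq_len(nrow(pts))) {
    P <- sum(true_w * c(1, pts[i, ]))
    up <- update_weights_rls(w, V, pts[i, ], P)
    w <- up$w; V <- up$V
  }
  # oracle: exact solution of the linear system
  expect_equal(w, true_w, tolerance = 1e-6)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > 0))

  # P equal to current prediction leaves w unchanged
  up2 <- update_weights_rls(w, V, pts[1, ], sum(w * c(1, pts[1, ])))
  expect_equal(up2$w, w)
})

test_that("error trace follows Widrow-Hoff with MAM averaging", {
  expect_equal(update_error(0.5, 1.5, beta = 0.2), 0.7)
  expect_equal(update_error(0.3, 0.3, beta = 0.2), 0.3)
  # MAM: while exp < 1/beta the trace is the running mean
  expect_equal(update_error(0.5, 1.5, beta = 0.2, expc = 2), 1.0)
  # geometric convergence to a constant error
  eps <- 0
  for (i in 1:200) eps <- update_error(eps, 0.7, beta = 0.2)
  expect_equal(eps, 0.7, tolerance = 1e-10)
})

test_that("accuracy is 1 below eps0 and the power law above it", {
  expect_equal(classifier_accuracy(0.005, eps0 = 0.01), 1)
  expect_equal(classifier_accuracy(0.02, eps0 = 0.01, alpha = 0.1, nu = 5),
               0.1 * 2^-5)
})

test_that("covering centers on the input with stretch in the stated band", {
  withr::local_seed(2)
  s <- runif(7)
  cl <- cover_classifier(s, stretch_hint = 0.1)
  expect_equal(cl$center, s)
  expect_true(all(cl$stretch > 0.05 & cl$stretch <= 0.15))
  expect_true(xcsf_matches(cl$center, cl$stretch, s))
  expect_equal(cl$w, numeric(8))
  expect_equal(classifier_prediction(cl$w, runif(7)), 0)
  expect_equal(cl$num, 1L)
})

test_that("match-set construction covers up to theta_mna and members all match", {
  p <- xcsf_params(theta_mna = 3L)
  pop <- xcsfqsar:::pop_new(2, p)
  s <- c(0.4, 0.6)
  withr::local_seed(3)
  M <- xcsfqsar:::build_match_set(pop, s, 1L, function(s) 0.2, p)
  expect_length(M, 3)
  for (m in M) {
    expect_true(xcsf_matches(pop$centers[m, ], pop$stretch[m, ], s))
  }
  # a pre-matched population with theta_mna = 1 triggers no covering
  p1 <- xcsf_params(theta_mna = 1L)
  M2 <- xcsfqsar:::build_match_set(pop, s, 2L, function(s) 0.2, p1)
  expect_equal(attr(M2, "n_cover"), 0L)
})

test_that("relative accuracies sum to one in every fitness update", {
  withr::local_seed(4)
  p <- xcsf_params()
  pop <- xcsfqsar:::pop_new(1, p)
  for (i in 1:5) {
    cl <- cover_classifier(runif(1), 0.5, p, ts = i)
    xcsfqsar:::pop_insert(pop, cl$center, cl$stretch, cl$w, runif(1, 0, 0.2),
                          cl$fit, sample(1:3, 1), cl$expc, cl$ts, 1, p)
  }
  idx <- which(pop$alive)
  kappa <- classifier_accuracy(pop$eps[idx], p$eps0, p$alpha, p$nu)
  rel <- kappa * pop$num[idx] / sum(kappa * pop$num[idx])
  expect_equal(sum(rel), 1)
})

test_that("deletion keeps the micro-population at the limit and favors high votes", {
  p <- xcsf_params(pop_limit = 10L)
  withr::local_seed(5)
  # fill beyond the limit, then delete down
  pop <- xcsfqsar:::pop_new(1, p)
  for (i in 1:13) {
    cl <- cover_classifier(runif(1), 0.3, p, ts = i)
    xcsfqsar:::pop_insert(pop, cl$center, cl$stretch, cl$w, cl$eps, cl$fit,
                          1L, cl$expc, cl$ts, 1, p)
  }
  xcsfqsar:::delete_down(pop, p)
  expect_lte(xcsfqsar:::pop_micro_size(pop), 10L)

  # binomial check: with votes 100:1 the heavy classifier dies ~99% of draws
  pop2 <- xcsfqsar:::pop_new(1, p)
  xcsfqsar:::pop_insert(pop2, 0.5, 0.3, c(0, 0), 0, 0.5, 1L, 0, 0, 100, p)
  xcsfqsar:::pop_insert(pop2, 0.5, 0.3, c(0, 0), 0, 0.5, 1L, 0, 0, 1, p)
  votes <- xcsfqsar:::deletion_votes(pop2, p)
  expect_equal(unname(votes), c(100, 1))
  hits <- mean(replicate(10000, xcsfqsar:::roulette(c(100, 1)) == 1))
  expect_gte(hits, 0.97)
})

test_that("GA respects its firing gate and crossover/mutation switches", {
  p <- xcsf_params(p_c = 0, p_m = 0)
  withr::local_seed(6)
  pop <- xcsfqsar:::pop_new(2, p)
  for (i in 1:2) {
    cl <- cover_classifier(runif(2), 0.3, p, ts = 0)
    xcsfqsar:::pop_insert(pop, cl$center, cl$stretch, cl$w, cl$eps, cl$fit,
                          1L, cl$expc, 0, 1, p)
  }
  M <- which(pop$alive)
  before <- pop$centers[M, ]
  # below the age gate: nothing happens
  expect_false(isTRUE(xcsfqsar:::ga_step(pop, M, t = 10L, p)))
  expect_equal(sum(pop$alive), 2)
  # above the gate with p_c = p_m = 0: offspring are exact condition clones
  expect_true(isTRUE(xcsfqsar:::ga_step(pop, M, t = 100L, p)))
  expect_equal(sum(pop$alive), 4)
  kids <- setdiff(which(pop$alive), M)
  for (kid in kids) {
    match_parent <- any(vapply(seq_len(nrow(before)), function(j) {
      isTRUE(all.equal(pop$centers[kid, ], before[j, ]))
    }, logical(1)))
    expect_true(match_parent)
  }
  expect_lte(xcsfqsar:::pop_micro_size(pop), p$pop_limit)
})

test_that("a single always-matching classifier with RLS reproduces OLS exactly", {
  withr::local_seed(7)
  n <- 200; d <- 7
  X <- matrix(runif(n * d), n, d)
  y <- 2 + X %*% runif(d, -1, 1) + rnorm(n, sd = 0.1)
  tab <- tiny_table(X, as.vector(y))
  p <- xcsf_params(pop_limit = 1L, cover_range = 1e9, theta_ga = Inf,
                   rls_delta_init = 1e9)
  m <- xcsf(tab, params = p, epochs = 1, seed = 8)
  expect_equal(nrow(m$population$W), 1)
  w_ols <- unname(coef(lm(y ~ X)))   # normal-equations oracle
  expect_lt(max(abs(as.vector(m$population$W[1, ]) - w_ols)), 1e-8)
})

test_that("XCSF learns an exact 1-D linear target to high accuracy", {
  withr::local_seed(9)
  x <- matrix(runif(200), ncol = 1)
  tab <- tiny_table(x, as.vector(1 + 2 * x))
  p <- xcsf_params(pop_limit = 10L, eps0 = 0.001)
  m <- xcsf(tab, params = p, epochs = 40, seed = 10)
  pr <- predict(m, tab)
  expect_lt(mse(activity_values(tab), pr$.pred), 1e-3)
  expect_lte(sum(m$population$num), 10)
})

test_that("training is deterministic given a seed and predictions are row-equivariant", {
  tab <- generate_synthetic(synthetic_spec(n_clusters = 2, dims = 3,
                                           samples_per_cluster = 40,
                                           seed = 11))
  trn <- normalize_descriptors(tab)
  m1 <- xcsf(trn, epochs = 3, seed = 12)
  m2 <- xcsf(trn, epochs = 3, seed = 12)
  expect_identical(m1$population, m2$population)

  X <- descriptor_matrix(trn)
  perm <- rev(seq_len(nrow(X)))
  expect_equal(predict(m1, X[perm, ])$.pred, predict(m1, X)$.pred[perm])
})

test_that("prediction flags out-of-coverage points and uses the nearest condition", {
  tab <- tiny_table(matrix(seq(0.4, 0.6, length.out = 30), ncol = 1),
                    seq(0.4, 0.6, length.out = 30))
  m <- xcsf(tab, params = xcsf_params(pop_limit = 5L, cover_range = 0.05),
            epochs = 2, seed = 13)
  far <- matrix(5, 1, 1)
  pr <- predict(m, far)
  expect_true(pr$.fallback)
  expect_equal(pr$.n_matched, 0L)
  expect_true(is.finite(pr$.pred))
  expect_error(predict(m, matrix(1, 1, 2)), "dimension")
})

test_that("micro-population never exceeds the limit during training", {
  tab <- generate_synthetic(synthetic_spec(n_clusters = 3, dims = 2,
                                           samples_per_cluster = 30,
                                           seed = 14))
  trn <- normalize_descriptors(tab)
  m <- xcsf(trn, params = xcsf_params(pop_limit = 15L), epochs = 5, seed = 15)
  expect_lte(sum(m$population$num), 15)
  expect_true(all(m$population$stretch > 0))
  expect_true(all(m$population$num >= 1))
})
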