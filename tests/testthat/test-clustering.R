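test_that("k-means finds forced optima and degenerate solutions", {
  X <- matrix(c(0, 0.1, 0.9, 1.0), ncol = 1)
  cm <- fit_kmeans(X, 2, seed = 1)
  expect_equal(sort(as.vector(cm$centers)), c(0.05, 0.95))
  expect_equal(cm$sse, 0.01)

  cm_n <- fit_kmeans(X, 4, seed = 1)
  expect_equal(cm_n$sse, 0)
  expect_equal(sort(as.vector(cm_n$centers)), as.vector(X[order(X)]))

  expect_error(fit_kmeans(X, 5, seed = 1), "k must be")
})

test_that("k-means recovers well-separated blobs exactly", {
  blobs <- two_blobs(n_per = 50, d = 7, sep = 0.5, sd = 0.02, seed = 2)
  cm <- fit_kmeans(blobs$X, 2, seed = 3)
  # oracle: brute-force nearest-center labeling must equal the generating labels
  agree <- max(mean(cm$assignments == blobs$labels),
               mean(cm$assignments == 3 - blobs$labels))
  expect_equal(agree, 1)
})

test_that("silhouette agrees with the O(n^2) brute-force oracle", {
  withr::local_seed(4)
  for (k in 2:3) {
    X <- matrix(runif(60 * 3), 60, 3)
    labels <- sample(k, 60, replace = TRUE)
    expect_equal(silhouette_score(X, labels), brute_silhouette(X, labels),
                 tolerance = 1e-12)
  }
})

test_that("silhouette scores tight blobs high and degenerate/swapped labelings correctly", {
  blobs <- two_blobs(n_per = 10, d = 3, sep = 0.8, sd = 0.01, seed = 5)
  good <- silhouette_score(blobs$X, blobs$labels)
  expect_gt(good, 0.9)

  withr::local_seed(6)
  swapped <- blobs$labels
  flip <- sample(20, 8)
  swapped[flip] <- 3 - swapped[flip]
  expect_gt(good, silhouette_score(blobs$X, swapped))

  X0 <- matrix(1, 10, 2)
  expect_equal(silhouette_score(X0, rep(1:2, 5)), 0)
  expect_error(silhouette_score(X0, rep(1, 10)), "2 clusters")
})

test_that("silhouette scan recovers the number of generating blobs", {
  withr::local_seed(7)
  centers <- rbind(rep(0.2, 5), rep(0.5, 5), rep(0.8, 5))
  X <- do.call(rbind, lapply(1:3, function(g) {
    matrix(rnorm(40 * 5, sd = 0.03), 40, 5) + rep(centers[g, ], each = 40)
  }))
  k <- choose_k(X, 2, 6, seed = 8)
  expect_equal(as.integer(k), 3L)
  prof <- attr(k, "profile")
  expect_equal(prof$k, 2:6)
  expect_equal(prof$silhouette[2], max(prof$silhouette))

  expect_equal(as.integer(choose_k(X, 4, 4, seed = 8)), 4L)
  expect_message(choose_k(X[1:5, ], 2, 10, seed = 8), "clamped")
})

test_that("cluster stretch is the mean member-to-center distance with singleton fallback", {
  X <- matrix(c(0, 0.2, 10), ncol = 1)
  cm <- fit_kmeans(X, 2, seed = 9)
  st <- suppressMessages(cluster_stretch(cm))
  expect_equal(sort(unname(st)), c(0.1, 0.1))   # singleton's 0 replaced by fallback
  expect_equal(attr(st, "fallback"), 0.1)

  # blob with known sd: mean distance ~ sd * E||z|| for 7-D standard normal
  withr::local_seed(10)
  Xb <- matrix(rnorm(2000 * 7, sd = 0.05), 2000, 7)
  cmb <- list(k = 1, centers = matrix(colMeans(Xb), 1),
              assignments = rep(1L, 2000),
              mean_dist = mean(sqrt(rowSums(sweep(Xb, 2, colMeans(Xb))^2))),
              sizes = 2000L)
  e_norm <- 0.05 * sqrt(2) * gamma(4) / gamma(3.5)   # E||N(0, sd^2 I_7)||
  expect_equal(cmb$mean_dist, e_norm, tolerance = 0.1)
})

test_that("k-means SSE is non-increasing over Lloyd iterations", {
  withr::local_seed(11)
  X <- matrix(runif(200 * 4), 200, 4)
  # instrument one run: run Lloyd manually from a k-means++ start
  centers <- xcsfqsar:::kmeanspp_centers(X, 5)
  sse_path <- numeric(0)
  assign <- xcsfqsar:::nearest_center(X, centers)
  for (it in 1:25) {
    for (g in 1:5) {
      member <- assign == g
      if (any(member)) centers[g, ] <- colMeans(X[member, , drop = FALSE])
    }
    assign <- xcsfqsar:::nearest_center(X, centers)
    sse_path <- c(sse_path,
                  sum(xcsfqsar:::point_center_dist2(X, centers, assign)))
  }
  expect_true(all(diff(sse_path) <= 1e-12))
})

test_that("bespoke k-means matches stats::kmeans on an easy problem", {
  blobs <- two_blobs(n_per = 40, d = 4, sep = 0.6, sd = 0.02, seed = 12)
  cm <- fit_kmeans(blobs$X, 2, seed = 13)
  ref <- stats::kmeans(blobs$X, 2, nstart = 5)
  expect_equal(cm$sse, ref$tot.withinss, tolerance = 1e-8)
})
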