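#' K-means partitioning of the descriptor space
#'
#' Lloyd's algorithm with Euclidean distance and k-means++-style seeding,
#' run `n_init` times from the given seed and keeping the restart with the
#' smallest within-cluster sum of squares. An emptied cluster is re-seeded
#' from the point farthest from its current center. The per-cluster mean
#' point-to-center distance is retained because it seeds the covering
#' stretch of the XCSF rule conditions (see [xcsf()]).
#'
#' @param x A [qsar_table] or numeric matrix (rows = samples).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Relative SSE improvement below which iteration stops.
#' @return A `cluster_model`: list with `k`, `centers` (k x d),
#'   `assignments` (1..k), `mean_dist`, `silhouette` (NA when k < 2),
#'   `sse` and `sizes`.
#' @export
fit_kmeans <- function(x, k, seed = 1L, n_init = 10L, max_iter = 300L,
                       tol = 1e-6) {
  X <- if (is.matrix(x)) x else descriptor_matrix(x)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be in [1, n]", call. = FALSE)
  best <- NULL
  withr::local_seed(seed)
  for (init in seq_len(n_init)) {
    res <- lloyd_once(X, k, max_iter, tol)
    if (is.null(best) || res$sse < best$sse) best <- res
  }
  d2 <- point_center_dist2(X, best$centers, best$assignments)
  mean_dist <- vapply(seq_len(k), function(g) {
    mean(sqrt(d2[best$assignments == g]))
  }, numeric(1))
  sil <- if (k >= 2) silhouette_score(X, best$assignments) else NA_real_
  structure(list(k = k, centers = best$centers,
                 assignments = best$assignments,
                 mean_dist = mean_dist, silhouette = sil,
                 sse = best$sse,
                 sizes = tabulate(best$assignments, k)),
            class = "cluster_model")
}

# squared distance from each point to its assigned center
point_center_dist2 <- function(X, centers, assign) {
  rowSums((X - centers[assign, , drop = FALSE])^2)
}

kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  centers <- X[idx, , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(centers, 1, function(c) rowSums(sweep(X, 2, c)^2))
    d2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers <- rbind(centers, X[sample.int(n, 1, prob = p), , drop = FALSE])
  }
  centers
}

lloyd_once <- function(X, k, max_iter, tol) {
  n <- nrow(X)
  centers <- kmeanspp_centers(X, k)
  sse_prev <- Inf
  assign <- nearest_center(X, centers)
  for (it in seq_len(max_iter)) {
    for (g in seq_len(k)) {
      member <- assign == g
      if (!any(member)) {
        # re-seed an empty cluster from the globally farthest point
        far <- which.max(point_center_dist2(X, centers, assign))
        centers[g, ] <- X[far, ]
        assign[far] <- g
        member <- assign == g
      }
      centers[g, ] <- colMeans(X[member, , drop = FALSE])
    }
    assign <- nearest_center(X, centers)
    sse <- sum(point_center_dist2(X, centers, assign))
    if (sse_prev - sse <= tol * max(sse_prev, .Machine$double.eps)) {
      sse_prev <- sse
      break
    }
    sse_prev <- sse
  }
  list(centers = centers, assignments = assign, sse = sse_prev)
}

nearest_center <- function(X, centers) {
  d2 <- vapply(seq_len(nrow(centers)), function(g) {
    rowSums(sweep(X, 2, centers[g, ])^2)
  }, numeric(nrow(X)))
  if (!is.matrix(d2)) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}

#' Mean silhouette width of a clustering
#'
#' For each sample, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to any other cluster; the
#' sample's silhouette is `(b - a) / max(a, b)`. Singleton-cluster samples
#' contribute 0, as does the degenerate `a = b = 0` case. The score is the
#' mean over all samples and lies in [-1, 1].
#'
#' @param x A [qsar_table] or numeric matrix.
#' @param assignments Integer cluster labels (at least 2 distinct).
#' @return The mean silhouette width.
#' @export
silhouette_score <- function(x, assignments) {
  X <- if (is.matrix(x)) x else descriptor_matrix(x)
  labs <- unique(assignments)
  if (length(labs) < 2) stop("silhouette needs at least 2 clusters",
                             call. = FALSE)
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  sizes <- table(factor(assignments, levels = labs))
  # mean distance from every point to every cluster, n x k
  M <- vapply(labs, function(g) {
    rowSums(D[, assignments == g, drop = FALSE])
  }, numeric(n))
  for (i in seq_len(n)) {
    g <- match(assignments[i], labs)
    ng <- sizes[[g]]
    if (ng == 1) { s[i] <- 0; next }
    a <- M[i, g] / (ng - 1)
    b <- min(M[i, -g] / as.numeric(sizes[-g]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of clusters by the silhouette method
#'
#' Scans `k` over `[k_min, k_max]`, fitting [fit_kmeans()] at each `k`, and
#' returns the `k` with the largest mean silhouette width (smallest `k` on
#' ties). `k_max` is clamped to `n - 1` with a message when necessary.
#'
#' @param x A [qsar_table] or matrix.
#' @param k_min,k_max Scan range (defaults 2 and 10).
#' @param seed,n_init Forwarded to [fit_kmeans()].
#' @return The chosen `k` (integer), with the silhouette profile as
#'   attribute `profile`.
#' @export
choose_k <- function(x, k_min = 2L, k_max = 10L, seed = 1L, n_init = 10L) {
  X <- if (is.matrix(x)) x else descriptor_matrix(x)
  n <- nrow(X)
  if (k_max >= n) {
    message("k_max clamped to n - 1 = ", n - 1)
    k_max <- n - 1L
  }
  ks <- seq.int(max(2L, k_min), k_max)
  sil <- vapply(ks, function(k) {
    fit_kmeans(X, k, seed = seed + k, n_init = n_init)$silhouette
  }, numeric(1))
  if (max(sil) < 0.25) {
    message("best silhouette ", signif(max(sil), 3),
            " is low; the data may not be clustered")
  }
  best <- ks[which.max(sil)]   # which.max takes the first (smallest k) tie
  attr(best, "profile") <- tibble::tibble(k = ks, silhouette = sil)
  best
}

#' Per-cluster covering stretch
#'
#' The average Euclidean distance between each member point and its cluster
#' center, per cluster — the "stretch variation" hint consumed when XCSF
#' covers a new input. A singleton cluster's 0 is replaced by the global
#' fallback (the mean over non-singleton clusters), which is also returned
#' as attribute `fallback` for use when a query point's cluster is
#' ambiguous.
#'
#' @param model A `cluster_model` from [fit_kmeans()].
#' @return Numeric length-k vector with attribute `fallback`.
#' @export
cluster_stretch <- function(model) {
  md <- model$mean_dist
  single <- model$sizes == 1
  fallback <- if (all(single)) NA_real_ else mean(md[!single])
  if (any(single)) {
    message(sum(single), " singleton cluster(s); stretch replaced by the ",
            "global fallback")
    md[single] <- fallback
  }
  attr(md, "fallback") <- fallback
  md
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("K-means model: k =", x$k, " sse =", signif(x$sse, 5),
      " silhouette =", signif(x$silhouette, 4), "\n")
  cat("sizes:", x$sizes, "\n")
  invisible(x)
}

#' @rdname fit_kmeans
#' @param model,object A `cluster_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cluster_model <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$k), size = x$sizes,
                 mean_dist = x$mean_dist)
}

#' @rdname fit_kmeans
#' @exportS3Method generics::glance
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, sse = x$sse, silhouette = x$silhouette)
}
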