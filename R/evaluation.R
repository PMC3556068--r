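#' k-fold partition of sample indices
#'
#' Randomly partitions `1:n` into `k` disjoint folds whose sizes differ by
#' at most one (the first `n %% k` folds get the extra sample), e.g.
#' n = 658, k = 10 gives eight folds of 66 and two of 65. Deterministic
#' given the seed.
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed.
#' @return A list of `k` integer index vectors.
#' @export
kfold_split <- function(n, k, seed = 1L) {
  if (k > n) stop("k must not exceed n", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  withr::local_seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(idx, rep(seq_len(k), times = sizes))
}

#' Mean squared error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return Mean of squared residuals.
#' @export
mse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch", call. = FALSE)
  }
  mean((y_true - y_pred)^2)
}

#' Model specifications for the cross-validation harness
#'
#' Each `model_*()` returns a specification consumed by [cross_validate()]:
#' a name, a repetition count (per-fold results are averaged over `reps`
#' differently-seeded runs; the XCSF default is 20 because its covering and
#' GA are stochastic, while MLR is deterministic), and fit/predict hooks.
#' The XCSF spec runs K-means on each training fold first — K chosen by the
#' silhouette scan unless `k` is fixed — and feeds the cluster stretch to
#' covering.
#'
#' @param params An [xcsf_params()] object.
#' @param epochs Training epochs per XCSF run.
#' @param k Fixed cluster count, or `NULL` to choose by silhouette.
#' @param k_range Silhouette scan range when `k` is `NULL`.
#' @param reps Repetitions per fold.
#' @param hidden,hidden_grid See [fit_ann()].
#' @return A `model_spec` list.
#' @export
model_mlr <- function(reps = 1L) {
  new_model_spec("MLR", reps,
                 fit = function(train, seed) fit_mlr(train),
                 predict = function(fit, test) predict(fit, test)$.pred)
}

#' @rdname model_mlr
#' @export
model_ann <- function(hidden = "auto", hidden_grid = 2:15, reps = 1L) {
  new_model_spec("ANN", reps,
                 fit = function(train, seed) {
                   fit_ann(train, hidden = hidden, hidden_grid = hidden_grid,
                           seed = seed)
                 },
                 predict = function(fit, test) predict(fit, test)$.pred)
}

#' @rdname model_mlr
#' @export
model_xcsf <- function(params = xcsf_params(), epochs = 50L, k = NULL,
                       k_range = c(2L, 10L), reps = 20L) {
  new_model_spec("XCSF", reps,
                 fit = function(train, seed) {
                   X <- descriptor_matrix(train)
                   kk <- if (is.null(k)) {
                     suppressMessages(
                       choose_k(X, k_range[1], k_range[2], seed = seed))
                   } else k
                   cm <- fit_kmeans(X, kk, seed = seed)
                   xcsf(train, params = params, clusters = cm,
                        epochs = epochs, seed = seed)
                 },
                 predict = function(fit, test) predict(fit, test)$.pred)
}

new_model_spec <- function(name, reps, fit, predict) {
  structure(list(name = name, reps = as.integer(reps), fit = fit,
                 predict = predict), class = "model_spec")
}

#' Cross-validated model comparison
#'
#' Runs k-fold cross-validation over a set of model specifications. Inside
#' each fold the descriptor scaler is fitted on the training part only and
#' applied to the held-out part with training statistics (no leakage);
#' every model is fitted on the scaled training fold and scored by test-fold
#' MSE, averaged over the specification's repetition count with derived
#' seeds. Stochastic preprocessing (K-means, silhouette scan) happens
#' inside the fold as part of the fit.
#'
#' @param data A [qsar_table] (unnormalized; scaling happens per fold).
#' @param models List of `model_spec`s, e.g.
#'   `list(model_mlr(), model_ann(), model_xcsf())`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the partition and all model seeds.
#' @param scale_method Passed to [fit_scaler()].
#' @return A `cv_report` with `fold_mse` (tibble fold x model), `summary`
#'   (mean and sample SD per model) and `pairwise` (paired t-tests).
#' @export
cross_validate <- function(data, models, k = 10L, seed = 1L,
                           scale_method = "minmax01") {
  stopifnot(length(models) >= 1)
  names(models) <- vapply(models, `[[`, character(1), "name")
  folds <- kfold_split(nrow(data), k, seed = seed)
  fold_mse <- matrix(NA_real_, k, length(models),
                     dimnames = list(NULL, names(models)))
  dat <- tibble::as_tibble(data)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train <- restore_qsar(dat[-test_idx, ], data)
    test <- restore_qsar(dat[test_idx, ], data)
    scaler <- fit_scaler(train, scale_method)
    train <- suppressWarnings(normalize_descriptors(train, scaler))
    test <- suppressWarnings(normalize_descriptors(test, scaler))
    y_test <- activity_values(test)
    for (mname in names(models)) {
      spec <- models[[mname]]
      errs <- vapply(seq_len(spec$reps), function(r) {
        rep_seed <- (seed * 1000L + f * 100L + r) %% .Machine$integer.max
        fit <- spec$fit(train, rep_seed)
        mse(y_test, spec$predict(fit, test))
      }, numeric(1))
      fold_mse[f, mname] <- mean(errs)
    }
  }
  fold_tbl <- dplyr::bind_cols(tibble::tibble(fold = seq_len(k)),
                               tibble::as_tibble(fold_mse))
  new_cv_report(fold_tbl, seed = seed)
}

new_cv_report <- function(fold_tbl, seed = NA_integer_, alpha = 0.05) {
  structure(list(fold_mse = fold_tbl,
                 summary = summarize_folds(fold_tbl),
                 pairwise = pairwise_tests(fold_tbl),
                 seed = seed, alpha = alpha),
            class = "cv_report")
}

#' Summarize per-fold MSEs
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' each model's per-fold MSE column.
#'
#' @param fold_tbl A tibble with a `fold` column and one numeric column per
#'   model, or the `fold_mse` element of a `cv_report`.
#' @return A tibble with columns `model`, `mean`, `sd`.
#' @export
summarize_folds <- function(fold_tbl) {
  cols <- setdiff(names(fold_tbl), "fold")
  if (nrow(fold_tbl) < 2) stop("need >= 2 folds for a sample SD",
                               call. = FALSE)
  tibble::tibble(
    model = cols,
    mean = unname(vapply(fold_tbl[cols], mean, numeric(1))),
    sd = unname(vapply(fold_tbl[cols], sd, numeric(1))))
}

#' Paired t-test on two per-fold error vectors
#'
#' Two-sided paired Student t-test on the per-fold differences
#' (df = n - 1), the convention used to compare cross-validated models on
#' the same folds.
#'
#' @param a,b Equal-length (>= 2) numeric vectors of per-fold errors.
#' @return A tibble with `t`, `df`, `p`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (var(a - b) == 0) {
    warning("zero-variance differences; p set to the edge case",
            call. = FALSE)
    return(tibble::tibble(t = 0, df = length(a) - 1,
                          p = if (all(a == b)) 1 else 0))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

pairwise_tests <- function(fold_tbl) {
  cols <- setdiff(names(fold_tbl), "fold")
  if (length(cols) < 2) {
    return(tibble::tibble(model_a = character(0), model_b = character(0),
                          t = numeric(0), df = numeric(0), p = numeric(0)))
  }
  pairs <- utils::combn(cols, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dplyr::bind_cols(tibble::tibble(model_a = a, model_b = b),
                     paired_t_test(fold_tbl[[a]], fold_tbl[[b]]))
  })
}

#' Significance table for a cross-validation report
#'
#' Marks each model pair significant iff p < alpha (strict), rendered with
#' the conventional delta/dash state column.
#'
#' @param report A `cv_report` (or its `pairwise` tibble).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `pair`, `p`, `alpha`, `significant`, `state`.
#' @export
significance_table <- function(report, alpha = 0.05) {
  pw <- if (inherits(report, "cv_report")) report$pairwise else report
  tibble::tibble(
    pair = paste(pw$model_a, "&", pw$model_b),
    p = pw$p, alpha = alpha,
    significant = pw$p < alpha,
    state = ifelse(pw$p < alpha, "Δ", "-"))
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report (", nrow(x$fold_mse), " folds)\n", sep = "")
  print(x$summary)
  cat("\nPairwise paired t-tests:\n")
  print(significance_table(x, x$alpha))
  invisible(x)
}

#' @rdname cross_validate
#' @param x,object A `cv_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) {
  tidyr::pivot_longer(x$fold_mse, -"fold", names_to = "model",
                      values_to = "mse")
}

#' @rdname cross_validate
#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "model",
                     values_from = c("mean", "sd"))
}

#' Per-fold MSE profile plot
#'
#' Line plot of test-fold MSE versus fold index for every compared model —
#' the visual companion of the cross-validation report.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$fold, .data$mse,
                               colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$fold_mse$fold) +
    ggplot2::labs(x = "fold", y = "test MSE", colour = NULL,
                  title = "Per-fold test MSE by model") +
    ggplot2::theme_minimal()
}
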