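#' Multiple linear regression baseline
#'
#' Ordinary least squares of activity on all descriptors via the QR
#' decomposition (`stats::lm`); exact on full-rank designs, minimum-norm
#' (with a warning) on rank-deficient ones. This is the global linear
#' comparator for the piecewise-linear XCSF model.
#'
#' @param data A [qsar_table].
#' @return An `mlr_model` wrapping the `lm` fit, with `training_mse`.
#' @export
fit_mlr <- function(data) {
  desc <- descriptors(data)
  df <- tibble::as_tibble(data)[desc]
  df$.y <- activity_values(data)
  fit <- stats::lm(make_formula(desc), data = df)
  if (any(is.na(coef(fit)))) {
    warning("rank-deficient design; aliased coefficients set to zero",
            call. = FALSE)
  }
  structure(list(fit = fit, descriptors = desc,
                 training_mse = mean(stats::residuals(fit)^2)),
            class = "mlr_model")
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  df <- if (is.matrix(newdata)) {
    stats::setNames(tibble::as_tibble(newdata, .name_repair = "minimal"),
                    object$descriptors)
  } else {
    tibble::as_tibble(newdata)[object$descriptors]
  }
  co <- coef(object$fit)
  co[is.na(co)] <- 0
  tibble::tibble(.pred = as.vector(
    cbind(1, as.matrix(df)) %*% co))
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("MLR baseline on", length(x$descriptors), "descriptors; training MSE",
      signif(x$training_mse, 4), "\n")
  invisible(x)
}

#' @rdname fit_mlr
#' @param x,object An `mlr_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mlr_model <- function(x, ...) {
  sm <- stats::coef(summary(x$fit))
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4])
}

#' @rdname fit_mlr
#' @exportS3Method generics::glance
glance.mlr_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared,
                 adj.r.squared = sm$adj.r.squared,
                 training_mse = x$training_mse,
                 df.residual = x$fit$df.residual)
}

#' Feed-forward neural-network baseline
#'
#' A three-layer perceptron (d-H-1: logistic hidden units, linear output)
#' fitted with `nnet::nnet`. An internal validation split of the training
#' data emulates the trial-and-error tuning of the hidden layer: when
#' `hidden = "auto"` each size in `hidden_grid` is trained on the sub-train
#' part and the size with the smallest validation MSE is kept. A small
#' weight decay regularizes in place of iteration-count early stopping.
#'
#' @param data A [qsar_table] (normalized descriptors recommended).
#' @param hidden `"auto"` or a fixed hidden-layer size.
#' @param hidden_grid Candidate sizes scanned when `hidden = "auto"`.
#' @param validation_frac Fraction of rows held out internally for size
#'   selection (default 0.15).
#' @param decay Weight decay passed to `nnet` (default 1e-3).
#' @param maxit Optimizer iteration cap (default 500).
#' @param seed Integer seed; fixed seed gives identical final weights.
#' @return An `ann_model`.
#' @export
fit_ann <- function(data, hidden = "auto", hidden_grid = 2:15,
                    validation_frac = 0.15, decay = 1e-3, maxit = 500,
                    seed = 1L) {
  X <- descriptor_matrix(data)
  y <- activity_values(data)
  n <- nrow(X)
  withr::local_seed(seed)
  sizes <- if (identical(hidden, "auto")) hidden_grid else as.integer(hidden)
  if (any(sizes < 1)) stop("hidden size must be >= 1", call. = FALSE)
  val <- sample.int(n, max(2, round(validation_frac * n)))
  tr <- setdiff(seq_len(n), val)
  best <- NULL
  for (H in sizes) {
    net <- nnet::nnet(X[tr, , drop = FALSE], y[tr], size = H, linout = TRUE,
                      decay = decay, maxit = maxit, trace = FALSE)
    vmse <- mean((y[val] - as.vector(stats::predict(net,
                                                    X[val, , drop = FALSE])))^2)
    if (is.null(best) || vmse < best$vmse) {
      best <- list(net = net, vmse = vmse, H = H)
    }
  }
  structure(list(net = best$net, hidden = best$H,
                 validation_mse = best$vmse,
                 descriptors = colnames(X),
                 training_mse = mean((y[tr] -
                   as.vector(stats::predict(best$net,
                                            X[tr, , drop = FALSE])))^2)),
            class = "ann_model")
}

#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else descriptor_matrix(newdata)
  if (ncol(X) != length(object$descriptors)) {
    stop("dimension mismatch", call. = FALSE)
  }
  tibble::tibble(.pred = as.vector(stats::predict(object$net, X)))
}

#' @export
print.ann_model <- function(x, ...) {
  cat("ANN baseline ", length(x$descriptors), "-", x$hidden, "-1; ",
      "validation MSE ", signif(x$validation_mse, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_ann
#' @param x,object An `ann_model`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ann_model <- function(x, ...) {
  tibble::tibble(hidden = x$hidden, validation_mse = x$validation_mse,
                 training_mse = x$training_mse,
                 n_weights = length(x$net$wts))
}
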