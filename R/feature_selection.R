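#' @importFrom stats cor lm add1 drop1 coef sd var
NULL

new_selection_report <- function(step, kept, removed, thresholds) {
  tibble::tibble(
    step = step,
    n_before = length(kept) + length(removed),
    n_after = length(kept),
    removed = list(removed),
    kept = list(kept),
    thresholds = list(thresholds))
}

append_report <- function(out, x, report) {
  attr(out, "selection") <- dplyr::bind_rows(attr(x, "selection"), report)
  out
}

drop_descriptors <- function(x, removed) {
  out <- tibble::as_tibble(x)[setdiff(names(x), removed)]
  restore_qsar(out, x)
}

#' Per-step feature-selection history
#'
#' @param x A [qsar_table] that has passed through one or more selection
#'   steps.
#' @return A tibble with one row per step: `step`, `n_before`, `n_after`,
#'   and list-columns `removed`, `kept`, `thresholds`.
#' @export
selection_history <- function(x) attr(x, "selection")

#' Remove near-constant descriptors
#'
#' Step 1 of the four-step descriptor reduction: a descriptor is removed iff
#' its modal value's relative frequency strictly exceeds
#' `constant_fraction` (default 0.8, i.e. "more than 80% constant").
#'
#' @param x A [qsar_table].
#' @param constant_fraction Modal-frequency threshold in (0, 1].
#' @return The reduced [qsar_table]; see [selection_history()] for the
#'   report.
#' @export
filter_near_constant <- function(x, constant_fraction = 0.8) {
  desc <- descriptors(x)
  if (!length(desc) || !nrow(x)) stop("empty table", call. = FALSE)
  mode_freq <- vapply(desc, function(d) {
    max(table(x[[d]])) / nrow(x)
  }, numeric(1))
  removed <- desc[mode_freq > constant_fraction]
  rep <- new_selection_report("near_constant", setdiff(desc, removed),
                              removed,
                              list(constant_fraction = constant_fraction))
  append_report(drop_descriptors(x, removed), x, rep)
}

# Pearson r of each descriptor against y; constant columns get r = 0.
target_correlations <- function(x) {
  y <- activity_values(x)
  X <- descriptor_matrix(x)
  r <- suppressWarnings(as.vector(cor(X, y)))
  r[is.na(r)] <- 0
  stats::setNames(r, colnames(X))
}

#' Keep descriptors correlated with activity
#'
#' Step 2: keep descriptor j iff |Pearson r(X_j, y)| >= `min_abs_r`
#' (default 0.7). The absolute value is used because a strong negative
#' correlate is as informative as a positive one; set `use_abs = FALSE` to
#' threshold the signed correlation instead. Constant descriptors are
#' treated as r = 0 and removed.
#'
#' @param x A [qsar_table].
#' @param min_abs_r Correlation threshold.
#' @param use_abs Threshold |r| (default) or signed r.
#' @return The reduced [qsar_table].
#' @export
filter_target_correlation <- function(x, min_abs_r = 0.7, use_abs = TRUE) {
  if (var(activity_values(x)) == 0) {
    stop("activity has zero variance", call. = FALSE)
  }
  r <- target_correlations(x)
  score <- if (use_abs) abs(r) else r
  removed <- names(r)[score < min_abs_r]
  rep <- new_selection_report("target_correlation",
                              setdiff(names(r), removed), removed,
                              list(min_abs_r = min_abs_r, use_abs = use_abs))
  append_report(drop_descriptors(x, removed), x, rep)
}

#' Remove cross-correlated descriptors
#'
#' Step 3: greedy de-duplication. Survivors are ranked by |r(X_j, y)|
#' descending (ties broken by column order) and scanned in rank order; a
#' descriptor is dropped when its |pairwise r| with an already-kept one
#' exceeds `max_abs_r` (default 0.7). Deterministic: of a correlated pair
#' the better target-correlate survives.
#'
#' @param x A [qsar_table].
#' @param max_abs_r Pairwise-correlation threshold.
#' @return The reduced [qsar_table].
#' @export
filter_cross_correlation <- function(x, max_abs_r = 0.7) {
  desc <- descriptors(x)
  if (length(desc) < 2) {
    rep <- new_selection_report("cross_correlation", desc, character(0),
                                list(max_abs_r = max_abs_r))
    return(append_report(drop_descriptors(x, character(0)), x, rep))
  }
  r_y <- abs(target_correlations(x))
  ord <- order(-r_y, seq_along(desc))   # rank by |r|, ties by column order
  X <- descriptor_matrix(x)
  C <- suppressWarnings(abs(cor(X)))
  C[is.na(C)] <- 0
  kept_idx <- integer(0)
  for (j in ord) {
    if (!length(kept_idx) || all(C[j, kept_idx] <= max_abs_r)) {
      kept_idx <- c(kept_idx, j)
    }
  }
  kept <- desc[sort(kept_idx)]
  removed <- setdiff(desc, kept)
  rep <- new_selection_report("cross_correlation", kept, removed,
                              list(max_abs_r = max_abs_r))
  append_report(drop_descriptors(x, removed), x, rep)
}

#' Stepwise multiple linear regression selection
#'
#' Step 4: classic bidirectional (forward-backward) stepwise selection on
#' partial-F p-values. At each round the candidate with the smallest
#' entry p-value below `p_enter` is added, then any included variable whose
#' removal p-value exceeds `p_remove` is dropped (worst first); the loop
#' stops when neither move applies or `max_vars` is reached. Candidates that
#' make the design rank-deficient are skipped. The OLS fit on the final set
#' and its training MSE are attached.
#'
#' @param x A [qsar_table].
#' @param p_enter Partial-F p-value to enter (default 0.05).
#' @param p_remove Partial-F p-value to remove (default 0.10).
#' @param max_vars Optional cap on the number of selected descriptors.
#' @return The reduced [qsar_table] with attributes `model` (the `lm` fit)
#'   and `training_mse`.
#' @export
stepwise_mlr <- function(x, p_enter = 0.05, p_remove = 0.10, max_vars = NULL) {
  desc <- descriptors(x)
  y <- activity_values(x)
  df <- tibble::as_tibble(x)[desc]
  df$.y <- y
  selected <- character(0)
  repeat {
    fit <- lm(make_formula(selected), data = df)
    pool <- setdiff(desc, selected)
    added <- FALSE
    if (length(pool) && (is.null(max_vars) || length(selected) < max_vars)) {
      a1 <- add1(fit, scope = make_formula(union(selected, pool)), test = "F")
      pv <- a1[["Pr(>F)"]][-1]
      names(pv) <- rownames(a1)[-1]
      pv <- pv[!is.na(pv)]   # NA = rank-deficient candidate, skipped
      if (length(pv) && min(pv) < p_enter) {
        selected <- c(selected, names(pv)[which.min(pv)])
        fit <- lm(make_formula(selected), data = df)
        added <- TRUE
      }
    }
    # backward pass: drop while the worst included variable exceeds p_remove
    repeat {
      if (length(selected) < 1) break
      d1 <- drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]][-1]
      names(pv) <- rownames(d1)[-1]
      if (!length(pv) || max(pv, na.rm = TRUE) <= p_remove) break
      worst <- names(pv)[which.max(pv)]
      selected <- setdiff(selected, worst)
      fit <- lm(make_formula(selected), data = df)
    }
    if (!added) break
  }
  fit <- lm(make_formula(selected), data = df)
  removed <- setdiff(desc, selected)
  rep <- new_selection_report("stepwise_mlr", selected, removed,
                              list(p_enter = p_enter, p_remove = p_remove,
                                   max_vars = max_vars))
  out <- append_report(drop_descriptors(x, removed), x, rep)
  attr(out, "model") <- fit
  attr(out, "training_mse") <- mean(stats::residuals(fit)^2)
  out
}

# env must contain the model data so add1/drop1 can re-evaluate the fit
make_formula <- function(vars, env = parent.frame()) {
  rhs <- if (length(vars)) paste(sprintf("`%s`", vars), collapse = " + ")
         else "1"
  stats::as.formula(paste(".y ~", rhs), env = env)
}

#' PCA-based representative descriptor selection
#'
#' Principal component analysis on the correlation matrix of the surviving
#' descriptors; components are retained by the Kaiser rule
#' (eigenvalue > 1) or as a fixed count. For each retained component, in
#' order of decreasing eigenvalue, the single descriptor with the largest
#' absolute loading not already chosen is selected (ties broken by column
#' order), yielding one representative per component.
#'
#' @param x A [qsar_table] (at least 2 descriptors).
#' @param n_components `"kaiser"` or an integer number of components.
#' @return The reduced [qsar_table]; attribute `loadings` holds the full
#'   loading matrix.
#' @export
pca_reduce <- function(x, n_components = "kaiser") {
  desc <- descriptors(x)
  if (length(desc) < 2) stop("need at least 2 descriptors", call. = FALSE)
  X <- descriptor_matrix(x)
  keep_sd <- apply(X, 2, sd) > 0
  if (!all(keep_sd)) {
    warning("constant descriptor(s) excluded from PCA: ",
            paste(desc[!keep_sd], collapse = ", "), call. = FALSE)
  }
  Xv <- X[, keep_sd, drop = FALSE]
  eg <- eigen(cor(Xv), symmetric = TRUE)
  if (identical(n_components, "kaiser")) {
    k <- max(1L, sum(eg$values > 1))
  } else {
    k <- as.integer(n_components)
    if (k > ncol(Xv)) stop("n_components exceeds descriptor count",
                           call. = FALSE)
  }
  loadings <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(Xv)
  chosen <- character(0)
  for (j in seq_len(k)) {
    load_j <- abs(loadings[, j])
    load_j[chosen] <- -Inf
    chosen <- c(chosen, names(load_j)[which.max(load_j)])
  }
  kept <- desc[desc %in% chosen]
  removed <- setdiff(desc, kept)
  rep <- new_selection_report("pca_reduce", kept, removed,
                              list(n_components = n_components,
                                   retained = k))
  out <- append_report(drop_descriptors(x, removed), x, rep)
  attr(out, "loadings") <- loadings
  out
}

#' Run the full descriptor-reduction pipeline
#'
#' Applies, in order: the near-constancy filter, the activity-correlation
#' filter, the cross-correlation filter, stepwise MLR selection and the
#' PCA representative step. Composing the steps is identical to calling
#' them sequentially; each contributes a row to [selection_history()].
#'
#' @param x A [qsar_table].
#' @param constant_fraction,min_abs_r,max_abs_r,p_enter,p_remove,max_vars,n_components
#'   Thresholds forwarded to the individual steps.
#' @return The reduced [qsar_table].
#' @export
select_features <- function(x, constant_fraction = 0.8, min_abs_r = 0.7,
                            max_abs_r = 0.7, p_enter = 0.05, p_remove = 0.10,
                            max_vars = NULL, n_components = "kaiser") {
  out <- x |>
    filter_near_constant(constant_fraction) |>
    filter_target_correlation(min_abs_r) |>
    filter_cross_correlation(max_abs_r) |>
    stepwise_mlr(p_enter, p_remove, max_vars)
  if (length(descriptors(out)) >= 2) out <- pca_reduce(out, n_components)
  out
}
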