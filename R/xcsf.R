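#' XCSF hyperparameters
#'
#' Bundles every tunable of the XCSF function-approximation engine. The
#' geometry is fixed to axis-parallel hyperellipsoidal conditions; the local
#' predictor is linear, updated either by recursive least squares (`"rls"`,
#' the default) or by the normalized delta rule (`"delta"`).
#'
#' @param pop_limit Micro-population bound N (sum of numerosities;
#'   default 30).
#' @param theta_mna Minimum match-set size before covering stops (default 1).
#' @param theta_ga GA firing threshold on the mean match-set age (default 50).
#' @param beta Learning rate for error, fitness and set-size estimates
#'   (default 0.2).
#' @param eta Correction rate of the delta-rule predictor (default 0.2).
#' @param x0 Constant input augmenting every state vector (default 1;
#'   must be nonzero).
#' @param eps0 Target error below which a rule counts as accurate, in
#'   activity units (default 0.05). Set this at the irreducible noise level
#'   of the activity: below it, the accuracy function cannot separate
#'   converged rules from newborns whose short error trace is transiently
#'   small, which destabilizes selection.
#' @param alpha,nu Accuracy-function constants (defaults 0.1, 5).
#' @param p_c Crossover probability (default 0.8).
#' @param p_m Per-allele mutation probability (default 0.04).
#' @param theta_del Deletion experience threshold (default 20).
#' @param delta_del Deletion fitness fraction (default 0.1).
#' @param cover_range Fallback covering stretch on the unit cube when no
#'   cluster hint is available (default 0.17).
#' @param stretch_span Factor converting a cluster's mean point-to-center
#'   distance into the covering stretch (default 2). A condition is
#'   centered on a member point, which sits about one mean radius from the
#'   cluster center, so reaching across the whole cluster needs about
#'   twice the mean radius.
#' @param predictor `"rls"` or `"delta"`.
#' @param rls_delta_init Initial diagonal of the RLS covariance
#'   (default 1000).
#' @param rls_lambda RLS forgetting factor (default 1 = no forgetting).
#' @param eps_init,fit_init Error and fitness of covering-born rules
#'   (defaults 0 and 0.01).
#' @return A list of class `xcsf_params`.
#' @export
xcsf_params <- function(pop_limit = 30L, theta_mna = 1L, theta_ga = 50,
                        beta = 0.2, eta = 0.2, x0 = 1, eps0 = 0.05,
                        alpha = 0.1, nu = 5, p_c = 0.8, p_m = 0.04,
                        theta_del = 20, delta_del = 0.1, cover_range = 0.17,
                        stretch_span = 2,
                        predictor = c("rls", "delta"),
                        rls_delta_init = 1000, rls_lambda = 1,
                        eps_init = 0, fit_init = 0.01) {
  predictor <- match.arg(predictor)
  stopifnot(pop_limit >= theta_mna, theta_mna >= 1, cover_range > 0,
            stretch_span > 0,
            x0 != 0, beta > 0, beta <= 1, p_c >= 0, p_c <= 1,
            p_m >= 0, p_m <= 1, rls_lambda > 0, rls_lambda <= 1)
  structure(as.list(environment()), class = "xcsf_params")
}

#' Elementary XCSF rule arithmetic
#'
#' The stateless building blocks of the engine, exposed for inspection and
#' testing. `xcsf_matches()` is the hyperellipsoid membership test:
#' a condition with center `c` and semi-axes `stretch` matches state `s` iff
#' `sum(((s - c)/stretch)^2) <= 1`. `classifier_prediction()` is the local
#' linear model `w0*x0 + sum(w[i]*s[i])`. `system_prediction()` combines
#' match-set predictions by the fitness-weighted (and numerosity-weighted)
#' average.
#'
#' @param center,stretch Condition center and strictly positive semi-axes
#'   (equal length d).
#' @param s Input state (length d).
#' @param w Weight vector of length d + 1 (bias first).
#' @param x0 Constant input paired with the bias weight.
#' @param p,fitness,num Per-member predictions, fitnesses and numerosities.
#' @return `xcsf_matches()` a logical; the predictions a numeric scalar.
#' @export
xcsf_matches <- function(center, stretch, s) {
  if (length(s) != length(center)) stop("dimension mismatch", call. = FALSE)
  sum(((s - center) / stretch)^2) <= 1
}

#' @rdname xcsf_matches
#' @export
classifier_prediction <- function(w, s, x0 = 1) {
  sum(w * c(x0, s))
}

#' @rdname xcsf_matches
#' @export
system_prediction <- function(p, fitness, num = rep(1, length(p))) {
  if (!length(p)) {
    stop("empty match set: covering must precede prediction", call. = FALSE)
  }
  sum(fitness * num * p) / sum(fitness * num)
}

#' Local-model and bookkeeping updates
#'
#' `update_weights_delta()` is the normalized delta rule (NLMS): with
#' augmented input `a = c(x0, s)`, `w <- w + eta/||a||^2 * (P - w.a) * a`.
#' `update_weights_rls()` is the recursive-least-squares update with gain
#' `k = V a / (lambda + a' V a)`. `update_error()` is the Widrow-Hoff error
#' trace `eps <- eps + beta * (|P - p| - eps)`, averaged MAM-style (running
#' mean) while the rule's experience is below `1/beta`.
#' `classifier_accuracy()` maps error to accuracy: 1 when `eps < eps0`,
#' otherwise `alpha * (eps/eps0)^(-nu)`.
#'
#' @param w Weight vector (bias first).
#' @param V RLS covariance matrix, (d+1) x (d+1).
#' @param s Input state.
#' @param P Target (reward) value.
#' @param eta,x0,lambda,beta,eps0,alpha,nu See [xcsf_params()].
#' @param eps Current error estimate.
#' @param abs_err Observed absolute error |P - p|.
#' @param expc Rule experience after the current presentation.
#' @return Updated weights (`delta`), a list `w`, `V` (`rls`), the updated
#'   error, or the accuracy value.
#' @export
update_weights_delta <- function(w, s, P, eta = 0.2, x0 = 1) {
  a <- c(x0, s)
  w + (eta / sum(a * a)) * (P - sum(w * a)) * a
}

#' @rdname update_weights_delta
#' @export
update_weights_rls <- function(w, V, s, P, x0 = 1, lambda = 1) {
  a <- c(x0, s)
  Va <- as.vector(V %*% a)
  k <- Va / (lambda + sum(a * Va))
  V2 <- (V - outer(k, Va)) / lambda
  list(w = w + k * (P - sum(w * a)),
       V = (V2 + t(V2)) / 2)   # keep V symmetric against roundoff drift
}

#' @rdname update_weights_delta
#' @export
update_error <- function(eps, abs_err, beta = 0.2, expc = Inf) {
  if (expc < 1 / beta) eps + (abs_err - eps) / expc
  else eps + beta * (abs_err - eps)
}

#' @rdname update_weights_delta
#' @export
classifier_accuracy <- function(eps, eps0 = 0.01, alpha = 0.1, nu = 5) {
  ifelse(eps < eps0, 1, alpha * (eps / eps0)^(-nu))
}

## ---- population store ------------------------------------------------------
## The population lives in an environment holding parallel arrays so that
## matching is a single vectorized operation; row i of each array is one
## macro-classifier. `alive` marks occupied rows.

pop_new <- function(d, params) {
  cap <- params$pop_limit + 4L
  e <- new.env(parent = emptyenv())
  e$d <- d
  e$centers <- matrix(NA_real_, cap, d)
  e$stretch <- matrix(NA_real_, cap, d)
  e$W <- matrix(0, cap, d + 1)
  e$V <- if (params$predictor == "rls") array(0, c(d + 1, d + 1, cap))
  e$eps <- numeric(cap)
  e$fit <- numeric(cap)
  e$num <- integer(cap)
  e$expc <- numeric(cap)
  e$ts <- numeric(cap)
  e$as_size <- numeric(cap)
  e$alive <- logical(cap)
  e
}

pop_grow <- function(pop, params) {
  add <- 8L
  d <- pop$d
  pop$centers <- rbind(pop$centers, matrix(NA_real_, add, d))
  pop$stretch <- rbind(pop$stretch, matrix(NA_real_, add, d))
  pop$W <- rbind(pop$W, matrix(0, add, d + 1))
  if (!is.null(pop$V)) {
    V2 <- array(0, c(d + 1, d + 1, nrow(pop$centers)))
    V2[, , seq_len(dim(pop$V)[3])] <- pop$V
    pop$V <- V2
  }
  for (f in c("eps", "fit", "expc", "ts", "as_size")) {
    pop[[f]] <- c(pop[[f]], numeric(add))
  }
  pop$num <- c(pop$num, integer(add))
  pop$alive <- c(pop$alive, logical(add))
}

pop_insert <- function(pop, center, stretch, w, eps, fit, num, expc, ts,
                       as_size, params) {
  i <- which(!pop$alive)[1]
  if (is.na(i)) {
    pop_grow(pop, params)
    i <- which(!pop$alive)[1]
  }
  pop$centers[i, ] <- center
  pop$stretch[i, ] <- stretch
  pop$W[i, ] <- w
  if (!is.null(pop$V)) {
    pop$V[, , i] <- diag(params$rls_delta_init, pop$d + 1)
  }
  pop$eps[i] <- eps
  pop$fit[i] <- fit
  pop$num[i] <- num
  pop$expc[i] <- expc
  pop$ts[i] <- ts
  pop$as_size[i] <- as_size
  pop$alive[i] <- TRUE
  i
}

pop_micro_size <- function(pop) sum(pop$num[pop$alive])

# indices of alive classifiers whose ellipsoid contains s
pop_match <- function(pop, s) {
  idx <- which(pop$alive)
  if (!length(idx)) return(integer(0))
  z <- (pop$centers[idx, , drop = FALSE] -
          rep(s, each = length(idx))) / pop$stretch[idx, , drop = FALSE]
  idx[rowSums(z * z) <= 1]
}

# ellipsoid (Mahalanobis-style) distance of s to every alive condition
pop_cond_dist <- function(pop, s) {
  idx <- which(pop$alive)
  z <- (pop$centers[idx, , drop = FALSE] -
          rep(s, each = length(idx))) / pop$stretch[idx, , drop = FALSE]
  stats::setNames(rowSums(z * z), idx)
}

#' Create a covering classifier
#'
#' Builds the rule XCSF inserts when too few classifiers match the current
#' input: the condition is centered on the input with each semi-axis drawn
#' uniformly from `(0.5 r, 1.5 r]` where `r` is the covering stretch (the
#' cluster-distance hint when available, else `cover_range`); the weight
#' vector starts at zero and the other parameters at their initial values.
#'
#' @param s The input state to cover.
#' @param stretch_hint Covering stretch `r`, or `NULL` to use
#'   `params$cover_range`.
#' @param params An [xcsf_params()] object.
#' @param ts Birth timestamp.
#' @return A list with the new rule's fields (not yet inserted).
#' @export
cover_classifier <- function(s, stretch_hint = NULL, params = xcsf_params(),
                             ts = 0) {
  r <- if (is.null(stretch_hint) || is.na(stretch_hint)) params$cover_range
       else stretch_hint
  d <- length(s)
  list(center = as.numeric(s),
       stretch = stats::runif(d, 0.5 * r, 1.5 * r),
       w = numeric(d + 1),
       eps = params$eps_init, fit = params$fit_init,
       num = 1L, expc = 0, ts = ts, as_size = 1)
}

# covering loop: returns match-set indices (macro count >= theta_mna)
# and the number of covering events as attribute "n_cover"
build_match_set <- function(pop, s, t, stretch_fun, params) {
  n_cover <- 0L
  repeat {
    M <- pop_match(pop, s)
    if (length(M) >= params$theta_mna) {
      attr(M, "n_cover") <- n_cover
      return(M)
    }
    cl <- cover_classifier(s, stretch_fun(s), params, ts = t)
    pop_insert(pop, cl$center, cl$stretch, cl$w, cl$eps, cl$fit, cl$num,
               cl$expc, cl$ts, cl$as_size, params)
    delete_down(pop, params)
    n_cover <- n_cover + 1L
  }
}

## ---- deletion --------------------------------------------------------------

deletion_votes <- function(pop, params) {
  idx <- which(pop$alive)
  vote <- pop$as_size[idx] * pop$num[idx]
  fbar <- sum(pop$fit[idx]) / sum(pop$num[idx])   # mean micro-fitness
  micro_fit <- pop$fit[idx] / pop$num[idx]
  low <- pop$expc[idx] > params$theta_del & micro_fit < params$delta_del * fbar
  vote[low] <- vote[low] * fbar / micro_fit[low]
  stats::setNames(vote, idx)
}

# roulette-delete micro-classifiers until sum(num) <= pop_limit
delete_down <- function(pop, params) {
  while (pop_micro_size(pop) > params$pop_limit) {
    vote <- deletion_votes(pop, params)
    pick <- as.integer(names(vote)[roulette(vote)])
    pop$num[pick] <- pop$num[pick] - 1L
    if (pop$num[pick] == 0L) pop$alive[pick] <- FALSE
  }
  invisible(pop)
}

roulette <- function(w) {
  if (all(w <= 0)) return(sample.int(length(w), 1))
  sample.int(length(w), 1, prob = w)
}

## ---- genetic algorithm -----------------------------------------------------

ga_step <- function(pop, M, t, params) {
  nM <- pop$num[M]
  if (t - sum(pop$ts[M] * nM) / sum(nM) <= params$theta_ga) {
    return(invisible(FALSE))
  }
  pop$ts[M] <- t
  p1 <- M[roulette(pop$fit[M])]
  p2 <- M[roulette(pop$fit[M])]
  d <- pop$d
  a1 <- c(pop$centers[p1, ], pop$stretch[p1, ])
  a2 <- c(pop$centers[p2, ], pop$stretch[p2, ])
  if (stats::runif(1) < params$p_c) {
    swap <- stats::runif(2 * d) < 0.5
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  for (a in c("a1", "a2")) {
    v <- get(a)
    mut <- stats::runif(2 * d) < params$p_m
    if (any(mut)) {
      # allele scale = 1 (the unit descriptor cube) for centers and stretch
      v[mut] <- v[mut] + stats::runif(sum(mut), -0.1, 0.1)
      v[(d + 1):(2 * d)] <- pmax(v[(d + 1):(2 * d)], 1e-6)
      assign(a, v)
    }
  }
  w_off <- (pop$W[p1, ] + pop$W[p2, ]) / 2
  eps_off <- (pop$eps[p1] + pop$eps[p2]) / 2
  fit_off <- 0.1 * (pop$fit[p1] + pop$fit[p2]) / 2
  as_off <- (pop$as_size[p1] + pop$as_size[p2]) / 2
  for (a in list(a1, a2)) {
    pop_insert(pop, a[1:d], a[(d + 1):(2 * d)], w_off, eps_off, fit_off,
               1L, 0, t, as_off, params)
  }
  delete_down(pop, params)
  invisible(TRUE)
}

## ---- training --------------------------------------------------------------

#' Fit an XCSF piecewise-linear model
#'
#' Trains the rule population online: for every training sample (in a
#' freshly shuffled order each epoch) the match set is built (covering if
#' needed), the system prediction is formed as the fitness-weighted average
#' of the matching local linear models, and every match-set member receives
#' a weight update (RLS or delta rule), an error-trace update, a set-size
#' update and an accuracy-based fitness update, after which the niche
#' genetic algorithm may fire. A [fit_kmeans()] model supplies the covering
#' stretch: a covered input uses the mean point-to-center distance of its
#' nearest cluster.
#'
#' Descriptors are expected on the unit cube (see
#' [normalize_descriptors()]); `cover_range` and the mutation scale assume
#' it.
#'
#' @param data A [qsar_table] with normalized descriptors.
#' @param params An [xcsf_params()] object.
#' @param clusters Optional `cluster_model` supplying the covering-stretch
#'   hint.
#' @param epochs Number of passes over the training data (default 50).
#' @param seed Optional integer seed; the run is fully reproducible given
#'   seed, data and parameters.
#' @return An `xcsf_model`: the frozen rule population, parameters, the
#'   per-epoch online training-MSE log, and the scaler attribute of `data`
#'   (if any).
#' @export
xcsf <- function(data, params = xcsf_params(), clusters = NULL,
                 epochs = 50L, seed = NULL) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  X <- descriptor_matrix(data)
  y <- activity_values(data)
  d <- ncol(X)
  if (!is.null(seed)) withr::local_seed(seed)

  stretch_fun <- make_stretch_fun(clusters, params)
  pop <- pop_new(d, params)
  t <- 0L
  n <- nrow(X)
  log_mse <- numeric(epochs)
  log_cover <- integer(epochs)
  log_ga <- integer(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    se <- 0
    for (i in ord) {
      t <- t + 1L
      s <- X[i, ]
      P <- y[i]
      M <- build_match_set(pop, s, t, stretch_fun, params)
      log_cover[ep] <- log_cover[ep] + attr(M, "n_cover")
      a <- c(params$x0, s)
      preds <- as.vector(pop$W[M, , drop = FALSE] %*% a)
      fn <- pop$fit[M] * pop$num[M]
      se <- se + (P - sum(fn * preds) / sum(fn))^2
      update_match_set(pop, M, s, a, P, preds, params)
      if (isTRUE(ga_step(pop, M, t, params))) log_ga[ep] <- log_ga[ep] + 1L
    }
    log_mse[ep] <- se / n
  }
  snap <- pop_snapshot(pop)
  structure(list(population = snap, params = params, d = d,
                 epochs = epochs, seed = seed,
                 descriptors = colnames(X),
                 log = tibble::tibble(epoch = seq_len(epochs),
                                      mse = log_mse,
                                      n_cover = log_cover,
                                      n_ga = log_ga),
                 scaler = attr(data, "scaler"),
                 stretch_hint = if (!is.null(clusters))
                   cluster_stretch(clusters)),
            class = "xcsf_model")
}

# Covering stretch lookup: the nearest cluster's mean point-to-center
# distance, converted to a cluster span by stretch_span (a covered rule is
# centered on a member point, not the cluster center).
make_stretch_fun <- function(clusters, params) {
  if (is.null(clusters)) return(function(s) params$cover_range)
  str_vec <- suppressMessages(cluster_stretch(clusters))
  centers <- clusters$centers
  function(s) {
    g <- which.min(rowSums(sweep(centers, 2, s)^2))
    r <- params$stretch_span * str_vec[g]
    if (is.na(r) || r <= 0) params$cover_range else r
  }
}

# one reinforcement pass over the match set; preds are pre-update
update_match_set <- function(pop, M, s, a, P, preds, params) {
  beta <- params$beta
  sum_num <- sum(pop$num[M])
  for (j in seq_along(M)) {
    m <- M[j]
    pop$expc[m] <- pop$expc[m] + 1
    if (params$predictor == "rls") {
      Va <- as.vector(pop$V[, , m] %*% a)
      k <- Va / (params$rls_lambda + sum(a * Va))
      pop$W[m, ] <- pop$W[m, ] + k * (P - preds[j])
      V2 <- (pop$V[, , m] - outer(k, Va)) / params$rls_lambda
      pop$V[, , m] <- (V2 + t(V2)) / 2
    } else {
      pop$W[m, ] <- pop$W[m, ] +
        (params$eta / sum(a * a)) * (P - preds[j]) * a
    }
    abs_err <- abs(P - sum(pop$W[m, ] * a))   # post-update prediction
    pop$eps[m] <- update_error(pop$eps[m], abs_err, beta, pop$expc[m])
    pop$as_size[m] <- if (pop$expc[m] < 1 / beta) {
      pop$as_size[m] + (sum_num - pop$as_size[m]) / pop$expc[m]
    } else {
      pop$as_size[m] + beta * (sum_num - pop$as_size[m])
    }
  }
  kappa <- classifier_accuracy(pop$eps[M], params$eps0, params$alpha,
                               params$nu)
  rel <- kappa * pop$num[M] / sum(kappa * pop$num[M])
  pop$fit[M] <- pop$fit[M] + beta * (rel - pop$fit[M])
  invisible(pop)
}

pop_snapshot <- function(pop) {
  idx <- which(pop$alive)
  list(centers = pop$centers[idx, , drop = FALSE],
       stretch = pop$stretch[idx, , drop = FALSE],
       W = pop$W[idx, , drop = FALSE],
       eps = pop$eps[idx], fit = pop$fit[idx], num = pop$num[idx],
       expc = pop$expc[idx], as_size = pop$as_size[idx], ts = pop$ts[idx])
}

#' Predict activities with a fitted XCSF model
#'
#' For each row the stored population is matched without covering and the
#' fitness-weighted prediction is returned. When no condition contains the
#' point, the nearest condition by ellipsoid distance supplies the
#' prediction and the row is flagged as a fallback.
#'
#' @param object An `xcsf_model`.
#' @param newdata A [qsar_table] or numeric matrix on the same (normalized)
#'   scale as the training data.
#' @param ... Unused.
#' @return A tibble with columns `.pred`, `.n_matched`, `.fallback`.
#' @export
predict.xcsf_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else descriptor_matrix(newdata)
  if (ncol(X) != object$d) stop("dimension mismatch", call. = FALSE)
  sn <- object$population
  x0 <- object$params$x0
  n <- nrow(X)
  out <- tibble::tibble(.pred = numeric(n), .n_matched = integer(n),
                        .fallback = logical(n))
  for (i in seq_len(n)) {
    s <- X[i, ]
    z <- (sn$centers - rep(s, each = nrow(sn$centers))) / sn$stretch
    d2 <- rowSums(z * z)
    M <- which(d2 <= 1)
    fb <- length(M) == 0
    if (fb) M <- which.min(d2)
    a <- c(x0, s)
    preds <- as.vector(sn$W[M, , drop = FALSE] %*% a)
    out$.pred[i] <- system_prediction(preds, sn$fit[M], sn$num[M])
    out$.n_matched[i] <- if (fb) 0L else length(M)
    out$.fallback[i] <- fb
  }
  out
}

#' @export
print.xcsf_model <- function(x, ...) {
  cat("XCSF model:", nrow(x$population$centers), "rules (",
      sum(x$population$num), "micro ), d =", x$d, "\n")
  cat("final online training MSE:",
      signif(utils::tail(x$log$mse, 1), 4), "\n")
  invisible(x)
}

#' Tidy an XCSF model into a rule table
#'
#' @param x,object An `xcsf_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per macro-classifier with error, fitness,
#'   numerosity, experience and list-columns `center`, `stretch`, `weights`.
#'   `glance()`: a one-row model summary.
#' @exportS3Method generics::tidy
tidy.xcsf_model <- function(x, ...) {
  sn <- x$population
  tibble::tibble(
    rule = seq_along(sn$eps),
    error = sn$eps, fitness = sn$fit, num = sn$num, exp = sn$expc,
    center = lapply(seq_len(nrow(sn$centers)), function(i) sn$centers[i, ]),
    stretch = lapply(seq_len(nrow(sn$stretch)), function(i) sn$stretch[i, ]),
    weights = lapply(seq_len(nrow(sn$W)), function(i) sn$W[i, ]))
}

#' @rdname tidy.xcsf_model
#' @exportS3Method generics::glance
glance.xcsf_model <- function(x, ...) {
  tibble::tibble(n_rules = length(x$population$eps),
                 micro_size = sum(x$population$num),
                 mean_error = mean(x$population$eps),
                 final_train_mse = utils::tail(x$log$mse, 1),
                 epochs = x$epochs)
}

#' Plot the XCSF online training curve
#'
#' @param object An `xcsf_model`.
#' @param ... Unused.
#' @return A ggplot of online training MSE per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.xcsf_model <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(.data$epoch, .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "online training MSE",
                  title = "XCSF training curve") +
    ggplot2::theme_minimal()
}
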