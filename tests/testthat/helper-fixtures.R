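# Small in-code fixtures shared across test files.

# minimal descriptor table from a matrix + activity vector
tiny_table <- function(X, y, ...) {
  if (ncol(X)) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qsar_table(dplyr::bind_cols(tibble::as_tibble(X),
                              tibble::tibble(activity = y)), ...)
}

# two well-separated gaussian blobs in d dimensions
two_blobs <- function(n_per = 50, d = 7, sep = 0.5, sd = 0.02, seed = 1) {
  withr::local_seed(seed)
  c1 <- rep(0.25, d)
  c2 <- c1 + sep / sqrt(d)
  X <- rbind(matrix(rnorm(n_per * d, sd = sd), n_per, d) +
               rep(c1, each = n_per),
             matrix(rnorm(n_per * d, sd = sd), n_per, d) +
               rep(c2, each = n_per))
  list(X = X, labels = rep(1:2, each = n_per))
}

# brute-force Pearson correlation (two-pass formula)
brute_cor <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# O(n^2) loop silhouette, the independent oracle
brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(D[i, labels == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# train/test split helper returning normalized qsar_tables
split_normalized <- function(tab, train_frac = 0.75, seed = 1) {
  n <- nrow(tab)
  withr::local_seed(seed)
  tr <- sort(sample.int(n, round(train_frac * n)))
  te <- setdiff(seq_len(n), tr)
  dat <- tibble::as_tibble(tab)
  train <- qsar_table(dat[tr, ], activity = attr(tab, "activity"),
                      id = attr(tab, "id"))
  test <- qsar_table(dat[te, ], activity = attr(tab, "activity"),
                     id = attr(tab, "id"))
  sc <- fit_scaler(train)
  list(train = normalize_descriptors(train, sc),
       test = normalize_descriptors(test, sc),
       train_idx = tr, test_idx = te)
}
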