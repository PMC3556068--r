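#' Construct a QSAR descriptor table
#'
#' A `qsar_table` is a tibble with one row per compound, one numeric column
#' per molecular descriptor, and a designated activity column (pIC50 units,
#' i.e. -log10 molar, by default). Optional per-descriptor metadata (category
#' and dimensionality tag, mirroring how descriptor software groups its
#' output) travels with the table as an attribute.
#'
#' @param data A data frame: descriptor columns (numeric), an activity
#'   column, and optionally an identifier column.
#' @param activity Name of the activity column. Default `"activity"`.
#' @param id Name of the compound-identifier column, or `NULL` if none.
#' @param meta Optional data frame with columns `descriptor`, `category`,
#'   `dim_tag` ("1D"/"2D"/"3D"). Descriptors absent from `meta` get
#'   `"unknown"` for both.
#' @return A tibble of class `qsar_table` with attributes `activity`, `id`
#'   and `meta`.
#' @export
qsar_table <- function(data, activity = "activity", id = NULL, meta = NULL) {
  data <- tibble::as_tibble(data)
  if (!activity %in% names(data)) {
    stop("activity column '", activity, "' not found", call. = FALSE)
  }
  desc <- setdiff(names(data), c(activity, id))
  num_ok <- vapply(data[desc], is.numeric, logical(1))
  if (any(!num_ok)) {
    stop("non-numeric descriptor column(s): ",
         paste(desc[!num_ok], collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(data[[activity]])) {
    stop("activity column must be numeric", call. = FALSE)
  }
  if (anyNA(data[c(desc, activity)])) {
    bad <- which(is.na(as.matrix(data[c(desc, activity)])), arr.ind = TRUE)
    stop("missing values at row ", bad[1, 1], ", column '",
         c(desc, activity)[bad[1, 2]],
         "' (use impute = TRUE in read_descriptor_table to mean-impute)",
         call. = FALSE)
  }
  meta <- build_meta(desc, meta)
  structure(data,
            class = c("qsar_table", class(tibble::tibble())),
            activity = activity, id = id, meta = meta)
}

build_meta <- function(desc, meta) {
  out <- tibble::tibble(descriptor = desc,
                        category = "unknown", dim_tag = "unknown")
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    stopifnot(all(c("descriptor", "category", "dim_tag") %in% names(meta)))
    i <- match(out$descriptor, meta$descriptor)
    out$category[!is.na(i)] <- meta$category[i[!is.na(i)]]
    out$dim_tag[!is.na(i)] <- meta$dim_tag[i[!is.na(i)]]
  }
  out
}

#' @export
print.qsar_table <- function(x, ...) {
  cat("# qsar_table: ", nrow(x), " compounds x ",
      length(descriptors(x)), " descriptors (activity: '",
      attr(x, "activity"), "')\n", sep = "")
  NextMethod()
}

# Subsetting a qsar_table with dplyr drops attributes; restore them with
# this helper whenever rows/columns change inside the package.
restore_qsar <- function(data, template, desc = NULL) {
  qsar_table(data,
             activity = attr(template, "activity"),
             id = attr(template, "id"),
             meta = attr(template, "meta"))
}

#' Descriptor column names, matrix and activity vector
#'
#' Accessors for the three views every modelling stage needs: the descriptor
#' names, the numeric descriptor matrix `X` (compounds x descriptors) and the
#' activity vector `y`.
#'
#' @param x A `qsar_table`.
#' @return `descriptors()` a character vector; `descriptor_matrix()` a
#'   numeric matrix; `activity_values()` a numeric vector.
#' @export
descriptors <- function(x) {
  setdiff(names(x), c(attr(x, "activity"), attr(x, "id")))
}

#' @rdname descriptors
#' @export
descriptor_matrix <- function(x) {
  as.matrix(x[descriptors(x)])
}

#' @rdname descriptors
#' @export
activity_values <- function(x) {
  x[[attr(x, "activity")]]
}

#' Read a descriptor table from CSV
#'
#' Reads a comma-separated descriptor table (header row required, "." decimal
#' separator), applies the activity transform, and attaches optional
#' descriptor metadata from a sidecar CSV with columns
#' `descriptor, category, dim_tag`.
#'
#' The default transform assumes the activity column holds IC50 in molar and
#' converts to pIC50 = -log10(IC50); use `"identity"` when the activity is
#' already on a log scale.
#'
#' @param path CSV file path.
#' @param activity Name of the activity column (fatal if absent).
#' @param transform One of `"identity"`, `"pIC50"`, `"log10"`.
#' @param id Optional identifier column name.
#' @param meta Optional sidecar CSV path or data frame of metadata.
#' @param impute If `TRUE`, mean-impute missing descriptor cells instead of
#'   rejecting the file.
#' @return A [qsar_table].
#' @export
read_descriptor_table <- function(path, activity = "activity",
                                  transform = c("identity", "pIC50", "log10"),
                                  id = NULL, meta = NULL, impute = FALSE) {
  transform <- match.arg(transform)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!activity %in% names(raw)) {
    stop("activity column '", activity, "' missing from ", path, call. = FALSE)
  }
  desc <- setdiff(names(raw), c(activity, id))
  for (d in desc) {
    if (!is.numeric(raw[[d]])) {
      v <- suppressWarnings(as.numeric(raw[[d]]))
      bad <- which(is.na(v) & !is.na(raw[[d]]))
      if (length(bad)) {
        stop("non-numeric value in column '", d, "', row ", bad[1],
             ": '", raw[[d]][bad[1]], "'", call. = FALSE)
      }
      raw[[d]] <- v
    }
  }
  if (impute && anyNA(raw[desc])) {
    for (d in desc) {
      miss <- is.na(raw[[d]])
      if (any(miss)) raw[[d]][miss] <- mean(raw[[d]], na.rm = TRUE)
    }
  }
  raw[[activity]] <- switch(transform,
    identity = raw[[activity]],
    pIC50 = -log10(raw[[activity]]),
    log10 = log10(raw[[activity]]))
  if (is.character(meta)) {
    meta <- readr::read_csv(meta, show_col_types = FALSE, progress = FALSE)
  }
  qsar_table(raw, activity = activity, id = id, meta = meta)
}

#' Write a descriptor table to CSV
#'
#' Values are written at full double precision so that a write/read
#' round-trip reproduces the table to at least 12 significant digits.
#'
#' @param x A [qsar_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Fit a descriptor scaler on training data
#'
#' Records per-descriptor scaling statistics (min/max or mean/sd) so that
#' held-out data can later be scaled with training-fold statistics only,
#' never its own — the split-safe convention used throughout the
#' cross-validation harness.
#'
#' @param x A [qsar_table] (training rows).
#' @param method `"minmax01"` (default; maps the training range to `[0, 1]`),
#'   `"zscore"`, or `"none"`.
#' @return A `qsar_scaler`: tibble with one row per descriptor plus a
#'   `method` attribute.
#' @export
fit_scaler <- function(x, method = c("minmax01", "zscore", "none")) {
  method <- match.arg(method)
  if (nrow(x) < 2) stop("need at least 2 rows to fit a scaler", call. = FALSE)
  X <- descriptor_matrix(x)
  s <- tibble::tibble(
    descriptor = colnames(X),
    min = unname(apply(X, 2, min)), max = unname(apply(X, 2, max)),
    mean = unname(colMeans(X)), sd = unname(apply(X, 2, stats::sd)))
  structure(s, method = method, class = c("qsar_scaler", class(s)))
}

#' Scale descriptors to the unit interval
#'
#' Applies min-max (or z-score) scaling per descriptor. When `scaler` is
#' `NULL` it is fitted on `x` itself and attached to the result; pass a
#' scaler fitted on the training fold to scale held-out rows. Constant
#' training columns map to 0.5 (with a warning); out-of-range held-out
#' values are deliberately not clipped, so test rows can fall outside
#' `[0, 1]`.
#'
#' @param x A [qsar_table].
#' @param scaler A `qsar_scaler` from [fit_scaler()], or `NULL` to fit here.
#' @param method Scaling method, used only when fitting (see [fit_scaler()]).
#' @return The scaled [qsar_table] with attribute `scaler`.
#' @export
normalize_descriptors <- function(x, scaler = NULL,
                                  method = c("minmax01", "zscore", "none")) {
  if (is.null(scaler)) scaler <- fit_scaler(x, match.arg(method))
  m <- attr(scaler, "method")
  out <- tibble::as_tibble(x)
  if (m != "none") {
    for (i in seq_len(nrow(scaler))) {
      d <- scaler$descriptor[i]
      if (!d %in% names(out)) next
      v <- out[[d]]
      if (m == "minmax01") {
        rng <- scaler$max[i] - scaler$min[i]
        if (rng == 0) {
          warning("constant descriptor '", d, "' mapped to 0.5", call. = FALSE)
          out[[d]] <- rep(0.5, length(v))
        } else {
          out[[d]] <- (v - scaler$min[i]) / rng
        }
      } else {
        out[[d]] <- if (scaler$sd[i] == 0) rep(0, length(v))
                    else (v - scaler$mean[i]) / scaler$sd[i]
      }
    }
  }
  out <- restore_qsar(out, x)
  attr(out, "scaler") <- scaler
  out
}
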