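#' Per-sample feature table
#'
#' A plain container pairing an `n_samples x n_features` matrix with one gait
#' phase label per row. The feature dimension is whatever the configured
#' layout produces (24 in the default layout: acceleration and angular rate
#' xyz for both shanks and both feet).
#'
#' @param values numeric matrix, samples in rows.
#' @param feature_names optional column names.
#' @param labels integer phase label per row (codes 2/3/4/5).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, feature_names = colnames(values), labels) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("feature values must be finite numerics", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("one label per sample row is required", call. = FALSE)
  if (!all(labels %in% 2:5))
    stop("labels must be gait phase codes 2, 3, 4 or 5", call. = FALSE)
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(values)))
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = labels), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  tb <- table(factor(x$labels, levels = c(5, 4, 3, 2),
                     labels = names(gait_phases())))
  cat("  labels:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Noise-injection data augmentation
#'
#' Replicates the table `factor` times: the original rows plus `factor - 1`
#' noisy copies. Per feature `j` the added noise is Gaussian with mean 0 and
#' standard deviation `scale * (max_i |x_ij| - |mean_j|)`, i.e. 10% of the
#' spread of the feature beyond its mean magnitude by default, mimicking
#' sensor noise while preserving each feature's scale. Labels are copied
#' unchanged.
#'
#' @param table a [feature_table()].
#' @param factor integer >= 1; output has `factor * n` rows.
#' @param scale noise magnitude as a fraction of the per-feature spread
#'   (default 0.10).
#' @param seed optional seed making the augmentation deterministic.
#' @return An augmented [feature_table()].
#' @export
augment_features <- function(table, factor, scale = 0.10, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("augmentation factor must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(table)
  x <- table$values
  n <- nrow(x); p <- ncol(x)
  sd_j <- pmax(scale * (apply(abs(x), 2, max) - abs(colMeans(x))), 0)
  gen <- function() {
    noise <- matrix(stats::rnorm(n * p), n, p) %*% diag(sd_j, p)
    x + noise
  }
  copies <- if (is.null(seed)) {
    replicate(factor - 1L, gen(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(factor - 1L, gen(), simplify = FALSE))
  }
  feature_table(do.call(rbind, c(list(x), copies)),
                feature_names = table$feature_names,
                labels = rep(table$labels, factor))
}

#' Standardize features to zero mean and unit variance
#'
#' Per feature: subtract the mean and divide by the population standard
#' deviation (divisor `N`, not `N - 1`). The fitted statistics are returned so
#' the identical affine map can be applied to validation and test data with
#' [apply_standardization()], avoiding leakage of test statistics into
#' training.
#'
#' @param table a [feature_table()].
#' @param eps optional variance floor; by default a constant feature is an
#'   error.
#' @return List with `table` (standardized) and `stats` (class
#'   `standardization_stats`: per-feature `mean` and `sd`).
#' @export
standardize_features <- function(table, eps = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$values
  mu <- colMeans(x)
  sd_j <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (is.null(eps)) {
    if (any(sd_j == 0))
      stop(sprintf("zero variance feature: %s",
                   paste(table$feature_names[sd_j == 0], collapse = ", ")),
           call. = FALSE)
  } else {
    sd_j <- pmax(sd_j, eps)
  }
  stats <- structure(list(mean = mu, sd = sd_j), class = "standardization_stats")
  list(table = apply_standardization(table, stats), stats = stats)
}

#' Apply previously fitted standardization statistics
#'
#' @param table a [feature_table()].
#' @param stats a `standardization_stats` object from
#'   [standardize_features()].
#' @return The standardized [feature_table()].
#' @export
apply_standardization <- function(table, stats) {
  stopifnot(inherits(table, "feature_table"),
            inherits(stats, "standardization_stats"))
  if (length(stats$mean) != ncol(table$values))
    stop("standardization stats dimension does not match the table",
         call. = FALSE)
  x <- sweep(sweep(table$values, 2, stats$mean), 2, stats$sd, "/")
  feature_table(x, table$feature_names, table$labels)
}

#' Sliding-window label-overlapping encoder
#'
#' Slices the per-sample feature stream into fixed-width windows (feature
#' rows x time columns) at the given stride. A window receives a label only
#' when its last `N` per-sample labels agree, where
#' `N = round(overlap_ratio * width)` (half-up); windows whose trailing labels
#' mix phases - the label-transition windows - are discarded. With the default
#' width 14, the overlap ratios 0.3/0.5/0.7 give N = 4, 7, 10.
#'
#' @param table a [feature_table()].
#' @param width window width in samples (default 14).
#' @param stride step between window starts, samples (default 1).
#' @param overlap_ratio fraction of the window that must share one label,
#'   in (0, 1].
#' @return An object of class `labeled_windows`: list with `windows`
#'   (`n_features x width x n_windows` array), `labels`, `n_last` (the N
#'   used) and `end_index` (last sample row of each emitted window).
#' @export
window_stream <- function(table, width = 14L, stride = 1L, overlap_ratio = 0.3) {
  stopifnot(inherits(table, "feature_table"))
  width <- as.integer(width); stride <- as.integer(stride)
  n <- nrow(table$values)
  if (width > n)
    stop("window width exceeds the number of samples", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  if (!is.numeric(overlap_ratio) || overlap_ratio <= 0 || overlap_ratio > 1)
    stop("overlap_ratio must lie in (0, 1]", call. = FALSE)
  n_last <- as.integer(floor(overlap_ratio * width + 0.5))
  n_last <- max(n_last, 1L)
  labels <- table$labels
  # run length of identical labels ending at each sample
  run <- integer(n); run[1] <- 1L
  if (n > 1L) for (i in 2:n)
    run[i] <- if (labels[i] == labels[i - 1L]) run[i - 1L] + 1L else 1L
  ends <- seq.int(width, n, by = stride)
  keep <- ends[run[ends] >= n_last]
  values <- t(table$values)                       # features x samples
  windows <- array(0, c(ncol(table$values), width, length(keep)))
  for (k in seq_along(keep))
    windows[, , k] <- values[, (keep[k] - width + 1L):keep[k]]
  structure(list(windows = windows, labels = labels[keep],
                 width = width, n_last = n_last, end_index = keep,
                 feature_names = table$feature_names),
            class = "labeled_windows")
}

#' @export
print.labeled_windows <- function(x, ...) {
  cat(sprintf("Labeled windows: %d windows of %d features x %d samples (last-N = %d)\n",
              length(x$labels), dim(x$windows)[1], x$width, x$n_last))
  tb <- table(factor(x$labels, levels = c(5, 4, 3, 2),
                     labels = names(gait_phases())))
  cat("  labels:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}
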