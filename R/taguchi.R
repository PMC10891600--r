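#' Design parameter levels
#'
#' The level sets of the eight design parameters explored by the
#' orthogonal-array study: one two-level factor (activation) and seven
#' three-level factors.
#'
#' @return Named list, factor name to vector of level values (in level
#'   order).
#' @export
design_levels <- function() {
  list(activation = c("tanh", "LeakyReLU"),
       overlap_ratio = c(0.3, 0.5, 0.7),
       layers = c(1L, 2L, 3L),
       optimizer = c("Adam", "Nadam", "AdamW"),
       hidden_units = c(32L, 64L, 128L),
       learning_rate = c(0.001, 0.002, 0.003),
       dropout = c(0.3, 0.5, 0.7),
       batch_size = c(3000L, 5000L, 7000L))
}

oa_fixture_path <- function(file) {
  system.file("extdata", file, package = "gaitfbf", mustWork = TRUE)
}

#' Build the L18 orthogonal-array experiment table
#'
#' Returns the bundled 18-run L18(2^1 x 3^7) assignment: one two-level factor
#' and seven three-level factors, balanced so every three-level factor takes
#' each level exactly 6 times and the two-level factor each level exactly 9
#' times. Column-to-factor assignment follows the bundled study design.
#'
#' @param factor_names names of the eight factors, in array-column order.
#' @param level_values named list mapping each factor to its level values
#'   (default [design_levels()]).
#' @param with_accuracy attach the bundled per-run test accuracies (default
#'   `FALSE`: the `accuracy` column is `NA`, to be filled by
#'   [run_oa_experiments()] or by hand).
#' @return An `oa_table`: data.frame of level indices with columns `set`, the
#'   eight factors, and `accuracy`; level values kept in
#'   `attr(, "level_values")`.
#' @export
build_l18 <- function(factor_names = names(design_levels()),
                      level_values = design_levels(),
                      with_accuracy = FALSE) {
  if (length(factor_names) != 8L)
    stop("the L18 design needs exactly 8 factors", call. = FALSE)
  if (!setequal(names(level_values), factor_names))
    stop("level_values must be named by the factors", call. = FALSE)
  n_lev <- vapply(level_values[factor_names], length, 1L)
  if (n_lev[1] != 2L || any(n_lev[-1] != 3L))
    stop("the L18 design needs 1 two-level factor followed by 7 three-level factors",
         call. = FALSE)
  raw <- utils::read.csv(oa_fixture_path("l18_orthogonal_array.csv"),
                         comment.char = "#")
  tab <- raw[, 2:9]
  names(tab) <- factor_names
  tab <- cbind(set = raw$set, tab,
               accuracy = if (with_accuracy) raw$test_accuracy else NA_real_)
  # balance invariants of the array
  stopifnot(nrow(tab) == 18L,
            all(table(tab[[factor_names[1]]]) == 9L),
            all(vapply(factor_names[-1],
                       function(f) all(table(tab[[f]]) == 6L), TRUE)))
  structure(tab, level_values = level_values,
            class = c("oa_table", "data.frame"))
}

oa_factor_names <- function(table) setdiff(names(table), c("set", "accuracy"))

#' Concrete hyperparameters for one orthogonal-array run
#'
#' @param table an `oa_table`.
#' @param row run index (1-18).
#' @param ... extra arguments passed to [hyper_params()] (e.g. `epochs`,
#'   `seed`).
#' @return A [hyper_params()] object with the row's level values.
#' @export
oa_row_params <- function(table, row, ...) {
  lv <- attr(table, "level_values")
  vals <- lapply(oa_factor_names(table), function(f)
    lv[[f]][table[[f]][row]])
  names(vals) <- oa_factor_names(table)
  do.call(hyper_params, c(vals, list(allow_custom = TRUE), list(...)))
}

#' Level-average analysis of an orthogonal-array experiment
#'
#' For each factor, averages the response (test accuracy) over the runs at
#' each level and picks the level with the highest mean; the optimal
#' combination maps the best levels through the factor level values. Ties
#' break toward the lower level index.
#'
#' @param table an `oa_table` with all 18 accuracies filled in.
#' @return An object of class `level_average_report`: list with `means`
#'   (factor -> level means), `best_level` (factor -> level index) and
#'   `optimal` (factor -> concrete value).
#' @export
level_average <- function(table) {
  stopifnot(inherits(table, "oa_table"))
  if (anyNA(table$accuracy))
    stop("all runs need an accuracy before level-average analysis",
         call. = FALSE)
  lv <- attr(table, "level_values")
  factors <- oa_factor_names(table)
  means <- lapply(factors, function(f)
    tapply(table$accuracy, table[[f]], mean))
  names(means) <- factors
  best <- vapply(means, function(m) unname(which.max(m)), 1L)
  optimal <- lapply(factors, function(f) lv[[f]][best[[f]]])
  names(optimal) <- factors
  structure(list(means = means, best_level = best, optimal = optimal),
            class = "level_average_report")
}

#' @export
print.level_average_report <- function(x, ...) {
  cat("Level-average analysis\n")
  for (f in names(x$means)) {
    cat(sprintf("  %-14s %s  -> level %d (%s)\n", f,
                paste(sprintf("%.2f", x$means[[f]]), collapse = " / "),
                x$best_level[[f]], format(x$optimal[[f]])))
  }
  invisible(x)
}

#' Improvement ratios of a model over the orthogonal-array runs
#'
#' Expresses a model's total test accuracy relative to the worst and the best
#' orthogonal-array run, as rounded percentages
#' (`100 * total / min(accuracies)` and `100 * total / max(accuracies)`).
#'
#' @param total_accuracy total test accuracy of the model, percent.
#' @param accuracies the 18 per-run accuracies.
#' @return Named vector `c(vs_worst = , vs_best = )`, rounded percent.
#' @export
improvement_ratios <- function(total_accuracy, accuracies) {
  c(vs_worst = round(100 * total_accuracy / min(accuracies)),
    vs_best = round(100 * total_accuracy / max(accuracies)))
}

#' Run the 18 orthogonal-array trainings on a synthetic dataset
#'
#' Trains one model per array row with the row's concrete hyperparameters
#' (epochs and batch size scaled for desk-scale synthetic data), evaluating
#' each on a held-out session, and fills in the accuracy column. The train
#' and test tables are re-windowed at each row's overlap ratio;
#' standardization is fitted on the training table only.
#'
#' @param table an `oa_table` (accuracies may be `NA`).
#' @param train_table,test_table raw (unstandardized) [feature_table()]s from
#'   disjoint sessions.
#' @param scale list with `epochs` and `batch_divisor` controlling the
#'   desk-scale reduction of the paper-scale training budget.
#' @param width,stride windowing parameters.
#' @param seed base seed; row `i` trains with seed `seed + i`.
#' @return The `oa_table` with the `accuracy` column filled.
#' @export
run_oa_experiments <- function(table, train_table, test_table,
                               scale = list(epochs = 6L, batch_divisor = 50),
                               width = 14L, stride = 1L, seed = 1L) {
  stopifnot(inherits(table, "oa_table"),
            inherits(train_table, "feature_table"),
            inherits(test_table, "feature_table"))
  for (i in seq_len(nrow(table))) {
    acc <- tryCatch({
      h <- oa_row_params(table, i, epochs = scale$epochs, seed = seed + i)
      std <- standardize_features(train_table)
      tr_w <- window_stream(std$table, width = width, stride = stride,
                            overlap_ratio = h$overlap_ratio)
      te_w <- window_stream(apply_standardization(test_table, std$stats),
                            width = width, stride = stride,
                            overlap_ratio = h$overlap_ratio)
      bs <- max(8L, as.integer(round(h$batch_size / scale$batch_divisor)))
      model <- build_model(h, n_features = dim(tr_w$windows)[1], width = width)
      model <- train_model(model, tr_w, split = 0.6, batch_size = bs)
      pred <- predict(model, te_w)
      evaluate_predictions(pred, te_w$labels)$total_accuracy
    }, error = function(e)
      stop(sprintf("orthogonal-array run %d failed: %s", i, conditionMessage(e)),
           call. = FALSE))
    table$accuracy[i] <- acc
  }
  table
}
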