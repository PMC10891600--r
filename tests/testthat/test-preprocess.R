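test_that("augmentation multiplies rows, keeps originals verbatim and scales the label histogram", {
  tab <- toy_table(n = 100)
  out <- augment_features(tab, factor = 15, seed = 7)
  expect_equal(nrow(out$values), 1500)
  expect_equal(out$values[1:100, ], tab$values)
  expect_equal(table(out$labels), table(tab$labels) * 15)
  expect_identical(augment_features(tab, 1), tab)
  expect_error(augment_features(tab, 0), "factor")
})

test_that("augmentation noise follows the max-minus-mean magnitude rule", {
  # a feature with max |x| = 5 and mean 1 must get noise sd 0.10 * (5 - 1)
  x <- cbind(a = c(5, 1, -3, 1), b = c(0.5, -0.5, 0.25, -0.25))
  tab <- feature_table(x, labels = rep(3L, 4))
  out <- augment_features(tab, factor = 4001, seed = 42)
  noise <- out$values[-(1:4), ] - do.call(rbind, replicate(4000, x, simplify = FALSE))
  expect_equal(sd(noise[, 1]), 0.10 * (5 - 1), tolerance = 0.03)
  expect_equal(mean(noise[, 1]), 0, tolerance = 0.02)
  # feature b: mean 0, max |x| = 0.5 -> sd 0.05
  expect_equal(sd(noise[, 2]), 0.05, tolerance = 0.03)
})

test_that("augmentation is deterministic under a seed and degenerate at scale 0", {
  tab <- toy_table()
  expect_identical(augment_features(tab, 3, seed = 5),
                   augment_features(tab, 3, seed = 5))
  dup <- augment_features(tab, 3, scale = 0)
  expect_equal(dup$values, rbind(tab$values, tab$values, tab$values))
})

test_that("standardization matches the population formula by hand", {
  tab <- feature_table(cbind(x = c(1, 2, 3)), labels = c(5L, 5L, 5L))
  out <- standardize_features(tab)
  expect_equal(unname(out$table$values[, 1]),
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(unname(out$stats$sd), sqrt(2 / 3), tolerance = 1e-12)
})

test_that("standardized columns have mean 0 and population sd 1", {
  tab <- toy_table(n = 57, p = 5, seed = 2)
  out <- standardize_features(tab)
  z <- out$table$values
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)) - 1)), 1e-10)
  # idempotent on already standardized data
  again <- standardize_features(out$table)
  expect_equal(again$table$values, z, tolerance = 1e-10)
  # invertible given the stats
  back <- sweep(sweep(z, 2, out$stats$sd, "*"), 2, out$stats$mean, "+")
  expect_equal(back, tab$values, tolerance = 1e-10)
})

test_that("constant features are an error unless a floor is given", {
  tab <- feature_table(cbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                       labels = rep(2L, 3))
  expect_error(standardize_features(tab), "zero variance feature: a")
  expect_silent(standardize_features(tab, eps = 1e-8))
})

test_that("training statistics transfer to test data as a fixed affine map", {
  train <- toy_table(n = 40, seed = 3)
  test <- toy_table(n = 20, seed = 4)
  test$values <- test$values + 2            # shifted test distribution
  std <- standardize_features(train)
  expect_equal(apply_standardization(train, std$stats)$values,
               std$table$values)
  # identity stats are the identity map
  id_stats <- structure(list(mean = rep(0, 3), sd = rep(1, 3)),
                        class = "standardization_stats")
  expect_equal(apply_standardization(test, id_stats)$values, test$values)
  # training stats differ from self-standardization on shifted data
  via_train <- apply_standardization(test, std$stats)$values
  via_self <- standardize_features(test)$table$values
  expect_gt(max(abs(via_train - via_self)), 0.5)
  bad <- structure(list(mean = 0, sd = 1), class = "standardization_stats")
  expect_error(apply_standardization(test, bad), "dimension")
})

test_that("windowing emits L - W + 1 fully-labeled windows on uniform labels", {
  tab <- toy_table(n = 20, labels = rep(4L, 20))
  w <- window_stream(tab, width = 14, stride = 1, overlap_ratio = 0.3)
  expect_equal(length(w$labels), 7)
  expect_true(all(w$labels == 4L))
  expect_equal(dim(w$windows), c(3, 14, 7))
  # content is the transposed slice
  expect_equal(w$windows[, , 1], t(tab$values[1:14, ]), ignore_attr = TRUE)
  expect_equal(w$n_last, 4)
})

test_that("the last-N labeling rule encodes and discards as specified", {
  labs <- c(rep(5L, 10), 2L, 2L, 2L, 2L)         # last 4 agree
  tab <- toy_table(n = 14, labels = labs)
  w <- window_stream(tab, width = 14, overlap_ratio = 0.3)
  expect_equal(w$labels, 2L)
  labs2 <- c(rep(5L, 10), 3L, 3L, 3L, 2L)        # trailing labels mix
  w2 <- window_stream(toy_table(n = 14, labels = labs2),
                      width = 14, overlap_ratio = 0.3)
  expect_length(w2$labels, 0)
  # at ratio 0.5 (N = 7) a run of only 4 trailing labels is not enough
  w3 <- window_stream(toy_table(n = 14, labels = labs),
                      width = 14, overlap_ratio = 0.5)
  expect_length(w3$labels, 0)
})

test_that("overlap ratios map to N = 4, 7, 10 and emitted labels match truth", {
  tab <- toy_table(n = 200, labels = rep(rep(c(5L, 4L, 3L, 2L), each = 25), 2))
  for (case in list(c(0.3, 4), c(0.5, 7), c(0.7, 10))) {
    w <- window_stream(tab, width = 14, overlap_ratio = case[1])
    expect_equal(w$n_last, case[2])
    # every emitted label equals the ground truth at the window's last sample
    expect_equal(w$labels, tab$labels[w$end_index])
    expect_lte(length(w$labels), 200 - 14 + 1)
  }
})

test_that("raising the overlap ratio never increases the window count", {
  set.seed(9)
  labs <- sample(c(5L, 4L, 3L, 2L), 300, replace = TRUE)
  labs <- inverse.rle(list(values = rle(labs)$values,
                           lengths = pmax(rle(labs)$lengths * 3L, 2L)))
  tab <- toy_table(n = length(labs), labels = labs)
  counts <- sapply(c(0.3, 0.5, 0.7), function(r)
    length(window_stream(tab, width = 14, overlap_ratio = r)$labels))
  expect_true(all(diff(counts) <= 0))
})

test_that("windowing validates its arguments", {
  tab <- toy_table(n = 10)
  expect_error(window_stream(tab, width = 14), "width exceeds")
  expect_error(window_stream(tab, width = 5, overlap_ratio = 0), "overlap_ratio")
  expect_error(window_stream(tab, width = 5, overlap_ratio = 1.2), "overlap_ratio")
})
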