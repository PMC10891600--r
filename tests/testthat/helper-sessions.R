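# Small cached synthetic sessions shared across test files. All noiseless so
# exact invariance properties can be asserted.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache))
    assign(key, expr, envir = .session_cache)
  get(key, envir = .session_cache)
}

quiet_session <- function(duration = 10, seed = 3, mounting = "random", ...) {
  cached(paste("sess", duration, seed, deparse(substitute(mounting)),
               paste(deparse(substitute(list(...))), collapse = ""), sep = "_"),
         simulate_session(sim_config(duration = duration, seed = seed,
                                     mounting = mounting,
                                     noise_accel = 0, noise_gyro = 0, ...)))
}

random_rot <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# quick feature table with known labels for preprocessing tests
toy_table <- function(n = 30, p = 3, labels = rep(c(5L, 3L), length.out = n),
                      seed = 1) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * p), n, p), labels = labels)
}

# small easily separable window set: one feature pair encodes the class
toy_windows <- function(n_per_class = 30, width = 6, n_features = 4, seed = 1) {
  set.seed(seed)
  lab <- rep(c(5L, 4L, 3L, 2L), each = n_per_class)
  n <- length(lab)
  X <- array(rnorm(n_features * width * n, sd = 0.1), c(n_features, width, n))
  centers <- matrix(c(2, 0, 0, 2, -2, 0, 0, -2), 2, 4)
  for (k in seq_len(n)) {
    cls <- match(lab[k], c(5L, 4L, 3L, 2L))
    X[1:2, , k] <- X[1:2, , k] + centers[, cls]
  }
  structure(list(windows = X, labels = lab, width = width, n_last = 1L,
                 end_index = seq_len(n),
                 feature_names = paste0("f", seq_len(n_features))),
            class = "labeled_windows")
}
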