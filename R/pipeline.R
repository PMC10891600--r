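#' End-to-end pipeline configuration
#'
#' Bundles everything one run needs: simulator configurations for the
#' training and test sessions (typically differing in heading and seed, to
#' emulate a new subject walking in a new direction), the preprocessing
#' parameters, the classifier hyperparameters, and desk-scale overrides.
#'
#' @param train,test [sim_config()]s for the two sessions.
#' @param use_fbf express features in the floating body-fixed frame (`TRUE`,
#'   the method under study) or raw global-frame coordinates (`FALSE`, the
#'   heading-dependent baseline).
#' @param augment_factor,augment_scale noise-injection augmentation of the
#'   training features ([augment_features()]); factor 1 disables it.
#' @param width,stride sliding-window parameters.
#' @param hyper a [hyper_params()] object.
#' @param epochs,batch_size optional desk-scale overrides of the
#'   hyperparameters.
#' @param split training fraction of the training windows.
#' @param seed seed for the augmentation stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(train = sim_config(duration = 40, seed = 11L),
                            test = sim_config(duration = 20, heading = pi / 2,
                                              seed = 12L),
                            use_fbf = TRUE,
                            augment_factor = 1L, augment_scale = 0.10,
                            width = 14L, stride = 1L,
                            hyper = optimal_hyper_params(),
                            epochs = NULL, batch_size = NULL,
                            split = 0.6, seed = 1L) {
  structure(list(train = train, test = test, use_fbf = use_fbf,
                 augment_factor = as.integer(augment_factor),
                 augment_scale = augment_scale,
                 width = as.integer(width), stride = as.integer(stride),
                 hyper = hyper, epochs = epochs, batch_size = batch_size,
                 split = split, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full recognition pipeline on synthetic sessions
#'
#' Simulate (or accept) a training and a test session, calibrate each from
#' its own stand-stoop gesture, express the distal sensor streams in the
#' floating body-fixed frame (or leave them in the global frame), label from
#' the ground truth, augment and standardize (statistics fitted on training
#' data only), window with the label-overlapping encoder, train the
#' bidirectional LSTM, and evaluate on the held-out session's windows.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; if given, the evaluation report and
#'   training history are written there as JSON/CSV.
#' @param train_session,test_session optional pre-built sessions overriding
#'   the simulator configs.
#' @return List with `report` (a `gait_eval`), `model`, `history`,
#'   `stats` (standardization) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         train_session = NULL, test_session = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  frame <- if (config$use_fbf) "fbf" else "global"
  tr_sess <- stage("simulate", if (is.null(train_session))
    simulate_session(config$train) else train_session)
  te_sess <- stage("simulate", if (is.null(test_session))
    simulate_session(config$test) else test_session)
  tr_feat <- stage("calibrate+transform",
                   session_features(tr_sess, frame = frame))
  te_feat <- stage("calibrate+transform",
                   session_features(te_sess, frame = frame))
  if (config$augment_factor > 1L)
    tr_feat <- stage("augment",
                     augment_features(tr_feat, config$augment_factor,
                                      config$augment_scale, seed = config$seed))
  std <- stage("standardize", standardize_features(tr_feat))
  te_std <- stage("standardize", apply_standardization(te_feat, std$stats))
  tr_w <- stage("window", window_stream(std$table, config$width, config$stride,
                                        config$hyper$overlap_ratio))
  te_w <- stage("window", window_stream(te_std, config$width, config$stride,
                                        config$hyper$overlap_ratio))
  model <- stage("train", {
    m <- build_model(config$hyper, n_features = dim(tr_w$windows)[1],
                     width = config$width)
    train_model(m, tr_w, split = config$split,
                epochs = config$epochs, batch_size = config$batch_size)
  })
  report <- stage("evaluate",
                  evaluate_predictions(predict(model, te_w), te_w$labels))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(confusion = report$confusion,
           per_phase_accuracy = as.list(report$per_phase_accuracy),
           total_accuracy = report$total_accuracy,
           frame = frame, seed = config$seed,
           n_train_windows = length(tr_w$labels),
           n_test_windows = length(te_w$labels)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }
  list(report = report, model = model, history = model$history,
       stats = std$stats, config = config)
}
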