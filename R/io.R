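#' Write a gait session to a directory
#'
#' One CSV per sensor (`t`, row-major orientation `r11..r33`, `ax..az`,
#' `gx..gz`), per-foot contact-state CSVs, a label CSV, and a JSON manifest
#' recording the sample rate, file names, calibration segment bounds and
#' session metadata.
#'
#' @param session a `gait_session`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sensor_files <- list()
  for (id in names(session$streams)) {
    s <- session$streams[[id]]
    n <- length(s$t)
    rot <- t(vapply(seq_len(n), function(i) as.vector(t(s$orient[, , i])),
                    numeric(9)))
    df <- data.frame(t = s$t, rot, s$accel, s$gyro)
    names(df) <- c("t", paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33)),
                   "ax", "ay", "az", "gx", "gy", "gz")
    f <- paste0(id, ".csv")
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(dir, f), row.names = FALSE, quote = FALSE)
    sensor_files[[id]] <- f
  }
  for (foot in names(session$fsr))
    utils::write.csv(session$fsr[[foot]], file.path(dir, paste0("fsr_", foot, ".csv")),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(t = session$streams[[1]]$t, phase = session$phases),
                   file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  meta <- session$meta
  meta$config <- sim_config_to_list(meta$config)
  manifest <- list(sample_rate = session$sample_rate,
                   sensors = sensor_files,
                   fsr = as.list(stats::setNames(paste0("fsr_", names(session$fsr), ".csv"),
                                                 names(session$fsr))),
                   labels = "labels.csv",
                   calib = session$calib,
                   meta = meta)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

sim_config_to_list <- function(config) {
  if (is.null(config)) return(NULL)
  cfg <- unclass(config)
  if (is.function(cfg$heading)) cfg$heading <- "<function>"
  if (is.list(cfg$mounting))
    cfg$mounting <- lapply(cfg$mounting, function(m) as.vector(t(m)))
  cfg
}

#' Read a gait session from a directory or manifest
#'
#' Validates the files as it reads them: every referenced sensor CSV must
#' exist, timestamps across streams must agree within half a sample period,
#' and every orientation row must be a proper rotation (orthonormal,
#' determinant +1) within `1e-6`; violations report the file and row.
#'
#' @param path session directory or path to its `manifest.json`.
#' @return A `gait_session`.
#' @export
read_session <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(manifest_path))
    stop(sprintf("no session manifest at '%s'", manifest_path), call. = FALSE)
  dir <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  rate <- man$sample_rate
  tol_t <- 0.5 / rate
  if (is.null(man$sensors$waist))
    stop("manifest lists no waist sensor stream", call. = FALSE)
  streams <- list()
  t_ref <- NULL
  for (id in names(man$sensors)) {
    f <- file.path(dir, man$sensors[[id]])
    if (!file.exists(f))
      stop(sprintf("missing sensor file '%s' for sensor '%s'", f, id),
           call. = FALSE)
    df <- utils::read.csv(f)
    need <- c("t", paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33)),
              "ax", "ay", "az", "gx", "gy", "gz")
    if (!all(need %in% names(df)))
      stop(sprintf("sensor file '%s' lacks required columns", f), call. = FALSE)
    n <- nrow(df)
    if (is.null(t_ref)) t_ref <- df$t
    if (n != length(t_ref) || any(abs(df$t - t_ref) > tol_t))
      stop(sprintf("timestamps of sensor '%s' are misaligned with the session", id),
           call. = FALSE)
    orient <- array(0, c(3, 3, n))
    rot <- as.matrix(df[, need[2:10]])
    for (i in seq_len(n)) {
      m <- matrix(rot[i, ], 3, 3, byrow = TRUE)
      if (!is_rotation_matrix(m, tol = 1e-6))
        stop(sprintf("sensor '%s' row %d: orientation is not a proper rotation",
                     id, i), call. = FALSE)
      orient[, , i] <- m
    }
    streams[[id]] <- list(t = df$t, orient = orient,
                          accel = as.matrix(df[, c("ax", "ay", "az")]),
                          gyro = as.matrix(df[, c("gx", "gy", "gz")]))
  }
  fsr <- lapply(man$fsr, function(f) utils::read.csv(file.path(dir, f)))
  phases <- utils::read.csv(file.path(dir, man$labels))$phase
  calib <- lapply(man$calib, unlist)
  structure(list(sample_rate = rate, streams = streams, fsr = fsr,
                 phases = as.integer(phases), calib = calib,
                 meta = man$meta),
            class = "gait_session")
}
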