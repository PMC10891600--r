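#' Body-fixed anatomical frame
#'
#' A reference frame aligned with the subject's anatomical planes at the
#' calibration pose: first column `x` points forward (sagittal horizontal
#' axis), second column `k` points along the mediolateral axis, third column
#' is the global vertical `(0, 0, 1)`. Constructed by orthonormalisation with
#' the vertical axis held fixed: `k` is projected onto the horizontal plane
#' and renormalised, then `x` is recomputed as `k` cross `z`.
#'
#' @param k mediolateral axis candidate (3-vector, need not be unit or
#'   horizontal).
#' @return An object of class `body_fixed_frame`: a 3x3 rotation matrix with
#'   columns `(x, k, z)`.
#' @export
body_fixed_frame <- function(k) {
  z <- c(0, 0, 1)
  kh <- c(k[1], k[2], 0)
  nk <- sqrt(sum(kh^2))
  if (nk < 1e-9)
    stop("stoop axis not horizontal: mediolateral axis parallel to global z",
         call. = FALSE)
  kh <- kh / nk
  x <- c(kh[2] * z[3] - kh[3] * z[2],
         kh[3] * z[1] - kh[1] * z[3],
         kh[1] * z[2] - kh[2] * z[1])
  frame <- cbind(x, kh, z, deparse.level = 0)
  dimnames(frame) <- NULL
  structure(frame, class = c("body_fixed_frame", "matrix", "array"))
}

#' @export
print.body_fixed_frame <- function(x, ...) {
  cat("Body-fixed frame (columns: forward x, mediolateral k, vertical z)\n")
  print(unclass(x), ...)
  invisible(x)
}

# Accepts an imu_stream, a 3x3xn array, a list of 3x3 matrices, or a single
# 3x3 matrix, and returns a list of rotation matrices.
as_rotation_list <- function(x) {
  if (is.list(x) && !is.null(x$orient)) x <- x$orient
  if (is.matrix(x) && all(dim(x) == c(3, 3))) return(list(x))
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  if (is.list(x)) return(x)
  stop("cannot interpret input as orientation samples", call. = FALSE)
}

#' Build the body-fixed frame from a stand-stoop calibration gesture
#'
#' The subject stands upright for a few seconds, then stoops (leans forward at
#' the hip) and holds. The averaged waist orientations of the two poses
#' determine the relative rotation of the gesture; its rotation axis,
#' expressed in the global frame and projected onto the horizontal plane, is
#' the mediolateral axis `k` of the body. The forward axis follows as
#' `x = k x z`, with the sign of `k` chosen so that `x` points along the
#' horizontal displacement of the body's up-axis during the stoop (the
#' forward-lean direction).
#'
#' @param stand,stoop waist orientation samples for the two poses: an
#'   `imu_stream`, a 3x3xn array, or a list of rotation matrices.
#' @param min_angle smallest acceptable stand-to-stoop rotation, degrees
#'   (default 10). Smaller gestures are rejected as degenerate.
#' @return A [body_fixed_frame()].
#' @export
create_body_fixed_frame <- function(stand, stoop, min_angle = 10) {
  r_stand <- mean_rotation(as_rotation_list(stand))
  r_stoop <- mean_rotation(as_rotation_list(stoop))
  # the gesture rotation expressed in global coordinates
  q <- r_stoop %*% t(r_stand)
  aa <- rotation_axis_angle(q)
  if (aa$angle < min_angle * pi / 180)
    stop(sprintf(
      "degenerate calibration gesture: stand-to-stoop rotation %.2f deg < %g deg",
      aa$angle * 180 / pi, min_angle), call. = FALSE)
  frame <- body_fixed_frame(aa$axis)
  # forward-lean direction: horizontal displacement of the up-axis
  lean <- (q %*% c(0, 0, 1))[1:2]
  if (sum(lean^2) > 1e-18 && sum(frame[1:2, 1] * lean) < 0)
    frame <- body_fixed_frame(-aa$axis)
  frame
}

#' Sensor-to-body alignment rotation
#'
#' The fixed rotation mapping a mounted sensor's frame to the body-fixed
#' frame, estimated at the stand pose: `R_C = t(sensor_stand) %*% body_frame`,
#' so that `sensor_stand %*% R_C == body_frame`.
#'
#' @param sensor_stand averaged sensor orientation during the stand pose
#'   (sensor frame to global).
#' @param body_frame a [body_fixed_frame()] (or any 3x3 rotation).
#' @return A 3x3 rotation matrix.
#' @export
compute_alignment <- function(sensor_stand, body_frame) {
  stopifnot_rotation(sensor_stand, "sensor_stand")
  stopifnot_rotation(unclass(body_frame), "body_frame")
  t(sensor_stand) %*% unclass(body_frame)
}

#' Floating body-fixed frame at the current sample
#'
#' Carries the body-fixed frame along with the waist sensor's orientation
#' change since calibration:
#' `R_FBf = waist_now %*% t(waist_stand) %*% body_frame`.
#' When the waist has not moved this reduces to the body frame itself.
#'
#' @param waist_now current waist sensor orientation (sensor to global).
#' @param waist_stand averaged waist orientation at the stand pose.
#' @param body_frame a [body_fixed_frame()].
#' @return A 3x3 rotation matrix (floating body-fixed frame to global).
#' @export
floating_frame <- function(waist_now, waist_stand, body_frame) {
  waist_now %*% t(waist_stand) %*% unclass(body_frame)
}

#' Express one IMU sample in the floating body-fixed frame
#'
#' Acceleration and angular rate are interpreted as sensor-frame readings,
#' rotated to global by the sample's orientation and then into the floating
#' frame; the orientation is additionally right-multiplied by the sensor's
#' alignment rotation so that a sensor mounted at any angle reports the same
#' transformed orientation.
#'
#' @param sample list with `orientation` (3x3), `accel` (3-vector), `gyro`
#'   (3-vector) and optionally `t`.
#' @param fbf floating body-fixed frame for this sample ([floating_frame()]).
#' @param alignment the sensor's alignment rotation ([compute_alignment()]).
#' @return The sample with all three quantities expressed in the floating
#'   frame.
#' @export
transform_sample <- function(sample, fbf, alignment) {
  gt <- t(fbf)
  r <- sample$orientation
  sample$orientation <- gt %*% r %*% alignment
  sample$accel <- as.vector(gt %*% (r %*% sample$accel))
  sample$gyro <- as.vector(gt %*% (r %*% sample$gyro))
  sample
}

#' Calibrate a session: body frame plus per-sensor alignments
#'
#' Averages each sensor's orientation over the marked stand segment, builds
#' the body-fixed frame from the waist sensor's stand and stoop segments, and
#' computes every sensor's alignment rotation.
#'
#' @param session a `gait_session` (see [simulate_session()] or
#'   [read_session()]) with `calib$stand` and `calib$stoop` time bounds and a
#'   `waist` stream.
#' @param min_angle passed to [create_body_fixed_frame()].
#' @return An object of class `calibration_result`: list with `body_frame`,
#'   `alignment_by_sensor`, `waist_stand`, `stand_by_sensor`.
#' @export
calibrate_session <- function(session, min_angle = 10) {
  if (is.null(session$streams[["waist"]]))
    stop("session has no waist sensor stream", call. = FALSE)
  if (is.null(session$calib$stand) || is.null(session$calib$stoop))
    stop("session has no marked stand/stoop calibration segments", call. = FALSE)
  seg <- function(stream, bounds) {
    idx <- which(stream$t >= bounds[1] & stream$t < bounds[2])
    if (length(idx) == 0L)
      stop("calibration segment contains no samples", call. = FALSE)
    stream$orient[, , idx, drop = FALSE]
  }
  waist <- session$streams[["waist"]]
  stand_by_sensor <- lapply(session$streams, function(s)
    mean_rotation(seg(s, session$calib$stand)))
  body_frame <- create_body_fixed_frame(
    seg(waist, session$calib$stand),
    seg(waist, session$calib$stoop),
    min_angle = min_angle)
  alignment <- lapply(stand_by_sensor, function(rs)
    compute_alignment(rs, body_frame))
  structure(list(
    body_frame = body_frame,
    alignment_by_sensor = alignment,
    waist_stand = stand_by_sensor[["waist"]],
    stand_by_sensor = stand_by_sensor
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Gait session calibration\n")
  cat("  sensors aligned:", paste(names(x$alignment_by_sensor), collapse = ", "), "\n")
  fwd <- x$body_frame[, 1]
  cat(sprintf("  body forward axis: (%.3f, %.3f, %.3f), heading %.1f deg\n",
              fwd[1], fwd[2], fwd[3], atan2(fwd[2], fwd[1]) * 180 / pi))
  invisible(x)
}

# Floating body-fixed frame for every sample of the session, as a 3x3xn array
# keyed by the waist stream's timestamps.
fbf_series <- function(session, calib) {
  waist <- session$streams[["waist"]]
  n <- length(waist$t)
  pre <- t(calib$waist_stand) %*% unclass(calib$body_frame)
  out <- array(0, c(3, 3, n))
  for (i in seq_len(n)) out[, , i] <- waist$orient[, , i] %*% pre
  out
}

#' Express every stream of a session in the floating body-fixed frame
#'
#' @param session a `gait_session`.
#' @param calib a [calibrate_session()] result for this session.
#' @return The session with all sensor streams transformed (orientations,
#'   accelerations and angular rates in floating body-fixed coordinates).
#' @export
transform_session <- function(session, calib) {
  fbf <- fbf_series(session, calib)
  for (id in names(session$streams)) {
    s <- session$streams[[id]]
    al <- calib$alignment_by_sensor[[id]]
    if (is.null(al))
      stop(sprintf("no alignment rotation for sensor '%s'", id), call. = FALSE)
    n <- length(s$t)
    for (i in seq_len(n)) {
      gt <- t(fbf[, , i])
      r <- s$orient[, , i]
      gr <- gt %*% r
      s$orient[, , i] <- gr %*% al
      s$accel[i, ] <- gr %*% s$accel[i, ]
      s$gyro[i, ] <- gr %*% s$gyro[i, ]
    }
    session$streams[[id]] <- s
  }
  session$meta$frame <- "fbf"
  session
}

#' Feature matrix for classification
#'
#' Builds the per-sample feature table from the four distal sensors (left and
#' right shank and foot): acceleration xyz and angular rate xyz per sensor, 24
#' channels in the default layout. With `frame = "fbf"` the streams are first
#' expressed in the floating body-fixed frame (requires `calib`); with
#' `frame = "global"` raw global-frame quantities are used (the heading-
#' dependent baseline).
#'
#' @param session a `gait_session`.
#' @param calib a [calibrate_session()] result (required for `frame = "fbf"`).
#' @param frame `"fbf"` or `"global"`.
#' @param sensors which streams contribute features (default the four distal
#'   sensors).
#' @param gait_only drop the calibration segments (default `TRUE`).
#' @return A [feature_table()] whose labels are the session's ground-truth
#'   phases.
#' @export
session_features <- function(session, calib = NULL,
                             frame = c("fbf", "global"),
                             sensors = c("shank_L", "shank_R", "foot_L", "foot_R"),
                             gait_only = TRUE) {
  frame <- match.arg(frame)
  if (frame == "fbf") {
    if (is.null(calib)) calib <- calibrate_session(session)
    session <- transform_session(session, calib)
  } else {
    session <- globalize_session(session)
  }
  keep <- rep(TRUE, length(session$phases))
  if (gait_only && !is.null(session$calib$stoop)) {
    t0 <- session$calib$stoop[2]
    keep <- session$streams[[1]]$t >= t0
  }
  cols <- list(); nms <- character(0)
  for (id in sensors) {
    s <- session$streams[[id]]
    if (is.null(s)) stop(sprintf("session has no stream '%s'", id), call. = FALSE)
    cols[[length(cols) + 1L]] <- s$accel[keep, , drop = FALSE]
    cols[[length(cols) + 1L]] <- s$gyro[keep, , drop = FALSE]
    nms <- c(nms, paste0(id, "_a", c("x", "y", "z")), paste0(id, "_g", c("x", "y", "z")))
  }
  values <- do.call(cbind, cols)
  colnames(values) <- nms
  feature_table(values, labels = session$phases[keep])
}

# Rotate sensor-frame accel/gyro readings into the global frame (no body
# frame involved): the heading-dependent representation the floating frame is
# designed to replace.
globalize_session <- function(session) {
  for (id in names(session$streams)) {
    s <- session$streams[[id]]
    for (i in seq_along(s$t)) {
      r <- s$orient[, , i]
      s$accel[i, ] <- r %*% s$accel[i, ]
      s$gyro[i, ] <- r %*% s$gyro[i, ]
    }
    session$streams[[id]] <- s
  }
  session$meta$frame <- "global"
  session
}
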