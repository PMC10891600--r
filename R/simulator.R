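#' Configuration for the synthetic gait simulator
#'
#' Describes one simulated walking trial: duration and sampling rate, cadence
#' and speed, the heading profile (which way the subject walks, and how it
#' changes over time), the split of the gait cycle into the four phases, how
#' each sensor is (mis)mounted on its segment, and sensor noise levels. The
#' simulated session always starts with a 5 s stand and a 5 s stoop
#' calibration gesture before the gait itself.
#'
#' @param duration gait duration in seconds (excluding the 10 s calibration).
#' @param sample_rate sampling rate in Hz (default 100).
#' @param cadence steps per minute (two steps per gait cycle; default 100).
#' @param speed walking speed in m/s, in the range 0.24-1.37 typical of
#'   overground walking at self-selected slow-to-brisk pace (default 0.9).
#'   Scales the linear-acceleration amplitudes.
#' @param heading heading profile in radians: a single number (constant
#'   heading), a function of gait time `f(t)`, or a two-column matrix /
#'   data.frame `(time, heading)` interpreted as piecewise constant.
#' @param phase_fractions named fractions of the gait cycle spent in each
#'   phase, `c(SW=, HS=, FC=, HO=)`; must be positive and sum to 1. Defaults
#'   SW 0.40, HS 0.15, FC 0.30, HO 0.15 (toe-off merged into heel-off).
#' @param mounting per-sensor mounting rotation of the sensor case relative
#'   to its segment: `"identity"`, `"random"` (a fresh random rotation per
#'   sensor, drawn from the session seed), or a named list of 3x3 rotations.
#' @param noise_accel,noise_gyro Gaussian sensor noise standard deviations
#'   (m/s^2 and rad/s). Defaults 0.05 and 0.01, small relative to the signal
#'   as for a consumer-grade IMU.
#' @param label_foot which foot's contact states define the session's
#'   ground-truth phase labels (`"right"` or `"left"`, default right).
#' @param seed integer seed governing all randomness in the session.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 60, sample_rate = 100, cadence = 100,
                       speed = 0.9, heading = 0,
                       phase_fractions = c(SW = 0.40, HS = 0.15, FC = 0.30, HO = 0.15),
                       mounting = "identity",
                       noise_accel = 0.05, noise_gyro = 0.01,
                       label_foot = c("right", "left"), seed = 1L) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  pf <- phase_fractions[c("SW", "HS", "FC", "HO")]
  if (anyNA(pf) || any(pf <= 0) || abs(sum(pf) - 1) > 1e-9)
    stop("phase_fractions must be positive, named SW/HS/FC/HO and sum to 1",
         call. = FALSE)
  structure(list(
    duration = duration, sample_rate = sample_rate, cadence = cadence,
    speed = speed, heading = heading, phase_fractions = pf,
    mounting = mounting, noise_accel = noise_accel, noise_gyro = noise_gyro,
    label_foot = match.arg(label_foot), seed = as.integer(seed)
  ), class = "sim_config")
}

sim_sensors <- c("waist", "shank_L", "shank_R", "foot_L", "foot_R")

# heading profile -> function of gait time
heading_fun <- function(heading) {
  if (is.function(heading)) return(heading)
  if (is.numeric(heading) && length(heading) == 1L)
    return(function(t) rep(heading, length(t)))
  h <- as.matrix(heading)
  if (ncol(h) != 2L) stop("piecewise heading must have columns (time, heading)",
                          call. = FALSE)
  function(t) h[pmax(1L, findInterval(t, h[, 1])), 2]
}

heading_rate <- function(hf, t, dt = 1e-3) {
  (hf(t + dt) - hf(t - dt)) / (2 * dt)
}

# Sagittal pitch and mediolateral roll templates per segment as functions of
# the cycle variable u in [0,1) (u = 0 at heel strike), plus derivatives
# w.r.t. u. Harmonic pairs at one and two cycles make u decodable from a
# short window; the small roll keeps all three gyro axes informative, as in
# real gait.
sim_templates <- list(
  shank = list(
    theta = function(u) 0.44 * sin(2 * pi * u) + 0.10 * cos(4 * pi * u),
    dtheta = function(u) 0.44 * 2 * pi * cos(2 * pi * u) - 0.10 * 4 * pi * sin(4 * pi * u),
    phi = function(u) 0.06 * sin(2 * pi * u + 0.8),
    dphi = function(u) 0.06 * 2 * pi * cos(2 * pi * u + 0.8)
  ),
  foot = list(
    theta = function(u) -0.26 * cos(2 * pi * u) + 0.17 * sin(4 * pi * u),
    dtheta = function(u) 0.26 * 2 * pi * sin(2 * pi * u) + 0.17 * 4 * pi * cos(4 * pi * u),
    phi = function(u) 0.08 * cos(2 * pi * u + 0.3),
    dphi = function(u) -0.08 * 2 * pi * sin(2 * pi * u + 0.3)
  ),
  waist = list(
    theta = function(u) 0.035 * sin(4 * pi * u),
    dtheta = function(u) 0.035 * 4 * pi * cos(4 * pi * u),
    phi = function(u) 0.03 * sin(2 * pi * u + 0.5),
    dphi = function(u) 0.03 * 2 * pi * cos(2 * pi * u + 0.5)
  )
)

# Linear acceleration of each segment in body coordinates (x forward, y left,
# z up), per unit walking speed, as a function of u.
sim_accel_template <- function(segment, u) {
  switch(segment,
    shank = cbind(1.3 * sin(2 * pi * u + 0.5),
                  0.3 * sin(4 * pi * u),
                  0.9 * cos(2 * pi * u)),
    foot = cbind(2.2 * sin(2 * pi * u + 1.0),
                 0.4 * cos(4 * pi * u + 0.5),
                 1.6 * cos(2 * pi * u + 0.7)),
    waist = cbind(0.5 * sin(4 * pi * u),
                  0.25 * sin(2 * pi * u),
                  0.6 * cos(4 * pi * u)))
}

GRAVITY <- 9.80665

# phase of the cycle variable: boundaries HS | FC | HO | SW in cycle order
# SW -> HS -> FC -> HO (codes 5 -> 4 -> 3 -> 2)
phase_of_u <- function(u, pf) {
  b <- cumsum(c(pf[["HS"]], pf[["FC"]], pf[["HO"]]))
  ifelse(u < b[1], 4L, ifelse(u < b[2], 3L, ifelse(u < b[3], 2L, 5L)))
}

fsr_of_phase <- function(phase) {
  # inverse of the labeling map: SW no contact, HS heel only, FC all three,
  # HO forefoot only
  toe <- as.integer(phase %in% c(3L, 2L))
  metatarsal <- as.integer(phase %in% c(3L, 2L))
  heel <- as.integer(phase %in% c(4L, 3L))
  data.frame(toe = toe, metatarsal = metatarsal, heel = heel)
}

random_rotation <- function() {
  # uniform via QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' Simulate a gait session
#'
#' Generates a complete synthetic trial: 5 s standing, 5 s stooping (the
#' calibration gesture), then cyclic gait at the configured cadence, speed and
#' heading. Each sensor stream contains per-sample orientation (sensor frame
#' to global), sensor-frame acceleration (specific force, including gravity)
#' and sensor-frame angular rate, derived analytically from smooth sagittal
#' pitch and linear-acceleration templates so that each gait phase occupies a
#' distinct part of the cycle with a distinct kinematic signature. Binary
#' 3-channel insole contact states and ground-truth phase labels are generated
#' consistently with the phase boundaries; the left leg runs half a cycle out
#' of phase with the right.
#'
#' @param config a [sim_config()].
#' @return An object of class `gait_session`: list with `sample_rate`,
#'   `streams` (per-sensor lists with `t`, `orient` 3x3xn, `accel` nx3,
#'   `gyro` nx3), `fsr` (per-foot data frames `t/toe/metatarsal/heel`),
#'   `phases` (per-sample label in 2/3/4/5), `calib` (stand/stoop bounds),
#'   and `meta`.
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_session_impl(config))
}

simulate_session_impl <- function(config) {
  rate <- config$sample_rate
  t_stand <- 5; t_stoop <- 5
  n_cal <- as.integer(round((t_stand + t_stoop) * rate))
  n_gait <- as.integer(round(config$duration * rate))
  n <- n_cal + n_gait
  t <- (seq_len(n) - 1) / rate
  gait_start <- t_stand + t_stoop
  is_gait <- t >= gait_start
  tg <- pmax(t - gait_start, 0)                       # gait time
  hf <- heading_fun(config$heading)
  psi0 <- hf(0)[1]
  psi <- ifelse(is_gait, hf(tg), psi0)
  dpsi <- ifelse(is_gait & is.function(config$heading), heading_rate(hf, tg), 0)

  # stoop pitch: smooth ramp to 35 deg over the first second, then hold
  beta_max <- 35 * pi / 180
  s01 <- function(x) { x <- pmin(pmax(x, 0), 1); x * x * (3 - 2 * x) }
  beta <- ifelse(t >= t_stand & t < gait_start, beta_max * s01(t - t_stand), 0)
  dbeta <- ifelse(t >= t_stand & t < t_stand + 1,
                  beta_max * 6 * (t - t_stand) * (1 - (t - t_stand)) / 1, 0)

  # cycle variables; gait starts at the beginning of full contact so the
  # label sequence continues smoothly from the flat-footed calibration
  cycle_period <- 120 / config$cadence
  pf <- config$phase_fractions
  u0 <- pf[["HS"]]
  u_r <- (u0 + tg / cycle_period) %% 1
  u_l <- (u_r + 0.5) %% 1

  phase_r <- ifelse(is_gait, phase_of_u(u_r, pf), 3L)
  phase_l <- ifelse(is_gait, phase_of_u(u_l, pf), 3L)

  mounting <- config$mounting
  if (identical(mounting, "identity"))
    mounting <- stats::setNames(rep(list(diag(3)), 5L), sim_sensors)
  if (identical(mounting, "random"))
    mounting <- stats::setNames(replicate(5L, random_rotation(), simplify = FALSE),
                                sim_sensors)
  for (id in sim_sensors)
    if (is.null(mounting[[id]]))
      stop(sprintf("mounting has no entry for sensor '%s'", id), call. = FALSE)

  segment_of <- c(waist = "waist", shank_L = "shank", shank_R = "shank",
                  foot_L = "foot", foot_R = "foot")
  u_of <- list(waist = u_r, shank_L = u_l, shank_R = u_r,
               foot_L = u_l, foot_R = u_r)

  streams <- list()
  for (id in sim_sensors) {
    seg <- segment_of[[id]]
    u <- u_of[[id]]
    tpl <- sim_templates[[seg]]
    theta <- ifelse(is_gait, tpl$theta(u), 0)
    dtheta_dt <- ifelse(is_gait, tpl$dtheta(u) / cycle_period, 0)
    phi <- ifelse(is_gait, tpl$phi(u), 0)
    dphi_dt <- ifelse(is_gait, tpl$dphi(u) / cycle_period, 0)
    # superimpose the whole-body stoop pitch during calibration
    theta <- theta + beta
    dtheta_dt <- dtheta_dt + dbeta
    ab <- sim_accel_template(seg, u) * config$speed
    ab[!is_gait, ] <- 0

    m <- mounting[[id]]
    mt <- t(m)
    orient <- array(0, c(3, 3, n))
    accel <- matrix(0, n, 3)
    gyro <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      ry <- rot_y(theta[i]); rx <- rot_x(phi[i])
      ryx <- ry %*% rx
      orient[, , i] <- rot_z(psi[i]) %*% ryx %*% m
      # specific force in sensor frame: gravity plus body-frame linear accel
      accel[i, ] <- mt %*% (t(ryx) %*% (ab[i, ] + c(0, 0, GRAVITY)))
      # angular rate in sensor frame: heading rate about global z, sagittal
      # pitch rate about the body y axis, roll rate about the segment x axis
      gyro[i, ] <- mt %*% (dpsi[i] * (t(ryx) %*% c(0, 0, 1)) +
                             t(rx) %*% c(0, dtheta_dt[i], 0) +
                             c(dphi_dt[i], 0, 0))
    }
    if (config$noise_accel > 0)
      accel <- accel + matrix(stats::rnorm(3 * n, 0, config$noise_accel), n, 3)
    if (config$noise_gyro > 0)
      gyro <- gyro + matrix(stats::rnorm(3 * n, 0, config$noise_gyro), n, 3)
    streams[[id]] <- list(t = t, orient = orient, accel = accel, gyro = gyro)
  }

  fsr <- list(left = cbind(t = t, fsr_of_phase(phase_l)),
              right = cbind(t = t, fsr_of_phase(phase_r)))
  phases <- if (config$label_foot == "right") phase_r else phase_l

  structure(list(
    sample_rate = rate,
    streams = streams,
    fsr = fsr,
    phases = as.integer(phases),
    calib = list(stand = c(0, t_stand), stoop = c(t_stand, gait_start)),
    meta = list(seed = config$seed, config = config, frame = "sensor")
  ), class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  n <- length(x$streams[[1]]$t)
  cat(sprintf("Gait session: %d samples at %g Hz (%.1f s), %d sensors\n",
              n, x$sample_rate, n / x$sample_rate, length(x$streams)))
  gait <- x$streams[[1]]$t >= x$calib$stoop[2]
  tb <- table(factor(x$phases[gait], levels = c(5, 4, 3, 2),
                     labels = c("SW", "HS", "FC", "HO")))
  cat("  gait phase samples:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Rotate a session's heading
#'
#' Left-multiplies every sensor orientation by a rotation of `delta` about the
#' global vertical, i.e. the identical walk executed facing a different
#' direction. Sensor-frame acceleration and angular-rate readings are
#' physically unchanged by a global heading offset; contact states and labels
#' are untouched.
#'
#' @param session a `gait_session`.
#' @param delta heading offset in radians.
#' @return The rotated session.
#' @export
rotate_heading <- function(session, delta) {
  rz <- rot_z(delta)
  for (id in names(session$streams)) {
    s <- session$streams[[id]]
    for (i in seq_along(s$t)) s$orient[, , i] <- rz %*% s$orient[, , i]
    session$streams[[id]] <- s
  }
  session
}

# evaluate code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
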