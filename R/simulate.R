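#' Activity archetype for the synthetic signal generator
#'
#' Each archetype holds the physical parameters of one activity: the resting
#' gravity orientation of the device, the arm-swing amplitude and cadence for
#' ambulatory activities, slow orientation wobble, and the additive noise
#' level.
#'
#' @param name Activity label.
#' @param gravity Unit 3-vector: direction of gravity in the device frame at
#'   rest.
#' @param swing_amp Arm-swing acceleration amplitude in g (0 for static
#'   postures).
#' @param cadence Swing frequency in Hz (0 for static postures).
#' @param wobble_sd Slow orientation wobble amplitude in degrees.
#' @param noise_sd Additive Gaussian noise SD per axis in g.
#' @param bout Typical bout duration in seconds.
#' @return A list of class \code{activity_archetype}.
#' @export
activity_archetype <- function(name, gravity, swing_amp = 0, cadence = 0,
                               wobble_sd = 0, noise_sd = 0.01, bout = 300) {
  gravity <- gravity / sqrt(sum(gravity^2))
  stopifnot(swing_amp >= 0, cadence >= 0, wobble_sd >= 0, noise_sd >= 0,
            bout > 0)
  structure(list(name = name, gravity = gravity, swing_amp = swing_amp,
                 cadence = cadence, wobble_sd = wobble_sd,
                 noise_sd = noise_sd, bout = bout),
            class = "activity_archetype")
}

#' Default archetype library
#'
#' Nine activities spanning the laboratory protocol: three static postures
#' with distinct gravity orientations, a quasi-random household activity,
#' three treadmill walking speeds, brisk walking, stairs and running.
#' Cadences and amplitudes follow typical adult values (walking step
#' frequency 1.6-1.9 Hz rising with speed, running 2.8 Hz with ~0.8 g swing
#' amplitude at the wrist).
#'
#' @return Named list of \code{activity_archetype} objects.
#' @export
default_archetypes <- function() {
  a <- list(
    activity_archetype("lying", c(0, 0, 1), wobble_sd = 2,
                       noise_sd = 0.010, bout = 300),
    activity_archetype("seated", c(0.35, 0.25, -0.90), wobble_sd = 3,
                       noise_sd = 0.015, bout = 300),
    activity_archetype("standing", c(0, -1, 0), wobble_sd = 4,
                       noise_sd = 0.020, bout = 240),
    activity_archetype("household", c(0.3, -0.9, -0.3), wobble_sd = 12,
                       noise_sd = 0.080, bout = 240),
    activity_archetype("walk_4kmh", c(0, -1, 0), swing_amp = 0.15,
                       cadence = 1.6, wobble_sd = 6, noise_sd = 0.030,
                       bout = 240),
    activity_archetype("walk_5kmh", c(0, -1, 0), swing_amp = 0.20,
                       cadence = 1.8, wobble_sd = 7, noise_sd = 0.030,
                       bout = 240),
    activity_archetype("walk_6kmh", c(0, -1, 0), swing_amp = 0.25,
                       cadence = 1.9, wobble_sd = 8, noise_sd = 0.030,
                       bout = 240),
    activity_archetype("brisk_walk", c(0, -1, 0), swing_amp = 0.45,
                       cadence = 2.2, wobble_sd = 10, noise_sd = 0.040,
                       bout = 240),
    activity_archetype("stairs", c(0, -1, 0), swing_amp = 0.40,
                       cadence = 1.4, wobble_sd = 10, noise_sd = 0.050,
                       bout = 180),
    activity_archetype("running", c(0, -1, 0), swing_amp = 0.80,
                       cadence = 2.8, wobble_sd = 14, noise_sd = 0.060,
                       bout = 240))
  stats::setNames(a, vapply(a, `[[`, "", "name"))
}

#' Simulation configuration
#'
#' @param schedule data.frame with columns \code{name} (archetype name) and
#'   \code{duration} (seconds), in order.
#' @param fs Sampling rate in Hz (80-100, matching the devices emulated).
#' @param wrist \code{"left"} or \code{"right"}; left-wrist wear mirrors the
#'   X and Z axes.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param archetypes Archetype library (default [default_archetypes()]).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(schedule, fs = 100, wrist = c("right", "left"),
                       seed = 1L, archetypes = default_archetypes()) {
  wrist <- match.arg(wrist)
  stopifnot(is.data.frame(schedule),
            all(c("name", "duration") %in% names(schedule)),
            all(schedule$duration > 0),
            fs >= 80, fs <= 100)
  missing <- setdiff(schedule$name, names(archetypes))
  if (length(missing)) {
    stop("unknown archetype(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(schedule = schedule, fs = fs, wrist = wrist,
                 seed = as.integer(seed), archetypes = archetypes),
            class = "sim_config")
}

#' Laboratory-style default protocol
#'
#' A schedule covering all nine default archetypes with 3-5 minute bouts, in
#' the order a laboratory visit would run them (postures first, then
#' increasing ambulation intensity). Suitable for end-to-end pipeline tests:
#' after 30 s transition trimming every bout still contributes at least 12
#' labelled 10-s windows.
#'
#' @inheritParams sim_config
#' @return A \code{sim_config}.
#' @export
default_protocol <- function(fs = 100, wrist = "right", seed = 1L) {
  arch <- default_archetypes()
  schedule <- data.frame(name = names(arch),
                         duration = vapply(arch, `[[`, numeric(1), "bout"),
                         stringsAsFactors = FALSE)
  sim_config(schedule, fs = fs, wrist = wrist, seed = seed,
             archetypes = arch)
}

# unit vector perpendicular to g
perp_unit <- function(g) {
  e <- if (abs(g[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- c(g[2] * e[3] - g[3] * e[2],
         g[3] * e[1] - g[1] * e[3],
         g[1] * e[2] - g[2] * e[1])
  v / sqrt(sum(v^2))
}

# samples for one bout; RNG assumed seeded
simulate_bout <- function(arch, duration, fs) {
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  g0 <- arch$gravity
  u <- perp_unit(g0)                      # tilt axis direction (u x g0 plane)
  w <- c(u[2] * g0[3] - u[3] * g0[2],     # w = u x g0, unit, perp to g0
         u[3] * g0[1] - u[1] * g0[3],
         u[1] * g0[2] - u[2] * g0[1])
  # slow orientation wobble: low-frequency sinusoid with random phase and a
  # random constant offset, amplitude wobble_sd degrees
  ph1 <- stats::runif(1, 0, 2 * pi)
  off <- stats::rnorm(1, 0, arch$wobble_sd / 2)
  theta <- (off + arch$wobble_sd * sin(2 * pi * 0.05 * t + ph1)) * pi / 180
  gait <- if (arch$cadence > 0) {
    # one gait phase per bout; tilt, bounce and sway are phase-locked to it
    # (as arm swing and step impact are in real gait), so window statistics
    # are comparable across bouts and studies
    2 * pi * arch$cadence * t + stats::runif(1, 0, 2 * pi)
  } else NULL
  if (!is.null(gait)) {
    # orientation oscillation at the cadence (arm swing tilts the device)
    tilt_amp <- min(30, 40 * arch$swing_amp)
    theta <- theta + tilt_amp * pi / 180 * sin(gait)
  }
  # rotate g0 towards w by theta (Rodrigues, axis u perpendicular to g0)
  gt <- outer(cos(theta), g0) + outer(sin(theta), w)
  if (!is.null(gait)) {
    # vertical bounce: magnitude modulation along gravity at the cadence,
    # plus a smaller perpendicular sway in quadrature
    bounce <- arch$swing_amp * sin(gait)
    sway <- 0.3 * arch$swing_amp * cos(gait)
    gt <- gt * (1 + bounce) + outer(sway, u)
  }
  gt + matrix(stats::rnorm(3 * n, 0, arch$noise_sd), n, 3)
}

#' Simulate a labelled wrist-accelerometer recording
#'
#' Generates a triaxial signal following the configured schedule: static
#' postures hold their gravity orientation plus slow wobble and noise;
#' ambulatory archetypes superpose, at the cadence, an orientation
#' oscillation, a magnitude modulation along gravity (so the ENMO series
#' carries the cadence as its dominant frequency) and a smaller perpendicular
#' sway. Left-wrist wear mirrors the X and Z axes. The label bouts exactly
#' match the schedule. Deterministic given the config seed.
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{recording} (a \code{raw_recording}) and
#'   \code{bouts} (data.frame \code{start,end,label}).
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  parts <- vector("list", nrow(cfg$schedule))
  starts <- numeric(nrow(cfg$schedule))
  t0 <- 0
  for (i in seq_len(nrow(cfg$schedule))) {
    arch <- cfg$archetypes[[cfg$schedule$name[i]]]
    parts[[i]] <- simulate_bout(arch, cfg$schedule$duration[i], cfg$fs)
    starts[i] <- t0
    t0 <- t0 + cfg$schedule$duration[i]
  }
  xyz <- do.call(rbind, parts)
  if (cfg$wrist == "left") {
    xyz[, 1] <- -xyz[, 1]
    xyz[, 3] <- -xyz[, 3]
  }
  n <- nrow(xyz)
  samples <- data.frame(time = (seq_len(n) - 1L) / cfg$fs,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  bouts <- data.frame(start = starts,
                      end = starts + cfg$schedule$duration,
                      label = cfg$schedule$name,
                      stringsAsFactors = FALSE)
  list(recording = raw_recording(samples, fs = cfg$fs, wrist = cfg$wrist),
       bouts = bouts)
}
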