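#' Generation configuration
#'
#' Controls how continuous trajectories are produced from via-point
#' sequences.  Segment durations follow a distance-proportional timing
#' policy: the time allotted to a segment is the Euclidean distance
#' between its via-points divided by `ref_speed`, floored at `min_T`.
#' Each segment is sampled on a uniform time step shared by the whole
#' trajectory, with `points_per_segment` points per average segment.
#'
#' @param points_per_segment Integer >= 2; average number of samples per
#'   segment (default 20).
#' @param ref_speed Reference pen speed (trajectory units per time unit)
#'   used by the timing policy (default 1: unit reference speed).
#' @param min_T Minimum segment duration (default 0.1).
#' @return A `generation_config` list.
#' @export
generation_config <- function(points_per_segment = 20, ref_speed = 1,
                              min_T = 0.1) {
  stopifnot(points_per_segment >= 2, ref_speed > 0, min_T > 0)
  structure(list(points_per_segment = as.integer(points_per_segment),
                 ref_speed = ref_speed, min_T = min_T),
            class = "generation_config")
}

#' Minimum-acceleration segment between two via-points
#'
#' The trajectory between consecutive via-points minimizes the time
#' integral of squared acceleration subject to position and velocity
#' boundary conditions; the unique solution is the cubic Hermite
#' interpolant per coordinate.
#'
#' @param bc Named list with `x0`, `y0`, `vx0`, `vy0` (start position
#'   and velocity), `x1`, `y1`, `vx1`, `vy1` (end), and `T` (duration,
#'   > 0).
#' @param n Number of evenly spaced samples to return, including both
#'   endpoints (>= 2).
#' @return A list with numeric vectors `t` (0..T), `x`, `y`, `vx`, `vy`.
#' @examples
#' bc <- list(x0 = 0, y0 = 0, vx0 = 0, vy0 = 0,
#'            x1 = 1, y1 = 0, vx1 = 0, vy1 = 0, T = 1)
#' min_acceleration_segment(bc, 5)$x  # 0, 0.15625, 0.5, 0.84375, 1
#' @export
min_acceleration_segment <- function(bc, n) {
  if (!is.finite(bc$T) || bc$T <= 0)
    stop("segment duration T must be > 0", call. = FALSE)
  if (n < 2) stop("need at least 2 samples per segment", call. = FALSE)
  t <- seq(0, bc$T, length.out = n)
  hermite <- function(p0, v0, p1, v1) {
    u <- t / bc$T
    h00 <- 2 * u^3 - 3 * u^2 + 1
    h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2
    h11 <- u^3 - u^2
    pos <- h00 * p0 + h10 * bc$T * v0 + h01 * p1 + h11 * bc$T * v1
    g00 <- (6 * u^2 - 6 * u) / bc$T
    g10 <- 3 * u^2 - 4 * u + 1
    g01 <- (-6 * u^2 + 6 * u) / bc$T
    g11 <- 3 * u^2 - 2 * u
    vel <- g00 * p0 + g10 * v0 + g01 * p1 + g11 * v1
    list(pos = pos, vel = vel)
  }
  hx <- hermite(bc$x0, bc$vx0, bc$x1, bc$vx1)
  hy <- hermite(bc$y0, bc$vy0, bc$y1, bc$vy1)
  list(t = t, x = hx$pos, y = hy$pos, vx = hx$vel, vy = hy$vel)
}

#' Generate a trajectory through a via-point sequence
#'
#' Concatenates minimum-acceleration segments between consecutive
#' via-points.  The result passes through every via-point with its
#' specified velocity exactly and is sampled on a single uniform time
#' step (segment durations are quantized to a whole number of steps).
#'
#' @param seq A [viapoint_seq()] in continuous trajectory units.
#' @param cfg A [generation_config()].
#' @return A [trajectory()].
#' @export
generate_trajectory <- function(seq, cfg = generation_config()) {
  stopifnot(inherits(seq, "viapoint_seq"))
  n_seg <- nrow(seq) - 1L
  d <- sqrt(diff(seq$x)^2 + diff(seq$y)^2)
  Tseg <- pmax(d / cfg$ref_speed, cfg$min_T)
  dt <- sum(Tseg) / ((cfg$points_per_segment - 1L) * n_seg)
  # a floor of 5 steps keeps every segment's landmarks resolvable by the
  # extractor (its min_sep merging would swallow shorter segments)
  steps <- pmax(5L, round(Tseg / dt))
  xs <- ys <- numeric(0)
  for (i in seq_len(n_seg)) {
    bc <- list(x0 = seq$x[i], y0 = seq$y[i],
               vx0 = seq$vx[i], vy0 = seq$vy[i],
               x1 = seq$x[i + 1L], y1 = seq$y[i + 1L],
               vx1 = seq$vx[i + 1L], vy1 = seq$vy[i + 1L],
               T = steps[i] * dt)
    sg <- min_acceleration_segment(bc, steps[i] + 1L)
    drop1 <- if (i == 1L) seq_along(sg$x) else -1L
    xs <- c(xs, sg$x[drop1]); ys <- c(ys, sg$y[drop1])
  }
  trajectory(dt * (seq_along(xs) - 1L), xs, ys)
}

#' Two-joint planar arm
#'
#' The simulated effector: a shoulder segment of length `L1` and a
#' forearm of length `L2` in the plane, with the elbow flexing on a
#' fixed side of the shoulder-to-endpoint line.
#'
#' @param L1,L2 Segment lengths (> 0), in trajectory units.
#' @param elbow_branch `"up"` or `"down"`: sign of the elbow angle.
#' @return A `two_joint_arm` list.
#' @export
two_joint_arm <- function(L1 = 0.25, L2 = 0.35, elbow_branch = "up") {
  stopifnot(L1 > 0, L2 > 0, elbow_branch %in% c("up", "down"))
  structure(list(L1 = L1, L2 = L2, elbow_branch = elbow_branch),
            class = "two_joint_arm")
}

#' Forward kinematics of the two-joint arm
#'
#' @param theta1 Shoulder angle (rad, from the +x axis).
#' @param theta2 Elbow angle (rad, relative to the upper arm).
#' @param arm A [two_joint_arm()].
#' @return A list with numeric `x` and `y`.
#' @export
forward_kinematics <- function(theta1, theta2, arm) {
  list(x = arm$L1 * cos(theta1) + arm$L2 * cos(theta1 + theta2),
       y = arm$L1 * sin(theta1) + arm$L2 * sin(theta1 + theta2))
}

#' Inverse kinematics of the two-joint arm
#'
#' Classical closed-form solution: the elbow angle from the law of
#' cosines (sign from the configured elbow branch), then
#' `theta1 = atan2(y, x) - atan2(L2 sin(theta2), L1 + L2 cos(theta2))`.
#'
#' @param x,y Endpoint position (vectors allowed).
#' @param arm A [two_joint_arm()].
#' @return A list with numeric `theta1` and `theta2`.
#' @export
inverse_kinematics <- function(x, y, arm) {
  r <- sqrt(x^2 + y^2)
  lo <- abs(arm$L1 - arm$L2); hi <- arm$L1 + arm$L2
  bad <- which(r < lo - 1e-9 | r > hi + 1e-9)
  if (length(bad))
    stop(sprintf(paste0("point at radius %.6g unreachable: the arm's",
                        " annulus is [%.6g, %.6g]"),
                 r[bad[1]], lo, hi), call. = FALSE)
  c2 <- pmin(pmax((r^2 - arm$L1^2 - arm$L2^2) / (2 * arm$L1 * arm$L2),
                  -1), 1)
  s <- if (arm$elbow_branch == "up") 1 else -1
  theta2 <- s * acos(c2)
  theta1 <- atan2(y, x) -
    atan2(arm$L2 * sin(theta2), arm$L1 + arm$L2 * cos(theta2))
  list(theta1 = theta1, theta2 = theta2)
}

#' Joint-space profile of a Cartesian trajectory
#'
#' Per-sample inverse kinematics followed by finite-difference joint
#' velocities and accelerations (the same central/one-sided scheme used
#' for pen velocities, applied twice).
#'
#' @param traj A [trajectory()] whose samples are all reachable.
#' @param arm A [two_joint_arm()].
#' @return A `joint_profile` list with `t`, `theta1`, `theta2`,
#'   `dtheta1`, `dtheta2`, `ddtheta1`, `ddtheta2`.
#' @export
joint_profiles <- function(traj, arm) {
  stopifnot(inherits(traj, "trajectory"))
  r <- sqrt(traj$x^2 + traj$y^2)
  bad <- which(r < abs(arm$L1 - arm$L2) - 1e-9 |
               r > arm$L1 + arm$L2 + 1e-9)
  if (length(bad))
    stop("trajectory sample ", bad[1], " is outside the arm's workspace",
         call. = FALSE)
  ik <- inverse_kinematics(traj$x, traj$y, arm)
  d1 <- fd_derivative(ik$theta1, traj$t)
  d2 <- fd_derivative(ik$theta2, traj$t)
  structure(list(t = traj$t,
                 theta1 = ik$theta1, theta2 = ik$theta2,
                 dtheta1 = d1, dtheta2 = d2,
                 ddtheta1 = fd_derivative(d1, traj$t),
                 ddtheta2 = fd_derivative(d2, traj$t)),
            class = "joint_profile")
}

#' Drive the arm with joint commands
#'
#' `execute_accelerations()` double-integrates joint accelerations from
#' an initial joint state with a semi-implicit Euler scheme and maps the
#' resulting angles through forward kinematics: the simulated arm's
#' writing path.  `execute_velocities()` is the velocity-command
#' variant, integrating joint velocities once.
#'
#' @param state Named list with initial `theta1`, `theta2`, `dtheta1`,
#'   `dtheta2` (the velocity entries are ignored by
#'   `execute_velocities()`).
#' @param acc Two-column matrix (or list of two vectors) of joint
#'   accelerations, one row per time step.
#' @param dt Time step.
#' @param arm A [two_joint_arm()].
#' @return A [trajectory()] of the arm endpoint.
#' @export
execute_accelerations <- function(state, acc, dt, arm) {
  if (is.list(acc) && !is.matrix(acc)) acc <- cbind(acc[[1]], acc[[2]])
  n <- nrow(acc)
  th <- matrix(0, n, 2)
  th[1, ] <- c(state$theta1, state$theta2)
  v <- c(state$dtheta1, state$dtheta2)
  if (n > 1L) for (k in 2:n) {
    v <- v + acc[k - 1L, ] * dt
    th[k, ] <- th[k - 1L, ] + v * dt
  }
  fk <- forward_kinematics(th[, 1], th[, 2], arm)
  trajectory(dt * (seq_len(n) - 1L), fk$x, fk$y)
}

#' @rdname execute_accelerations
#' @param vel Two-column matrix (or list of two vectors) of joint
#'   velocities, one row per time step.
#' @export
execute_velocities <- function(state, vel, dt, arm) {
  if (is.list(vel) && !is.matrix(vel)) vel <- cbind(vel[[1]], vel[[2]])
  n <- nrow(vel)
  th <- matrix(0, n, 2)
  th[1, ] <- c(state$theta1, state$theta2)
  if (n > 1L) for (k in 2:n) {
    th[k, ] <- th[k - 1L, ] + vel[k - 1L, ] * dt
  }
  fk <- forward_kinematics(th[, 1], th[, 2], arm)
  trajectory(dt * (seq_len(n) - 1L), fk$x, fk$y)
}

#' Map the writing box into the arm's workspace
#'
#' The letter box (grid units) is placed, by a similarity transform, in
#' front of the arm at a configurable reach and size so every sample is
#' reachable.
#'
#' @param traj A [trajectory()] in writing-box units.
#' @param arm A [two_joint_arm()].
#' @param box_height Height of the writing box in its own units
#'   (default 40).
#' @param reach Fraction of maximum reach at which the box centre is
#'   placed (default 0.75).
#' @param size Box height as a fraction of maximum reach (default 0.25).
#' @return A [trajectory()] in arm workspace units.
#' @export
workspace_placement <- function(traj, arm, box_height = 40,
                                reach = 0.75, size = 0.25) {
  span <- arm$L1 + arm$L2
  s <- size * span / box_height
  cx <- reach * span
  trajectory(traj$t,
             cx + s * (traj$x - box_height / 2),
             s * (traj$y - box_height / 2))
}
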