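#' Via-point sequences
#'
#' A via-point is a four-dimensional landmark (x, y, vx, vy) on a pen
#' trajectory, placed where the horizontal or the vertical velocity
#' component vanishes (a vertical or horizontal tangent), where both
#' vanish (a cusp), and at the stroke start and end.  A letter is encoded
#' by the ordered sequence of its via-points; the sequence length is
#' capped at 16.
#'
#' @param x,y Numeric positions (trajectory units).
#' @param vx,vy Numeric velocities (units/time).
#' @param kind Character vector; one of `"start"`, `"end"`,
#'   `"horizontal_tangent"`, `"vertical_tangent"`, `"cusp"`, or `"free"`
#'   (interior points of sampled sequences whose velocity is not pinned
#'   to zero in either component).
#' @param sample_index Fractional 1-based index into the source
#'   trajectory; strictly increasing.
#' @return A data frame of class `viapoint_seq`.
#' @export
viapoint_seq <- function(x, y, vx, vy, kind, sample_index) {
  n <- length(x)
  stopifnot(length(y) == n, length(vx) == n, length(vy) == n,
            length(kind) == n, length(sample_index) == n)
  if (n < 2L || n > 16L)
    stop("a via-point sequence has between 2 and 16 points (got ", n, ")",
         call. = FALSE)
  valid <- c("start", "end", "horizontal_tangent", "vertical_tangent",
             "cusp", "free")
  if (!all(kind %in% valid))
    stop("unknown via-point kind: ", paste(setdiff(kind, valid),
         collapse = ", "), call. = FALSE)
  if (kind[1] != "start" || kind[n] != "end")
    stop("sequence must begin with a start and finish with an end point",
         call. = FALSE)
  if (any(diff(sample_index) <= 0))
    stop("via-point sample indices must be strictly increasing",
         call. = FALSE)
  structure(data.frame(x = x, y = y, vx = vx, vy = vy, kind = kind,
                       sample_index = sample_index),
            class = c("viapoint_seq", "data.frame"))
}

#' @export
print.viapoint_seq <- function(x, ...) {
  cat(sprintf("<viapoint_seq> %d points\n", nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# fractional-index linear interpolation into a sample series
interp_at <- function(f, q) {
  i <- pmin(floor(q), length(f) - 1L)
  w <- q - i
  (1 - w) * f[i] + w * f[i + 1L]
}

# zero events of one velocity component: fractional indices where the
# component crosses zero (linear interpolation) or dwells below eps for a
# run of samples (collapsed to the run midpoint).  Runs touching either
# trajectory end are absorbed by the start/end via-points.
component_zero_events <- function(v, eps) {
  n <- length(v)
  s <- as.integer(sign(v))
  s[abs(v) < eps] <- 0L
  ev <- numeric(0)
  r <- rle(s)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  zero <- which(r$values == 0L & lo > 1L & hi < n)
  if (length(zero)) ev <- c(ev, (lo[zero] + hi[zero]) / 2)
  # strict sign changes between adjacent non-zero samples
  i <- which(s[-n] * s[-1L] < 0L)
  if (length(i)) ev <- c(ev, i + v[i] / (v[i] - v[i + 1L]))
  sort(ev)
}

# merge events of one component that fall within min_sep samples of each
# other, keeping the one with the smaller residual speed
merge_close_events <- function(ev, speed_at, min_sep) {
  while (length(ev) > 1L) {
    gap <- diff(ev)
    k <- which(gap < min_sep)
    if (!length(k)) break
    k <- k[1L]
    drop <- if (speed_at(ev[k]) <= speed_at(ev[k + 1L])) k + 1L else k
    ev <- ev[-drop]
  }
  ev
}

#' Extract the via-point sequence of a trajectory
#'
#' The deterministic perception model: velocities are estimated by finite
#' differences, zero crossings (and dwells) of each component are located
#' with sub-sample precision by linear interpolation, near-coincident
#' zeroes of both components merge into a cusp, and the stroke start and
#' end are always included.
#'
#' @param traj A [trajectory()].
#' @param eps Velocity-zero tolerance, in velocity units.  Default:
#'   `1e-3` times the robust (95th percentile) peak speed of the
#'   trajectory.
#' @param min_sep Minimum separation between distinct via-points, in
#'   samples (default 3).  Closer detections of the same component merge
#'   (the one with the smaller residual speed is kept); closer detections
#'   of opposite components merge into a cusp; detections this close to
#'   the trajectory ends are absorbed by the start/end points.
#' @return A [viapoint_seq()].  More than 16 detections raise an error of
#'   class `viapoint_overflow` naming the count.
#' @examples
#' t <- seq(0, 1, length.out = 101)
#' arch <- trajectory(t, t, sin(pi * t))
#' extract_viapoints(arch)
#' @export
extract_viapoints <- function(traj, eps = NULL, min_sep = 3) {
  stopifnot(inherits(traj, "trajectory"))
  n <- n_samples(traj)
  v <- estimate_velocities(traj)
  speed <- sqrt(v$vx^2 + v$vy^2)
  if (is.null(eps)) {
    eps <- 1e-3 * stats::quantile(speed, 0.95, names = FALSE)
    if (eps <= 0) eps <- 1e-12       # stationary input: everything dwells
  }
  speed_at <- function(q) interp_at(v$vx, q)^2 + interp_at(v$vy, q)^2

  keep_interior <- function(ev)
    ev[ev > 1 + min_sep & ev < n - min_sep]
  evx <- merge_close_events(keep_interior(component_zero_events(v$vx, eps)),
                            speed_at, min_sep)
  evy <- merge_close_events(keep_interior(component_zero_events(v$vy, eps)),
                            speed_at, min_sep)

  # pair near-coincident x- and y-events into cusps
  used_y <- logical(length(evy))
  idx <- numeric(0); kind <- character(0)
  for (q in evx) {
    j <- which(!used_y & abs(evy - q) < min_sep)
    if (length(j)) {
      j <- j[which.min(abs(evy[j] - q))]
      used_y[j] <- TRUE
      idx <- c(idx, (q + evy[j]) / 2); kind <- c(kind, "cusp")
    } else {
      idx <- c(idx, q); kind <- c(kind, "vertical_tangent")
    }
  }
  if (any(!used_y)) {
    idx <- c(idx, evy[!used_y])
    kind <- c(kind, rep("horizontal_tangent", sum(!used_y)))
  }
  ord <- order(idx)
  idx <- idx[ord]; kind <- kind[ord]

  total <- length(idx) + 2L
  if (total > 16L) {
    cnd <- structure(class = c("viapoint_overflow", "error", "condition"),
                     list(message = paste0(total,
                       " via-points detected (maximum 16); smooth the",
                       " trajectory and retry"),
                       call = NULL, count = total))
    stop(cnd)
  }
  all_idx <- c(1, idx, n)
  viapoint_seq(x = interp_at(traj$x, all_idx),
               y = interp_at(traj$y, all_idx),
               vx = interp_at(v$vx, all_idx),
               vy = interp_at(v$vy, all_idx),
               kind = c("start", kind, "end"),
               sample_index = all_idx)
}

#' Discretization grid for via-points
#'
#' The letter representation lives on a discrete grid: positions on 41
#' integer values 0..40 (a canonical writing box) and velocities on 7
#' integer values -3..3.  The grid stores the affine maps between
#' trajectory units and these bins; it is fitted once per corpus and kept
#' inside the model so that writer-style size and slant cues survive
#' discretization.
#'
#' @param x_min,y_min Lower-left corner of the writing box in trajectory
#'   units.
#' @param height Height of the box in trajectory units; the same scale is
#'   applied to x so the aspect ratio is preserved.
#' @param vel_scale Velocity (units/time) mapped to the extreme bins
#'   (+/-3).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(x_min = 0, y_min = 0, height = 40, vel_scale = 3) {
  if (!is.finite(height) || height <= 0)
    stop("degenerate grid: height must be > 0", call. = FALSE)
  if (!is.finite(vel_scale) || vel_scale <= 0)
    stop("degenerate grid: vel_scale must be > 0", call. = FALSE)
  structure(list(x_min = x_min, y_min = y_min, height = height,
                 vel_scale = vel_scale,
                 n_pos_bins = 41L, n_vel_bins = 7L),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(paste0("<grid_spec> box corner (%.3g, %.3g), height %.3g,",
                     " vel scale %.3g; 41 position bins, 7 velocity bins\n"),
              x$x_min, x$y_min, x$height, x$vel_scale))
  invisible(x)
}

#' Fit a discretization grid to a corpus of via-point sequences
#'
#' The writing box spans the corpus-wide y range (letter height) with the
#' x scale tied to it (aspect preserved, box centred on the x data); the
#' velocity scale maps the 95th percentile of |v| components at
#' via-points to the extreme bins.
#'
#' @param seqs A list of [viapoint_seq()] objects.
#' @return A [grid_spec()].
#' @export
fit_grid <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  xs <- unlist(lapply(seqs, `[[`, "x"))
  ys <- unlist(lapply(seqs, `[[`, "y"))
  vs <- abs(unlist(lapply(seqs, function(s) c(s$vx, s$vy))))
  height <- max(ys) - min(ys)
  if (height <= 0) stop("degenerate corpus: zero letter height",
                        call. = FALSE)
  vel_scale <- stats::quantile(vs, 0.95, names = FALSE)
  if (vel_scale <= 0) vel_scale <- 1
  grid_spec(x_min = mean(range(xs)) - height / 2, y_min = min(ys),
            height = height, vel_scale = vel_scale)
}

#' Discretize and undiscretize via-point sequences
#'
#' Positions are affinely mapped into the 0..40 box, rounded to the
#' nearest integer and clipped; velocities are scaled so `vel_scale` maps
#' to bin 3, rounded and clipped to -3..3.
#'
#' @param seq A [viapoint_seq()].
#' @param grid A [grid_spec()].
#' @return An integer matrix with one row per via-point and columns
#'   `xb`, `yb` (0..40) and `vxb`, `vyb` (-3..3).
#' @export
discretize_sequence <- function(seq, grid) {
  stopifnot(inherits(seq, "viapoint_seq"), inherits(grid, "grid_spec"))
  ps <- 40 / grid$height
  clip <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  m <- cbind(
    xb  = clip(round((seq$x - grid$x_min) * ps), 0L, 40L),
    yb  = clip(round((seq$y - grid$y_min) * ps), 0L, 40L),
    vxb = clip(round(3 * seq$vx / grid$vel_scale), -3L, 3L),
    vyb = clip(round(3 * seq$vy / grid$vel_scale), -3L, 3L))
  storage.mode(m) <- "integer"
  m
}

#' @rdname discretize_sequence
#' @param bins Integer matrix as returned by `discretize_sequence()`.
#' @return `undiscretize_sequence()` returns a [viapoint_seq()] with bin
#'   centres mapped back to trajectory units; interior kinds are labelled
#'   from the zero velocity bins (`"free"` when neither component is 0).
#' @export
undiscretize_sequence <- function(bins, grid) {
  stopifnot(is.matrix(bins), ncol(bins) == 4L, inherits(grid, "grid_spec"))
  n <- nrow(bins)
  kind <- ifelse(bins[, "vxb"] == 0L & bins[, "vyb"] == 0L, "cusp",
          ifelse(bins[, "vyb"] == 0L, "horizontal_tangent",
          ifelse(bins[, "vxb"] == 0L, "vertical_tangent", "free")))
  kind[1] <- "start"; kind[n] <- "end"
  viapoint_seq(x = grid$x_min + bins[, "xb"] * grid$height / 40,
               y = grid$y_min + bins[, "yb"] * grid$height / 40,
               vx = bins[, "vxb"] * grid$vel_scale / 3,
               vy = bins[, "vyb"] * grid$vel_scale / 3,
               kind = kind,
               sample_index = seq_len(n))
}
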