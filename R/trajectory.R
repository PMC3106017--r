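#' Planar pen trajectory
#'
#' A trajectory is a uniformly sampled planar pen path: time stamps `t`
#' (constant step), abscissa `x` and ordinate `y`.  It is the visual input
#' of the perception model and the output of the motor model.
#'
#' @param t Numeric vector of time stamps, strictly increasing with a
#'   constant step (relative tolerance 1e-9).
#' @param x,y Numeric vectors of planar coordinates, same length as `t`.
#' @return An object of class `trajectory`: a list with elements `t`, `x`,
#'   `y`.
#' @examples
#' tr <- trajectory(seq(0, 1, by = 0.1), 0:10, rep(0, 11))
#' n_samples(tr)
#' @export
trajectory <- function(t, x, y) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 2L || length(x) != length(t) || length(y) != length(t))
    stop("trajectory needs >= 2 samples with equal-length t, x, y",
         call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("trajectory samples must be finite", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("trajectory time stamps must be strictly increasing", call. = FALSE)
  step <- mean(dt)
  if (any(abs(dt - step) > 1e-9 * max(abs(t[length(t)] - t[1]), 1)))
    stop("trajectory time step must be uniform", call. = FALSE)
  structure(list(t = t, x = x, y = y), class = "trajectory")
}

#' @rdname trajectory
#' @param traj A `trajectory`.
#' @export
n_samples <- function(traj) length(traj$t)

#' @export
print.trajectory <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<trajectory> %d samples, t in [%g, %g] (dt = %g)\n",
              n, x$t[1], x$t[n], x$t[2] - x$t[1]))
  cat(sprintf("  x in [%.3g, %.3g], y in [%.3g, %.3g]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Finite-difference velocity estimate
#'
#' Approximates the pen velocity from sampled positions: central
#' differences at interior samples, one-sided differences at the two ends.
#'
#' @param traj A [trajectory()].
#' @return A list with numeric vectors `vx` and `vy`, same length as the
#'   trajectory.
#' @examples
#' tr <- trajectory(seq(0, 1, by = 0.1), seq(0, 1, by = 0.1)^2, rep(0, 11))
#' estimate_velocities(tr)$vx
#' @export
estimate_velocities <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  list(vx = fd_derivative(traj$x, traj$t),
       vy = fd_derivative(traj$y, traj$t))
}

# central differences inside, one-sided at the ends
fd_derivative <- function(f, t) {
  n <- length(f)
  d <- numeric(n)
  if (n == 2L) {
    d[] <- (f[2] - f[1]) / (t[2] - t[1])
    return(d)
  }
  d[1] <- (f[2] - f[1]) / (t[2] - t[1])
  d[n] <- (f[n] - f[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (f[i + 1] - f[i - 1]) / (t[i + 1] - t[i - 1])
  d
}

#' Read and write trajectory CSV files
#'
#' The on-disk dialect is a plain CSV with header exactly `t,x,y`, decimal
#' point, one sample per row.
#'
#' @param path File path.
#' @return `read_trajectory_csv()` returns a [trajectory()];
#'   `write_trajectory_csv()` returns `path` invisibly.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path))
    stop("trajectory file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(names(df), c("t", "x", "y")))
    stop("trajectory CSV must have header t,x,y (got: ",
         paste(names(df), collapse = ","), ")", call. = FALSE)
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("non-numeric or missing values in ", path, " at row ", bad[1],
         call. = FALSE)
  trajectory(df$t, df$x, df$y)
}

#' @rdname read_trajectory_csv
#' @param traj A [trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(t = traj$t, x = traj$x, y = traj$y)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Erase a span of consecutive samples from a trajectory
#'
#' Used to build partially occluded stimuli for the recognition
#' experiments.  Tail (or head) spans simply shorten the trajectory; an
#' interior span is closed up by shifting the later part so the time base
#' remains uniform (the via-point extractor requires a single uniformly
#' sampled series).
#'
#' @param traj A [trajectory()].
#' @param start_index First sample to remove (1-based).
#' @param length Number of consecutive samples to remove; 0 is a no-op.
#' @return A [trajectory()] with the span removed.
#' @export
truncate_trajectory <- function(traj, start_index, length) {
  stopifnot(inherits(traj, "trajectory"))
  n <- n_samples(traj)
  if (length == 0L) return(traj)
  if (start_index < 1L || length < 0L || start_index + length - 1L > n)
    stop("truncation span [", start_index, ", ", start_index + length - 1L,
         "] outside trajectory of ", n, " samples", call. = FALSE)
  keep <- setdiff(seq_len(n), seq(start_index, length.out = length))
  if (length(keep) < 2L)
    stop("truncation must leave at least 2 samples", call. = FALSE)
  dt <- traj$t[2] - traj$t[1]
  trajectory(traj$t[1] + dt * (seq_along(keep) - 1L),
             traj$x[keep], traj$y[keep])
}
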