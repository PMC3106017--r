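#' Task results
#'
#' Every inference task returns a `task_result`: a normalized posterior
#' over the task's labels, an answer (the posterior argmax, or a seeded
#' draw from the posterior when `answer_policy = "sample"`), and any
#' artifacts produced on the way (via-point sequences, simulated
#' trajectories).
#'
#' @name task_result
NULL

new_task_result <- function(posterior, answer, artifacts = list()) {
  structure(list(posterior = posterior, answer = answer,
                 artifacts = artifacts), class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  top <- sort(x$posterior, decreasing = TRUE)
  top <- top[seq_len(min(5, length(top)))]
  cat("<task_result> answer:", x$answer, "\n  top posterior:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

normalize_log_posterior <- function(le) {
  p <- exp(le - logsumexp(le))
  p / sum(p)
}

draw_answer <- function(posterior, answer_policy, seed) {
  if (answer_policy == "argmax") return(names(posterior)[which.max(posterior)])
  if (is.null(seed))
    stop("answer_policy = \"sample\" needs a seed", call. = FALSE)
  with_seed(seed, sample(names(posterior), 1L, prob = posterior))
}

# log evidence over letters for one discretized sequence; writer NULL
# marginalizes over writers with a uniform prior
letter_log_evidence <- function(bins, model, writer = NULL) {
  S <- sequence_log_score_all(bins, model)
  if (is.null(writer)) {
    apply(S, 2, logsumexp) - log(nrow(S))
  } else {
    wi <- match(writer, model$writers)
    if (is.na(wi)) stop("unknown writer: ", writer, call. = FALSE)
    S[wi, ]
  }
}

writer_log_evidence <- function(bins, model, letter = NULL) {
  S <- sequence_log_score_all(bins, model)
  if (is.null(letter)) {
    apply(S, 1, logsumexp) - log(ncol(S))
  } else {
    li <- match(letter, model$letters)
    if (is.na(li)) stop("unknown letter: ", letter, call. = FALSE)
    S[, li]
  }
}

perceive_bins <- function(traj, model) {
  discretize_sequence(extract_viapoints(traj), model$grid)
}

# regeneration timing must honour the input's own pace: segment
# durations are distance / reference speed, so the reference speed is
# taken from the input trajectory (median sample speed).  Otherwise the
# extracted boundary velocities would be wildly inconsistent with the
# allotted segment times for inputs faster or slower than the default.
match_input_speed <- function(cfg, traj) {
  v <- estimate_velocities(traj)
  sp <- stats::median(sqrt(v$vx^2 + v$vy^2))
  if (is.finite(sp) && sp > 0) cfg$ref_speed <- sp
  cfg
}

#' Letter recognition
#'
#' Extracts and discretizes the via-points of the input trajectory and
#' computes the posterior over letters: proportional to the sequence
#' likelihood for a known writer, or to the uniform-prior average of the
#' per-writer likelihoods when the writer is unknown.
#'
#' @param traj A [trajectory()].
#' @param model A fitted [fit_letter_model()].
#' @param writer Writer label, or `NULL` when the writer is unknown
#'   (marginalized).
#' @param answer_policy `"argmax"` for the deterministic mode or
#'   `"sample"` to draw the answer from the posterior (needs `seed`).
#' @param seed Seed for the answer draw.
#' @return A [task_result] over letters.
#' @export
recognize_letter <- function(traj, model, writer = NULL,
                             answer_policy = c("argmax", "sample"),
                             seed = NULL) {
  answer_policy <- match.arg(answer_policy)
  vp <- extract_viapoints(traj)
  bins <- discretize_sequence(vp, model$grid)
  post <- normalize_log_posterior(letter_log_evidence(bins, model, writer))
  new_task_result(post, draw_answer(post, answer_policy, seed),
                  list(viapoints = vp, bins = bins))
}

#' Writer recognition
#'
#' Symmetric to [recognize_letter()] with the roles of letter and writer
#' exchanged: posterior over writers for a known letter, or with the
#' letter marginalized under a uniform prior.
#'
#' @inheritParams recognize_letter
#' @param letter Letter label, or `NULL` when unknown.
#' @return A [task_result] over writers.
#' @export
recognize_writer <- function(traj, model, letter = NULL,
                             answer_policy = c("argmax", "sample"),
                             seed = NULL) {
  answer_policy <- match.arg(answer_policy)
  vp <- extract_viapoints(traj)
  bins <- discretize_sequence(vp, model$grid)
  post <- normalize_log_posterior(writer_log_evidence(bins, model, letter))
  new_task_result(post, draw_answer(post, answer_policy, seed),
                  list(viapoints = vp, bins = bins))
}

#' Joint letter-and-writer recognition
#'
#' Posterior over all (writer, letter) pairs; its marginals equal the
#' marginalized single-label posteriors.
#'
#' @inheritParams recognize_letter
#' @return A [task_result] whose posterior is named
#'   `"writer:letter"`; the artifact `posterior_matrix` holds the
#'   writers x letters matrix.
#' @export
recognize_joint <- function(traj, model,
                            answer_policy = c("argmax", "sample"),
                            seed = NULL) {
  answer_policy <- match.arg(answer_policy)
  vp <- extract_viapoints(traj)
  bins <- discretize_sequence(vp, model$grid)
  S <- sequence_log_score_all(bins, model)
  le <- as.numeric(S)
  post <- normalize_log_posterior(le)
  P <- matrix(post, nrow(S), ncol(S), dimnames = dimnames(S))
  names(post) <- as.character(outer(model$writers, model$letters, paste,
                                    sep = ":"))
  new_task_result(post, draw_answer(post, answer_policy, seed),
                  list(viapoints = vp, bins = bins,
                       posterior_matrix = P))
}

# motor-coherence projection for a sampled via-point sequence: each
# velocity component is re-oriented along the local position progression
# (zeroed at extrema, where the sampled sign is unreliable) and capped
# so the cubic segments stay monotone between via-points.  The sampled
# magnitudes (the style information) are kept; only kinematically
# incoherent signs and overshoots are corrected, since the
# dimension-independence of the representation lets a raw draw pair a
# leftward velocity with rightward movement.
coherent_velocities <- function(seq, cfg) {
  n <- nrow(seq)
  # resolve exact coordinate ties (bin centres can coincide) with a
  # sub-bin nudge along the direction of travel, so no segment is
  # perfectly flat in either coordinate (a flat segment would read back
  # as a spurious dwell via-point)
  deflatten <- function(p) {
    d <- diff(p)
    s <- propagate_signs(sign(d))
    for (i in which(d == 0)) p[i + 1L] <- p[i + 1L] + 0.25 * s[i]
    p
  }
  seq$x <- deflatten(seq$x)
  seq$y <- deflatten(seq$y)
  dx <- diff(seq$x); dy <- diff(seq$y)
  dist <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  Tseg <- pmax(dist / cfg$ref_speed, cfg$min_T)
  fix <- function(v, dd) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      if (i == 1L) { sgn <- sign(dd[1]); cap <- 2.5 * abs(dd[1]) / Tseg[1] }
      else if (i == n) {
        sgn <- sign(dd[n - 1L]); cap <- 2.5 * abs(dd[n - 1L]) / Tseg[n - 1L]
      } else if (sign(dd[i - 1L]) == sign(dd[i]) && dd[i] != 0) {
        sgn <- sign(dd[i])
        cap <- 2.5 * min(abs(dd[i - 1L]) / Tseg[i - 1L],
                         abs(dd[i]) / Tseg[i])
      } else { sgn <- 0; cap <- 0 }
      out[i] <- sgn * min(abs(v[i]), cap)
    }
    out
  }
  seq$vx <- fix(seq$vx, dx)
  seq$vy <- fix(seq$vy, dy)
  seq
}

# fill zero entries of a sign vector with the nearest non-zero sign
# (previous first, then following); all-zero input falls back to +1
propagate_signs <- function(s) {
  nz <- which(s != 0)
  if (!length(nz)) return(rep(1, length(s)))
  for (i in seq_along(s)) {
    if (s[i] == 0) {
      prev <- nz[nz < i]
      s[i] <- if (length(prev)) s[max(prev)] else s[min(nz)]
    }
  }
  s
}

# sample a via-point sequence, re-drawing (with derived seeds) when the
# draw is degenerate as a motor plan: two consecutive via-points on the
# same position bin, or an interior via-point that is an extremum of
# neither coordinate (the dimension-independent draw can produce such
# points, but they are not landmarks of any trajectory through the
# sequence, so the plan could not reproduce its own via-points)
sample_valid_bins <- function(letter, writer, model, seed,
                              max_retries = 50L) {
  seeds <- c(seed, derive_seeds(seed, max_retries))
  for (s in seeds) {
    b <- sample_viapoint_sequence(letter, writer, model, s)
    dup <- any(diff(b[, "xb"]) == 0L & diff(b[, "yb"]) == 0L)
    if (dup) next
    n <- nrow(b)
    if (n > 2L) {
      sx <- propagate_signs(sign(diff(b[, "xb"])))
      sy <- propagate_signs(sign(diff(b[, "yb"])))
      i <- 2:(n - 1L)
      landmark <- sx[i - 1L] != sx[i] | sy[i - 1L] != sy[i]
      if (!all(landmark)) next
    }
    return(b)
  }
  stop("sampled a degenerate via-point sequence ", max_retries + 1L,
       " times for letter ", letter, call. = FALSE)
}

#' Write a letter
#'
#' Two-step production: a discretized via-point sequence is drawn from
#' the letter representation (ancestral sampling), mapped back to the
#' continuous workspace, and turned into a full trajectory through
#' minimum-acceleration segments.  With an effector, the trajectory is
#' placed in the arm's workspace, converted to joint profiles, and the
#' joint accelerations are replayed through the simulated arm.
#'
#' @param letter,writer Labels known to the model.
#' @param model A fitted [fit_letter_model()].
#' @param seed Integer seed; the trajectory is deterministic given it.
#' @param cfg A [generation_config()].
#' @param effector Optional [two_joint_arm()].
#' @return A list with `trajectory` (writing-box units), `bins`,
#'   `viapoints`, and — when an effector is given — `joints` (a
#'   joint profile) and `arm_trajectory` (the path written by replaying
#'   joint accelerations through the arm).
#' @export
write_letter <- function(letter, writer, model, seed,
                         cfg = generation_config(), effector = NULL) {
  bins <- sample_valid_bins(letter, writer, model, seed)
  vp <- coherent_velocities(undiscretize_sequence(bins, model$grid), cfg)
  traj <- generate_trajectory(vp, cfg)
  out <- list(trajectory = traj, bins = bins, viapoints = vp)
  if (!is.null(effector)) {
    placed <- workspace_placement(traj, effector)
    jp <- joint_profiles(placed, effector)
    out$joints <- jp
    out$arm_trajectory <- execute_accelerations(
      list(theta1 = jp$theta1[1], theta2 = jp$theta2[1],
           dtheta1 = jp$dtheta1[1], dtheta2 = jp$dtheta2[1]),
      cbind(jp$ddtheta1, jp$ddtheta2), placed$t[2] - placed$t[1],
      effector)
  }
  out
}

#' Copy a trajectory
#'
#' Model-free copying: via-points are extracted from the input and a new
#' trajectory is generated through them.  The copy passes through every
#' input via-point (position and velocity) exactly; no letter knowledge
#' is involved, so any trajectory within the 16-via-point budget can be
#' copied.
#'
#' @param traj A [trajectory()].
#' @param cfg A [generation_config()].
#' @param effector Optional [two_joint_arm()] for arm playback.
#' @return A list with `trajectory` (the planned copy), `viapoints`,
#'   and optionally `arm_trajectory`.
#' @export
copy_trajectory <- function(traj, cfg = generation_config(),
                            effector = NULL) {
  vp <- extract_viapoints(traj)
  out_traj <- generate_trajectory(vp, match_input_speed(cfg, traj))
  out <- list(trajectory = out_traj, viapoints = vp)
  if (!is.null(effector)) {
    placed <- workspace_placement(out_traj, effector)
    jp <- joint_profiles(placed, effector)
    out$arm_trajectory <- execute_accelerations(
      list(theta1 = jp$theta1[1], theta2 = jp$theta2[1],
           dtheta1 = jp$dtheta1[1], dtheta2 = jp$dtheta2[1]),
      cbind(jp$ddtheta1, jp$ddtheta2), placed$t[2] - placed$t[1],
      effector)
  }
  out
}

#' Copy a letter through the letter representation
#'
#' Reads the input under the reading writer's models, then produces a
#' new trajectory in the output writer's style by drawing from the
#' posterior-weighted mixture of letter models: a letter is drawn from
#' the reading posterior and a via-point sequence is sampled from that
#' letter under the output writer, without ever committing to a letter
#' in the returned result.  An unknown symbol is thus rendered as the
#' closest letter of the repertoire.
#'
#' @param traj A [trajectory()].
#' @param reading_writer Writer label used to read the input (or `NULL`
#'   to marginalize).
#' @param output_writer Writer label whose style the copy is produced
#'   in.
#' @param model A fitted [fit_letter_model()].
#' @param seed Integer seed.
#' @param cfg A [generation_config()].
#' @return A list with `trajectory`, `posterior` (over letters, from
#'   reading), `bins` and `viapoints` of the produced sequence.
#' @export
copy_letter <- function(traj, reading_writer, output_writer, model, seed,
                        cfg = generation_config()) {
  r <- recognize_letter(traj, model, reading_writer)
  seeds <- derive_seeds(seed, 2L)
  letter <- with_seed(seeds[1],
                      sample(names(r$posterior), 1L, prob = r$posterior))
  bins <- sample_valid_bins(letter, output_writer, model, seeds[2])
  vp <- undiscretize_sequence(bins, model$grid)
  list(trajectory = generate_trajectory(vp, cfg),
       posterior = r$posterior, bins = bins, viapoints = vp)
}

#' Letter recognition with internal motor simulation
#'
#' Combines two likelihood terms: the perception term scores the
#' via-points extracted from the input; the simulation term feeds those
#' via-points through the motor model (minimum-acceleration
#' regeneration), re-extracts via-points from the simulated trajectory
#' with the same perception algorithm, and scores them too.  The
#' posterior is proportional to the product of the two unnormalized
#' terms, computed in log space.
#'
#' @inheritParams recognize_letter
#' @param cfg A [generation_config()] for the internal simulation.
#' @return A [task_result] over letters; artifacts include the
#'   simulated trajectory and both via-point sequences, plus the two
#'   per-letter log-evidence terms.
#' @export
recognize_with_simulation <- function(traj, model, writer = NULL,
                                      cfg = generation_config(),
                                      answer_policy = c("argmax", "sample"),
                                      seed = NULL) {
  answer_policy <- match.arg(answer_policy)
  vp <- withCallingHandlers(
    extract_viapoints(traj),
    viapoint_overflow = function(e)
      message("via-point overflow in the perception branch"))
  bins <- discretize_sequence(vp, model$grid)
  term1 <- letter_log_evidence(bins, model, writer)
  sim <- generate_trajectory(vp, match_input_speed(cfg, traj))
  vp_sim <- withCallingHandlers(
    extract_viapoints(sim),
    viapoint_overflow = function(e)
      message("via-point overflow in the simulation branch"))
  bins_sim <- discretize_sequence(vp_sim, model$grid)
  term2 <- letter_log_evidence(bins_sim, model, writer)
  post <- normalize_log_posterior(term1 + term2)
  new_task_result(post, draw_answer(post, answer_policy, seed),
                  list(viapoints = vp, simulated = sim,
                       simulated_viapoints = vp_sim,
                       log_evidence_perception = term1,
                       log_evidence_simulation = term2))
}
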