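#' Synthetic cursive letter prototypes
#'
#' Hand-designed via-point skeletons for the 22 single-stroke lowercase
#' letters (the alphabet minus i, j, t and x, which need a pen-up
#' movement).  Each skeleton is an ordered set of knots in the canonical
#' 0..40 writing box with a kind flag: `start`, `end`,
#' `horizontal_tangent` (a y extremum), `vertical_tangent` (an x
#' extremum) or `cusp` (pen reversal).  Knot velocities are derived from
#' the local geometry when a trial is synthesized.  The letterforms are
#' mutually distinguishable and roughly letter-like rather than copies
#' of any real hand; some letters carry an allograph variant with a
#' different via-point count, and the tall-ascender forms (l, b, h, k)
#' are deliberately confusable.
#'
#' @return A named list; each element is a list of variant data frames
#'   with columns `x`, `y`, `kind`.
#' @export
default_prototypes <- function() {
  k <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    kinds <- c(S = "start", E = "end", H = "horizontal_tangent",
               V = "vertical_tangent", C = "cusp")
    data.frame(x = as.numeric(m[, 2]), y = as.numeric(m[, 3]),
               kind = unname(kinds[m[, 1]]))
  }
  protos <- list(
    a = list(k("S",27,26, "H",17,29, "V",7,20, "H",17,11, "V",29,20,
               "C",28,27, "E",35,11)),
    b = list(k("S",8,11, "H",11,38, "H",14,10, "V",24,18, "H",15,26,
               "E",11,17)),
    c = list(k("S",30,24, "H",19,28, "V",8,20, "H",19,12, "E",30,16)),
    d = list(k("S",27,25, "H",17,28, "V",7,20, "H",17,12, "V",29,20,
               "C",28,36, "E",34,11)),
    e = list(k("S",8,12, "V",22,20, "H",14,27, "V",4,19, "H",14,11,
               "E",27,15)),
    f = list(k("S",8,13, "C",13,39, "C",10,1, "E",16,13)),
    g = list(k("S",27,25, "H",17,28, "V",7,20, "H",17,12, "C",28,26,
               "H",22,1, "V",14,5, "E",28,8)),
    h = list(k("S",6,11, "C",10,38, "C",8,10, "H",19,27, "E",27,11)),
    k = list(k("S",6,11, "C",10,38, "C",8,10, "H",24,27, "E",28,10)),
    l = list(k("S",6,11, "V",17,26, "H",11,38, "V",5,24, "H",12,10,
               "E",24,14),                       # upright, looped: 6 pts
             k("S",6,11, "C",12,38, "V",8,13, "H",13,10,
               "E",24,15)),                      # slanted allograph: 5 pts
    m = list(k("S",4,11, "H",9,26, "H",14,10, "H",19,26, "H",24,10,
               "H",29,26, "E",34,10)),
    n = list(k("S",6,11, "H",13,26, "H",19,10, "H",26,26, "E",32,10)),
    o = list(k("S",30,22, "H",19,29, "V",8,20, "H",19,11, "V",30,21,
               "E",26,28)),
    p = list(k("S",5,24, "H",9,1, "H",14,27, "V",24,18, "C",13,10,
               "E",26,14)),
    q = list(k("S",27,25, "H",17,28, "V",7,20, "H",17,12, "H",28,26,
               "H",31,2, "E",36,9)),
    r = list(k("S",6,11, "C",10,28, "C",8,12, "H",16,22, "E",20,9)),
    s = list(k("S",6,11, "C",12,28, "V",4,18, "H",12,10, "E",22,14)),
    u = list(k("S",5,27, "H",10,11, "H",16,27, "H",22,11, "E",27,26)),
    v = list(k("S",6,27, "H",14,10, "E",22,26)),
    w = list(k("S",3,26, "H",8,10, "H",12,24, "H",17,10, "H",21,24,
               "H",26,10, "E",31,26)),
    y = list(k("S",5,26, "H",10,11, "C",16,27, "H",10,1, "V",5,5,
               "E",14,9)),
    z = list(k("S",4,26, "C",20,29, "V",5,12, "E",22,8)))
  protos
}

#' Writer style
#'
#' A parametric writing style applied to letter prototypes: a slant
#' shear, per-axis scaling, a roundness factor multiplying tangent
#' speeds, Gaussian trial-to-trial jitter at via-points, and a bias over
#' allograph variants.
#'
#' @param name Writer label.
#' @param slant Shear angle in degrees; positive slants tops to the
#'   right (`x' = x + (y - 20) tan(slant)`).
#' @param scale_x,scale_y Multiplicative scales about the box centre.
#' @param roundness Multiplier on the pen speed at tangent via-points
#'   (rounder styles sweep through extrema faster).
#' @param jitter_pos Std of via-point position noise (grid units).
#' @param jitter_vel Std of via-point velocity noise (grid units/time).
#' @param allograph_bias Probability of a letter's primary variant; the
#'   remainder is split over its other allographs.
#' @return A `writer_style` list.
#' @export
writer_style <- function(name, slant = 0, scale_x = 1, scale_y = 1,
                         roundness = 1, jitter_pos = 0.8,
                         jitter_vel = 0.08, allograph_bias = 0.8) {
  stopifnot(scale_x > 0, scale_y > 0, roundness > 0,
            jitter_pos >= 0, jitter_vel >= 0,
            allograph_bias >= 0, allograph_bias <= 1)
  structure(list(name = name, slant = slant, scale_x = scale_x,
                 scale_y = scale_y, roundness = roundness,
                 jitter_pos = jitter_pos, jitter_vel = jitter_vel,
                 allograph_bias = allograph_bias),
            class = "writer_style")
}

#' Default writer styles
#'
#' Four styles with distinct slant, scale and roundness, including one
#' markedly rounded and one markedly slanted hand, so both letter and
#' writer recognition are learnable from the synthetic corpus.
#'
#' @return A list of four [writer_style()] objects.
#' @export
default_writer_styles <- function() {
  list(writer_style("upright"),
       writer_style("slanted", slant = 18, scale_x = 0.95,
                    roundness = 0.9),
       writer_style("rounded", slant = 4, scale_x = 1.15, scale_y = 0.95,
                    roundness = 1.4),
       writer_style("cramped", slant = -10, scale_x = 0.8,
                    scale_y = 1.05, roundness = 0.75))
}

# velocities at skeleton knots from local geometry.  Tangent knots get
# the nominal speed along the travel direction, capped relative to the
# adjacent chords so the cubic segments stay monotone in the constrained
# component (no spurious zero crossings); cusps are zero; terminals move
# along the adjacent chord at a fraction of the nominal speed.
skeleton_velocities <- function(knots, ref_speed = 1, roundness = 1,
                                min_T = 0.1) {
  n <- nrow(knots)
  dx <- diff(knots$x); dy <- diff(knots$y)
  dist <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  Tseg <- pmax(dist / ref_speed, min_T)
  vx <- vy <- numeric(n)
  nominal <- ref_speed * roundness
  for (i in seq_len(n)) {
    kind <- knots$kind[i]
    if (kind == "cusp") next
    if (kind == "start") {
      u <- c(dx[1], dy[1]) / dist[1]
      vx[i] <- 0.8 * nominal * u[1]; vy[i] <- 0.8 * nominal * u[2]
    } else if (kind == "end") {
      u <- c(dx[n - 1], dy[n - 1]) / dist[n - 1]
      vx[i] <- 0.8 * nominal * u[1]; vy[i] <- 0.8 * nominal * u[2]
    } else if (kind == "horizontal_tangent") {
      s <- sign(if (dx[i] != 0) dx[i] else dx[i - 1])
      cap <- 2.5 * min(abs(dx[i - 1]) / Tseg[i - 1],
                       abs(dx[i]) / Tseg[i])
      vx[i] <- s * min(nominal, cap)
    } else if (kind == "vertical_tangent") {
      s <- sign(if (dy[i] != 0) dy[i] else dy[i - 1])
      cap <- 2.5 * min(abs(dy[i - 1]) / Tseg[i - 1],
                       abs(dy[i]) / Tseg[i])
      vy[i] <- s * min(nominal, cap)
    }
  }
  list(vx = vx, vy = vy)
}

#' Synthesize one handwriting trial
#'
#' Draws an allograph variant, applies the writer's scale and slant to
#' the skeleton, adds seeded Gaussian jitter at the via-points, derives
#' knot velocities from the transformed geometry, and generates the
#' full pen trajectory through minimum-acceleration segments.
#' Deterministic given the seed.
#'
#' @param prototype One element of [default_prototypes()] (a list of
#'   variant data frames), or a single variant data frame.
#' @param style A [writer_style()].
#' @param seed Integer seed.
#' @param cfg A [generation_config()].
#' @return A [trajectory()].
#' @export
synthesize_trial <- function(prototype, style, seed,
                             cfg = generation_config()) {
  if (is.data.frame(prototype)) prototype <- list(prototype)
  with_seed(seed, {
    nv <- length(prototype)
    probs <- if (nv == 1L) 1 else
      c(style$allograph_bias, rep((1 - style$allograph_bias) / (nv - 1L),
                                  nv - 1L))
    knots <- prototype[[sample.int(nv, 1L, prob = probs)]]
    x <- 20 + style$scale_x * (knots$x - 20)
    y <- 20 + style$scale_y * (knots$y - 20)
    x <- x + (y - 20) * tanpi(style$slant / 180)
    x <- x + stats::rnorm(length(x), 0, style$jitter_pos)
    y <- y + stats::rnorm(length(y), 0, style$jitter_pos)
    clipped <- x < 0 | x > 40 | y < 0 | y > 40
    if (any(clipped)) {
      warning("via-point jittered outside the writing box; clipped",
              call. = FALSE)
      x <- pmin(pmax(x, 0), 40); y <- pmin(pmax(y, 0), 40)
    }
    tk <- data.frame(x = x, y = y, kind = knots$kind)
    v <- skeleton_velocities(tk, ref_speed = cfg$ref_speed,
                             roundness = style$roundness,
                             min_T = cfg$min_T)
    vx <- v$vx + stats::rnorm(length(x), 0, style$jitter_vel)
    vy <- v$vy + stats::rnorm(length(y), 0, style$jitter_vel)
    seq <- viapoint_seq(x, y, vx, vy, knots$kind,
                        seq_len(nrow(knots)))
    generate_trajectory(seq, cfg)
  })
}

#' Build a synthetic handwriting corpus
#'
#' For every (writer style, letter) pair, synthesizes the requested
#' number of trials with per-trial seeds derived from the corpus seed.
#' Each trial is validated through the via-point extractor (a rare
#' jitter configuration exceeding 16 via-points is re-drawn, up to 10
#' times, with further derived seeds).  The manifest records everything
#' needed to rebuild the corpus bit-identically.
#'
#' @param styles List of [writer_style()] objects.
#' @param trials_per_letter Trials per (writer, letter) pair.
#' @param seed Corpus seed.
#' @param letters Letters to include (default: all 22 prototypes).
#' @param cfg A [generation_config()].
#' @return A `writing_corpus`: list with `trajectories` (list of
#'   [trajectory()]), `viapoints` (their extracted [viapoint_seq()]s),
#'   `labels` (data frame with `letter`, `writer`, `trial`, `seed`) and
#'   `manifest`.
#' @export
build_corpus <- function(styles = default_writer_styles(),
                         trials_per_letter = 40, seed = 1,
                         letters = names(default_prototypes()),
                         cfg = generation_config()) {
  stopifnot(length(styles) >= 1L, trials_per_letter >= 1L)
  protos <- default_prototypes()[letters]
  writers <- vapply(styles, `[[`, "", "name")
  n_total <- length(styles) * length(letters) * trials_per_letter
  seeds <- derive_seeds(seed, 2L * n_total)  # second half for retries
  trajectories <- vector("list", n_total)
  viapoints <- vector("list", n_total)
  labels <- data.frame(letter = character(n_total),
                       writer = character(n_total),
                       trial = integer(n_total), seed = integer(n_total))
  i <- 0L; retry_pool <- n_total
  for (w in seq_along(styles)) for (l in seq_along(letters)) {
    for (tr in seq_len(trials_per_letter)) {
      i <- i + 1L
      s <- seeds[i]
      for (attempt in 1:10) {
        tj <- synthesize_trial(protos[[l]], styles[[w]], s, cfg)
        vp <- tryCatch(extract_viapoints(tj),
                       viapoint_overflow = function(e) NULL)
        if (!is.null(vp)) break
        retry_pool <- retry_pool + 1L
        s <- seeds[retry_pool]
      }
      if (is.null(vp))
        stop("could not synthesize a valid trial for letter ",
             letters[l], ", writer ", writers[w], call. = FALSE)
      trajectories[[i]] <- tj
      viapoints[[i]] <- vp
      labels$letter[i] <- letters[l]; labels$writer[i] <- writers[w]
      labels$trial[i] <- tr; labels$seed[i] <- s
    }
  }
  structure(list(
    trajectories = trajectories, viapoints = viapoints, labels = labels,
    manifest = list(seed = seed, trials_per_letter = trials_per_letter,
                    letters = letters, writers = writers,
                    styles = lapply(styles, unclass),
                    generation = unclass(cfg))),
    class = "writing_corpus")
}

#' @export
print.writing_corpus <- function(x, ...) {
  cat(sprintf("<writing_corpus> %d trajectories: %d writers x %d letters x %d trials\n",
              length(x$trajectories), length(x$manifest$writers),
              length(x$manifest$letters), x$manifest$trials_per_letter))
  invisible(x)
}

#' Fit the letter model to (a subset of) a corpus
#'
#' Fits the discretization grid on the selected trials, discretizes
#' their via-point sequences, and fits the Laplace-smoothed Markov
#' letter representation.
#'
#' @param corpus A [build_corpus()] result.
#' @param indices Trial indices to train on (default: all).
#' @param pos_width,vel_width Smoothing widths, see
#'   [fit_letter_model()].
#' @param writer_set Writer label universe (default: the corpus
#'   manifest's writers); restrict it for leave-one-writer-out fits.
#' @return A [fit_letter_model()] result.
#' @export
fit_corpus_model <- function(corpus, indices = NULL,
                             pos_width = 9, vel_width = 7,
                             writer_set = corpus$manifest$writers) {
  stopifnot(inherits(corpus, "writing_corpus"))
  if (is.null(indices)) indices <- seq_along(corpus$trajectories)
  seqs <- corpus$viapoints[indices]
  grid <- fit_grid(seqs)
  bins <- lapply(seqs, discretize_sequence, grid = grid)
  fit_letter_model(bins,
                   letters = corpus$labels$letter[indices],
                   writers = corpus$labels$writer[indices],
                   letter_set = corpus$manifest$letters,
                   writer_set = writer_set,
                   grid = grid,
                   pos_width = pos_width, vel_width = vel_width)
}
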