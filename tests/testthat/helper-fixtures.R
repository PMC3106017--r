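# shared fixtures, built once per test run and cached

fixture_env <- new.env(parent = emptyenv())

# reference synthetic corpus: 4 default writer styles x 22 letters x 40
# trials, fixed reference seed
default_corpus <- function() {
  if (is.null(fixture_env$corpus))
    fixture_env$corpus <- suppressWarnings(build_corpus(seed = 20211))
  fixture_env$corpus
}

default_model <- function() {
  if (is.null(fixture_env$model))
    fixture_env$model <- fit_corpus_model(default_corpus())
  fixture_env$model
}

# analytic trajectories with known via-point structure
line_traj <- function(n = 51)
  trajectory(seq(0, 1, length.out = n),
             seq(0, 10, length.out = n), rep(0, n))

arch_traj <- function(n = 101) {
  t <- seq(0, 1, length.out = n)
  trajectory(t, t, sin(pi * t))
}

# full circle starting at theta = pi/4 so the four cardinal tangent
# points are interior
circle_traj <- function(n = 201) {
  th <- seq(pi / 4, pi / 4 + 2 * pi, length.out = n)
  trajectory(seq(0, 1, length.out = n), cos(th), sin(th))
}

# tiny labelled corpus of discretized sequences for two synthetic
# "letters" with disjoint via-point supports
toy_two_letter_fit <- function(extra_letters = character()) {
  seq_a <- cbind(xb = c(2L, 10L, 2L), yb = c(2L, 10L, 18L),
                 vxb = c(1L, 0L, 1L), vyb = c(1L, 1L, 0L))
  seq_b <- cbind(xb = c(38L, 30L, 38L), yb = c(38L, 30L, 22L),
                 vxb = c(-1L, 0L, -1L), vyb = c(-1L, -1L, 0L))
  bins <- c(replicate(3, seq_a, simplify = FALSE),
            replicate(3, seq_b, simplify = FALSE))
  fit_letter_model(bins,
                   letters = rep(c("A", "B"), each = 3),
                   writers = rep("w0", 6),
                   letter_set = c("A", "B", extra_letters),
                   writer_set = "w0")
}
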