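# regenerate a clean trial of a letter for task tests
clean_trial <- function(letter, style = writer_style("w", jitter_pos = 0,
                                                     jitter_vel = 0),
                        seed = 1)
  synthesize_trial(default_prototypes()[[letter]], style, seed)

test_that("disjoint-support toy letters are recognized near-certainly", {
  model <- toy_two_letter_fit()
  vp <- undiscretize_sequence(
    cbind(xb = c(2L, 10L, 2L), yb = c(2L, 10L, 18L),
          vxb = c(1L, 0L, 1L), vyb = c(1L, 1L, 0L)), model$grid)
  tr <- generate_trajectory(vp)
  r <- recognize_letter(tr, model, "w0")
  expect_equal(r$answer, "A")
  expect_gt(r$posterior[["A"]], 0.99)
})

test_that("posteriors are normalized and strictly positive", {
  model <- default_model()
  tr <- clean_trial("e")
  for (r in list(recognize_letter(tr, model, "upright"),
                 recognize_letter(tr, model),
                 recognize_writer(tr, model, "e"),
                 recognize_joint(tr, model),
                 recognize_with_simulation(tr, model, "upright"))) {
    expect_equal(sum(r$posterior), 1, tolerance = 1e-12)
    expect_true(all(r$posterior > 0))
    expect_true(r$answer %in% names(r$posterior))
  }
})

test_that("writer-marginal recognition equals a brute-force double loop", {
  model <- default_model()
  tr <- clean_trial("s")
  bins <- discretize_sequence(extract_viapoints(tr), model$grid)
  # oracle: per-(writer, letter) scalar scores mixed explicitly
  W <- length(model$writers); L <- length(model$letters)
  ev <- matrix(NA_real_, W, L)
  for (w in seq_len(W)) for (l in seq_len(L))
    ev[w, l] <- exp(sequence_log_score(bins, model$letters[l],
                                       model$writers[w], model))
  expected <- colSums(ev / W)
  expected <- expected / sum(expected)
  r <- recognize_letter(tr, model)
  expect_equal(unname(r$posterior), unname(expected), tolerance = 1e-9)

  # letter-marginal writer recognition likewise
  expected_w <- rowSums(ev / L); expected_w <- expected_w / sum(expected_w)
  rw <- recognize_writer(tr, model)
  expect_equal(unname(rw$posterior), unname(expected_w),
               tolerance = 1e-9)
})

test_that("joint posterior marginals match the single-label tasks", {
  model <- default_model()
  tr <- clean_trial("g", seed = 3)
  rj <- recognize_joint(tr, model)
  P <- rj$artifacts$posterior_matrix
  rl <- recognize_letter(tr, model)
  rw <- recognize_writer(tr, model)
  expect_equal(unname(colSums(P)), unname(rl$posterior),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(P)), unname(rw$posterior),
               tolerance = 1e-12)
})

test_that("recognition on letters without data is uniform", {
  model <- toy_two_letter_fit(extra_letters = c("U1", "U2"))
  vp <- undiscretize_sequence(
    cbind(xb = c(20L, 25L), yb = c(20L, 30L), vxb = c(1L, 1L),
          vyb = c(2L, 1L)), model$grid)
  r <- recognize_letter(generate_trajectory(vp), model, "w0")
  expect_equal(r$posterior[["U1"]], r$posterior[["U2"]],
               tolerance = 1e-12)
})

test_that("writing is seed-deterministic but varies across seeds", {
  model <- default_model()
  w1 <- write_letter("m", "rounded", model, 42)
  w2 <- write_letter("m", "rounded", model, 42)
  expect_identical(w1$trajectory, w2$trajectory)
  w3 <- write_letter("m", "rounded", model, 43)
  expect_false(identical(w1$bins, w3$bins))
})

test_that("writing through the arm reproduces the planned letter", {
  model <- default_model()
  arm <- two_joint_arm()
  w <- write_letter("c", "upright", model, 7, effector = arm)
  expect_s3_class(w$arm_trajectory, "trajectory")
  placed <- workspace_placement(w$trajectory, arm)
  unit <- 0.25 * (arm$L1 + arm$L2) / 40
  err <- max(sqrt((w$arm_trajectory$x - placed$x)^2 +
                  (w$arm_trajectory$y - placed$y)^2))
  expect_lt(err, 2 * unit)
})

test_that("the writing loop closes: written letters are read back", {
  model <- default_model()
  ok <- 0
  for (l in c("a", "f", "n", "w")) for (s in 1:5) {
    w <- write_letter(l, "upright", model, s)
    r <- recognize_letter(w$trajectory, model, "upright")
    ok <- ok + (r$answer == l)
  }
  expect_gte(ok, 18)
})

test_that("copies coincide with the input at every via-point", {
  inputs <- list(clean_trial("o"), clean_trial("z", seed = 2),
                 line_traj())
  for (tr in inputs) {
    cp <- copy_trajectory(tr)
    vp <- cp$viapoints
    for (i in seq_len(nrow(vp))) {
      d <- sqrt((cp$trajectory$x - vp$x[i])^2 +
                (cp$trajectory$y - vp$y[i])^2)
      expect_lt(min(d), 1e-9)
    }
  }
})

test_that("unknown symbols are copied without any letter knowledge", {
  th <- seq(0, 3 * pi, length.out = 200)
  spiral <- trajectory(seq(0, 1, length.out = 200),
                       (1 + th) * cos(th) / 10, (1 + th) * sin(th) / 10)
  cp <- copy_trajectory(spiral)
  expect_s3_class(cp$trajectory, "trajectory")
  expect_lte(nrow(cp$viapoints), 16)
  # the copy follows the spiral closely between via-points too
  ref <- cbind(spiral$x, spiral$y)
  err <- max(apply(cbind(cp$trajectory$x, cp$trajectory$y), 1, function(p)
    min(sqrt((ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2))))
  expect_lt(err, 0.4)
})

test_that("letter copying transfers the output writer's style", {
  model <- default_model()
  tr <- clean_trial("b", writer_style("w", jitter_pos = 0,
                                      jitter_vel = 0), 1)
  cp1 <- copy_letter(tr, "upright", "slanted", model, 11)
  cp2 <- copy_letter(tr, "upright", "slanted", model, 11)
  expect_identical(cp1$trajectory, cp2$trajectory)
  votes <- 0
  for (s in 1:6) {
    cp <- copy_letter(tr, "upright", "slanted", model, s)
    rw <- recognize_writer(cp$trajectory, model, "b")
    votes <- votes + (rw$answer == "slanted")
  }
  expect_gte(votes, 4)
})

test_that("an unfamiliar input is copied as the nearest letter", {
  model <- default_model()
  # a blob that is no letter of the repertoire
  vp <- viapoint_seq(x = c(10, 25, 12), y = c(12, 25, 30),
                     vx = c(1, 0.5, -0.5), vy = c(1, 0.8, 0.5),
                     kind = c("start", "free", "end"),
                     sample_index = 1:3)
  blob <- generate_trajectory(vp)
  cp <- copy_letter(blob, "upright", "upright", model, 2)
  r <- recognize_letter(cp$trajectory, model, "upright")
  expect_true(r$answer %in% model$letters)
})

test_that("the simulation posterior factorizes over the two terms", {
  model <- default_model()
  tr <- clean_trial("h", seed = 5)
  r <- recognize_with_simulation(tr, model, "upright")
  t1 <- r$artifacts$log_evidence_perception
  t2 <- r$artifacts$log_evidence_simulation
  s <- t1 + t2
  expect_equal(unname(r$posterior),
               unname(exp(s - max(s)) / sum(exp(s - max(s)))),
               tolerance = 1e-12)
  # oracle: both terms recomputed independently from the artifacts
  b1 <- discretize_sequence(r$artifacts$viapoints, model$grid)
  b2 <- discretize_sequence(r$artifacts$simulated_viapoints, model$grid)
  wi <- match("upright", model$writers)
  expect_equal(t1, sequence_log_score_all(b1, model)[wi, ])
  expect_equal(t2, sequence_log_score_all(b2, model)[wi, ])
})

test_that("identical simulated percepts square the posterior", {
  model <- default_model()
  tr <- clean_trial("l", seed = 9)
  r <- recognize_with_simulation(tr, model, "upright")
  b1 <- discretize_sequence(r$artifacts$viapoints, model$grid)
  b2 <- discretize_sequence(r$artifacts$simulated_viapoints, model$grid)
  if (identical(b1, b2)) {
    t1 <- r$artifacts$log_evidence_perception
    sq <- exp(2 * (t1 - max(t1))); sq <- sq / sum(sq)
    expect_equal(unname(r$posterior), unname(sq), tolerance = 1e-12)
  }
  expect_equal(r$answer,
               recognize_letter(tr, model, "upright")$answer)
})

test_that("motor simulation rescues the committed truncated letter", {
  model <- default_model()
  tr <- read_trajectory_csv(
    system.file("extdata", "synthetic_truncated_letter.csv",
                package = "graphomotor"))
  plain <- recognize_letter(tr, model, "rounded")
  sim <- recognize_with_simulation(tr, model, "rounded")
  expect_false(plain$answer == "b")
  expect_equal(sim$answer, "b")
})

test_that("sampled and argmax answer policies behave as configured", {
  model <- toy_two_letter_fit()
  vp <- undiscretize_sequence(
    cbind(xb = c(2L, 10L, 2L), yb = c(2L, 10L, 18L),
          vxb = c(1L, 0L, 1L), vyb = c(1L, 1L, 0L)), model$grid)
  tr <- generate_trajectory(vp)
  expect_error(recognize_letter(tr, model, "w0",
                                answer_policy = "sample"), "seed")
  r1 <- recognize_letter(tr, model, "w0", answer_policy = "sample",
                         seed = 5)
  r2 <- recognize_letter(tr, model, "w0", answer_policy = "sample",
                         seed = 5)
  expect_identical(r1$answer, r2$answer)
})
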