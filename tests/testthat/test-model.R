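test_that("the Laplace succession law matches direct evaluation", {
  expect_equal(laplace_probability(0, 0, 41), 1 / 41)
  expect_equal(laplace_probability(3, 10, 41), 4 / 51)
  # normalization: counts summing to n give probabilities summing to 1
  counts <- c(4, 0, 6, 0, 0)
  expect_equal(sum(laplace_probability(counts, sum(counts), 5)), 1)
  expect_error(laplace_probability(-1, 3, 41), "requires")
  expect_error(laplace_probability(5, 3, 41), "requires")
  expect_error(laplace_probability(0, 0, 1), "requires")
})

test_that("binomial smoothing conserves mass, fixes uniforms, spreads deltas", {
  expect_error(smooth_counts(1:5, 4), "odd")

  u <- rep(3.5, 41)
  expect_equal(smooth_counts(u, 9), u, tolerance = 1e-12)

  # a unit count away from boundaries spreads as binomial(8, k)/256
  d <- numeric(41); d[21] <- 1
  sm <- smooth_counts(d, 9)
  expect_equal(sm[17:25], choose(8, 0:8) / 256, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-9)

  set.seed(4)
  for (i in 1:20) {
    v <- rpois(41, 2) * runif(41)
    v[1:3] <- v[1:3] + 5   # boundary-heavy mass
    expect_equal(sum(smooth_counts(v, 9)), sum(v), tolerance = 1e-9)
    w <- rpois(7, 1)
    expect_equal(sum(smooth_counts(w, 7)), sum(w), tolerance = 1e-9)
  }
})

test_that("fitting validates labels and rejects empty corpora", {
  b <- cbind(xb = c(1L, 2L), yb = c(1L, 2L), vxb = c(0L, 0L),
             vyb = c(0L, 1L))
  expect_error(fit_letter_model(list(), character(), character()),
               "empty")
  expect_error(
    fit_letter_model(list(b), "z", "w0", letter_set = "a",
                     writer_set = "w0"),
    "letter label")
  expect_error(
    fit_letter_model(list(b), "a", "w9", letter_set = "a",
                     writer_set = "w0"),
    "writer label")
})

test_that("unobserved contexts fall back to the uniform Laplace floor", {
  model <- toy_two_letter_fit()
  # context: previous x bin 39 at index 2 for letter A was never seen
  expect_equal(model$n_trans[[1]][40, 1, 1, 1], 0)
  b <- cbind(xb = c(5L, 39L, 7L), yb = c(2L, 10L, 18L),
             vxb = c(0L, 0L, 0L), vyb = c(0L, 0L, 0L))
  # the x transition term for that context contributes log(1/41)
  s <- sequence_log_score(b, "A", "w0", model)
  expect_true(is.finite(s))
})

test_that("duplicated corpora double raw counts and smoothing is linear", {
  b1 <- cbind(xb = c(3L, 12L), yb = c(5L, 9L), vxb = c(1L, 0L),
              vyb = c(0L, -1L))
  m1 <- fit_letter_model(list(b1), "a", "w", letter_set = "a",
                         writer_set = "w")
  m2 <- fit_letter_model(list(b1, b1), c("a", "a"), c("w", "w"),
                         letter_set = "a", writer_set = "w")
  for (d in 1:4) {
    expect_equal(m2$init_raw[[d]], 2 * m1$init_raw[[d]])
    expect_equal(m2$init[[d]], 2 * m1$init[[d]], tolerance = 1e-12)
    expect_equal(m2$trans[[d]], 2 * m1$trans[[d]], tolerance = 1e-12)
  }
})

test_that("free-parameter accounting reproduces the printed figures", {
  expect_equal(count_free_parameters(4, 22, 41, 7, order = 1), 296032)
  expect_equal(count_free_parameters(4, 22, 41, 7, order = 2), 11885984)
  expect_equal(count_free_parameters(4, 22, 41, 7, order = 3), 485566048)
  expect_equal(count_free_parameters(4, 22, 41, 7, joint = TRUE),
               597042141696)
  expect_error(count_free_parameters(4, 22, 41, 7, order = 2,
                                     joint = TRUE), "order 1")
})

test_that("fitted table shapes agree with the parameter accounting", {
  model <- toy_two_letter_fit()
  W <- length(model$writers); L <- length(model$letters)
  P <- dim(model$trans[[1]])[1]; V <- dim(model$trans[[3]])[1]
  per_index <- 2 * W * L * P * (P - 1) + 2 * W * L * V * (V - 1)
  expect_equal(per_index,
               count_free_parameters(W, L, P, V, order = 1))
  expect_equal(dim(model$trans[[1]])[2], P)   # conditioned on same dim
  expect_equal(dim(model$trans[[3]])[2], V)
})

test_that("sequence scores equal a brute-force product of Laplace terms", {
  model <- toy_two_letter_fit()
  b <- cbind(xb = c(2L, 10L, 3L), yb = c(2L, 11L, 18L),
             vxb = c(1L, 0L, 1L), vyb = c(1L, 1L, 0L))
  # independent oracle: accumulate the Laplace terms one by one
  wi <- 1L; li <- 1L
  off <- c(1L, 1L, 4L, 4L); K <- c(41L, 41L, 7L, 7L)
  expected <- log((model$len_counts[nrow(b) - 1, wi, li] + 1) /
                  (model$n_len[wi, li] + 15))
  for (d in 1:4) {
    v <- b[, d] + off[d]
    expected <- expected +
      log((model$init[[d]][v[1], wi, li] + 1) /
          (model$n_init[[d]][wi, li] + K[d]))
    for (j in 2:nrow(b))
      expected <- expected +
        log((model$trans[[d]][v[j], v[j - 1], j - 1, wi, li] + 1) /
            (model$n_trans[[d]][v[j - 1], j - 1, wi, li] + K[d]))
  }
  expect_equal(sequence_log_score(b, "A", "w0", model), expected)
  expect_error(sequence_log_score(b, "Z", "w0", model), "unknown letter")
})

test_that("letters without training data score all equal-length inputs alike", {
  model <- toy_two_letter_fit(extra_letters = c("U1", "U2"))
  b1 <- cbind(xb = c(2L, 30L), yb = c(9L, 3L), vxb = c(0L, 1L),
              vyb = c(1L, 0L))
  b2 <- cbind(xb = c(33L, 5L), yb = c(21L, 36L), vxb = c(-2L, 0L),
              vyb = c(0L, 2L))
  expect_equal(sequence_log_score(b1, "U1", "w0", model),
               sequence_log_score(b2, "U2", "w0", model))
})

test_that("training exemplars outscore far-shifted sequences", {
  model <- toy_two_letter_fit()
  exemplar <- cbind(xb = c(2L, 10L, 2L), yb = c(2L, 10L, 18L),
                    vxb = c(1L, 0L, 1L), vyb = c(1L, 1L, 0L))
  shifted <- exemplar
  shifted[, c("xb", "yb")] <- shifted[, c("xb", "yb")] + 20L
  expect_gt(sequence_log_score(exemplar, "A", "w0", model),
            sequence_log_score(shifted, "A", "w0", model))
})

test_that("an added observation never lowers its own Laplace probability", {
  set.seed(12)
  for (i in 1:50) {
    counts <- rpois(41, 1)
    v <- sample(41, 1)
    before <- laplace_probability(counts[v], sum(counts), 41)
    counts[v] <- counts[v] + 1
    after <- laplace_probability(counts[v], sum(counts), 41)
    expect_gte(after, before)
  }
})

test_that("fitted conditional distributions are normalized and positive", {
  model <- default_model()
  set.seed(31)
  for (rep in 1:60) {
    d <- sample(4, 1)
    wi <- sample(length(model$writers), 1)
    li <- sample(length(model$letters), 1)
    K <- dim(model$init[[d]])[1]
    p0 <- laplace_probability(model$init[[d]][, wi, li],
                              model$n_init[[d]][wi, li], K)
    expect_equal(sum(p0), 1, tolerance = 1e-12)
    expect_true(all(p0 > 0))
    prev <- sample(K, 1); j <- sample(15, 1)
    p1 <- laplace_probability(model$trans[[d]][, prev, j, wi, li],
                              model$n_trans[[d]][prev, j, wi, li], K)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_true(all(p1 > 0))
  }
})

test_that("via-point sampling is seed-deterministic and variable", {
  model <- default_model()
  a <- sample_viapoint_sequence("a", "upright", model, 99)
  b <- sample_viapoint_sequence("a", "upright", model, 99)
  expect_identical(a, b)
  draws <- lapply(1:8, function(s)
    sample_viapoint_sequence("a", "upright", model, s))
  expect_gt(length(unique(lapply(draws, c))), 1)
  for (d in draws) {
    expect_true(all(d[, c("xb", "yb")] >= 0 & d[, c("xb", "yb")] <= 40))
    expect_true(all(abs(d[, c("vxb", "vyb")]) <= 3))
    expect_true(nrow(d) >= 2 && nrow(d) <= 16)
  }
  expect_error(sample_viapoint_sequence("?", "upright", model, 1),
               "unknown letter")
})

test_that("a single-exemplar model reproduces its exemplar when sampled", {
  b1 <- cbind(xb = c(3L, 12L, 30L), yb = c(5L, 9L, 2L),
              vxb = c(1L, 0L, 2L), vyb = c(0L, -1L, 1L))
  m <- fit_letter_model(list(b1), "a", "w", letter_set = "a",
                        writer_set = "w")
  for (s in 1:25)
    expect_identical(unname(sample_viapoint_sequence("a", "w", m, s)),
                     unname(b1))
})

test_that("model files reload to an identical model", {
  small <- suppressWarnings(
    build_corpus(trials_per_letter = 2, seed = 5,
                 letters = c("a", "o", "l"),
                 styles = default_writer_styles()[1:2]))
  m1 <- fit_corpus_model(small)
  path <- withr::local_tempfile(fileext = ".json")
  write_letter_model(m1, path)
  m2 <- read_letter_model(path)
  b <- discretize_sequence(small$viapoints[[1]], m1$grid)
  expect_equal(sequence_log_score_all(b, m2),
               sequence_log_score_all(b, m1), tolerance = 1e-12)
  expect_identical(sample_viapoint_sequence("o", m1$writers[1], m2, 7),
                   sample_viapoint_sequence("o", m1$writers[1], m1, 7))
  expect_equal(m2$grid$height, m1$grid$height)
})
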