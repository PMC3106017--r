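#' K-fold cross-validated recognition on a corpus
#'
#' Splits each (writer, letter) cell's trials into `k` contiguous folds
#' (e.g. 8 folds of a 40-trial corpus give the 35-train / 5-test
#' protocol), refits the model — including the grid — on each training
#' split, and answers on the held-out trials.  Answers are drawn from
#' the posterior with per-trial derived seeds (set
#' `answer_policy = "argmax"` for the deterministic variant).
#'
#' @param corpus A [build_corpus()] result (balanced).
#' @param task One of `"letter"` (writer known), `"letter_marginal"`
#'   (writer unknown), `"writer"` (letter known), `"letter_sim"`
#'   (writer known, with internal motor simulation).
#' @param k Number of folds; must divide `trials_per_letter`.
#' @param seed Seed for the answer draws.
#' @param answer_policy `"sample"` (default) or `"argmax"`.
#' @param cfg A [generation_config()] for the simulation branch.
#' @return A list with `rate` (overall correct-answer rate),
#'   `confusion` (row-normalized confusion matrix over the task's
#'   labels), `per_fold` rates and `n` test trials.
#' @export
kfold_evaluate <- function(corpus,
                           task = c("letter", "letter_marginal",
                                    "writer", "letter_sim"),
                           k = 8, seed = 1,
                           answer_policy = c("sample", "argmax"),
                           cfg = generation_config()) {
  task <- match.arg(task)
  answer_policy <- match.arg(answer_policy)
  stopifnot(inherits(corpus, "writing_corpus"))
  tpl <- corpus$manifest$trials_per_letter
  if (tpl %% k != 0)
    stop("k = ", k, " must divide trials_per_letter = ", tpl,
         call. = FALSE)
  tab <- table(corpus$labels$writer, corpus$labels$letter)
  if (length(unique(as.vector(tab))) != 1L)
    stop("corpus is unbalanced across (writer, letter) cells",
         call. = FALSE)
  fold_of <- (corpus$labels$trial - 1L) %/% (tpl %/% k) + 1L
  lab_set <- if (task == "writer") corpus$manifest$writers else
    corpus$manifest$letters
  truth_all <- if (task == "writer") corpus$labels$writer else
    corpus$labels$letter
  conf <- matrix(0, length(lab_set), length(lab_set),
                 dimnames = list(truth = lab_set, answer = lab_set))
  seeds <- derive_seeds(seed, length(corpus$trajectories))
  per_fold <- numeric(k); n_total <- 0L; n_correct <- 0L
  for (f in seq_len(k)) {
    train <- which(fold_of != f); test <- which(fold_of == f)
    model <- fit_corpus_model(corpus, train)
    ok <- 0L
    for (i in test) {
      bins <- discretize_sequence(corpus$viapoints[[i]], model$grid)
      le <- switch(task,
        letter = letter_log_evidence(bins, model,
                                     corpus$labels$writer[i]),
        letter_marginal = letter_log_evidence(bins, model, NULL),
        writer = writer_log_evidence(bins, model,
                                     corpus$labels$letter[i]),
        letter_sim = {
          t1 <- letter_log_evidence(bins, model,
                                    corpus$labels$writer[i])
          sim_bins <- tryCatch({
            sim <- generate_trajectory(
              corpus$viapoints[[i]],
              match_input_speed(cfg, corpus$trajectories[[i]]))
            discretize_sequence(extract_viapoints(sim), model$grid)
          }, viapoint_overflow = function(e) NULL)
          if (is.null(sim_bins)) t1 else
            t1 + letter_log_evidence(sim_bins, model,
                                     corpus$labels$writer[i])
        })
      post <- normalize_log_posterior(le)
      ans <- draw_answer(post, answer_policy, seeds[i])
      conf[truth_all[i], ans] <- conf[truth_all[i], ans] + 1
      if (ans == truth_all[i]) ok <- ok + 1L
    }
    per_fold[f] <- ok / length(test)
    n_total <- n_total + length(test); n_correct <- n_correct + ok
  }
  conf <- conf / pmax(rowSums(conf), 1)
  list(rate = n_correct / n_total, confusion = conf,
       per_fold = per_fold, n = n_total)
}

#' Novel-writer letter recognition
#'
#' Leave-one-writer-out protocol: the model is trained on all writers
#' but one and tested on every trial of the held-out writer, with the
#' writer variable marginalized at test time.  Generalizing across
#' hands is harder than recognizing a known hand, so this rate is
#' expected to sit below the within-writer rate on the same corpus.
#'
#' @inheritParams kfold_evaluate
#' @return A list with `rate`, `per_writer` rates and `n`.
#' @export
novel_writer_evaluate <- function(corpus, seed = 1,
                                  answer_policy = c("sample", "argmax")) {
  answer_policy <- match.arg(answer_policy)
  stopifnot(inherits(corpus, "writing_corpus"))
  writers <- corpus$manifest$writers
  seeds <- derive_seeds(seed, length(corpus$trajectories))
  per_writer <- stats::setNames(numeric(length(writers)), writers)
  n_total <- 0L; n_correct <- 0L
  for (w in writers) {
    train <- which(corpus$labels$writer != w)
    test <- which(corpus$labels$writer == w)
    model <- fit_corpus_model(corpus, train,
                              writer_set = setdiff(writers, w))
    ok <- 0L
    for (i in test) {
      bins <- discretize_sequence(corpus$viapoints[[i]], model$grid)
      post <- normalize_log_posterior(
        letter_log_evidence(bins, model, NULL))
      ans <- draw_answer(post, answer_policy, seeds[i])
      if (ans == corpus$labels$letter[i]) ok <- ok + 1L
    }
    per_writer[w] <- ok / length(test)
    n_total <- n_total + length(test); n_correct <- n_correct + ok
  }
  list(rate = n_correct / n_total, per_writer = per_writer, n = n_total)
}
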