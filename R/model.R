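#' Laplace succession law
#'
#' Add-one-smoothed categorical probability estimate: with `count_v`
#' observations of a value out of `n` total observations over `K`
#' possible values, the estimated probability is `(count_v + 1)/(n + K)`.
#' It is uniform (`1/K`) before any data and never zero.
#'
#' @param count_v Non-negative count of the value (may be fractional
#'   after smoothing).
#' @param n Total observations in the conditioning context
#'   (`n >= count_v`).
#' @param K Number of possible values (`K >= 2`).
#' @return The probability estimate.
#' @examples
#' laplace_probability(0, 0, 41)   # 1/41
#' laplace_probability(3, 10, 41)  # 4/51
#' @export
laplace_probability <- function(count_v, n, K) {
  if (any(count_v < 0) || any(n < count_v) || K < 2)
    stop("laplace_probability requires 0 <= count_v <= n and K >= 2",
         call. = FALSE)
  (count_v + 1) / (n + K)
}

# binomial smoothing kernel of odd width w: choose(w-1, 0:(w-1)) / 2^(w-1)
binomial_kernel <- function(width) {
  if (width %% 2 != 1) stop("smoothing width must be odd", call. = FALSE)
  choose(width - 1, 0:(width - 1)) / 2^(width - 1)
}

#' Binomial smoothing of count vectors
#'
#' Convolves each count vector (the first axis of `counts`) with a
#' binomial kernel of the given odd width.  At the boundaries the kernel
#' is truncated and its in-range weights renormalized (normalized
#' convolution), then the whole vector is rescaled so its total is
#' exactly preserved.  A uniform vector is a fixed point; an interior
#' unit count spreads as `choose(width-1, k) / 2^(width-1)`.
#'
#' @param counts A numeric vector, matrix, or array; smoothing acts
#'   along the first axis.
#' @param width Odd kernel width (9 for position dimensions, 7 for
#'   velocity dimensions).
#' @return Smoothed counts with the same shape.
#' @export
smooth_counts <- function(counts, width) {
  k <- binomial_kernel(width)
  d <- dim(counts)
  K <- if (is.null(d)) length(counts) else d[1]
  h <- (width - 1L) / 2L
  S <- matrix(0, K, K)
  for (i in seq_len(K)) {
    j <- max(1L, i - h):min(K, i + h)
    w <- k[j - i + h + 1L]
    S[i, j] <- w / sum(w)
  }
  M <- if (is.null(d)) matrix(counts, ncol = 1) else
    matrix(counts, nrow = K)
  out <- S %*% M
  tot_in <- colSums(M); tot_out <- colSums(out)
  scale <- ifelse(tot_out > 0, tot_in / tot_out, 1)
  out <- sweep(out, 2, scale, `*`)
  if (is.null(d)) as.numeric(out) else array(out, dim = d)
}

# dimension bookkeeping: 1 = x, 2 = y (41 position bins, offset 1),
# 3 = vx, 4 = vy (7 velocity bins, offset 4 so bin -3 -> index 1)
DIM_K   <- c(41L, 41L, 7L, 7L)
DIM_OFF <- c(1L, 1L, 4L, 4L)
MAX_VP  <- 16L
N_LEN   <- 15L  # sequence lengths 2..16

#' Fit the probabilistic letter representation
#'
#' Counts discretized via-point observations per (writer, letter,
#' via-point index, dimension): for the first via-point a marginal table
#' per dimension, for each subsequent index a first-order Markov
#' transition table conditioned on the same dimension of the previous
#' via-point.  Counts are smoothed with a binomial filter (width 9 for
#' positions, 7 for velocities) and turned into probabilities by the
#' Laplace succession law at query time.  A Laplace-smoothed table of
#' via-point counts N in 2..16 per (writer, letter) lets sequences of
#' different lengths compete in one posterior.
#'
#' @param corpus_bins List of integer bin matrices (rows = via-points,
#'   columns `xb`, `yb`, `vxb`, `vyb`), as from [discretize_sequence()].
#' @param letters,writers Character vectors: label of each sequence.
#' @param letter_set,writer_set Ordered label universes; default the
#'   sorted unique labels.
#' @param grid The [grid_spec()] the corpus was discretized with (stored
#'   in the model).
#' @param pos_width,vel_width Binomial smoothing widths (odd).
#' @return An object of class `letter_model`.
#' @export
fit_letter_model <- function(corpus_bins, letters, writers,
                             letter_set = sort(unique(letters)),
                             writer_set = sort(unique(writers)),
                             grid = grid_spec(),
                             pos_width = 9, vel_width = 7) {
  if (length(corpus_bins) == 0L) stop("empty corpus", call. = FALSE)
  stopifnot(length(letters) == length(corpus_bins),
            length(writers) == length(corpus_bins))
  if (!all(letters %in% letter_set))
    stop("letter label outside the declared letter set: ",
         paste(unique(setdiff(letters, letter_set)), collapse = ", "),
         call. = FALSE)
  if (!all(writers %in% writer_set))
    stop("writer label outside the declared writer set: ",
         paste(unique(setdiff(writers, writer_set)), collapse = ", "),
         call. = FALSE)
  W <- length(writer_set); L <- length(letter_set)
  li <- match(letters, letter_set); wi <- match(writers, writer_set)

  init  <- lapply(1:4, function(d) array(0, c(DIM_K[d], W, L)))
  trans <- lapply(1:4, function(d)
    array(0, c(DIM_K[d], DIM_K[d], MAX_VP - 1L, W, L)))
  len_counts <- array(0, c(N_LEN, W, L))

  for (s in seq_along(corpus_bins)) {
    b <- corpus_bins[[s]]
    N <- nrow(b)
    if (N < 2L || N > MAX_VP)
      stop("sequence ", s, " has ", N, " via-points (must be 2..16)",
           call. = FALSE)
    w <- wi[s]; l <- li[s]
    len_counts[N - 1L, w, l] <- len_counts[N - 1L, w, l] + 1
    for (d in 1:4) {
      bb <- b[, d] + DIM_OFF[d]
      init[[d]][bb[1L], w, l] <- init[[d]][bb[1L], w, l] + 1
      if (N > 1L) for (j in 2:N) {
        trans[[d]][bb[j], bb[j - 1L], j - 1L, w, l] <-
          trans[[d]][bb[j], bb[j - 1L], j - 1L, w, l] + 1
      }
    }
  }

  width_of <- c(pos_width, pos_width, vel_width, vel_width)
  init_raw <- init; trans_raw <- trans
  for (d in 1:4) {
    init[[d]]  <- smooth_counts(init[[d]],  width_of[d])
    trans[[d]] <- smooth_counts(trans[[d]], width_of[d])
  }

  model <- structure(list(
    format_version = 1L,
    letters = letter_set, writers = writer_set, grid = grid,
    smoothing = list(pos_width = pos_width, vel_width = vel_width),
    init = init, trans = trans,
    init_raw = init_raw, trans_raw = trans_raw,
    len_counts = len_counts,
    n_init  = lapply(init, function(a) apply(a, c(2, 3), sum)),
    n_trans = lapply(trans, function(a) apply(a, c(2, 3, 4, 5), sum)),
    n_len   = apply(len_counts, c(2, 3), sum)),
    class = "letter_model")
  model
}

#' @export
print.letter_model <- function(x, ...) {
  cat(sprintf(paste0("<letter_model> %d letters x %d writers, %g observed",
                     " sequences\n"),
              length(x$letters), length(x$writers), sum(x$len_counts)))
  cat("  letters:", paste(x$letters, collapse = " "), "\n")
  cat("  writers:", paste(x$writers, collapse = " "), "\n")
  invisible(x)
}

#' Log-probability of a discretized via-point sequence
#'
#' Sums, over via-point indices and the four dimensions, the log Laplace
#' probabilities of each observed bin given the previous one (the first
#' index is unconditioned), plus the log probability of the sequence
#' length.  `sequence_log_score_all()` evaluates the same quantity for
#' every (writer, letter) pair at once.
#'
#' @param bins Integer bin matrix as from [discretize_sequence()].
#' @param letter,writer Labels known to the model.
#' @param model A [fit_letter_model()] result.
#' @return `sequence_log_score()`: a scalar log-probability.
#'   `sequence_log_score_all()`: a writers x letters matrix.
#' @export
sequence_log_score <- function(bins, letter, writer, model) {
  li <- match(letter, model$letters); wi <- match(writer, model$writers)
  if (is.na(li)) stop("unknown letter: ", letter, call. = FALSE)
  if (is.na(wi)) stop("unknown writer: ", writer, call. = FALSE)
  sequence_log_score_all(bins, model)[wi, li]
}

#' @rdname sequence_log_score
#' @export
sequence_log_score_all <- function(bins, model) {
  stopifnot(inherits(model, "letter_model"))
  N <- nrow(bins)
  if (N < 2L || N > MAX_VP)
    stop("sequence length must be 2..16", call. = FALSE)
  W <- length(model$writers); L <- length(model$letters)
  S <- log(matrix(model$len_counts[N - 1L, , ], W, L) + 1) -
       log(matrix(model$n_len, W, L) + N_LEN)
  for (d in 1:4) {
    K <- DIM_K[d]
    bb <- bins[, d] + DIM_OFF[d]
    S <- S + log(matrix(model$init[[d]][bb[1L], , ], W, L) + 1) -
             log(model$n_init[[d]] + K)
    if (N > 1L) for (j in 2:N) {
      S <- S +
        log(matrix(model$trans[[d]][bb[j], bb[j - 1L], j - 1L, , ],
                   W, L) + 1) -
        log(matrix(model$n_trans[[d]][bb[j - 1L], j - 1L, , ], W, L) + K)
    }
  }
  dimnames(S) <- list(model$writers, model$letters)
  S
}

#' Draw a via-point sequence from the letter representation
#'
#' Ancestral sampling: the via-point count N is drawn from the length
#' table, the first via-point from the per-dimension initial tables, and
#' each subsequent via-point dimension-wise from the first-order
#' conditional tables.  Production draws from the raw (unsmoothed)
#' empirical distribution of each context (`c/n`), with a uniform
#' fallback for contexts that were never observed.  Recognition, by
#' contrast, always scores with the smoothed Laplace law: the add-one
#' floor and the binomial spread are what keep unseen evidence finite
#' and generalizable, but letting either leak into production would
#' scatter draws onto never-observed bins (the floor alone covers
#' roughly half the draw mass per dimension when, as here, the number
#' of training trials is comparable to the number of bins).
#'
#' @param letter,writer Labels known to the model.
#' @param model A [fit_letter_model()] result.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return An integer bin matrix (columns `xb`, `yb`, `vxb`, `vyb`).
#' @export
sample_viapoint_sequence <- function(letter, writer, model, seed) {
  li <- match(letter, model$letters); wi <- match(writer, model$writers)
  if (is.na(li)) stop("unknown letter: ", letter, call. = FALSE)
  if (is.na(wi)) stop("unknown writer: ", writer, call. = FALSE)
  draw_prob <- function(counts) {
    n <- sum(counts)
    if (n > 0) counts / n else rep(1 / length(counts), length(counts))
  }
  with_seed(seed, {
    N <- sample(2:MAX_VP, 1L,
                prob = draw_prob(model$len_counts[, wi, li]))
    b <- matrix(0L, N, 4L,
                dimnames = list(NULL, c("xb", "yb", "vxb", "vyb")))
    for (d in 1:4) {
      K <- DIM_K[d]
      p1 <- draw_prob(model$init_raw[[d]][, wi, li])
      b[1L, d] <- sample.int(K, 1L, prob = p1) - DIM_OFF[d]
      for (j in 2:N) {
        prev <- b[j - 1L, d] + DIM_OFF[d]
        pj <- draw_prob(model$trans_raw[[d]][, prev, j - 1L, wi, li])
        b[j, d] <- sample.int(K, 1L, prob = pj) - DIM_OFF[d]
      }
    }
    b
  })
}

#' Free-parameter accounting of the letter representation
#'
#' Number of free parameters of the per-via-point conditional tables,
#' for `W` writers, `L` letters, `P` position bins and `V` velocity bins.
#' Under the dimension-separable Markov model of order `k` each of the
#' two position dimensions contributes `W*L*P^k*(P-1)` parameters and
#' each velocity dimension `W*L*V^k*(V-1)` (one parameter per table is
#' fixed by normalization).  The non-separable (`joint = TRUE`)
#' first-order alternative over the full 4-D domain would need
#' `W*L*(P^2*V^2)*(P^2*V^2 - 1)`.
#'
#' @param n_writers,n_letters,pos_bins,vel_bins Domain sizes (>= 1).
#' @param order Markov order, 1, 2 or 3.
#' @param joint If `TRUE`, count the non-separable first-order model.
#' @return The exact count as a double (may exceed 32-bit integer range).
#' @examples
#' count_free_parameters(4, 22, 41, 7, order = 1)  # 296032
#' @export
count_free_parameters <- function(n_writers, n_letters, pos_bins, vel_bins,
                                  order = 1, joint = FALSE) {
  stopifnot(n_writers >= 1, n_letters >= 1, pos_bins >= 2, vel_bins >= 2,
            order %in% 1:3)
  if (joint) {
    if (order != 1)
      stop("the joint (non-separable) count is defined for order 1",
           call. = FALSE)
    D <- pos_bins^2 * vel_bins^2
    return(n_writers * n_letters * D * (D - 1))
  }
  2 * n_writers * n_letters * pos_bins^order * (pos_bins - 1) +
    2 * n_writers * n_letters * vel_bins^order * (vel_bins - 1)
}

#' Save and load a fitted letter model
#'
#' The model file is a versioned JSON archive holding labels, grid,
#' smoothing configuration, the raw count tables and the length table
#' at full double precision; the smoothed tables are reconstructed
#' deterministically on load, so reloading reproduces the model
#' exactly.
#'
#' @param model A [fit_letter_model()] result.
#' @param path File path.
#' @return `read_letter_model()` returns the `letter_model`;
#'   `write_letter_model()` returns `path` invisibly.
#' @export
write_letter_model <- function(model, path) {
  stopifnot(inherits(model, "letter_model"))
  obj <- list(
    format_version = model$format_version,
    letters = model$letters, writers = model$writers,
    grid = unclass(model$grid), smoothing = model$smoothing,
    init_raw = lapply(model$init_raw, as.numeric),
    trans_raw = lapply(model$trans_raw, as.numeric),
    len_counts = as.numeric(model$len_counts))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_letter_model
#' @export
read_letter_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported model file version in ", path, call. = FALSE)
  W <- length(obj$writers); L <- length(obj$letters)
  init_raw <- lapply(1:4, function(d)
    array(obj$init_raw[[d]], c(DIM_K[d], W, L)))
  trans_raw <- lapply(1:4, function(d)
    array(obj$trans_raw[[d]], c(DIM_K[d], DIM_K[d], MAX_VP - 1L, W, L)))
  width_of <- c(obj$smoothing$pos_width, obj$smoothing$pos_width,
                obj$smoothing$vel_width, obj$smoothing$vel_width)
  init <- lapply(1:4, function(d) smooth_counts(init_raw[[d]], width_of[d]))
  trans <- lapply(1:4, function(d) smooth_counts(trans_raw[[d]],
                                                 width_of[d]))
  structure(list(
    format_version = 1L,
    letters = obj$letters, writers = obj$writers,
    grid = grid_spec(obj$grid$x_min, obj$grid$y_min, obj$grid$height,
                     obj$grid$vel_scale),
    smoothing = obj$smoothing,
    init = init, trans = trans,
    init_raw = init_raw, trans_raw = trans_raw,
    len_counts = array(obj$len_counts, c(N_LEN, W, L)),
    n_init  = lapply(init, function(a) apply(a, c(2, 3), sum)),
    n_trans = lapply(trans, function(a) apply(a, c(2, 3, 4, 5), sum)),
    n_len   = apply(array(obj$len_counts, c(N_LEN, W, L)),
                    c(2, 3), sum)),
    class = "letter_model")
}
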