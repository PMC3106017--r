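#' Write and read a corpus on disk
#'
#' A corpus directory holds one trajectory CSV per trial
#' (`traj_000001.csv`, ...) plus a `manifest.json` recording labels,
#' per-trial seeds, style parameters and the generation configuration —
#' everything needed to rebuild the corpus from seeds alone.
#'
#' @param corpus A [build_corpus()] result.
#' @param dir Directory path (created if missing).
#' @return `read_corpus()` returns a `writing_corpus`;
#'   `write_corpus()` returns `dir` invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "writing_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("traj_%06d.csv", seq_along(corpus$trajectories))
  for (i in seq_along(corpus$trajectories))
    write_trajectory_csv(corpus$trajectories[[i]], file.path(dir, files[i]))
  manifest <- corpus$manifest
  manifest$labels <- cbind(corpus$labels, file = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  labels <- manifest$labels
  trajectories <- lapply(file.path(dir, labels$file), read_trajectory_csv)
  viapoints <- lapply(trajectories, extract_viapoints)
  manifest$labels <- NULL
  structure(list(trajectories = trajectories, viapoints = viapoints,
                 labels = labels[c("letter", "writer", "trial", "seed")],
                 manifest = manifest),
            class = "writing_corpus")
}
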