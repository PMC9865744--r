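# Class balancing (random undersampling) and stratified splitting.
# Both are pure functions of (input, seed); no global RNG state is touched.

#' Random undersampling to the minority class
#'
#' Keeps, for every class, exactly `min(class counts)` observations sampled
#' uniformly without replacement; all other observations are dropped.
#'
#' @param labels Character (or factor) vector of per-frame states.
#' @param seed Integer seed; the same seed always yields the same selection.
#' @return Sorted integer vector of retained positions in `labels`.
#' @export
undersample <- function(labels, seed) {
  classes <- if (is.factor(labels)) {
    levels(labels)
  } else if (length(labels) > 0 && all(labels %in% STATE_LEVELS)) {
    STATE_LEVELS
  } else {
    unique(labels)
  }
  labels <- as.character(labels)
  if (length(labels) == 0) abort("no labels given")
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0)) {
    abort(paste0("class absent from labels: ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  k <- min(counts)
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(labels), labels),
                  function(ix) sample(ix, k)), use.names = FALSE)
  })
  sort(idx)
}

#' Stratified train/validation split
#'
#' Splits the given observations class by class: each class contributes
#' `round(train_fraction * class count)` training observations drawn
#' uniformly without replacement, the remainder going to validation. On a
#' balanced input (after [undersample()]) both subsets are exactly
#' balanced.
#'
#' @param indices Integer vector of observation identifiers (e.g. the
#'   output of [undersample()]).
#' @param labels Class labels aligned with `indices`.
#' @param train_fraction Fraction of each class used for training,
#'   in (0, 1). Default 0.7.
#' @param seed Integer seed.
#' @return List with sorted integer vectors `train` and `validation`
#'   (disjoint, union = `indices`).
#' @export
stratified_split <- function(indices, labels, train_fraction = 0.7, seed) {
  if (!(is.numeric(train_fraction) && train_fraction > 0 &&
        train_fraction < 1)) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  if (length(indices) != length(labels)) {
    abort("indices and labels must be the same length")
  }
  labels <- as.character(labels)
  train <- withr::with_seed(seed, {
    unlist(lapply(split(indices, labels), function(ix) {
      sample(ix, round(train_fraction * length(ix)))
    }), use.names = FALSE)
  })
  list(train = sort(train), validation = sort(setdiff(indices, train)))
}

#' Write / read plain-text index files (one index per line)
#' @param split A [stratified_split()] result.
#' @param dir Output directory.
#' @return File paths invisibly / the restored list.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("train.idx", "validation.idx"))
  writeLines(as.character(split$train), paths[1])
  writeLines(as.character(split$validation), paths[2])
  invisible(paths)
}

#' @rdname write_split
#' @export
read_split <- function(dir) {
  list(train = as.integer(readLines(file.path(dir, "train.idx"))),
       validation = as.integer(readLines(file.path(dir, "validation.idx"))))
}
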