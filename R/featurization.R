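# Featurization: atom-level frames -> residue centers of mass -> flat
# per-frame feature vectors -> min-max normalization.

#' Per-residue center of mass
#'
#' Mass-weighted mean position of each residue's atoms. Input is tidy: one
#' row per atom.
#'
#' @param atoms Data frame with columns `res_index`, `x`, `y`, `z`, `mass`
#'   (atomic mass units; all strictly positive).
#' @return Tibble `res_index,x,y,z` with one row per residue, ordered by
#'   `res_index`.
#' @export
center_of_mass <- function(atoms) {
  atoms <- as_tibble(atoms)
  req <- c("res_index", "x", "y", "z", "mass")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("no atoms given")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    abort("atom masses must be finite and > 0")
  }
  atoms |>
    group_by(.data$res_index) |>
    summarise(x = sum(.data$x * .data$mass) / sum(.data$mass),
              y = sum(.data$y * .data$mass) / sum(.data$mass),
              z = sum(.data$z * .data$mass) / sum(.data$mass),
              .groups = "drop") |>
    arrange(.data$res_index)
}

#' Flatten COM frames into model input vectors
#'
#' Each frame's M x 3 center-of-mass block becomes one residue-major row
#' vector `(x1, y1, z1, x2, y2, z2, ...)` of length 3M, so residue i always
#' owns features `3i-2, 3i-1, 3i`. This ordering is relied on by the
#' relevance aggregation.
#'
#' @param frames Long COM tibble (`frame,res_index,x,y,z`, as in a
#'   [trajectory()]), or a `trajectory`.
#' @return Numeric matrix, one row per frame (ordered by `frame`), `3M`
#'   columns; row names are the frame indices. Attribute `frame_info` holds
#'   a tibble with the per-frame `frame`, and `probe_distance`/`label`
#'   columns when present.
#' @export
flatten_frames <- function(frames) {
  if (inherits(frames, "trajectory")) frames <- frames$frames
  frames <- as_tibble(frames)
  frames <- arrange(frames, .data$frame, .data$res_index)
  m <- dplyr::n_distinct(frames$res_index)
  nf <- dplyr::n_distinct(frames$frame)
  if (nrow(frames) != m * nf) {
    abort("frames do not form a complete frame x residue grid")
  }
  # residue-major within a frame: x,y,z interleaved
  coords <- t(matrix(rbind(frames$x, frames$y, frames$z), nrow = 3 * m))
  frame_ids <- unique(frames$frame)
  rownames(coords) <- frame_ids
  info <- frames |>
    dplyr::distinct(.data$frame, .keep_all = TRUE) |>
    select(dplyr::any_of(c("frame", "probe_distance", "label")))
  attr(coords, "frame_info") <- info
  coords
}

#' Inverse of frame flattening
#'
#' @param v Length-`3M` numeric vector (one flattened frame).
#' @return M x 3 matrix of coordinates (columns x, y, z).
#' @export
unflatten_frame <- function(v) {
  if (length(v) %% 3 != 0) abort("vector length is not a multiple of 3")
  matrix(v, ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Fit a per-feature min-max scaler
#'
#' Learns per-column minimum and maximum from a training matrix. The
#' transform maps each feature linearly so the training data lie in
#' `[0, 1]`; constant columns map to 0. Held-out data are not clipped, so
#' values outside the training range land outside `[0, 1]` - this keeps the
#' input linear for the relevance analysis.
#'
#' @param train Numeric matrix, rows = frames, columns = features.
#' @return Object of class `minmax_scaler` with fields `min`, `max`.
#' @export
fit_minmax <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 1 || ncol(train) < 1) abort("empty training matrix")
  structure(list(min = apply(train, 2, min), max = apply(train, 2, max)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#' @param scaler A [fit_minmax()] result.
#' @param x Numeric matrix (or single vector) with the same column count the
#'   scaler was fitted on.
#' @return Normalized matrix of the same shape.
#' @export
apply_minmax <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(scaler$min)) {
    abort(paste0("scaler fitted on ", length(scaler$min),
                 " features, data has ", ncol(x)))
  }
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1  # constant feature -> 0 after centering
  sweep(sweep(x, 2, scaler$min, "-"), 2, rng, "/")
}

#' Serialize / restore a min-max scaler as JSON
#' @param scaler A `minmax_scaler`.
#' @param path JSON file path.
#' @return `path` invisibly / the restored scaler.
#' @export
write_minmax <- function(scaler, path) {
  jsonlite::write_json(list(min = scaler$min, max = scaler$max), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_minmax
#' @export
read_minmax <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = obj$min, max = obj$max), class = "minmax_scaler")
}
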