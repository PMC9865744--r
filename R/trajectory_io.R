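#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr group_by summarise mutate filter arrange select n left_join
#'   distinct pull across bind_rows count
#' @import Rcpp
#' @useDynLib conformotif, .registration = TRUE
NULL

# the 15 tokens of the receptor region vocabulary
REGION_TOKENS <- c(paste0("H", 1:7), paste0("ICL", 1:3), paste0("ECL", 1:3),
                   "N-terminus", "C-terminus")

#' Region vocabulary for residue annotations
#'
#' The closed set of region tokens a residue annotation may carry: the seven
#' transmembrane helices `H1..H7`, the intracellular and extracellular loops
#' `ICL1..ICL3` / `ECL1..ECL3`, and the two termini.
#'
#' @return Character vector of the 15 allowed region tokens.
#' @export
region_tokens <- function() REGION_TOKENS

#' Construct a trajectory object
#'
#' A trajectory bundles the long-format center-of-mass (COM) table (one row
#' per residue per frame) with its residue annotations and an identifier.
#' Most package functions operate on the tibbles directly; the object exists
#' to keep the pieces together and validated.
#'
#' @param frames Tibble with columns `frame`, `res_index`, `x`, `y`, `z` and
#'   optionally `probe_distance` (Angstrom) and `label`
#'   (active/intermediate/inactive).
#' @param annotations Tibble of residue annotations as returned by
#'   [read_annotations()], or `NULL`.
#' @param id Trajectory identifier string.
#' @param probe_pair Integer pair of probe residue indices, or `NULL`.
#' @param thresholds Numeric `c(low, high)` labeling thresholds, or `NULL`.
#'
#' @return An object of class `trajectory`: a list with elements `id`,
#'   `frames`, `annotations`, `probe_pair`, `thresholds`, `n_residues`.
#' @export
trajectory <- function(frames, annotations = NULL, id = "trajectory",
                       probe_pair = NULL, thresholds = NULL) {
  frames <- as_tibble(frames)
  req <- c("frame", "res_index", "x", "y", "z")
  missing_cols <- setdiff(req, names(frames))
  if (length(missing_cols) > 0) {
    abort(paste0("frames is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(frames) > 0) {
    if (!all(is.finite(frames$x) & is.finite(frames$y) & is.finite(frames$z))) {
      abort("non-finite coordinate in frames")
    }
    per_frame <- dplyr::count(frames, .data$frame)
    m <- per_frame$n[1]
    bad <- per_frame$frame[per_frame$n != m]
    if (length(bad) > 0) {
      abort(paste0("malformed trajectory: frame ", bad[1], " has ",
                   per_frame$n[per_frame$frame == bad[1]][1],
                   " residue rows, expected ", m))
    }
  } else {
    m <- 0L
  }
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
    if (m > 0 && nrow(annotations) != m) {
      abort(paste0("annotations cover ", nrow(annotations),
                   " residues but frames have ", m))
    }
  }
  structure(
    list(id = id, frames = frames, annotations = annotations,
         probe_pair = probe_pair, thresholds = thresholds,
         n_residues = as.integer(m)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  nf <- dplyr::n_distinct(x$frames$frame)
  cat(sprintf("<trajectory '%s': %d frames x %d residues%s>\n",
              x$id, nf, x$n_residues,
              if (!is.null(x$frames$label)) ", labeled" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dplyr::n_distinct(traj$frames$frame)

com_col_types <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  parsers <- list(frame = readr::col_integer(),
                  res_index = readr::col_integer(),
                  x = readr::col_double(), y = readr::col_double(),
                  z = readr::col_double(),
                  probe_distance = readr::col_double(),
                  label = readr::col_character())
  do.call(readr::cols,
          c(parsers[intersect(names(parsers), header)],
            .default = list(readr::col_guess())))
}

#' Read a canonical center-of-mass trajectory table
#'
#' The canonical on-disk format is a CSV with header
#' `frame,res_index,x,y,z` and optional `probe_distance,label` columns, one
#' row per residue per frame, plus an optional JSON sidecar `<path>.json`
#' holding `{id, n_residues, probe_pair, thresholds}`.
#'
#' @param path Path to the COM CSV.
#' @param annotations Optional annotation tibble to attach.
#' @return A [trajectory()].
#' @export
read_com_table <- function(path, annotations = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  frames <- suppressWarnings(
    readr::read_csv(path, col_types = com_col_types(path), progress = FALSE))
  if (nrow(readr::problems(frames)) > 0) {
    p <- readr::problems(frames)[1, ]
    abort(paste0("parse error in ", path, " at line ", p$row + 1L,
                 ": expected ", p$expected, ", got '", p$actual, "'"))
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  tr <- trajectory(
    frames,
    annotations = annotations,
    id = meta$id %||% sub("\\.csv$", "", basename(path)),
    probe_pair = if (!is.null(meta$probe_pair)) as.integer(meta$probe_pair),
    thresholds = meta$thresholds
  )
  if (!is.null(meta$n_residues) && nrow(frames) > 0 &&
      tr$n_residues != meta$n_residues) {
    abort(paste0("sidecar declares ", meta$n_residues,
                 " residues but table has ", tr$n_residues))
  }
  tr
}

#' Write a canonical center-of-mass trajectory table
#'
#' Coordinates and probe distances are written with 6-decimal fixed
#' precision, which [read_com_table()] reproduces exactly.
#'
#' @param traj A [trajectory()].
#' @param path Output CSV path; a JSON sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_com_table <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  out <- traj$frames
  num <- intersect(c("x", "y", "z", "probe_distance"), names(out))
  out <- mutate(out, across(dplyr::all_of(num), ~ sprintf("%.6f", .x)))
  ok <- tryCatch({ readr::write_csv(out, path, progress = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("cannot write ", path, ": ",
                                conditionMessage(ok)))
  meta <- list(id = traj$id, n_residues = traj$n_residues)
  if (!is.null(traj$probe_pair)) meta$probe_pair <- traj$probe_pair
  if (!is.null(traj$thresholds)) meta$thresholds <- traj$thresholds
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

validate_annotations <- function(ann) {
  ann <- as_tibble(ann)
  req <- c("index", "name", "region")
  missing_cols <- setdiff(req, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("annotations missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"generic_number" %in% names(ann)) ann$generic_number <- NA_character_
  ann$index <- as.integer(ann$index)
  if (anyDuplicated(ann$index) > 0) {
    abort(paste0("duplicate residue index: ",
                 ann$index[duplicated(ann$index)][1]))
  }
  ann <- arrange(ann, .data$index)
  m <- nrow(ann)
  if (!identical(ann$index, seq_len(m))) {
    missing_idx <- setdiff(seq_len(max(ann$index)), ann$index)
    abort(paste0("residue indices must be contiguous 1..M; ",
                 if (length(missing_idx) > 0)
                   paste0("missing index ", missing_idx[1])
                 else paste0("indices run ", min(ann$index), "..",
                             max(ann$index))))
  }
  bad_region <- setdiff(unique(ann$region), REGION_TOKENS)
  if (length(bad_region) > 0) {
    abort(paste0("unknown region token '", bad_region[1], "'; allowed: ",
                 paste(REGION_TOKENS, collapse = ", ")))
  }
  # each region must be one contiguous run of indices
  runs <- rle(ann$region)
  if (anyDuplicated(runs$values) > 0) {
    abort(paste0("region '", runs$values[duplicated(runs$values)][1],
                 "' occupies non-contiguous index runs"))
  }
  select(ann, "index", "name", "generic_number", "region")
}

#' Read a residue annotation table
#'
#' CSV with header `index,name,generic_number,region`: 1-based contiguous
#' residue index, residue name (3-letter code + sequence number, e.g.
#' `VAL31`), optional Ballesteros-Weinstein generic number (e.g. `1.30`),
#' and region token (see [region_tokens()]). Enforces contiguity, index
#' uniqueness, the closed region vocabulary, and that each region is one
#' contiguous run.
#'
#' @param path Path to the annotation CSV.
#' @return Tibble `index,name,generic_number,region`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ann <- readr::read_csv(
    path,
    col_types = readr::cols(index = readr::col_integer(),
                            name = readr::col_character(),
                            generic_number = readr::col_character(),
                            region = readr::col_character()),
    progress = FALSE)
  validate_annotations(ann)
}

#' Write a residue annotation table
#' @param annotations Annotation tibble (validated on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  ann <- validate_annotations(annotations)
  readr::write_csv(ann, path, progress = FALSE)
  invisible(path)
}

#' Bundled synthetic region map for the 282-residue receptor
#'
#' Returns the path of a shipped annotation file assigning each of the 282
#' residues of the studied adrenergic receptor to a region. The helix/loop
#' boundaries are a synthetic stand-in (plausible for this receptor family
#' and consistent with the key-residue tables the package reproduces), not
#' an authoritative topology; replace it with your own annotation CSV for
#' real analyses.
#'
#' @return File path of `b2ar_regions_synthetic.csv`.
#' @export
b2ar_region_map <- function() {
  system.file("extdata", "b2ar_regions_synthetic.csv",
              package = "conformotif", mustWork = TRUE)
}
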