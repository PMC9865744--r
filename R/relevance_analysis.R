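# Aggregation of input relevance to residues and regions, sampling of
# correctly predicted frames for explanation, and key-residue (motif)
# extraction via interquartile-range fences.

#' Collapse feature relevance to residues
#'
#' A residue's relevance is the sum of the relevance of its three COM
#' coordinates divided by the number of coordinates, i.e. the mean over
#' x/y/z. Total relevance is conserved up to that 1/3 factor.
#'
#' @param relevance Length-3M numeric vector, or an [explain()] tibble
#'   (its `relevance` column is used).
#' @return Tibble `res_index,relevance` of length M.
#' @export
residue_relevance <- function(relevance) {
  if (is.data.frame(relevance)) relevance <- relevance$relevance
  if (length(relevance) %% 3 != 0) {
    abort("input relevance length is not a multiple of 3")
  }
  m <- length(relevance) %/% 3
  tibble(res_index = seq_len(m),
         relevance = colMeans(matrix(relevance, nrow = 3)))
}

#' Sample correctly predicted frames for explanation
#'
#' Draws `n_traj` trajectories without replacement, pools their frames, and
#' keeps exactly `per_state` correctly predicted frames per conformational
#' state (sampled uniformly). Deterministic given the seed.
#'
#' @param model A trained `conformo_cnn`.
#' @param features Normalized feature matrix for all frames.
#' @param frame_info Tibble aligned with the rows of `features`, with
#'   columns `trajectory` (id) and `label` (true state).
#' @param n_traj Number of trajectories to sample (default 100; capped at
#'   the number available).
#' @param per_state Correctly predicted frames kept per state. `NULL`
#'   (default) uses the largest equal count available.
#' @param seed Integer seed.
#' @return Tibble `row,trajectory,label` (`row` indexes `features`),
#'   `per_state` rows per state, all correctly predicted.
#' @export
select_explanation_frames <- function(model, features, frame_info,
                                      n_traj = 100L, per_state = NULL,
                                      seed = 1L) {
  stopifnot(nrow(features) == nrow(frame_info))
  if (!all(c("trajectory", "label") %in% names(frame_info))) {
    abort("frame_info needs columns trajectory and label")
  }
  traj_ids <- unique(frame_info$trajectory)
  n_traj <- min(n_traj, length(traj_ids))
  chosen <- withr::with_seed(derive_seed(seed, 1L),
                             sample(traj_ids, n_traj))
  rows <- which(frame_info$trajectory %in% chosen)
  pred <- predict(model, features[rows, , drop = FALSE])
  correct <- tibble(row = rows, trajectory = frame_info$trajectory[rows],
                    label = frame_info$label[rows]) |>
    filter(pred == .data$label)
  counts <- table(factor(correct$label, levels = model$class_levels))
  if (is.null(per_state)) per_state <- min(counts)
  short <- counts < per_state
  if (any(short) || per_state < 1) {
    abort(paste0("not enough correctly predicted frames for state(s) ",
                 paste(names(counts)[short], collapse = ", "), " (have ",
                 paste(counts[short], collapse = ", "), ", need ",
                 per_state, ")"))
  }
  withr::with_seed(derive_seed(seed, 2L), {
    correct |>
      group_by(.data$label) |>
      dplyr::slice_sample(n = per_state) |>
      dplyr::ungroup() |>
      arrange(.data$row)
  })
}

#' Average per-frame residue relevance maps
#'
#' Elementwise arithmetic mean of residue-level maps belonging to one
#' explained class.
#'
#' @param maps List of `residue_relevance()` tibbles (or a tibble with
#'   columns `frame_id,res_index,relevance`).
#' @return Tibble `res_index,relevance` (the averaged map), with attribute
#'   `n_maps`.
#' @export
average_maps <- function(maps) {
  if (is.data.frame(maps)) {
    maps <- split(maps[c("res_index", "relevance")], maps$frame_id)
  }
  if (length(maps) == 0) abort("no maps to average")
  m <- nrow(maps[[1]])
  if (!all(vapply(maps, nrow, 1L) == m)) abort("maps differ in length")
  avg <- rowMeans(vapply(maps, function(d) d$relevance, numeric(m)))
  out <- tibble(res_index = maps[[1]]$res_index, relevance = avg)
  attr(out, "n_maps") <- length(maps)
  out
}

#' Build per-class average relevance maps
#'
#' Runs [explain()] on every selected frame (each explained with its own,
#' correctly predicted, class) and averages the residue-level maps per
#' class.
#'
#' @param model A trained `conformo_cnn`.
#' @param features Normalized feature matrix.
#' @param selection A [select_explanation_frames()] result.
#' @param cfg An [lrp_config()].
#' @return Tibble `class,res_index,relevance` (classes in
#'   [state_levels()] order), with attribute `frame_maps`: tibble
#'   `class,row,res_index,relevance` of the underlying per-frame maps.
#' @export
relevance_maps <- function(model, features, selection,
                           cfg = lrp_config()) {
  per_frame <- purrr::pmap(selection, function(row, trajectory, label) {
    rel <- explain(model, features[row, ], class = label, cfg = cfg)
    residue_relevance(rel) |>
      mutate(class = label, row = row)
  }) |> dplyr::bind_rows()
  avg <- per_frame |>
    group_by(.data$class, .data$res_index) |>
    summarise(relevance = mean(.data$relevance), .groups = "drop") |>
    mutate(class = factor(.data$class, levels = model$class_levels)) |>
    arrange(.data$class, .data$res_index) |>
    mutate(class = as.character(.data$class))
  attr(avg, "frame_maps") <- select(per_frame, "class", "row", "res_index",
                                    "relevance")
  avg
}

#' Key-residue (motif) extraction via IQR fences
#'
#' Residues whose average relevance falls outside
#' `[Q1 - f * IQR, Q3 + f * IQR]` (strict exceedance), with quartiles by
#' linear interpolation (`stats::quantile` type 7). These outliers of the
#' relevance distribution are the residues most characteristic of (side
#' `above_upper`) or most counteracting (side `below_lower`) the explained
#' state.
#'
#' @param map Tibble `res_index,relevance` (one class's average map).
#' @param annotations Residue annotation tibble ([read_annotations()]).
#' @param fence_factor Tukey fence multiplier, >= 0. Default 1.5.
#' @return Tibble `res_index,residue,region,avg_relevance,side`, sorted by
#'   residue index; zero rows when nothing exceeds the fences.
#' @export
iqr_motifs <- function(map, annotations, fence_factor = 1.5) {
  if (fence_factor < 0) abort("fence_factor must be nonnegative")
  if (nrow(map) < 4) abort("need at least 4 residues for quartile fences")
  annotations <- validate_annotations(annotations)
  q <- stats::quantile(map$relevance, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - fence_factor * iqr
  upper <- q[2] + fence_factor * iqr
  map |>
    filter(.data$relevance > upper | .data$relevance < lower) |>
    mutate(side = ifelse(.data$relevance > upper, "above_upper",
                         "below_lower")) |>
    left_join(annotations, by = c(res_index = "index")) |>
    arrange(.data$res_index) |>
    select("res_index", residue = "name", "region",
           avg_relevance = "relevance", "side")
}

#' Total and average relevance per receptor region
#'
#' Sums the relevance of each region's residues over all selected frames;
#' the average divides the total by (region residue count x frame count),
#' i.e. mean relevance per residue per frame.
#'
#' @param frame_maps Tibble `row,res_index,relevance` of per-frame residue
#'   maps for one class (e.g. `attr(relevance_maps(...), "frame_maps")`
#'   filtered to a class; `row` identifies the frame).
#' @param annotations Residue annotation tibble covering every residue.
#' @return Tibble `region,total_relevance,average_relevance`, one row per
#'   region present, in annotation order.
#' @export
region_summary <- function(frame_maps, annotations) {
  annotations <- validate_annotations(annotations)
  missing_res <- setdiff(unique(frame_maps$res_index), annotations$index)
  if (length(missing_res) > 0) {
    abort(paste0("unannotated residue index: ", missing_res[1]))
  }
  n_frames <- dplyr::n_distinct(frame_maps$row)
  region_order <- unique(annotations$region)
  frame_maps |>
    left_join(annotations, by = c(res_index = "index")) |>
    group_by(.data$region) |>
    summarise(total_relevance = sum(.data$relevance),
              n_residues = dplyr::n_distinct(.data$res_index),
              .groups = "drop") |>
    mutate(average_relevance = .data$total_relevance /
             (.data$n_residues * n_frames),
           region = factor(.data$region, levels = region_order)) |>
    arrange(.data$region) |>
    mutate(region = as.character(.data$region)) |>
    select("region", "total_relevance", "average_relevance")
}
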