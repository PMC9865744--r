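# Conformational-state labeling from the probe-pair alpha-carbon distance.

STATE_LEVELS <- c("active", "intermediate", "inactive")

#' Conformational state class order
#'
#' The fixed class order used everywhere in the package (labels, model
#' outputs, reports): active, intermediate, inactive.
#'
#' @return Character vector of the three state names.
#' @export
state_levels <- function() STATE_LEVELS

#' Labeling configuration
#'
#' Probe residue pair and distance thresholds for the three-state rule.
#' Defaults are the receptor-activation criterion the package was built
#' around: the alpha-carbon distance between residues 131 (helix 3) and 272
#' (helix 6), inactive at <= 8.5 Angstrom, active at >= 14 Angstrom.
#'
#' @param probe_pair Integer pair of residue indices.
#' @param low Inactive bound in Angstrom (inclusive).
#' @param high Active bound in Angstrom (inclusive).
#' @return List of class `labeling_config`.
#' @export
labeling_config <- function(probe_pair = c(131L, 272L), low = 8.5,
                            high = 14.0) {
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && low < high)) {
    abort("invalid labeling config: need 0 < low < high")
  }
  structure(list(probe_pair = as.integer(probe_pair), low = low, high = high),
            class = "labeling_config")
}

#' Probe-pair alpha-carbon distance
#'
#' Euclidean distance between the two probe residues' alpha-carbon
#' positions.
#'
#' @param ca_i,ca_j Length-3 numeric coordinates (Angstrom) of the two
#'   alpha-carbons.
#' @return Distance in Angstrom.
#' @export
probe_distance <- function(ca_i, ca_j) {
  if (length(ca_i) != 3 || any(!is.finite(ca_i))) {
    abort("missing or non-finite alpha-carbon coordinates for residue i")
  }
  if (length(ca_j) != 3 || any(!is.finite(ca_j))) {
    abort("missing or non-finite alpha-carbon coordinates for residue j")
  }
  sqrt(sum((ca_i - ca_j)^2))
}

#' Label conformational states from probe distances
#'
#' The three predicates partition the distance axis: active iff
#' `d >= high`, inactive iff `d <= low`, intermediate otherwise (both
#' boundaries inclusive on their own side).
#'
#' @param distance Numeric vector of probe distances (Angstrom, >= 0).
#' @param cfg A [labeling_config()].
#' @return Character vector of states (`active`/`intermediate`/`inactive`).
#' @export
label_state <- function(distance, cfg = labeling_config()) {
  stopifnot(inherits(cfg, "labeling_config"))
  if (any(!is.finite(distance)) || any(distance < 0)) {
    abort("probe distances must be finite and >= 0")
  }
  dplyr::case_when(
    distance >= cfg$high ~ "active",
    distance <= cfg$low ~ "inactive",
    .default = "intermediate"
  )
}

#' Label every frame of a trajectory
#'
#' Applies [label_state()] to the per-frame probe distances carried in the
#' COM table and writes the `label` column.
#'
#' @param traj A [trajectory()] whose frames carry `probe_distance`.
#' @param cfg A [labeling_config()].
#' @return The trajectory with a populated `label` column and an attached
#'   `label_distribution` attribute (tibble `label,n` over all three states,
#'   zero counts included).
#' @export
label_trajectory <- function(traj, cfg = labeling_config()) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- traj$frames
  if (nrow(fr) > 0) {
    if (!"probe_distance" %in% names(fr) || anyNA(fr$probe_distance)) {
      bad <- if (!"probe_distance" %in% names(fr)) "all" else
        fr$frame[is.na(fr$probe_distance)][1]
      abort(paste0("frame(s) missing probe distance: ", bad))
    }
    fr$label <- label_state(fr$probe_distance, cfg)
  } else if (!"label" %in% names(fr)) {
    fr$label <- character(0)
  }
  dist_tbl <- tibble(label = STATE_LEVELS) |>
    left_join(
      fr |> dplyr::distinct(.data$frame, .data$label) |> count(.data$label),
      by = "label") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  traj$frames <- fr
  traj$thresholds <- c(cfg$low, cfg$high)
  traj$probe_pair <- cfg$probe_pair
  attr(traj, "label_distribution") <- dist_tbl
  traj
}
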