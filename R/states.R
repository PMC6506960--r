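#' State-assignment configuration
#'
#' Controls the discretization of MC ratios into methylation states and the
#' coverage filter. Sites with coverage below `min_coverage` (or with a
#' missing ratio) are assigned `NA` rather than a state; `min_coverage = 0`
#' disables the filter.
#'
#' @param min_coverage minimum read depth for a site to receive a state
#'   (default 3, i.e. sites under 3X become `NA`).
#' @param boundaries the three interior interval edges splitting \[0, 1\]
#'   into the four states. Lower edges are closed, upper edges open, except
#'   that 1 belongs to the top state.
#' @return An object of class `state_config`.
#' @export
state_config <- function(min_coverage = 3L, boundaries = c(0.25, 0.5, 0.75)) {
  min_coverage <- as.integer(min_coverage)
  if (is.na(min_coverage) || min_coverage < 0)
    stop("min_coverage must be a non-negative integer")
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 3 || is.unsorted(boundaries, strictly = TRUE) ||
      boundaries[1] <= 0 || boundaries[3] >= 1)
    stop("boundaries must be three strictly increasing values inside (0, 1)")
  structure(list(min_coverage = min_coverage, boundaries = boundaries),
            class = "state_config")
}

#' Assign methylation states to MC ratios
#'
#' Maps each ratio to A \[0, 0.25), B \[0.25, 0.5), C \[0.5, 0.75) or
#' D \[0.75, 1\]; the upper bound 1 is included in D. A site whose coverage is
#' below the configured minimum, or whose ratio is missing, gets `NA`.
#'
#' @param mc_ratio numeric vector of methylated-read fractions in \[0, 1\]
#'   (`NA` allowed).
#' @param coverage integer vector of read depths, recycled against
#'   `mc_ratio`.
#' @param config a [state_config()].
#' @return Character vector of states (`"A"`-`"D"` or `NA`).
#' @examples
#' assign_state(c(0.20, 0.67, 1.0, NA), c(15, 21, 19, 0))
#' @export
assign_state <- function(mc_ratio, coverage, config = state_config()) {
  if (any(!is.na(mc_ratio) & (mc_ratio < 0 | mc_ratio > 1)))
    stop("mc_ratio outside [0, 1]")
  n <- max(length(mc_ratio), length(coverage))
  mc_ratio <- rep_len(mc_ratio, n)
  coverage <- rep_len(coverage, n)
  # findInterval with left-closed intervals: 0.25 -> B, 0.5 -> C, 0.75 -> D
  idx <- findInterval(mc_ratio, config$boundaries) + 1L
  state <- meth_states()[idx]
  state[is.na(mc_ratio) | coverage < config$min_coverage] <- NA_character_
  state
}

#' Annotate a track with methylation states
#'
#' @param track a [meth_track()].
#' @param config a [state_config()].
#' @return The track with a `state` column added; order and site count are
#'   unchanged.
#' @export
annotate_states <- function(track, config = state_config()) {
  track$state <- assign_state(track$mc_ratio, track$coverage, config)
  track
}

#' Compute forward distances between consecutive CG sites
#'
#' Attaches to each site the base-pair gap to the next CG site downstream on
#' the forward strand (`position[i + 1] - position[i]`); the last site's
#' distance is missing. Distances are computed for every site regardless of
#' state.
#'
#' @param track a [meth_track()].
#' @return The track with a `distance` column added.
#' @export
compute_forward_distances <- function(track) {
  n <- nrow(track)
  track$distance <- if (n == 0) integer(0) else c(diff(track$position), NA_integer_)
  track
}

#' Annotate a track with states and forward distances
#'
#' Convenience wrapper running [annotate_states()] then
#' [compute_forward_distances()].
#'
#' @inheritParams annotate_states
#' @return The fully annotated track.
#' @export
annotate_track <- function(track, config = state_config()) {
  compute_forward_distances(annotate_states(track, config))
}
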