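#' Construct a per-CpG methylation track
#'
#' A methylation track holds the ordered per-CpG records of one chromosome of
#' one sample or tissue: 1-based forward-strand position, sequencing coverage,
#' and MC ratio (methylated reads / total reads, in \[0, 1\]). After
#' annotation (see [annotate_track()]) it additionally carries the discretized
#' methylation state and the forward distance to the next CG site.
#'
#' @param df data frame with columns `chrom`, `position`, `coverage`,
#'   `mc_ratio` (and optionally `state`, `distance`).
#' @param sample_id label identifying the sample or tissue.
#' @param sort_positions sort records by position if they arrive unsorted
#'   (with a warning). Duplicated positions are always an error.
#' @return An object of class `meth_track`: a data frame with attributes
#'   `sample_id` and `chrom`.
#' @examples
#' tr <- meth_track(data.frame(chrom = "chr1", position = c(10L, 14L),
#'                             coverage = c(5L, 8L), mc_ratio = c(0.1, 0.9)),
#'                  sample_id = "S1")
#' @export
meth_track <- function(df, sample_id = "sample", sort_positions = TRUE) {
  required <- c("chrom", "position", "coverage", "mc_ratio")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)
  df$position <- as.integer(df$position)
  df$coverage <- as.integer(df$coverage)
  df$mc_ratio <- as.numeric(df$mc_ratio)

  if (nrow(df) > 0) {
    if (length(unique(df$chrom)) > 1)
      stop("all records of a track must share one chromosome; found: ",
           paste(unique(df$chrom), collapse = ", "))
    if (anyNA(df$position) || anyNA(df$coverage))
      stop("position and coverage must not be missing")
    if (any(df$coverage < 0))
      stop("coverage must be non-negative")
    bad <- !is.na(df$mc_ratio) & (df$mc_ratio < 0 | df$mc_ratio > 1)
    if (any(bad))
      stop("mc_ratio outside [0, 1] at position(s) ",
           paste(utils::head(df$position[bad], 5), collapse = ", "))
    orphan <- !is.na(df$mc_ratio) & df$coverage == 0
    if (any(orphan))
      stop("mc_ratio present with coverage 0 at position(s) ",
           paste(utils::head(df$position[orphan], 5), collapse = ", "))
    if (is.unsorted(df$position, strictly = TRUE)) {
      if (anyDuplicated(df$position))
        stop("duplicated position(s): ",
             paste(utils::head(df$position[duplicated(df$position)], 5),
                   collapse = ", "))
      if (!sort_positions)
        stop("positions are not strictly increasing")
      warning("positions were not sorted; sorting by position")
      df <- df[order(df$position), , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(df,
            sample_id = sample_id,
            chrom = if (nrow(df) > 0) df$chrom[1] else NA_character_,
            class = c("meth_track", "data.frame"))
}

#' @export
print.meth_track <- function(x, ...) {
  cat(sprintf("<meth_track> sample '%s', %s, %d CG site(s)%s\n",
              attr(x, "sample_id"), attr(x, "chrom"), nrow(x),
              if (is_annotated(x)) ", annotated" else ""))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Test whether a track carries states and forward distances
#'
#' @param track a [meth_track()].
#' @return `TRUE` when both the `state` and `distance` columns are present.
#' @export
is_annotated <- function(track) {
  all(c("state", "distance") %in% names(track))
}

sample_id <- function(track) attr(track, "sample_id")

stop_if_unannotated <- function(track) {
  if (!is_annotated(track))
    stop("track must be annotated with states and distances first; ",
         "see annotate_track()")
  invisible(track)
}

#' The four methylation states
#'
#' Ordered labels of the MC-ratio discretization: A no/low \[0, 0.25),
#' B low/partial \[0.25, 0.5), C partial/high \[0.5, 0.75), D high/full
#' \[0.75, 1\].
#' @return `c("A", "B", "C", "D")`
#' @export
meth_states <- function() c("A", "B", "C", "D")
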