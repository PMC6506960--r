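#' Segment a track into similarly methylated regions
#'
#' A similarly methylated region (SMR) is a maximal run of consecutive CG
#' sites sharing one methylation state. An `NA` site terminates the current
#' run (no bridging) unless `na_breaks = FALSE`, in which case `NA` sites are
#' transparent and runs continue across them (a sensitivity option). Runs
#' with fewer than `min_count` sites are discarded; the default of 2 matches
#' the reporting convention that single-site runs are not regions.
#'
#' An SMR's `length` is `last_position - first_position`, i.e. the sum of the
#' member-to-member forward distances, so the shortest reportable two-site
#' SMR (adjacent CGCG) has length 2.
#'
#' @param track an annotated [meth_track()].
#' @param min_count minimum CG sites per reported run (default 2).
#' @param na_breaks whether `NA` sites break runs (default `TRUE`).
#' @return An object of class `smr_set`: data frame with columns `state`,
#'   `chrom`, `first_position`, `last_position`, `cg_count`, `length`,
#'   ordered and disjoint, with attribute `sample_id`.
#' @export
segment_smrs <- function(track, min_count = 2L, na_breaks = TRUE) {
  stop_if_unannotated(track)
  if (min_count < 1) stop("min_count must be at least 1")
  state <- track$state
  pos <- track$position
  if (!na_breaks) {
    keep <- !is.na(state)
    state <- state[keep]
    pos <- pos[keep]
  }
  empty <- data.frame(state = character(0), chrom = character(0),
                      first_position = integer(0), last_position = integer(0),
                      cg_count = integer(0), length = integer(0))
  if (length(state) == 0)
    return(structure(empty, sample_id = sample_id(track),
                     class = c("smr_set", "data.frame")))
  r <- rle(ifelse(is.na(state), "NA", state))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "NA" & r$lengths >= min_count
  out <- data.frame(state = r$values[keep],
                    chrom = rep(attr(track, "chrom"), sum(keep)),
                    first_position = pos[starts[keep]],
                    last_position = pos[ends[keep]],
                    cg_count = r$lengths[keep],
                    row.names = NULL)
  out$length <- out$last_position - out$first_position
  structure(out, sample_id = sample_id(track),
            class = c("smr_set", "data.frame"))
}

#' Empty six-number-summary sentinel
#'
#' @return Named numeric vector of `NA`s with `n = 0`.
#' @keywords internal
empty_summary <- function() {
  c(min = NA_real_, q1 = NA_real_, median = NA_real_, mean = NA_real_,
    q3 = NA_real_, max = NA_real_, n = 0)
}

#' Six-number summary of SMR counts or lengths
#'
#' Minimum, first quartile, median, mean, third quartile and maximum of one
#' metric (`"count"` = CG sites per SMR, `"length"` = bp span) for one
#' state's SMRs. To blunt the influence of a single extreme region, exactly
#' one occurrence of the maximum value is removed before summarizing when
#' `drop_largest` is `TRUE` (the default). Quartiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' @param smrset an `smr_set` from [segment_smrs()].
#' @param state one of `"A"`-`"D"`.
#' @param metric `"count"` or `"length"`.
#' @param drop_largest remove one maximal value before summarizing.
#' @return Named numeric vector `min`, `q1`, `median`, `mean`, `q3`, `max`,
#'   `n` (values summarized); all-`NA` sentinel with `n = 0` when no values
#'   remain.
#' @export
summarize_smrs <- function(smrset, state, metric = c("count", "length"),
                           drop_largest = TRUE) {
  metric <- match.arg(metric)
  state <- match.arg(state, meth_states())
  x <- smrset[smrset$state == state,
              if (metric == "count") "cg_count" else "length"]
  if (drop_largest && length(x) > 0)
    x <- x[-which.max(x)]
  if (length(x) == 0) return(empty_summary())
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(min = min(x), q1 = q[1], median = q[2], mean = mean(x),
    q3 = q[3], max = max(x), n = length(x))
}

#' SMR summary report across samples
#'
#' One row per sample x state x metric with the six-number summary of the
#' (optionally largest-trimmed) SMR counts and lengths; the layout written to
#' `smr_summary_<sample>.csv`.
#'
#' @param smrsets named list of `smr_set`s, one per sample.
#' @param drop_largest see [summarize_smrs()].
#' @return Data frame with columns `sample`, `state`, `metric`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`, `n`.
#' @export
smr_report <- function(smrsets, drop_largest = TRUE) {
  if (is.null(names(smrsets)))
    names(smrsets) <- vapply(smrsets, function(s) {
      id <- attr(s, "sample_id"); if (is.null(id)) "sample" else id
    }, character(1))
  rows <- list()
  for (s in names(smrsets)) for (st in meth_states())
    for (m in c("count", "length")) {
      sm <- summarize_smrs(smrsets[[s]], st, m, drop_largest)
      rows[[length(rows) + 1]] <-
        data.frame(sample = s, state = st, metric = m, t(sm))
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract one metric's values per sample for distribution tests
#'
#' @param smrsets named list of `smr_set`s.
#' @param state one of `"A"`-`"D"`.
#' @param metric `"count"` or `"length"`.
#' @return Named list of numeric vectors (untrimmed), one per sample.
#' @export
smr_metric_groups <- function(smrsets, state, metric = c("count", "length")) {
  metric <- match.arg(metric)
  state <- match.arg(state, meth_states())
  lapply(smrsets, function(s)
    s[s$state == state, if (metric == "count") "cg_count" else "length"])
}
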