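#' Build methylation state pairs from an annotated track
#'
#' Pairs each CG site with the next CG site downstream (positional adjacency,
#' same strand, no intervening CG). A candidate pair is kept only when both
#' members have a non-`NA` state; pairs never bridge across `NA` sites. The
#' pair's distance is the forward distance of its left member.
#'
#' @param track an annotated [meth_track()].
#' @return Data frame with columns `initial`, `terminal` (states `"A"`-`"D"`)
#'   and `distance` (bp), one row per retained pair, in genomic order.
#' @export
build_state_pairs <- function(track) {
  stop_if_unannotated(track)
  n <- nrow(track)
  if (n < 2)
    return(data.frame(initial = character(0), terminal = character(0),
                      distance = integer(0)))
  initial <- track$state[-n]
  terminal <- track$state[-1]
  distance <- track$distance[-n]
  keep <- !is.na(initial) & !is.na(terminal)
  data.frame(initial = initial[keep], terminal = terminal[keep],
             distance = distance[keep], row.names = NULL)
}

#' Construct a transition count table
#'
#' A 4x4 table of initial -> terminal methylation state-pair counts with row
#' percentages (`100 * count / row sum`; a zero row reports `NA`
#' percentages).
#'
#' @param counts 4x4 non-negative matrix with rows = initial and columns =
#'   terminal states, in A-D order (dimnames optional).
#' @param sample_id label.
#' @return An object of class `transition_table` with elements `sample_id`,
#'   `counts` and `percentages`.
#' @export
transition_table <- function(counts, sample_id = "sample") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 4)))
    stop("counts must be a 4x4 matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(initial = meth_states(), terminal = meth_states())
  rs <- rowSums(counts)
  pct <- 100 * sweep(counts, 1, rs, "/")
  pct[rs == 0, ] <- NA_real_
  structure(list(sample_id = sample_id, counts = counts, percentages = pct),
            class = "transition_table")
}

#' Count methylation state pairs
#'
#' Tabulates the 4x4 initial -> terminal counts of a pair sequence and
#' derives row percentages.
#'
#' @param pairs data frame from [build_state_pairs()].
#' @param sample_id label.
#' @return A [transition_table()].
#' @export
count_transitions <- function(pairs, sample_id = "sample") {
  counts <- table(factor(pairs$initial, levels = meth_states()),
                  factor(pairs$terminal, levels = meth_states()))
  transition_table(unclass(counts), sample_id = sample_id)
}

#' @export
print.transition_table <- function(x, digits = 2, ...) {
  cat(sprintf("<transition_table> sample '%s', %d pairs\n",
              x$sample_id, sum(x$counts)))
  cat("Counts:\n"); print(x$counts)
  cat("Percentages (by row):\n"); print(round(x$percentages, digits))
  invisible(x)
}

#' Default distance bins
#'
#' The eleven half-open distance intervals \[0, 50), \[50, 100), ...,
#' \[450, 500), \[500, Inf) used to profile state-pair occurrence against
#' the gap between the two CG sites.
#' @return Numeric vector of left edges plus `Inf`.
#' @export
default_distance_bins <- function() c(seq(0, 500, by = 50), Inf)

bin_labels <- function(edges) {
  sprintf("[%s,%s)", edges[-length(edges)], edges[-1])
}

#' Stratify state pairs by distance bin
#'
#' Assigns every pair to the unique half-open bin containing its distance and
#' tabulates per-bin 4x4 counts. Percent occurrence within a bin is the
#' pair-type count divided by the bin's total pair count (times 100);
#' a row-conditioned denominator is available via [distance_profile()].
#'
#' @param pairs data frame from [build_state_pairs()].
#' @param bin_edges increasing numeric edges; the final bin must be
#'   open-ended (`Inf`) so every distance is covered.
#' @param sample_id label.
#' @return An object of class `binned_transitions`: list with `sample_id`,
#'   `bin_edges`, `labels`, `counts` (array bin x initial x terminal) and
#'   `bin_totals`.
#' @export
bin_transitions_by_distance <- function(pairs,
                                        bin_edges = default_distance_bins(),
                                        sample_id = "sample") {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  if (!is.infinite(bin_edges[length(bin_edges)]))
    stop("the final bin must be open-ended (last edge Inf)")
  labs <- bin_labels(bin_edges)
  bin <- cut(pairs$distance, breaks = bin_edges, right = FALSE, labels = labs)
  if (anyNA(bin))
    stop("pair distance outside the binning range; ",
         "extend bin_edges to cover all distances")
  counts <- table(bin = bin,
                  initial = factor(pairs$initial, levels = meth_states()),
                  terminal = factor(pairs$terminal, levels = meth_states()))
  counts <- array(counts, dim = dim(counts), dimnames = dimnames(counts))
  structure(list(sample_id = sample_id, bin_edges = bin_edges, labels = labs,
                 counts = counts,
                 bin_totals = apply(counts, 1, sum)),
            class = "binned_transitions")
}

#' Distance profile of one state pair
#'
#' Percent occurrence of a given initial -> terminal pair per distance bin:
#' with the `"bin-total"` denominator (default) the share of that bin's total
#' pairs; with `"row-total"` the share of that bin's pairs starting in the
#' same initial state. Empty denominators yield `NA`.
#'
#' @param binned a `binned_transitions` from [bin_transitions_by_distance()].
#' @param pair two-letter pair label (e.g. `"AD"`) or character vector
#'   `c(initial, terminal)`.
#' @param denominator `"bin-total"` or `"row-total"`.
#' @return Data frame with columns `bin`, `count`, `total` and `percent`.
#' @export
distance_profile <- function(binned, pair,
                             denominator = c("bin-total", "row-total")) {
  denominator <- match.arg(denominator)
  if (length(pair) == 1) pair <- strsplit(pair, "")[[1]]
  if (length(pair) != 2 || !all(pair %in% meth_states()))
    stop("pair must name two states among A, B, C, D, e.g. \"AD\"")
  cnt <- binned$counts[, pair[1], pair[2]]
  total <- if (denominator == "bin-total") binned$bin_totals
           else apply(binned$counts[, pair[1], , drop = FALSE], 1, sum)
  data.frame(bin = binned$labels, count = as.numeric(cnt),
             total = as.numeric(total),
             percent = ifelse(total > 0, 100 * cnt / total, NA_real_),
             row.names = NULL)
}

#' Full distance-profile table
#'
#' Percent occurrence of all 16 state pairs per distance bin, in the layout
#' written to `profile_<sample>.csv`.
#'
#' @inheritParams distance_profile
#' @return Data frame: one row per bin, one column per pair plus `bin` and
#'   `total`.
#' @export
profile_table <- function(binned, denominator = c("bin-total", "row-total")) {
  denominator <- match.arg(denominator)
  out <- data.frame(bin = binned$labels, total = as.numeric(binned$bin_totals))
  for (i in meth_states()) for (j in meth_states()) {
    out[[paste0(i, j)]] <-
      distance_profile(binned, c(i, j), denominator)$percent
  }
  out
}

#' Collapse a binned table to its marginal transition table
#'
#' Summing the per-bin counts over bins reproduces [count_transitions()]
#' exactly; exposed for consistency checks and reporting.
#'
#' @param binned a `binned_transitions`.
#' @return A [transition_table()].
#' @export
marginal_transitions <- function(binned) {
  transition_table(apply(binned$counts, c(2, 3), sum),
                   sample_id = binned$sample_id)
}
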