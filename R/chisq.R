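#' Build a samples-by-terminal-states contingency table
#'
#' Stacks the counts row of a chosen initial state across samples: row k of
#' the result is sample k's `initial_state` row of its transition table, so
#' columns are the terminal states A-D.
#'
#' @param tables list of [transition_table()]s (at least two), ideally named.
#' @param initial_state one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return Numeric matrix (samples x 4) with sample-id rownames.
#' @export
build_contingency <- function(tables, initial_state) {
  initial_state <- match.arg(initial_state, meth_states())
  if (length(tables) < 2)
    stop("need at least 2 samples to build a contingency table")
  rows <- lapply(tables, function(tt) tt$counts[initial_state, ])
  ids <- unname(vapply(tables, function(tt) tt$sample_id, character(1)))
  ct <- do.call(rbind, rows)
  dimnames(ct) <- list(sample = ids, terminal = meth_states())
  zero <- rowSums(ct) == 0
  if (any(zero))
    stop("sample(s) with an all-zero '", initial_state, "' row: ",
         paste(ids[zero], collapse = ", "))
  ct
}

#' Pearson chi-squared test on a contingency table
#'
#' Classic Pearson test without continuity correction: expected counts
#' `E = row total x column total / grand total`, statistic
#' `sum((O - E)^2 / E)`, df `(r - 1)(c - 1)`, upper-tail chi-squared p-value.
#' A p-value that underflows to zero is reported as the smallest
#' representable positive double and displayed as `~0`. `flag_min_expected`
#' is set when the smallest expected cell falls below 5 (the usual validity
#' caveat, relevant in the divide-by-10^n scan). All-zero rows or columns
#' (which can arise after heavy down-scaling) are dropped before testing,
#' reducing the degrees of freedom; their labels are recorded in `dropped`.
#'
#' @param ct non-negative numeric matrix, samples x categories (at least
#'   2 x 2). Fractional counts are allowed (used by the unrounded
#'   sensitivity scan).
#' @return An object of class `chisq_result` with `statistic`, `df`,
#'   `p_value`, `expected`, `observed`, `min_expected`,
#'   `flag_min_expected`.
#' @export
pearson_chi_square <- function(ct) {
  ct <- as.matrix(ct)
  if (any(ct < 0)) stop("counts must be non-negative")
  if (sum(ct) <= 0) stop("contingency table has zero grand total")
  # all-zero rows/columns carry no information and make the statistic
  # undefined (expected 0); drop them, which reduces df accordingly
  dropped_rows <- rownames(ct)[rowSums(ct) == 0]
  dropped_cols <- colnames(ct)[colSums(ct) == 0]
  ct <- ct[rowSums(ct) > 0, colSums(ct) > 0, drop = FALSE]
  if (nrow(ct) < 2 || ncol(ct) < 2)
    stop("fewer than 2 non-zero rows or columns remain; test undefined")
  fit <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
  p <- fit$p.value
  underflow <- p == 0
  if (underflow) p <- .Machine$double.xmin
  structure(list(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = p,
                 p_underflow = underflow,
                 expected = fit$expected,
                 observed = ct,
                 min_expected = min(fit$expected),
                 flag_min_expected = min(fit$expected) < 5,
                 dropped = c(dropped_rows, dropped_cols)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  p_disp <- if (isTRUE(x$p_underflow)) "~0" else format(x$p_value, digits = 4)
  cat(sprintf("Pearson chi-squared: X2 = %.2f, df = %d, p = %s\n",
              x$statistic, x$df, p_disp))
  if (x$flag_min_expected)
    cat(sprintf("warning: smallest expected count %.2f < 5\n", x$min_expected))
  invisible(x)
}

#' Decompose a chi-squared statistic into per-cell contributions
#'
#' Each cell's `(O - E)^2 / E` term, with row (per-sample) and column
#' (per-terminal-state) aggregates; the cells sum exactly to the Pearson
#' statistic, attributing the overall difference to individual samples and
#' state pairs.
#'
#' @param ct contingency matrix as for [pearson_chi_square()].
#' @return An object of class `contribution_table` with `cells`,
#'   `by_sample`, `by_terminal_state` and `statistic`.
#' @export
cell_contributions <- function(ct) {
  res <- pearson_chi_square(ct)
  cells <- (res$observed - res$expected)^2 / res$expected
  structure(list(cells = cells,
                 by_sample = rowSums(cells),
                 by_terminal_state = colSums(cells),
                 statistic = res$statistic),
            class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, digits = 2, ...) {
  cat(sprintf("Chi-squared contributions (statistic %.2f):\n", x$statistic))
  print(round(x$cells, digits))
  invisible(x)
}

#' Divide contingency counts by a scale factor
#'
#' The large-count sensitivity device: counts are divided by `divisor` and
#' then rounded per `rounding` — `"half-up"` (nearest integer, halves away
#' from zero; the default), `"floor"`, or `"none"` (keep fractional counts,
#' under which the Pearson statistic scales exactly as 1/divisor).
#'
#' @param ct contingency matrix.
#' @param divisor positive number.
#' @param rounding rounding rule applied after division.
#' @return Scaled matrix with the same dimnames.
#' @export
scale_counts <- function(ct, divisor,
                         rounding = c("half-up", "floor", "none")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(divisor) || length(divisor) != 1 || divisor <= 0)
    stop("divisor must be a single positive number")
  x <- as.matrix(ct) / divisor
  switch(rounding,
         "half-up" = floor(x + 0.5),  # non-negative counts: half away from 0
         "floor" = floor(x),
         "none" = x)
}

#' Divide-by-10^n sensitivity scan
#'
#' Re-runs the per-initial-state chi-squared test after dividing the counts
#' by each divisor (default 1, 10, 100, 1000), to expose significance driven
#' purely by the very large number of CG pairs. Results whose smallest
#' expected count drops below 5 are flagged and should not be interpreted.
#'
#' @inheritParams build_contingency
#' @param divisors positive numbers (default `c(1, 10, 100, 1000)`).
#' @param rounding rounding rule, see [scale_counts()].
#' @return Named list of `chisq_result` (one per divisor), each with an
#'   added `divisor` element. Use [sensitivity_table()] for a flat summary.
#' @export
sensitivity_scan <- function(tables, initial_state,
                             divisors = c(1, 10, 100, 1000),
                             rounding = c("half-up", "floor", "none")) {
  rounding <- match.arg(rounding)
  if (any(divisors <= 0)) stop("divisors must be positive")
  ct <- build_contingency(tables, initial_state)
  out <- lapply(divisors, function(d) {
    res <- tryCatch(pearson_chi_square(scale_counts(ct, d, rounding)),
                    error = function(e)
                      # table degenerates after down-scaling (e.g. all counts
                      # round to 0): report an unusable, flagged result
                      structure(list(statistic = NA_real_, df = NA_integer_,
                                     p_value = NA_real_, p_underflow = FALSE,
                                     expected = NULL, observed = NULL,
                                     min_expected = NA_real_,
                                     flag_min_expected = TRUE,
                                     dropped = character(0),
                                     error = conditionMessage(e)),
                                class = "chisq_result"))
    res$divisor <- d
    res
  })
  names(out) <- as.character(divisors)
  out
}

#' Flatten a sensitivity scan into a data frame
#'
#' @param scan result of [sensitivity_scan()].
#' @return Data frame with columns `divisor`, `statistic`, `df`, `p_value`,
#'   `min_expected`, `flag_min_expected`.
#' @export
sensitivity_table <- function(scan) {
  data.frame(divisor = vapply(scan, function(r) r$divisor, numeric(1)),
             statistic = vapply(scan, function(r) r$statistic, numeric(1)),
             df = vapply(scan, function(r) r$df, numeric(1)),
             p_value = vapply(scan, function(r) r$p_value, numeric(1)),
             min_expected = vapply(scan, function(r) r$min_expected, numeric(1)),
             flag_min_expected = vapply(scan, function(r) r$flag_min_expected,
                                        logical(1)),
             row.names = NULL)
}

#' Pairwise chi-squared follow-up tests
#'
#' One 2 x 4 Pearson test per unordered sample pair for a given initial
#' state, used to locate which samples drive a significant omnibus test. No
#' multiplicity adjustment is applied by default; `p_adjust = "BH"` adds
#' Benjamini-Hochberg adjusted p-values.
#'
#' @inheritParams build_contingency
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return Named list (`"S1.vs.S2"`) of `chisq_result`; when adjusted, each
#'   gains a `p_adjusted` element.
#' @export
pairwise_chi_square <- function(tables, initial_state, p_adjust = "none") {
  ct <- build_contingency(tables, initial_state)
  ids <- rownames(ct)
  combs <- utils::combn(seq_along(ids), 2)
  out <- apply(combs, 2, function(k) pearson_chi_square(ct[k, , drop = FALSE]),
               simplify = FALSE)
  names(out) <- apply(combs, 2, function(k) paste(ids[k], collapse = ".vs."))
  if (p_adjust != "none") {
    adj <- stats::p.adjust(vapply(out, function(r) r$p_value, numeric(1)),
                           method = p_adjust)
    for (i in seq_along(out)) out[[i]]$p_adjusted <- adj[i]
  }
  out
}
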