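#' Published spleen transition-pair counts (3S1T)
#'
#' The 4x4 methylation state-pair counts for chromosome 1 (forward strand) of
#' the spleen tissue of Roadmap Epigenomics samples STL001, STL002 and
#' STL003, as published. Rows are the initial, columns the terminal state.
#' These serve as worked-example inputs for the chi-squared comparison layer
#' and as calibration for the synthetic generator.
#'
#' @return Named list of three [transition_table()]s.
#' @export
spleen_transition_counts <- function() {
  m <- function(...) matrix(c(...), nrow = 4, byrow = TRUE)
  counts <- list(
    STL001 = m(159513, 12082,   7505,   16928,
                12129, 13298,  14876,   30868,
                 7398, 15037,  41996,  119380,
                17048, 30890, 119492, 1425036),
    STL002 = m(170787, 13663,   9638,   18661,
                13745, 17814,  21403,   35313,
                 9592, 21348,  63698,  151667,
                18723, 35534, 151708, 1308261),
    STL003 = m(209282, 13179,   8953,   17408,
                13282, 20626,  22691,   34669,
                 9104, 22403,  71035,  154423,
                17244, 35103, 154381, 1342781))
  mapply(transition_table, counts, names(counts), SIMPLIFY = FALSE)
}

#' Published tissue transition percentages (1S8T)
#'
#' The 4x4 methylation state-pair row percentages for chromosome 1 (forward
#' strand) of eight tissues of Roadmap Epigenomics sample STL001, as
#' published. Each row sums to ~100. Dividing by 100 yields row-stochastic
#' matrices usable as base transition kernels for the synthetic generator's
#' multi-tissue scenarios.
#'
#' @return Named list of eight 4x4 matrices (rows initial, columns terminal
#'   state, in percent).
#' @export
tissue_transition_percentages <- function() {
  m <- function(...) {
    out <- matrix(c(...), nrow = 4, byrow = TRUE)
    dimnames(out) <- list(initial = meth_states(), terminal = meth_states())
    out
  }
  list(
    Bladder      = m(83.26,  6.62,  3.90,  6.23,
                     14.03, 24.60, 25.51, 35.86,
                      3.90, 11.65, 27.34, 57.11,
                      1.05,  2.81,  9.59, 86.54),
    Gastric      = m(79.25,  7.53,  5.08,  8.14,
                     13.96, 22.65, 25.90, 37.49,
                      3.98, 10.64, 26.56, 58.82,
                      1.19,  2.91, 10.98, 84.92),
    Lung         = m(79.58,  6.78,  4.19,  9.45,
                     17.20, 20.25, 20.32, 42.23,
                      4.47,  8.32, 22.13, 65.09,
                      1.16,  2.04,  7.49, 89.32),
    Psoas        = m(74.16,  8.84,  6.60, 10.40,
                     14.55, 21.15, 24.93, 39.38,
                      4.75, 10.78, 24.99, 59.49,
                      1.39,  3.15, 10.89, 84.57),
    SigmoidColon = m(86.99,  4.38,  2.73,  5.90,
                     12.46, 23.87, 25.10, 38.57,
                      2.81,  9.03, 30.42, 57.75,
                      0.85,  1.95,  8.02, 89.18),
    SmallBowel   = m(85.48,  5.08,  3.55,  5.89,
                     11.66, 24.47, 27.92, 35.96,
                      2.92, 10.32, 31.69, 55.07,
                      0.94,  2.51, 10.46, 86.09),
    Spleen       = m(81.37,  6.16,  3.83,  8.64,
                     17.04, 18.69, 20.90, 43.37,
                      4.03,  8.18, 22.85, 64.95,
                      1.07,  1.94,  7.50, 89.49),
    Thymus       = m(86.27,  4.12,  2.19,  7.42,
                     18.33, 17.02, 14.77, 49.89,
                      5.66,  8.92, 17.17, 68.24,
                      1.01,  1.52,  3.49, 93.98))
}
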