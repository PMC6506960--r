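# Shared fixtures and independent oracles.

# The seven-row worked example: per-CpG records whose annotation yields
# states B, D, D, A, D, C, NA and distances 12, 3, 14, 17, 45, 31, NA.
# The first site's coverage is below 3X, yet the example keeps its state;
# reproducing that exactly requires min_coverage = 0 (see example_config).
example_track <- function() {
  meth_track(data.frame(
    chrom = "chr1",
    position = c(434314L, 434326L, 434329L, 434343L, 434360L, 434405L, 434436L),
    coverage = c(2L, 19L, 17L, 15L, 20L, 21L, 0L),
    mc_ratio = c(0.3, 1, 1, 0.20, 0.8, 0.67, NA)),
    sample_id = "example")
}
example_config <- function() state_config(min_coverage = 0)

# Build an annotated track directly from a state string; NA entries become
# uncovered sites. Ratios are placed at state-interval midpoints.
track_from_states <- function(states, positions = NULL, sample_id = "fixture") {
  mid <- c(A = 0.1, B = 0.35, C = 0.6, D = 0.9)
  n <- length(states)
  if (is.null(positions)) positions <- seq(100L, by = 20L, length.out = n)
  coverage <- ifelse(is.na(states), 0L, 10L)
  ratio <- ifelse(is.na(states), NA_real_, mid[states])
  annotate_track(meth_track(data.frame(chrom = "chr1", position = positions,
                                       coverage = coverage, mc_ratio = ratio),
                            sample_id = sample_id))
}

random_states <- function(n, na_prob = 0.1) {
  s <- sample(c(meth_states(), NA), n, replace = TRUE,
              prob = c(rep((1 - na_prob) / 4, 4), na_prob))
  s
}

random_track <- function(n, na_prob = 0.1, sample_id = "random") {
  pos <- cumsum(sample(2:200, n, replace = TRUE))
  track_from_states(random_states(n, na_prob), positions = pos,
                    sample_id = sample_id)
}

# --- independent oracles -------------------------------------------------

# Pearson chi-squared by direct formula evaluation (no stats::chisq.test).
chisq_oracle <- function(ct) {
  E <- outer(rowSums(ct), colSums(ct)) / sum(ct)
  list(statistic = sum((ct - E)^2 / E),
       df = (nrow(ct) - 1) * (ncol(ct) - 1),
       p_value = stats::pchisq(sum((ct - E)^2 / E),
                               (nrow(ct) - 1) * (ncol(ct) - 1),
                               lower.tail = FALSE))
}

# Tie-corrected Kruskal-Wallis H by direct mid-rank computation.
kw_oracle <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  list(h_statistic = H, df = length(groups) - 1,
       p_value = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Brute-force run-length segmentation over the state string.
smr_oracle <- function(states, positions, min_count = 2L) {
  runs <- list()
  start <- 1L
  n <- length(states)
  for (i in seq_len(n)) {
    end_of_run <- i == n || is.na(states[i]) || is.na(states[i + 1]) ||
      states[i + 1] != states[i]
    if (end_of_run) {
      if (!is.na(states[start]) && (i - start + 1L) >= min_count)
        runs[[length(runs) + 1L]] <- data.frame(
          state = states[start], first_position = positions[start],
          last_position = positions[i], cg_count = i - start + 1L,
          length = positions[i] - positions[start])
      start <- i + 1L
    }
  }
  if (length(runs) == 0)
    return(data.frame(state = character(0), first_position = integer(0),
                      last_position = integer(0), cg_count = integer(0),
                      length = integer(0)))
  do.call(rbind, runs)
}

write_track_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}
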