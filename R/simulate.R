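#' Stationary distribution of a transition matrix
#'
#' @param T0 row-stochastic matrix.
#' @return Probability vector pi with `pi %*% T0 == pi`.
#' @export
stationary_distribution <- function(T0) {
  e <- eigen(t(T0))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(T0))
}

#' Simulation configuration for synthetic methylation tracks
#'
#' Defines a generative model for one chromosome's per-CpG methylation
#' records with controlled within-sample co-methylation structure:
#'
#' * CG positions with fixed spacing or shifted-geometric spacing (minimum
#'   2 bp, mean `spacing_mean`);
#' * a latent methylation-state Markov chain whose kernel relaxes with
#'   genomic distance d from the base matrix `T0` toward its stationary
#'   distribution: `T(d) = w T0 + (1 - w) 1 pi'` with `w = exp(-d /
#'   decay_length)` — nearby CpGs co-methylate, far-apart CpGs decouple;
#' * a per-state MC-ratio emission, uniform within the state's interval
#'   (optionally shrunk inward by `emission_margin` so discretization is
#'   noise-free at high coverage);
#' * read sampling: coverage is Poisson(`coverage_mean`) truncated at >= 1,
#'   with an independent zero-coverage probability `zero_coverage_prob`;
#'   observed methylated reads are Binomial(coverage, true ratio).
#'
#' Defaults emulate Roadmap-like WGBS of human chromosome 1: ~100 bp mean
#' CpG spacing, 30X coverage, 5% uncovered sites, the published STL001
#' spleen transition percentages as `T0`, and a 300 bp co-methylation decay
#' length.
#'
#' @param n_sites number of CG sites.
#' @param spacing_model `"geometric"` (shifted geometric, min 2 bp) or
#'   `"fixed"`.
#' @param spacing_mean mean gap in bp (>= 2); for `"fixed"` the constant gap.
#' @param coverage_mean mean read depth (Poisson, truncated at >= 1).
#' @param zero_coverage_prob probability a site has no reads at all.
#' @param base_transition 4x4 row-stochastic base kernel `T0` (default:
#'   STL001 spleen percentages / 100).
#' @param stationary stationary 4-vector `pi` (default: computed from `T0`).
#' @param decay_length distance-decay scale lambda in bp (> 0).
#' @param emission_margin inward shrink of each state's emission interval
#'   (in ratio units, `0 <= margin < 0.125`).
#' @param chrom chromosome label.
#' @param start_position position of the first CG site.
#' @param seed integer seed used by [simulate_track()]; `NULL` uses the
#'   current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10000L,
                       spacing_model = c("geometric", "fixed"),
                       spacing_mean = 100,
                       coverage_mean = 30,
                       zero_coverage_prob = 0.05,
                       base_transition = NULL,
                       stationary = NULL,
                       decay_length = 300,
                       emission_margin = 0,
                       chrom = "chr1",
                       start_position = 10001L,
                       seed = NULL) {
  spacing_model <- match.arg(spacing_model)
  if (n_sites < 1) stop("n_sites must be positive")
  if (spacing_mean < 2) stop("spacing_mean must be at least 2 bp")
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  if (zero_coverage_prob < 0 || zero_coverage_prob >= 1)
    stop("zero_coverage_prob must be in [0, 1)")
  if (decay_length <= 0) stop("decay_length must be positive")
  if (emission_margin < 0 || emission_margin >= 0.125)
    stop("emission_margin must be in [0, 0.125)")
  if (is.null(base_transition))
    base_transition <- spleen_transition_counts()$STL001$percentages / 100
  base_transition <- as.matrix(base_transition)
  if (!all(dim(base_transition) == c(4, 4)))
    stop("base_transition must be 4x4")
  rs <- rowSums(base_transition)
  if (any(abs(rs - 1) > 1e-6))
    stop("base_transition rows must sum to 1 (tolerance 1e-6); ",
         "divide percentages by 100 first")
  base_transition <- base_transition / rs  # exact row-stochastic
  dimnames(base_transition) <- list(initial = meth_states(),
                                    terminal = meth_states())
  if (is.null(stationary)) stationary <- stationary_distribution(base_transition)
  if (abs(sum(stationary) - 1) > 1e-8 || any(stationary < 0))
    stop("stationary must be a probability vector")
  stationary <- stats::setNames(as.numeric(stationary) / sum(stationary),
                                meth_states())
  structure(list(n_sites = as.integer(n_sites),
                 spacing_model = spacing_model,
                 spacing_mean = spacing_mean,
                 coverage_mean = coverage_mean,
                 zero_coverage_prob = zero_coverage_prob,
                 base_transition = base_transition,
                 stationary = stationary,
                 decay_length = decay_length,
                 emission_margin = emission_margin,
                 chrom = chrom,
                 start_position = as.integer(start_position),
                 seed = seed),
            class = "sim_config")
}

#' Distance-dependent transition kernel
#'
#' `T(d) = w T0 + (1 - w) 1 pi'` with `w = exp(-d / lambda)`: at small gaps
#' the state of the next CpG follows the base kernel (strong co-methylation),
#' at large gaps it is an independent draw from the stationary distribution.
#'
#' @param config a [sim_config()].
#' @param d gap in bp (>= 1).
#' @return 4x4 row-stochastic matrix.
#' @export
transition_matrix_at_distance <- function(config, d) {
  if (d < 1) stop("distance must be at least 1 bp")
  w <- exp(-d / config$decay_length)
  w * config$base_transition +
    (1 - w) * matrix(config$stationary, nrow = 4, ncol = 4, byrow = TRUE,
                     dimnames = dimnames(config$base_transition))
}

state_interval <- function(margin = 0) {
  lo <- c(A = 0, B = 0.25, C = 0.5, D = 0.75) + margin
  hi <- c(A = 0.25, B = 0.5, C = 0.75, D = 1) - margin
  list(lo = lo, hi = hi)
}

#' Simulate a synthetic methylation track with ground truth
#'
#' Draws positions, latent states, true MC ratios, coverage and observed
#' methylated reads per the generative model in [sim_config()]. The observed
#' ratio is methylated reads / coverage (missing at zero coverage). The same
#' seed always yields the same track.
#'
#' @param config a [sim_config()].
#' @return List with `track` (an unannotated [meth_track()]) and `truth`
#'   (class `sim_truth`): data frame of `position`, `latent_state`,
#'   `true_ratio`, plus the config as an attribute.
#' @export
simulate_track <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_sites
  gaps <- if (n == 1) integer(0)
          else if (config$spacing_model == "fixed")
            rep(as.integer(round(config$spacing_mean)), n - 1)
          else 2L + stats::rgeom(n - 1, prob = 1 / (config$spacing_mean - 1))
  positions <- config$start_position + c(0L, cumsum(gaps))

  states <- meth_states()
  latent <- character(n)
  latent[1] <- sample(states, 1, prob = config$stationary)
  if (n > 1) {
    w <- exp(-gaps / config$decay_length)
    u <- stats::runif(n - 1)
    T0 <- config$base_transition
    pi0 <- config$stationary
    for (i in 2:n) {
      p <- w[i - 1] * T0[latent[i - 1], ] + (1 - w[i - 1]) * pi0
      idx <- findInterval(u[i - 1], cumsum(p), left.open = TRUE) + 1L
      latent[i] <- states[min(idx, 4L)]  # guard FP slack in cumsum
    }
  }

  iv <- state_interval(config$emission_margin)
  true_ratio <- stats::runif(n, iv$lo[latent], iv$hi[latent])

  zero <- stats::runif(n) < config$zero_coverage_prob
  mu <- config$coverage_mean
  # Poisson truncated at >= 1 via inverse-CDF above the zero mass
  coverage <- stats::qpois(stats::runif(n, stats::dpois(0, mu), 1), mu)
  coverage[zero] <- 0L
  meth_reads <- stats::rbinom(n, coverage, true_ratio)
  mc_ratio <- ifelse(coverage > 0, meth_reads / coverage, NA_real_)

  track <- meth_track(data.frame(chrom = config$chrom, position = positions,
                                 coverage = coverage, mc_ratio = mc_ratio),
                      sample_id = "synthetic")
  truth <- structure(data.frame(position = positions, latent_state = latent,
                                true_ratio = true_ratio),
                     config = config, class = c("sim_truth", "data.frame"))
  list(track = track, truth = truth)
}

#' Compare pipeline estimates against the generator's ground truth
#'
#' Quantifies recovery of the latent structure from the observed track:
#' per distance bin, the maximum absolute deviation (percentage points)
#' between the pipeline's row transition percentages and those of the latent
#' state chain; and the latent-vs-observed state confusion matrix for sites
#' that received a state.
#'
#' @param track the simulated [meth_track()] (annotated or not; annotated
#'   with `config` if needed).
#' @param truth the matching `sim_truth`.
#' @param config [state_config()] for annotation.
#' @param bin_edges distance bins, see [bin_transitions_by_distance()].
#' @return List with `by_bin` (data frame `bin`, `n_pairs`, `max_abs_dev`),
#'   `overall_max_abs_dev` (marginal tables), `confusion` (4x5 latent x
#'   observed counts, `NA` column included) and `state_agreement` (percent of
#'   state-assigned sites whose observed state equals the latent state).
#' @export
recovery_report <- function(track, truth, config = state_config(),
                            bin_edges = default_distance_bins()) {
  if (nrow(track) != nrow(truth))
    stop("track and truth have different lengths")
  if (!is_annotated(track)) track <- annotate_track(track, config)

  latent_track <- track
  latent_track$state <- truth$latent_state

  obs_pairs <- build_state_pairs(track)
  lat_pairs <- build_state_pairs(latent_track)
  obs_bin <- bin_transitions_by_distance(obs_pairs, bin_edges)
  lat_bin <- bin_transitions_by_distance(lat_pairs, bin_edges)

  row_pct <- function(m) {
    rs <- rowSums(m)
    out <- 100 * sweep(m, 1, rs, "/")
    out[rs == 0, ] <- NA_real_
    out
  }
  by_bin <- data.frame(bin = obs_bin$labels,
                       n_pairs = as.numeric(obs_bin$bin_totals),
                       max_abs_dev = NA_real_)
  for (b in seq_along(obs_bin$labels)) {
    dev <- abs(row_pct(obs_bin$counts[b, , ]) - row_pct(lat_bin$counts[b, , ]))
    if (any(is.finite(dev))) by_bin$max_abs_dev[b] <- max(dev, na.rm = TRUE)
  }
  overall <- abs(marginal_transitions(obs_bin)$percentages -
                 marginal_transitions(lat_bin)$percentages)
  overall_max <- if (any(is.finite(overall))) max(overall, na.rm = TRUE)
                 else NA_real_

  obs_state <- factor(ifelse(is.na(track$state), "NA", track$state),
                      levels = c(meth_states(), "NA"))
  confusion <- table(latent = factor(truth$latent_state,
                                     levels = meth_states()),
                     observed = obs_state)
  assigned <- !is.na(track$state)
  agreement <- if (any(assigned))
    100 * mean(track$state[assigned] == truth$latent_state[assigned])
  else NA_real_

  list(by_bin = by_bin, overall_max_abs_dev = overall_max,
       confusion = confusion, state_agreement = agreement)
}
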