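#' Read and annotate a set of methylation tables
#'
#' @param inputs named character vector `c(label = path, ...)`.
#' @param dialect input dialect, see [read_methylation_table()].
#' @param config [state_config()].
#' @return Named list of annotated [meth_track()]s, all on one chromosome.
#' @export
load_tracks <- function(inputs, dialect = "native", config = state_config()) {
  if (is.null(names(inputs)) || any(names(inputs) == ""))
    stop("inputs must be a named vector: c(label = path, ...)")
  if (anyDuplicated(names(inputs)))
    stop("input labels must be unique")
  tracks <- lapply(seq_along(inputs), function(i)
    annotate_track(read_methylation_table(inputs[[i]], dialect = dialect,
                                          sample_id = names(inputs)[i]),
                   config))
  names(tracks) <- names(inputs)
  chroms <- unique(vapply(tracks, function(t) attr(t, "chrom"), character(1)))
  chroms <- chroms[!is.na(chroms)]
  if (length(chroms) > 1)
    stop("inputs mix chromosomes: ", paste(chroms, collapse = ", "))
  tracks
}

write_manifest <- function(out_dir, command, params, outputs) {
  manifest <- list(command = command,
                   package_version = as.character(utils::packageVersion("cometh")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   parameters = params,
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_transition_csv <- function(tt, path) {
  df <- data.frame(initial = meth_states(), tt$counts, tt$percentages)
  names(df) <- c("initial", paste0("count_", meth_states()),
                 paste0("pct_", meth_states()))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the transition-pattern comparison end to end
#'
#' For each annotated track: build state pairs, tabulate the 4x4 transition
#' table and the distance-binned occurrence profile. Across samples, per
#' initial state: omnibus Pearson chi-squared test, per-cell contribution
#' decomposition, divide-by-10^n sensitivity scan, and (when the omnibus
#' p-value falls below `alpha`, or always with `force_pairwise`) pairwise
#' follow-up tests. All tables are written as CSV under `out_dir`, along
#' with a JSON run manifest.
#'
#' @param tracks named list of annotated [meth_track()]s (>= 1; comparisons
#'   need >= 2).
#' @param out_dir output directory (created if needed).
#' @param bin_edges distance bins for the profiles.
#' @param divisors sensitivity-scan divisors.
#' @param alpha significance level gating pairwise follow-ups.
#' @param force_pairwise run pairwise tests regardless of the omnibus.
#' @param exclude sample labels to drop before the comparisons (outlier
#'   removal; descriptive per-sample outputs are still written).
#' @param profile_denominator see [distance_profile()].
#' @return Invisibly, a list with `transitions`, `binned`, `chisq`
#'   (per state: `omnibus`, `contributions`, `scan`, `pairwise`).
#' @export
run_analysis1 <- function(tracks, out_dir,
                          bin_edges = default_distance_bins(),
                          divisors = c(1, 10, 100, 1000),
                          alpha = 0.05,
                          force_pairwise = FALSE,
                          exclude = character(0),
                          profile_denominator = "bin-total") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)

  transitions <- list()
  binned <- list()
  for (s in names(tracks)) {
    pairs <- build_state_pairs(tracks[[s]])
    transitions[[s]] <- count_transitions(pairs, sample_id = s)
    binned[[s]] <- bin_transitions_by_distance(pairs, bin_edges, sample_id = s)
    outputs <- c(outputs,
      write_transition_csv(transitions[[s]],
                           file.path(out_dir, paste0("transitions_", s, ".csv"))))
    pf <- file.path(out_dir, paste0("profile_", s, ".csv"))
    utils::write.csv(profile_table(binned[[s]], profile_denominator),
                     pf, row.names = FALSE)
    outputs <- c(outputs, pf)
  }

  chisq <- list()
  cmp <- transitions[setdiff(names(transitions), exclude)]
  if (length(cmp) >= 2) {
    for (st in meth_states()) {
      scan <- sensitivity_scan(cmp, st, divisors)
      omnibus <- scan[[which(divisors == 1)[1]]]
      if (is.null(omnibus)) omnibus <- pearson_chi_square(build_contingency(cmp, st))
      contrib <- cell_contributions(build_contingency(cmp, st))
      pw <- if (force_pairwise || omnibus$p_value < alpha)
        pairwise_chi_square(cmp, st) else NULL

      cf <- file.path(out_dir, paste0("chisq_", st, ".csv"))
      utils::write.csv(sensitivity_table(scan), cf, row.names = FALSE)
      kf <- file.path(out_dir, paste0("contributions_", st, ".csv"))
      cdf <- data.frame(sample = rownames(contrib$cells), contrib$cells,
                        total = contrib$by_sample)
      utils::write.csv(cdf, kf, row.names = FALSE)
      outputs <- c(outputs, cf, kf)
      if (!is.null(pw)) {
        pwf <- file.path(out_dir, paste0("chisq_pairwise_", st, ".csv"))
        pdf_ <- data.frame(pair = names(pw),
                           statistic = vapply(pw, function(r) r$statistic, 1),
                           df = vapply(pw, function(r) r$df, 1),
                           p_value = vapply(pw, function(r) r$p_value, 1))
        utils::write.csv(pdf_, pwf, row.names = FALSE)
        outputs <- c(outputs, pwf)
      }
      chisq[[st]] <- list(omnibus = omnibus, contributions = contrib,
                          scan = scan, pairwise = pw)
    }
  }
  write_manifest(out_dir, "analysis1",
                 list(samples = names(tracks), exclude = exclude,
                      bin_edges = bin_edges, divisors = divisors,
                      alpha = alpha, force_pairwise = force_pairwise,
                      profile_denominator = profile_denominator),
                 basename(outputs))
  invisible(list(transitions = transitions, binned = binned, chisq = chisq))
}

#' Run the SMR distribution comparison end to end
#'
#' For each annotated track: segment similarly methylated regions, export
#' them as BED6, and write the per-state six-number summaries of CG count
#' and bp length. Across samples, per state and metric: omnibus
#' Kruskal-Wallis test and conditional pairwise follow-ups, written as
#' `kw_count.csv` / `kw_length.csv`, plus a JSON run manifest.
#'
#' @inheritParams run_analysis1
#' @param min_count minimum CG sites per reported SMR.
#' @param drop_largest trim one maximum before summarizing.
#' @return Invisibly, a list with `smrs`, `report`, `kw` (per metric, per
#'   state: `omnibus`, `pairwise`).
#' @export
run_analysis2 <- function(tracks, out_dir,
                          min_count = 2L,
                          drop_largest = TRUE,
                          alpha = 0.05,
                          force_pairwise = FALSE,
                          exclude = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)

  smrs <- lapply(names(tracks), function(s)
    segment_smrs(tracks[[s]], min_count = min_count))
  names(smrs) <- names(tracks)
  for (s in names(smrs)) {
    bf <- file.path(out_dir, paste0("smr_", s, ".bed"))
    export_smr_bed(smrs[[s]], bf)
    sf <- file.path(out_dir, paste0("smr_summary_", s, ".csv"))
    utils::write.csv(smr_report(smrs[s], drop_largest), sf, row.names = FALSE)
    outputs <- c(outputs, bf, sf)
  }

  kw <- list()
  cmp <- smrs[setdiff(names(smrs), exclude)]
  if (length(cmp) >= 2) {
    for (metric in c("count", "length")) {
      per_state <- list()
      rows <- list()
      for (st in meth_states()) {
        groups <- smr_metric_groups(cmp, st, metric)
        nonempty <- lengths(groups) > 0
        if (sum(nonempty) < 2) next
        groups <- groups[nonempty]
        omnibus <- kruskal_wallis(groups)
        pw <- if (force_pairwise || omnibus$p_value < alpha)
          pairwise_kw(groups) else NULL
        per_state[[st]] <- list(omnibus = omnibus, pairwise = pw)
        tab <- kw_table(omnibus, pw)
        tab <- data.frame(state = st, tab)
        rows[[st]] <- tab
      }
      if (length(rows) > 0) {
        kf <- file.path(out_dir, paste0("kw_", metric, ".csv"))
        utils::write.csv(do.call(rbind, rows), kf, row.names = FALSE)
        outputs <- c(outputs, kf)
      }
      kw[[metric]] <- per_state
    }
  }
  write_manifest(out_dir, "analysis2",
                 list(samples = names(tracks), exclude = exclude,
                      min_count = min_count, drop_largest = drop_largest,
                      alpha = alpha, force_pairwise = force_pairwise),
                 basename(outputs))
  invisible(list(smrs = smrs,
                 report = smr_report(smrs, drop_largest),
                 kw = kw))
}
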