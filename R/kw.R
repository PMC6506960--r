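#' Kruskal-Wallis rank test across groups
#'
#' Compares k value distributions (e.g. SMR CG counts or bp lengths across
#' samples) with the tie-corrected Kruskal-Wallis H statistic on mid-ranks
#' and the chi-squared approximation with k - 1 degrees of freedom. Tie
#' correction always applies — SMR counts are heavily tied at small values.
#' The degenerate case in which every pooled value is identical returns
#' `H = 0, p = 1` rather than an error.
#'
#' @param groups list of non-empty numeric vectors (k >= 2), ideally named.
#' @return An object of class `kw_result` with `h_statistic`, `df`,
#'   `p_value`, `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    res <- list(h_statistic = 0, df = length(groups) - 1L, p_value = 1,
                group_sizes = as.integer(sizes))
    return(structure(res, class = "kw_result"))
  }
  g <- factor(rep(seq_along(groups), times = sizes))
  fit <- stats::kruskal.test(pooled, g)
  structure(list(h_statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value,
                 group_sizes = as.integer(sizes)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %s (n = %s)\n",
              x$h_statistic, x$df, format(x$p_value, digits = 4),
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Pairwise Kruskal-Wallis follow-up tests
#'
#' One two-group test (df = 1) per unordered pair of labeled groups,
#' locating which samples drive a significant omnibus result. No
#' multiplicity adjustment by default; `p_adjust = "BH"` adds
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param groups named list of non-empty numeric vectors (k >= 2).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return Named list (`"S1.vs.S2"`) of `kw_result`.
#' @export
pairwise_kw <- function(groups, p_adjust = "none") {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  combs <- utils::combn(names(groups), 2)
  out <- apply(combs, 2, function(k) kruskal_wallis(groups[k]),
               simplify = FALSE)
  names(out) <- apply(combs, 2, paste, collapse = ".vs.")
  if (p_adjust != "none") {
    adj <- stats::p.adjust(vapply(out, function(r) r$p_value, numeric(1)),
                           method = p_adjust)
    for (i in seq_along(out)) out[[i]]$p_adjusted <- adj[i]
  }
  out
}

#' Flatten omnibus plus pairwise Kruskal-Wallis results
#'
#' @param omnibus a `kw_result` (or `NULL`).
#' @param pairwise named list from [pairwise_kw()] (or `NULL`).
#' @return Data frame with columns `comparison`, `h_statistic`, `df`,
#'   `p_value`.
#' @export
kw_table <- function(omnibus = NULL, pairwise = NULL) {
  rows <- list()
  if (!is.null(omnibus))
    rows[["omnibus"]] <- data.frame(comparison = "all",
                                    h_statistic = omnibus$h_statistic,
                                    df = omnibus$df,
                                    p_value = omnibus$p_value)
  for (nm in names(pairwise))
    rows[[nm]] <- data.frame(comparison = nm,
                             h_statistic = pairwise[[nm]]$h_statistic,
                             df = pairwise[[nm]]$df,
                             p_value = pairwise[[nm]]$p_value)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
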