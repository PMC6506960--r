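#' Read a per-CpG methylation table
#'
#' Reads one chromosome of one sample in either the native four-column layout
#' (`chrom`, `position`, `coverage`, `mc_ratio`, with optional `state` and
#' `distance` columns which are ignored on input) or the Bismark coverage
#' layout (`chrom`, `start`, `end`, `%methylation`, `count_M`, `count_U`),
#' mapped to the native schema with `coverage = count_M + count_U` and
#' `mc_ratio = count_M / coverage` (missing when coverage is 0; the percentage
#' column is ignored).
#'
#' Records are validated (ratios in \[0, 1\], no duplicate positions, a
#' present ratio requires positive coverage). Unsorted input is sorted by
#' position with a warning. If a `strand` column is present, reverse-strand
#' records are dropped with a message; only the forward strand is modeled.
#'
#' @param path file path.
#' @param dialect `"native"` or `"bismark-cov"`.
#' @param sample_id label for the track; defaults to the file name without
#'   extension.
#' @param sep field delimiter (default tab).
#' @param header whether the file has a header line (default `TRUE` for
#'   native, `FALSE` for bismark-cov).
#' @param na_string literal used for missing ratios (default `"NA"`).
#' @return A [meth_track()].
#' @export
read_methylation_table <- function(path,
                                   dialect = c("native", "bismark-cov"),
                                   sample_id = NULL,
                                   sep = "\t",
                                   header = NULL,
                                   na_string = "NA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(header)) header <- dialect == "native"

  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = header,
                      na.strings = na_string, stringsAsFactors = FALSE,
                      colClasses = NA, comment.char = "", quote = ""),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))

  if (nrow(raw) == 0)
    return(meth_track(data.frame(chrom = character(0), position = integer(0),
                                 coverage = integer(0), mc_ratio = numeric(0)),
                      sample_id = sample_id))

  if (dialect == "native") {
    if (header) {
      nm <- tolower(names(raw))
      nm[nm %in% c("chr", "chromosome")] <- "chrom"
      nm[nm %in% c("pos", "position")] <- "position"
      nm[nm %in% c("sequence.coverage", "sequence_coverage",
                   "seq_coverage")] <- "coverage"
      nm[nm %in% c("mc.ratio", "mc_ratio", "ratio", "mcratio")] <- "mc_ratio"
      names(raw) <- nm
      need <- c("chrom", "position", "coverage", "mc_ratio")
      if (!all(need %in% nm))
        stop("cannot resolve columns in ", path, "; need ",
             paste(need, collapse = ", "))
    } else {
      if (ncol(raw) < 4) stop("native dialect needs at least 4 columns")
      names(raw)[1:4] <- c("chrom", "position", "coverage", "mc_ratio")
    }
    df <- raw[, c("chrom", "position", "coverage", "mc_ratio")]
    if ("strand" %in% names(raw)) {
      rev <- raw$strand != "+"
      if (any(rev)) {
        message("dropping ", sum(rev), " reverse-strand record(s)")
        df <- df[!rev, , drop = FALSE]
      }
    }
  } else {
    if (ncol(raw) < 6)
      stop("bismark-cov dialect needs 6 columns (chrom, start, end, ",
           "%methylation, count_M, count_U)")
    names(raw)[1:6] <- c("chrom", "position", "end", "pct", "count_m", "count_u")
    cov <- raw$count_m + raw$count_u
    df <- data.frame(chrom = raw$chrom, position = raw$position,
                     coverage = cov,
                     mc_ratio = ifelse(cov > 0, raw$count_m / cov, NA_real_))
  }

  bad_row <- which(is.na(suppressWarnings(as.numeric(df$position))) |
                   is.na(suppressWarnings(as.numeric(df$coverage))))
  if (length(bad_row) > 0)
    stop("malformed row at line ", bad_row[1] + as.integer(header),
         " of ", path)
  meth_track(df, sample_id = sample_id)
}

#' Write an annotated methylation table
#'
#' Writes a tab-separated table with the six columns `chrom`, `position`,
#' `coverage`, `mc_ratio`, `state`, `distance`, one row per CG site in
#' position order. Missing ratios, states and the final site's distance are
#' written as the missing literal.
#'
#' @param track an annotated [meth_track()].
#' @param path output file path.
#' @param na_string literal for missing values (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_annotated_table <- function(track, path, na_string = "NA") {
  stop_if_unannotated(track)
  df <- as.data.frame(track)[, c("chrom", "position", "coverage",
                                 "mc_ratio", "state", "distance")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = na_string,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Export SMRs as BED6
#'
#' Converts the native 1-based inclusive CpG coordinates to BED's 0-based
#' half-open convention: `start = first_position - 1`,
#' `end = last_position + 1`, so the interval covers the G of the final CpG.
#' Name is the methylation state, score the CG count, strand `+`.
#'
#' @param smrset an `smr_set` from [segment_smrs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_smr_bed <- function(smrset, path) {
  if (nrow(smrset) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = smrset$chrom,
                    start = smrset$first_position - 1L,
                    end = smrset$last_position + 1L,
                    name = smrset$state,
                    score = smrset$cg_count,
                    strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
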