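#' Sliding-window feature density track
#'
#' Computes a density track over `[0, chrom_length)` with overlapping
#' sliding windows.  `count_per_mb` counts feature start positions per
#' window, scaled to features/Mb; `percent_bp` reports the percentage of
#' window bp covered by the merged (union of) feature intervals, so
#' splitting an interval into abutting pieces does not change the track.
#'
#' @param features Feature intervals: a data.frame with `start`/`end`
#'   (0-based half-open bp) or, for `count_per_mb`, a numeric vector of
#'   start positions.
#' @param chrom_length Chromosome length in bp.
#' @param window,step Window and slide step in bp (`step <= window`); the
#'   terminal window is truncated at the chromosome end.
#' @param mode `"count_per_mb"` or `"percent_bp"`.
#' @param chrom Chromosome name stored in the track.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @examples
#' densityWindows(c(1e5, 2e5, 3e5), 2e6, mode = "count_per_mb")
#' @export
densityWindows <- function(features, chrom_length, window = 1e6,
                           step = 0.2e6, mode = c("count_per_mb",
                                                  "percent_bp"),
                           chrom = "chr") {
  mode <- match.arg(mode)
  if (step > window) stop("step must be <= window")
  starts <- seq(0, max(0, chrom_length - step), by = step)
  starts <- starts[starts < chrom_length]
  ends <- pmin(starts + window, chrom_length)
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (mode == "count_per_mb") {
    pos <- if (is.data.frame(features)) features$start else
      as.numeric(features)
    if (any(pos < 0 | pos >= chrom_length))
      stop("feature positions outside chromosome bounds")
    value <- vapply(seq_along(starts), function(i)
      sum(pos >= starts[i] & pos < ends[i]) / ((ends[i] - starts[i]) / 1e6),
      0)
  } else {
    if (!is.data.frame(features) ||
        !all(c("start", "end") %in% names(features)))
      stop("percent_bp mode needs a data.frame with start and end")
    if (any(features$start < 0 | features$end > chrom_length))
      stop("feature intervals outside chromosome bounds")
    ir <- IRanges::reduce(IRanges::IRanges(features$start + 1,
                                           features$end))
    cov <- IRanges::coverage(ir, width = chrom_length)
    vs <- IRanges::viewSums(IRanges::Views(cov, start = starts + 1,
                                           end = ends))
    value <- 100 * vs / (ends - starts)
  }
  data.frame(chrom = chrom, start = starts, end = ends, value = value)
}

#' Rank tests of a focal chromosome's density track against autosomes
#'
#' Runs a two-sided Mann-Whitney-Wilcoxon test of the focal chromosome's
#' window values against each autosome's, then adjusts the p values
#' across autosomes with the Holm step-down procedure.
#'
#' @param track_x Density track of the focal chromosome (from
#'   [densityWindows()]).
#' @param autosome_tracks Named list of autosome density tracks.
#' @param min_windows Minimum windows required per chromosome.
#' @return data.frame with `chrom`, `n_windows`, `U`, `p`, `p_adj`
#'   (Holm), ordered as supplied.
#' @export
compareChromosomes <- function(track_x, autosome_tracks,
                               min_windows = 10L) {
  if (!nrow(track_x)) stop("empty focal track")
  if (nrow(track_x) < min_windows)
    stop("focal chromosome has fewer than ", min_windows, " windows")
  rows <- lapply(names(autosome_tracks), function(nm) {
    tr <- autosome_tracks[[nm]]
    if (is.null(tr) || !nrow(tr)) stop("empty track for ", nm)
    if (nrow(tr) < min_windows)
      stop(nm, " has fewer than ", min_windows, " windows")
    wt <- suppressWarnings(
      stats::wilcox.test(track_x$value, tr$value, exact = FALSE))
    data.frame(chrom = nm, n_windows = nrow(tr),
               U = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}
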