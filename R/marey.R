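#' Build a Marey map from anchored markers
#'
#' Joins marker anchors with their genetic-map positions for one sex,
#' sorts by physical position and fits a monotone non-decreasing cM curve
#' by isotonic (least-squares) regression.  Markers whose raw cM deviates
#' from the fit by more than `outlier_cm` are flagged but kept.
#'
#' @param anchors data.frame from [anchorMarkers()].
#' @param markers Genetic-map marker table with `marker_id` and
#'   `cm_female` / `cm_male` columns (cM, NA allowed per sex).
#' @param chrom Chromosome to build the map for.
#' @param sex `"female"` or `"male"`: which cM column to use.
#' @param outlier_cm Outlier flag threshold in cM.
#' @return A [MareyMap-class] object.
#' @export
buildMareyMap <- function(anchors, markers, chrom = NULL,
                          sex = c("female", "male"), outlier_cm = 2) {
  sex <- match.arg(sex)
  cm_col <- paste0("cm_", sex)
  if (!cm_col %in% names(markers)) stop("markers lack column ", cm_col)
  if (is.null(chrom)) {
    chrom <- unique(anchors$chrom)
    if (length(chrom) != 1L)
      stop("anchors span several chromosomes; give `chrom`")
  }
  a <- anchors[anchors$chrom == chrom, ]
  d <- merge(a, markers[, c("marker_id", cm_col)], by = "marker_id")
  d <- d[!is.na(d[[cm_col]]), ]
  if (nrow(d) < 2L)
    stop("need at least 2 anchored markers with ", sex, " cM on ", chrom)
  d <- d[order(d$position, d$marker_id), ]
  fit <- stats::isoreg(d$position, d[[cm_col]])
  cm_fit <- if (is.null(fit$ord)) fit$yf else fit$yf[order(fit$ord)]
  points <- data.frame(marker_id = d$marker_id, bp = d$position,
                       cm = d[[cm_col]], cm_fit = cm_fit,
                       outlier = abs(d[[cm_col]] - cm_fit) > outlier_cm)
  new("MareyMap", chrom = chrom, sex = sex, points = points)
}

#' Windowed recombination-rate estimation from a Marey map
#'
#' Slides a window along the chromosome; within each window the rate is
#' the range of the smoothed cM values of the markers inside, divided by
#' the bp span of those markers (cM/Mb).  Windows with fewer than two
#' markers get `NA`; [segmentRegions()] interpolates them from neighbours
#' for segmentation only.
#'
#' @param marey A [MareyMap-class].
#' @param window,step Window and step sizes in bp (`window >= step`).
#' @param chrom_length Chromosome length in bp; defaults to the last
#'   marker position.
#' @return A [RecombinationProfile-class].
#' @export
recombinationRate <- function(marey, window = 10e6, step = 2e6,
                              chrom_length = NULL) {
  if (window < step) stop("window must be >= step")
  p <- mareyPoints(marey)
  if (is.null(chrom_length)) chrom_length <- max(p$bp)
  starts <- seq(0, max(0, chrom_length - window), by = step)
  if (starts[length(starts)] + window < chrom_length)
    starts <- c(starts, chrom_length - window)
  ends <- pmin(starts + window, chrom_length)
  rate <- n_mark <- numeric(length(starts))
  for (i in seq_along(starts)) {
    sel <- p$bp >= starts[i] & p$bp < ends[i]
    n_mark[i] <- sum(sel)
    if (n_mark[i] < 2L) { rate[i] <- NA_real_; next }
    span <- max(p$bp[sel]) - min(p$bp[sel])
    rate[i] <- if (span <= 0) 0 else
      (max(p$cm_fit[sel]) - min(p$cm_fit[sel])) / (span / 1e6)
  }
  new("RecombinationProfile", chrom = marey@chrom, sex = marey@sex,
      windows = data.frame(start = starts, end = ends, rate = rate,
                           n_markers = as.integer(n_mark)),
      window = window, step = step)
}
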