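#' Segment a chromosome into distal recombining and pericentromeric
#' rarely recombining regions
#'
#' Windows with rate below `threshold` are classed suppressed (windows
#' with too few markers are first interpolated linearly from neighbouring
#' windows, for segmentation only).  The pericentromeric region is the
#' longest contiguous suppressed run of at least `min_run` windows that
#' contains, or failing that is nearest to, the chromosome midpoint.  The
#' bp boundaries of the region are then refined by half-plateau
#' interpolation: on each side the adjacent recombining flank's plateau
#' rate r is estimated (median of the flank run) and the boundary is
#' placed where the windowed rate profile, interpolated linearly between
#' window midpoints, crosses halfway between the suppressed level and r
#' — a window centred exactly on a sharp rate change has rate r/2, so
#' this crossing is an unbiased boundary estimator.  When no crossing
#' exists the midpoint between the outermost suppressed window and its
#' recombining neighbour is used.
#'
#' @param profile A [RecombinationProfile-class].
#' @param threshold Suppression threshold in cM/Mb.
#' @param min_run Minimum suppressed run length in windows.
#' @param chrom_length Chromosome length in bp (default: last window end).
#' @param marey Optional [MareyMap-class] the profile was computed from.
#'   When given, boundaries are refined on the fitted cM curve itself:
#'   the pericentromeric plateau level is estimated from the markers
#'   inside the suppressed run and each boundary is placed at the
#'   midpoint of the marker gap where the monotone fit reaches (left) or
#'   leaves (right) that level, which localises the boundary to within
#'   half a marker spacing instead of a window width.
#' @return A [RegionSegmentation-class]; if no suppressed run of
#'   sufficient length exists the pericentromeric interval is empty and
#'   the whole chromosome is labelled `distal_p`.
#' @export
segmentRegions <- function(profile, threshold = 0.25, min_run = 3L,
                           chrom_length = NULL, marey = NULL) {
  w <- profileWindows(profile)
  if (nrow(w) < min_run)
    stop("profile must have at least min_run windows")
  if (is.null(chrom_length)) chrom_length <- max(w$end)
  mid <- (w$start + w$end) / 2
  rate <- w$rate
  if (anyNA(rate)) {
    known <- !is.na(rate)
    if (sum(known) < 2L) stop("too few informative windows")
    rate <- stats::approx(mid[known], rate[known], xout = mid,
                          rule = 2)$y
  }
  suppressed <- rate < threshold
  runs <- rle(suppressed)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= min_run)
  if (!length(cand)) {
    iv <- data.frame(start = 0, end = chrom_length, label = "distal_p")
    return(new("RegionSegmentation", chrom = profile@chrom,
               chrom_length = chrom_length, intervals = iv,
               boundaries = numeric()))
  }
  centre <- chrom_length / 2
  covers <- vapply(cand, function(k)
    mid[run_start[k]] <= centre && mid[run_end[k]] >= centre, TRUE)
  pick <- if (any(covers)) {
    cc <- cand[covers]
    cc[which.max(runs$lengths[cc])]
  } else {
    d <- vapply(cand, function(k)
      min(abs(c(mid[run_start[k]], mid[run_end[k]]) - centre)), 0)
    cand[which.min(d)]
  }
  i1 <- run_start[pick]; i2 <- run_end[pick]
  b1 <- if (i1 == 1L) 0 else
    .refineBoundary(mid, rate, flank = seq_len(i1 - 1L),
                    run = i1:i2, side = "left")
  b2 <- if (i2 == nrow(w)) chrom_length else
    .refineBoundary(mid, rate, flank = (i2 + 1L):nrow(w),
                    run = i1:i2, side = "right")
  if (!is.null(marey)) {
    W <- profile@window
    if (i1 > 1L) {
      r1 <- .changePoint(mareyPoints(marey), b1, W, side = "left")
      if (!is.na(r1)) b1 <- r1
    }
    if (i2 < nrow(w)) {
      r2 <- .changePoint(mareyPoints(marey), b2, W, side = "right")
      if (!is.na(r2)) b2 <- r2
    }
    if (b2 < b1) { b1 <- mean(c(b1, b2)); b2 <- b1 }
  }
  iv <- data.frame(start = c(0, b1, b2),
                   end = c(b1, b2, chrom_length),
                   label = c("distal_p", "pericentromeric", "distal_q"))
  iv <- iv[iv$end - iv$start > 0, ]
  rownames(iv) <- NULL
  new("RegionSegmentation", chrom = profile@chrom,
      chrom_length = chrom_length, intervals = iv,
      boundaries = c(b1, b2))
}

# Half-plateau crossing between a suppressed run and its recombining
# flank.  `flank`/`run` are window indices; returns a bp position.
.refineBoundary <- function(mid, rate, flank, run, side) {
  # restrict the flank to its contiguous recombining run adjacent to the
  # suppressed run
  flank <- if (side == "left") rev(flank) else flank
  r_flank <- rate[flank]
  r_sup <- stats::median(rate[run])
  r_d <- stats::median(r_flank)
  r_half <- (r_d + r_sup) / 2
  ord <- if (side == "left") c(sort(flank), run) else c(run, sort(flank))
  x <- mid[ord]; y <- rate[ord]
  cross <- which((y[-length(y)] - r_half) * (y[-1] - r_half) <= 0)
  if (!length(cross)) {
    # fallback: midpoint between outermost suppressed window and its
    # recombining neighbour
    edge <- if (side == "left") c(max(flank), run[1]) else
      c(run[length(run)], min(flank))
    return(mean(mid[edge]))
  }
  # crossing closest to the run edge
  edge_pos <- if (side == "left") length(flank) + 0.5 else
    length(run) + 0.5
  k <- cross[which.min(abs(cross + 0.5 - edge_pos))]
  y1 <- y[k]; y2 <- y[k + 1]
  if (y1 == y2) return((x[k] + x[k + 1]) / 2)
  x[k] + (r_half - y1) / (y2 - y1) * (x[k + 1] - x[k])
}

# Marker-level boundary refinement by segmented regression: around the
# coarse boundary, raw marker cM is modelled as a linear ramp meeting a
# constant plateau (continuous at the breakpoint); the breakpoint
# minimising the residual sum of squares over a marker-position grid is
# the refined boundary.  `side = "left"` expects ramp-then-plateau,
# `side = "right"` plateau-then-ramp.
.changePoint <- function(points, b_coarse, W, side) {
  p <- points[order(points$bp), ]
  zone <- abs(p$bp - b_coarse) <= 1.5 * W
  bp <- p$bp[zone]; cm <- p$cm[zone]
  if (length(bp) < 8L) return(NA_real_)
  cand <- sort(unique(bp))
  cand <- cand[cand > min(bp) & cand < max(bp)]
  if (length(cand) < 2L) return(NA_real_)
  best <- NA_real_; best_sse <- Inf
  for (beta in cand) {
    x <- if (side == "left") pmin(bp - beta, 0) else pmax(bp - beta, 0)
    fit <- stats::lm.fit(cbind(1, x), cm)
    slope <- fit$coefficients[2]
    if (is.na(slope) || slope <= 0) next
    sse <- sum(fit$residuals^2)
    if (sse < best_sse) { best_sse <- sse; best <- beta }
  }
  best
}

#' Label profile windows by segmentation region
#'
#' @param profile A [RecombinationProfile-class].
#' @param segmentation A [RegionSegmentation-class].
#' @param rule `"contained"` labels a window only when it lies entirely
#'   inside one region (windows straddling a boundary get NA);
#'   `"midpoint"` labels by the region containing the window midpoint.
#' @return Character vector of region labels, one per window.
#' @export
windowRegions <- function(profile, segmentation,
                          rule = c("contained", "midpoint")) {
  rule <- match.arg(rule)
  w <- profileWindows(profile)
  iv <- segmentIntervals(segmentation)
  lab <- rep(NA_character_, nrow(w))
  for (i in seq_len(nrow(iv))) {
    sel <- if (rule == "contained")
      w$start >= iv$start[i] & w$end <= iv$end[i]
    else {
      m <- (w$start + w$end) / 2
      m >= iv$start[i] & m < iv$end[i]
    }
    lab[sel] <- iv$label[i]
  }
  lab
}

#' Mean windowed recombination rate over labelled regions
#'
#' @inheritParams windowRegions
#' @param labels Region labels to average over.
#' @return Mean rate (cM/Mb) of the selected windows (NA rates dropped).
#' @export
regionRateMean <- function(profile, segmentation,
                           labels = c("distal_p", "distal_q"),
                           rule = "contained") {
  lab <- windowRegions(profile, segmentation, rule = rule)
  w <- profileWindows(profile)
  mean(w$rate[!is.na(lab) & lab %in% labels], na.rm = TRUE)
}

#' Pseudoautosomal boundary from segmentation and marker linkage labels
#'
#' Returns the distal_p/pericentromeric boundary as the PAR boundary
#' estimate, together with the bp interval between the last
#' pseudoautosomal and the first sex-linked anchored marker for
#' comparison.
#'
#' @param segmentation A [RegionSegmentation-class].
#' @param anchors data.frame with `marker_id` and `position`.
#' @param linkage Named character vector per marker_id with values
#'   `"pseudoautosomal"` or `"sex_linked"`.
#' @return list with `boundary` (bp), `interval` (bp pair: last PAR
#'   marker to first sex-linked marker) and `n_interleaved` (markers
#'   whose label conflicts with a simple left/right split).
#' @export
pseudoautosomalBoundary <- function(segmentation, anchors, linkage) {
  lab <- linkage[anchors$marker_id]
  pos <- anchors$position
  sl <- pos[!is.na(lab) & lab == "sex_linked"]
  par <- pos[!is.na(lab) & lab == "pseudoautosomal"]
  if (!length(sl)) stop("no sex-linked markers")
  lo <- if (length(par)) max(par[par < min(sl)], 0) else 0
  interval <- c(lo, min(sl))
  inter <- sum(par > min(sl)) + sum(sl < max(c(par, -Inf)))
  b <- segmentBoundaries(segmentation)
  if (!length(b)) stop("segmentation has no pericentromeric boundary")
  list(boundary = b[1], interval = interval,
       n_interleaved = as.integer(inter))
}
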