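#' @import methods
NULL

#' Marey map: genetic position against physical position
#'
#' Holds the (bp, cM) marker series of one chromosome and sex together
#' with a monotone (isotonic least-squares) fit of cM on bp.  Outlying
#' markers are flagged, never removed.
#'
#' @slot chrom Chromosome name.
#' @slot sex `"female"` or `"male"`.
#' @slot points data.frame with columns `marker_id`, `bp`, `cm`,
#'   `cm_fit`, `outlier`, sorted by `bp`.
#' @exportClass MareyMap
setClass("MareyMap",
         representation(chrom = "character", sex = "character",
                        points = "data.frame"),
         validity = function(object) {
           p <- object@points
           msg <- character()
           need <- c("marker_id", "bp", "cm", "cm_fit", "outlier")
           if (!all(need %in% names(p)))
             msg <- c(msg, "points must have marker_id, bp, cm, cm_fit, outlier")
           else {
             if (is.unsorted(p$bp)) msg <- c(msg, "points must be sorted by bp")
             if (any(diff(p$cm_fit) < -1e-9))
               msg <- c(msg, "cm_fit must be non-decreasing")
             if (any(p$cm < 0)) msg <- c(msg, "cM must be >= 0")
           }
           if (length(msg)) msg else TRUE
         })

#' Windowed recombination-rate profile
#'
#' @slot chrom Chromosome name.
#' @slot sex Sex of the underlying map.
#' @slot windows data.frame with `start`, `end` (bp, 0-based half-open),
#'   `rate` (cM/Mb; NA when fewer than two markers fall in the window)
#'   and `n_markers`.
#' @slot window,step Window and step sizes in bp.
#' @exportClass RecombinationProfile
setClass("RecombinationProfile",
         representation(chrom = "character", sex = "character",
                        windows = "data.frame", window = "numeric",
                        step = "numeric"),
         validity = function(object) {
           w <- object@windows
           msg <- character()
           if (!all(c("start", "end", "rate", "n_markers") %in% names(w)))
             msg <- c(msg, "windows must have start, end, rate, n_markers")
           else if (any(w$rate < 0, na.rm = TRUE))
             msg <- c(msg, "rates must be >= 0")
           if (object@window < object@step)
             msg <- c(msg, "window must be >= step")
           if (length(msg)) msg else TRUE
         })

#' Chromosome segmentation into distal and pericentromeric regions
#'
#' @slot chrom Chromosome name.
#' @slot chrom_length Chromosome length in bp.
#' @slot intervals data.frame with `start`, `end` (bp, 0-based half-open)
#'   and `label` among `distal_p`, `pericentromeric`, `distal_q`;
#'   non-empty intervals partition `[0, chrom_length)` in that order.
#' @slot boundaries Numeric bp positions of the labelled boundaries.
#' @exportClass RegionSegmentation
setClass("RegionSegmentation",
         representation(chrom = "character", chrom_length = "numeric",
                        intervals = "data.frame", boundaries = "numeric"),
         validity = function(object) {
           iv <- object@intervals
           msg <- character()
           if (!all(c("start", "end", "label") %in% names(iv)))
             return("intervals must have start, end, label")
           if (nrow(iv)) {
             if (abs(sum(iv$end - iv$start) - object@chrom_length) > 1e-6)
               msg <- c(msg, "interval lengths must sum to chrom_length")
             if (iv$start[1] != 0 ||
                 any(abs(iv$start[-1] - iv$end[-nrow(iv)]) > 1e-6))
               msg <- c(msg, "intervals must tile the chromosome")
             ord <- c("distal_p", "pericentromeric", "distal_q")
             if (!all(iv$label %in% ord) ||
                 is.unsorted(match(iv$label, ord)))
               msg <- c(msg, "labels must appear in order distal_p, pericentromeric, distal_q")
           }
           if (length(msg)) msg else TRUE
         })

#' @describeIn MareyMap-class marker points accessor
#' @param object,x A `MareyMap`.
#' @export
mareyPoints <- function(x) x@points

#' @describeIn RecombinationProfile-class window accessor
#' @param x A `RecombinationProfile`.
#' @export
profileWindows <- function(x) x@windows

#' @describeIn RegionSegmentation-class interval accessor
#' @param x A `RegionSegmentation`.
#' @export
segmentIntervals <- function(x) x@intervals

#' @describeIn RegionSegmentation-class boundary accessor
#' @export
segmentBoundaries <- function(x) x@boundaries

setMethod("show", "MareyMap", function(object) {
  p <- object@points
  cat("MareyMap:", object@chrom, "(", object@sex, "map )\n",
      " ", nrow(p), "markers,", sum(p$outlier), "flagged outliers\n",
      "  bp range:", format(min(p$bp), big.mark = ","), "-",
      format(max(p$bp), big.mark = ","), "\n",
      "  map length:", round(max(p$cm_fit), 2), "cM\n")
})

setMethod("show", "RecombinationProfile", function(object) {
  w <- object@windows
  cat("RecombinationProfile:", object@chrom, "(", object@sex, ")\n",
      " ", nrow(w), "windows of", object@window / 1e6, "Mb, step",
      object@step / 1e6, "Mb\n",
      "  mean rate:", round(mean(w$rate, na.rm = TRUE), 3), "cM/Mb (",
      sum(is.na(w$rate)), "windows with <2 markers )\n")
})

setMethod("show", "RegionSegmentation", function(object) {
  iv <- object@intervals
  cat("RegionSegmentation:", object@chrom, "\n")
  for (i in seq_len(nrow(iv)))
    cat(sprintf("  %-16s %12.0f - %12.0f  (%.1f Mb)\n", iv$label[i],
                iv$start[i], iv$end[i], (iv$end[i] - iv$start[i]) / 1e6))
})
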