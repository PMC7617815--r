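#' Simulate a chromosome-scale genetic map with distal recombination
#'
#' Emulates the recombination landscape of a large plant chromosome:
#' actively recombining distal segments on both arms and a rarely
#' recombining central (pericentromeric) segment.  The underlying rate
#' function is piecewise constant; marker cM positions are the integral of
#' that rate function at the marker bp position plus bounded Gaussian
#' noise, and markers are placed more densely where the rate is higher.
#' Alongside the marker table the generator emits an alignment hit table
#' in 12-column (`-outfmt 6` dialect) form in which rows satisfy or
#' violate the anchoring filters in controlled proportions, plus the true
#' region boundaries.
#'
#' @param chrom_length Chromosome length in bp.
#' @param distal_p_length,distal_q_length Lengths (bp) of the recombining
#'   p-arm and q-arm distal segments.
#' @param rate_distal,rate_center Recombination rates (cM/Mb) of the
#'   distal and central segments.
#' @param n_markers Number of markers (>= 10).
#' @param noise_cm Standard deviation (cM) of marker position noise; 0
#'   gives a noiseless map.
#' @param chrom,linkage_group Names used in output tables.
#' @param prop_fail_identity,prop_fail_length,prop_extra_exon Proportions
#'   of markers given an extra sub-threshold-identity hit, a
#'   sub-threshold-length hit, and a second passing (higher-start) exon
#'   hit respectively.
#' @param marker_floor Baseline marker placement weight (cM/Mb equivalent)
#'   so zero-rate regions still receive markers.
#' @return list with `markers` (marker_id, linkage_group, cm_female,
#'   cm_male), `hits` (12-column hit data.frame), `truth` (boundaries,
#'   rates, true marker positions) and `map_function` (the noiseless
#'   bp -> cM function).
#' @examples
#' set.seed(1)
#' m <- simulateGeneticMap(1e8, 1e7, 5e6, 2, 0, n_markers = 50)
#' @export
simulateGeneticMap <- function(chrom_length = 370597487,
                               distal_p_length = 25.6e6,
                               distal_q_length = 15e6,
                               rate_distal = 2, rate_center = 0,
                               n_markers = 400L, noise_cm = 0.25,
                               chrom = "ChrX", linkage_group = "LG12",
                               prop_fail_identity = 0.05,
                               prop_fail_length = 0.05,
                               prop_extra_exon = 0.3,
                               marker_floor = 0.25) {
  if (n_markers < 10L) stop("n_markers must be >= 10")
  if (distal_p_length + distal_q_length >= chrom_length)
    stop("distal segments must be shorter than the chromosome")
  b1 <- distal_p_length
  b2 <- chrom_length - distal_q_length
  seg_start <- c(0, b1, b2)
  seg_end <- c(b1, b2, chrom_length)
  seg_rate <- c(rate_distal, rate_center, rate_distal)
  cum_cm <- cumsum(c(0, seg_rate * (seg_end - seg_start) / 1e6))
  map_fun <- function(bp) {
    i <- findInterval(bp, seg_start, rightmost.closed = TRUE)
    i[i < 1L] <- 1L; i[i > 3L] <- 3L
    cum_cm[i] + seg_rate[i] * (bp - seg_start[i]) / 1e6
  }

  w <- (seg_rate + marker_floor) * (seg_end - seg_start)
  n_seg <- stats::rmultinom(1L, n_markers, w / sum(w))[, 1]
  bp <- sort(unlist(lapply(1:3, function(i)
    stats::runif(n_seg[i], seg_start[i], seg_end[i]))))
  bp <- round(bp)
  cm <- map_fun(bp)
  if (noise_cm > 0) cm <- pmax(0, cm + stats::rnorm(length(bp), 0, noise_cm))

  ids <- sprintf("mk%04d", seq_along(bp))
  markers <- data.frame(marker_id = ids, linkage_group = linkage_group,
                        cm_female = round(cm, 3), cm_male = round(cm, 3))

  # hit table: one passing hit at the true position per marker; extra
  # exon hits start higher so the minimum-start rule recovers the truth
  n <- length(bp)
  good <- data.frame(qseqid = ids, sseqid = chrom,
                     pident = round(stats::runif(n, 97.5, 99.9), 2),
                     length = as.integer(round(stats::runif(n, 120, 500))),
                     sstart = bp + 1)
  extra_idx <- which(stats::runif(n) < prop_extra_exon)
  extra <- if (length(extra_idx)) data.frame(
    qseqid = ids[extra_idx], sseqid = chrom,
    pident = round(stats::runif(length(extra_idx), 97.5, 99.9), 2),
    length = as.integer(round(stats::runif(length(extra_idx), 120, 400))),
    sstart = bp[extra_idx] + 1 +
      as.integer(round(stats::runif(length(extra_idx), 500, 5000))))
  bad_i <- which(stats::runif(n) < prop_fail_identity)
  bad_ident <- if (length(bad_i)) data.frame(
    qseqid = ids[bad_i], sseqid = chrom,
    pident = round(stats::runif(length(bad_i), 80, 96.9), 2),
    length = as.integer(round(stats::runif(length(bad_i), 120, 400))),
    sstart = as.integer(round(stats::runif(length(bad_i), 1, chrom_length))))
  bad_l <- which(stats::runif(n) < prop_fail_length)
  bad_len <- if (length(bad_l)) data.frame(
    qseqid = ids[bad_l], sseqid = chrom,
    pident = round(stats::runif(length(bad_l), 97.5, 99.9), 2),
    length = as.integer(round(stats::runif(length(bad_l), 30, 99))),
    sstart = as.integer(round(stats::runif(length(bad_l), 1, chrom_length))))
  hits <- rbind(good, extra, bad_ident, bad_len)
  hits <- data.frame(
    qseqid = hits$qseqid, sseqid = hits$sseqid, pident = hits$pident,
    length = hits$length, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = hits$length,
    sstart = as.numeric(hits$sstart),
    send = as.numeric(hits$sstart) + hits$length - 1,
    evalue = 1e-50, bitscore = 200)
  hits <- hits[order(hits$qseqid, hits$sstart), ]
  rownames(hits) <- NULL

  list(markers = markers, hits = hits,
       truth = list(boundaries = c(b1, b2), chrom_length = chrom_length,
                    rate_distal = rate_distal, rate_center = rate_center,
                    total_cm = cum_cm[4],
                    marker_bp = stats::setNames(bp, ids)),
       map_function = map_fun)
}

#' Simulate negative-binomial allele-specific expression counts
#'
#' Per gene, draws a lognormally varying baseline per-copy mean and
#' negative-binomial counts per sample and allele copy.  Females draw two
#' X copies (summed into `counts_x`); males draw one X copy and, for
#' sex-linked genes, one Y copy whose mean is `y_degeneration` times the X
#' copy mean for the gene's region.  Autosomal genes behave like fully
#' expressed two-copy genes in both sexes.  All samples are given the same
#' library size, emulating equal-depth libraries.
#'
#' @param genes data.frame with columns `gene_id` and `region` (labels
#'   among `PAR`, `Xpr`, `qXdr`, `autosome`).
#' @param y_degeneration Named vector mapping region to the Y-copy
#'   expression fraction (0..1); regions absent from the map default to 1.
#' @param n_males,n_females Samples per sex.
#' @param mean_count Baseline per-copy negative-binomial mean.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   must be > 0.
#' @param gene_sd Lognormal sd of per-gene baseline means.
#' @param library_size Common library size recorded for every sample.
#' @return list with `records` (gene_id, sample_id, sex, counts_x,
#'   counts_y, library_size) and `truth` (per-gene per-copy means).
#' @export
simulateExpression <- function(genes,
                               y_degeneration = c(PAR = 1, Xpr = 0.6,
                                                  qXdr = 0.2, autosome = 1),
                               n_males = 25L, n_females = 25L,
                               mean_count = 100, dispersion = 0.1,
                               gene_sd = 0.5, library_size = 1e6) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  stopifnot(all(c("gene_id", "region") %in% names(genes)))
  delta <- unname(y_degeneration[genes$region])
  delta[is.na(delta)] <- 1
  if (any(delta < 0 | delta > 1)) stop("y_degeneration must lie in [0, 1]")
  size <- 1 / dispersion
  mu <- mean_count * stats::rlnorm(nrow(genes), -gene_sd^2 / 2, gene_sd)
  males <- if (n_males) sprintf("male%02d", seq_len(n_males)) else character()
  females <- if (n_females) sprintf("female%02d", seq_len(n_females)) else character()
  ng <- nrow(genes)
  rec <- list()
  has_y <- genes$region != "autosome"
  for (s in males) {
    cx <- stats::rnbinom(ng, mu = mu, size = size) +
      ifelse(has_y, 0L, stats::rnbinom(ng, mu = mu, size = size))
    cy <- ifelse(has_y, stats::rnbinom(ng, mu = delta * mu, size = size), 0L)
    rec[[s]] <- data.frame(gene_id = genes$gene_id, sample_id = s,
                           sex = "M", counts_x = cx, counts_y = cy,
                           library_size = library_size)
  }
  for (s in females) {
    cx <- stats::rnbinom(ng, mu = mu, size = size) +
      stats::rnbinom(ng, mu = mu, size = size)
    rec[[s]] <- data.frame(gene_id = genes$gene_id, sample_id = s,
                           sex = "F", counts_x = cx, counts_y = 0L,
                           library_size = library_size)
  }
  list(records = do.call(rbind, c(rec, list(make.row.names = FALSE))),
       truth = data.frame(gene_id = genes$gene_id, region = genes$region,
                          mu_per_copy = mu, y_degeneration = delta))
}

#' Place features uniformly at prescribed per-region densities
#'
#' @param intervals data.frame with `start`, `end` (bp, 0-based half-open)
#'   and `density` (features per Mb) columns.
#' @return Sorted numeric vector of feature start positions; each interval
#'   receives `round(density * length/1e6)` features placed uniformly.
#' @export
simulateFeaturePositions <- function(intervals) {
  stopifnot(all(c("start", "end", "density") %in% names(intervals)))
  pos <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    n <- round(intervals$density[i] *
                 (intervals$end[i] - intervals$start[i]) / 1e6)
    if (n < 1) return(numeric())
    stats::runif(n, intervals$start[i], intervals$end[i])
  }))
  sort(round(pos))
}
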