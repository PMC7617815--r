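#' Anchor genetic-map markers to genomic coordinates
#'
#' Filters alignment hits to those with identity strictly greater than
#' `min_identity` and alignment length strictly greater than `min_length`,
#' then resolves one genomic position per marker: among passing hits the
#' modal chromosome is chosen (most passing hits, ties broken by summed
#' alignment length), and the marker is placed at the minimum start
#' coordinate of its passing hits there.  A transcript marker typically
#' produces one hit per exon, so the lowest hit position marks the gene
#' start.  Markers with no passing hit are omitted.
#'
#' @param hits data.frame of alignment hits with at least `qseqid`,
#'   `sseqid`, `pident`, `length`, `sstart`, `send` (1-based inclusive,
#'   as in 12-column tabular output; see [readBlastHits()]).
#' @param min_identity Identity threshold in percent (strict >).
#' @param min_length Alignment length threshold in bp (strict >).
#' @param chrom_lengths Optional named vector of chromosome lengths; hits
#'   on unknown chromosomes are skipped with a warning.
#' @return data.frame with columns `marker_id`, `chrom`, `position`
#'   (0-based bp) and `n_hits_used`, one row per anchored marker, sorted
#'   by marker_id.  Idempotent and independent of hit input order.
#' @examples
#' hits <- data.frame(qseqid = "M1", sseqid = "chr1",
#'                    pident = c(98.2, 99.0), length = c(150, 120),
#'                    sstart = c(1000001, 1003501), send = c(1000150, 1003620))
#' anchorMarkers(hits)
#' @export
anchorMarkers <- function(hits, min_identity = 97, min_length = 100,
                          chrom_lengths = NULL) {
  if (min_identity < 0 || min_length < 0) stop("thresholds must be >= 0")
  empty <- data.frame(marker_id = character(), chrom = character(),
                      position = numeric(), n_hits_used = integer())
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  h <- data.table::as.data.table(hits)
  if (!is.null(chrom_lengths)) {
    unknown <- !h$sseqid %in% names(chrom_lengths)
    if (any(unknown)) {
      warning(sum(unknown), " hits reference unknown chromosomes; skipped")
      h <- h[!unknown]
    }
  }
  h <- h[pident > min_identity & length > min_length]
  if (nrow(h) == 0L) return(empty)
  # modal chromosome per marker: hit count, then summed alignment length
  by_chrom <- h[, list(n = .N, tot_len = sum(length)),
                by = list(qseqid, sseqid)]
  data.table::setorder(by_chrom, qseqid, -n, -tot_len, sseqid)
  modal <- by_chrom[, .SD[1L], by = qseqid]
  h <- h[modal[, c("qseqid", "sseqid")], on = c("qseqid", "sseqid")]
  anchors <- h[, list(chrom = sseqid[1L],
                      position = min(pmin(sstart, send)) - 1,  # to 0-based
                      n_hits_used = .N),
               by = qseqid]
  data.table::setnames(anchors, "qseqid", "marker_id")
  data.table::setorder(anchors, marker_id)
  if (!is.null(chrom_lengths)) {
    bad <- anchors$position >= chrom_lengths[anchors$chrom]
    if (any(bad)) {
      warning(sum(bad), " anchors beyond chromosome bounds; dropped")
      anchors <- anchors[!bad]
    }
  }
  as.data.frame(anchors)
}
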