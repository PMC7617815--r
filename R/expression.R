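#' Counts-per-million normalisation of allele-resolved expression records
#'
#' @param records data.frame with `counts_x`, `counts_y` and
#'   `library_size` columns.
#' @return The records with `cpm_x`, `cpm_y` and `cpm_total` columns
#'   appended (`counts * 1e6 / library_size`).
#' @export
normalizeCpm <- function(records) {
  if (any(records$library_size <= 0)) stop("library_size must be > 0")
  records$cpm_x <- records$counts_x * 1e6 / records$library_size
  records$cpm_y <- records$counts_y * 1e6 / records$library_size
  records$cpm_total <- records$cpm_x + records$cpm_y
  records
}

#' Per-gene expression-bias summary
#'
#' Summarises total (X+Y in males, X+X in females) expression per gene:
#' female and male mean CPM, the female:male log2 ratio, and the mean Y
#' fraction of male expression.
#'
#' @param records Allele-resolved expression records (see
#'   [simulateExpression()]): `gene_id`, `sample_id`, `sex`, `counts_x`,
#'   `counts_y`, `library_size`.
#' @param regions Optional gene -> region map (named vector or data.frame
#'   with `gene_id`, `region`).
#' @return data.frame with one row per gene: `gene_id`, `region`,
#'   `mean_female_cpm`, `mean_male_cpm`, `log2_bias` (NA unless both
#'   means are positive) and `xy_ratio_male`.
#' @export
biasSummary <- function(records, regions = NULL) {
  rec <- data.table::as.data.table(normalizeCpm(records))
  out <- rec[, {
    f <- cpm_total[sex == "F"]
    m <- cpm_total[sex == "M"]
    ymean <- counts_y[sex == "M"]
    tmean <- counts_x[sex == "M"] + counts_y[sex == "M"]
    list(mean_female_cpm = mean(f), mean_male_cpm = mean(m),
         log2_bias = if (length(f) && length(m) &&
                         mean(f) > 0 && mean(m) > 0)
           log2(mean(f) / mean(m)) else NA_real_,
         xy_ratio_male = if (sum(tmean) > 0) sum(ymean) / sum(tmean)
           else NA_real_)
  }, by = gene_id]
  out <- as.data.frame(out)
  if (!is.null(regions)) {
    reg <- if (is.data.frame(regions)) {
      stats::setNames(regions$region, regions$gene_id)
    } else regions
    out$region <- unname(reg[out$gene_id])
    out <- out[, c("gene_id", "region", "mean_female_cpm", "mean_male_cpm",
                   "log2_bias", "xy_ratio_male")]
  }
  out
}

#' Paired test of X against Y expression within males
#'
#' Two-sided paired t-test of per-gene mean male X-copy CPM against mean
#' male Y-copy CPM.  Genes without male data are dropped; an all-zero
#' difference vector is reported as t = 0, p = 1.
#'
#' @param records Allele-resolved expression records.
#' @return list with `t`, `df`, `p`, `n`, `mean_x_cpm`, `mean_y_cpm`.
#' @export
xyExpressionTest <- function(records) {
  rec <- data.table::as.data.table(normalizeCpm(records))
  per_gene <- rec[sex == "M",
                  list(x = mean(cpm_x), y = mean(cpm_y)), by = gene_id]
  n <- nrow(per_gene)
  if (n < 3L) stop("paired X/Y expression test requires >= 3 genes")
  d <- per_gene$x - per_gene$y
  if (stats::sd(d) == 0)
    return(list(t = 0, df = n - 1L, p = 1, n = n,
                mean_x_cpm = mean(per_gene$x), mean_y_cpm = mean(per_gene$y)))
  tt <- stats::t.test(per_gene$x, per_gene$y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n = n, mean_x_cpm = mean(per_gene$x), mean_y_cpm = mean(per_gene$y))
}

#' Pairwise region comparisons of female:male expression bias
#'
#' Welch two-sample t-tests of per-gene log2(female/male) bias between
#' every pair of regions; pairs where either region has fewer than 3
#' genes with defined bias are skipped with a warning.
#'
#' @param bias Per-gene summaries from [biasSummary()] with a `region`
#'   column.
#' @param regions Regions to compare (default: all present).
#' @return data.frame with `region_a`, `region_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
regionBiasCompare <- function(bias, regions = NULL) {
  b <- bias[!is.na(bias$log2_bias) & !is.na(bias$region), ]
  if (is.null(regions)) regions <- sort(unique(b$region))
  if (length(regions) < 2L) stop("need at least two regions")
  pairs <- utils::combn(regions, 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    ra <- pairs[1, k]; rb <- pairs[2, k]
    xa <- b$log2_bias[b$region == ra]
    xb <- b$log2_bias[b$region == rb]
    if (length(xa) < 3L || length(xb) < 3L) {
      warning("skipping ", ra, " vs ", rb, ": fewer than 3 genes")
      next
    }
    tt <- stats::t.test(xa, xb)  # Welch
    rows[[k]] <- data.frame(region_a = ra, region_b = rb,
                            n_a = length(xa), n_b = length(xb),
                            mean_a = mean(xa), mean_b = mean(xb),
                            t = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value)
  }
  do.call(rbind, rows)
}
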