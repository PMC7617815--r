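#' Additive three-taxon branch decomposition of pairwise distances
#'
#' Given pairwise distances among X, Y and an outgroup on the fixed
#' topology ((X,Y),OG), recovers per-branch lengths by the additive
#' (three-point) formulas
#' \deqn{b_X = (d_{XY} + d_{X,OG} - d_{Y,OG})/2}
#' \deqn{b_Y = (d_{XY} + d_{Y,OG} - d_{X,OG})/2}
#' \deqn{b_{OG} = (d_{X,OG} + d_{Y,OG} - d_{XY})/2}
#' with negative estimates clamped to zero.  Applied separately to the
#' synonymous and nonsynonymous distance classes this yields per-branch
#' dS and dN, and per-branch omega = dN/dS where dS > 0.
#'
#' @param d_xy,d_x_og,d_y_og Pairwise distances for one class (numeric).
#' @return Named numeric vector `c(branch_X, branch_Y, branch_OG)`, or all
#'   NA when any input is NA.
#' @export
branchDecompose <- function(d_xy, d_x_og, d_y_og) {
  if (anyNA(c(d_xy, d_x_og, d_y_og)))
    return(c(branch_X = NA_real_, branch_Y = NA_real_, branch_OG = NA_real_))
  b <- c(branch_X = (d_xy + d_x_og - d_y_og) / 2,
         branch_Y = (d_xy + d_y_og - d_x_og) / 2,
         branch_OG = (d_x_og + d_y_og - d_xy) / 2)
  pmax(b, 0)
}

#' Per-gene branch dS, dN and omega from pairwise triplet estimates
#'
#' @param estimates data.frame as returned by [tripletDivergence()],
#'   possibly concatenated over genes (long format, one row per gene x
#'   pair).
#' @return data.frame with one row per gene x branch (`branch_X`,
#'   `branch_Y`, `branch_OG`) and columns `dS`, `dN`, `omega`.
#' @export
branchEstimates <- function(estimates) {
  est <- data.table::as.data.table(estimates)
  wide <- data.table::dcast(est, gene_id ~ pair, value.var = c("dS", "dN"))
  out <- wide[, {
    bs <- branchDecompose(dS_XY, dS_X_OG, dS_Y_OG)
    bn <- branchDecompose(dN_XY, dN_X_OG, dN_Y_OG)
    list(branch = names(bs), dS = unname(bs), dN = unname(bn),
         omega = ifelse(!is.na(bs) & bs > 0, bn / bs, NA_real_))
  }, by = gene_id]
  as.data.frame(out)
}

#' Region-wise summary of divergence statistics
#'
#' Averages per-gene statistics within regions, reporting the mean,
#' standard error (sd/sqrt(n)) and the number of genes contributing to each
#' statistic (NA estimates are dropped per statistic).
#'
#' @param stats data.frame with a `gene_id` column and numeric statistic
#'   columns.
#' @param regions Named character vector or data.frame (`gene_id`,
#'   `region`) assigning genes to regions.
#' @param columns Statistic columns to summarise (default: all numeric).
#' @return data.frame with one row per region x statistic: `region`,
#'   `statistic`, `n`, `mean`, `se`.  Regions with no genes are omitted
#'   with a warning; `se` is NA for single-gene summaries.
#' @export
aggregateRegion <- function(stats, regions, columns = NULL) {
  st <- data.table::as.data.table(stats)
  if (is.data.frame(regions)) {
    reg <- data.table::as.data.table(regions)[, c("gene_id", "region")]
  } else {
    reg <- data.table::data.table(gene_id = names(regions),
                                  region = unname(regions))
  }
  st <- merge(st, reg, by = "gene_id")
  if (nrow(st) == 0L) {
    warning("no genes with region labels; empty summary")
    return(data.frame(region = character(), statistic = character(),
                      n = integer(), mean = numeric(), se = numeric()))
  }
  if (is.null(columns))
    columns <- setdiff(names(st)[vapply(st, is.numeric, TRUE)], "gene_id")
  long <- data.table::melt(st, id.vars = c("gene_id", "region"),
                           measure.vars = columns,
                           variable.name = "statistic", value.name = "value")
  out <- long[!is.na(value),
              list(n = .N, mean = mean(value),
                   se = if (.N > 1L) stats::sd(value) / sqrt(.N) else NA_real_),
              by = list(region, statistic)]
  as.data.frame(out[order(region, statistic)])
}

#' Paired test for elevated Y-branch omega
#'
#' Two-sided paired t-test of per-gene omega on the Y branch against omega
#' on the X branch; genes missing either value are dropped.  Degenerate
#' all-zero differences are reported as t = 0, p = 1.
#'
#' @param omega_x,omega_y Numeric vectors of per-gene omega estimates.
#' @return list with `t`, `df`, `p`, `n`, `mean_diff`.
#' @export
pairedOmegaTest <- function(omega_x, omega_y) {
  keep <- !is.na(omega_x) & !is.na(omega_y)
  x <- omega_x[keep]; y <- omega_y[keep]
  n <- length(x)
  if (n < 3L) stop("paired omega test requires at least 3 genes")
  d <- y - x
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = n - 1L, p = 1, n = n, mean_diff = mean(d)))
  }
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n, mean_diff = unname(tt$estimate))
}
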