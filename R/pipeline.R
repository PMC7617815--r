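#' Default pipeline configuration
#'
#' Returns the configuration for a full desk-scale run: two sex-linked
#' region classes of gametolog genes with region-specific divergence and
#' Y-expression parameters, a two-generation cross, an X-like chromosome
#' map geometry and expression sampling.  Values can be overridden by
#' supplying a (possibly nested) list, or loaded from YAML with
#' [readPipelineConfig()].
#'
#' @param overrides Named list merged over the defaults (nested lists are
#'   merged recursively).
#' @return Configuration list.
#' @export
defaultPipelineConfig <- function(overrides = list()) {
  cfg <- list(
    regions = list(
      Xpr = list(n_genes = 30L, dS_XY = 0.063, dS_X_OG = 0.120,
                 omega_X = 0.315, omega_Y = 0.591, y_expression = 0.6),
      qXdr = list(n_genes = 30L, dS_XY = 0.091, dS_X_OG = 0.123,
                  omega_X = 0.267, omega_Y = 0.408, y_expression = 0.2)),
    n_codons = 200L,
    cross = list(n_sons_genomic = 5L, n_daughters_genomic = 5L,
                 n_sons_rna = 0L, n_daughters_rna = 0L,
                 coverage_genomic = 20, coverage_rna = 20,
                 read_length = 150L, insert_size = 400L,
                 error_rate = 0.002, maternal_het_rate = 0.002),
    map = list(chrom_length = 370597487, distal_p_length = 25.6e6,
               distal_q_length = 15e6, rate_distal = 2, rate_center = 0,
               n_markers = 400L, noise_cm = 0.25),
    marey = list(window = 10e6, step = 2e6, threshold = 0.25,
                 min_run = 3L),
    expression = list(n_males = 25L, n_females = 25L, mean_count = 100,
                      dispersion = 0.1),
    scan = list(window = 1e6, step = 0.2e6, gene_density_distal = 17.8,
                gene_density_peri = 6.6))
  .mergeConfig(cfg, overrides)
}

.mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with (a subset of) the fields of
#'   [defaultPipelineConfig()].
#' @return Configuration list (defaults filled in).
#' @export
readPipelineConfig <- function(path) {
  defaultPipelineConfig(yaml::read_yaml(path))
}

#' Run the full simulation-and-recovery pipeline
#'
#' Executes every stage on synthetic data: gametolog-triplet simulation,
#' cross simulation, Y-SNP classification, read partitioning, Y-consensus
#' reconstruction, divergence estimation with branch decomposition,
#' genetic-map simulation, Marey-map building, windowed recombination
#' rates, region segmentation, expression simulation and bias tests, and
#' windowed gene-density scans.  Tabular results are written to `outdir`
#' together with a run manifest (config, seed, package version and md5
#' checksum per output), and a summary juxtaposing recovered statistics
#' with the simulation truth.
#'
#' @param config Configuration list from [defaultPipelineConfig()].
#' @param outdir Output directory.
#' @param seed Integer seed governing all randomness.
#' @return Invisibly, a list with the in-memory stage results
#'   (`divergence`, `segmentation`, `profile`, `expression`, `scan`,
#'   `validation`, `manifest`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir,
                        seed = 1L) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  set.seed(seed)
  log_msg <- function(stage, ...) message("[", stage, "] ", ...)

  # --- gametolog triplets per region ---------------------------------
  log_msg("simulate", "gametolog triplets")
  trips <- lapply(names(config$regions), function(r) {
    p <- config$regions[[r]]
    simulateGametologTriplets(p$n_genes, config$n_codons, p$dS_XY,
                              p$dS_X_OG, p$omega_X, p$omega_Y, region = r)
  })
  names(trips) <- names(config$regions)
  comb <- list(x = do.call(c, unname(lapply(trips, `[[`, "x"))),
               y = do.call(c, unname(lapply(trips, `[[`, "y"))),
               og = do.call(c, unname(lapply(trips, `[[`, "og"))),
               truth = do.call(rbind, c(unname(lapply(trips, `[[`, "truth")),
                                        list(make.row.names = FALSE))))
  gene_region <- stats::setNames(
    comb$truth$region[!duplicated(comb$truth$gene_id)],
    unique(comb$truth$gene_id))

  # --- cross, classification, consensus ------------------------------
  log_msg("simulate", "cross")
  y_expr <- stats::setNames(
    vapply(gene_region, function(r) config$regions[[r]]$y_expression, 0),
    names(gene_region))
  cross <- do.call(simulateCross,
                   c(list(triplets = comb, y_expression = y_expr),
                     config$cross))
  log_msg("ysnp", "classifying diagnostic sites")
  sites <- classifySites(cross$observations, cross$pedigree)
  log_msg("partition", "partitioning read pairs")
  males <- cross$pedigree$sample_id[cross$pedigree$sex == "M"]
  assign <- partitionReads(cross$overlaps, sites, reads = cross$reads,
                           sample_ids = males)
  log_msg("consensus", "building Y consensus sequences")
  consensuses <- lapply(names(cross$haplotypes), function(g)
    buildConsensus(cross$reads, cross$read_errors, cross$haplotypes,
                   assign, g))
  names(consensuses) <- names(cross$haplotypes)
  y_true <- stats::setNames(
    vapply(cross$haplotypes, `[[`, "", "y"), names(cross$haplotypes))
  validation <- validateAgainstTruth(sites, cross$truth_sites,
                                     consensuses, y_true)

  # --- divergence ----------------------------------------------------
  log_msg("divergence", "NG86 and branch decomposition")
  est <- do.call(rbind, lapply(names(consensuses), function(g)
    tripletDivergence(as.character(comb$x[[g]]),
                      consensuses[[g]]$sequence,
                      as.character(comb$og[[g]]), gene_id = g)))
  branches <- branchEstimates(est)
  ds_xy <- est[est$pair == "XY", c("gene_id", "dS")]
  ds_xog <- est[est$pair == "X_OG", c("gene_id", "dS")]
  om_x <- branches[branches$branch == "branch_X", c("gene_id", "omega")]
  om_y <- branches[branches$branch == "branch_Y", c("gene_id", "omega")]
  per_gene <- Reduce(function(a, b) merge(a, b, by = "gene_id"), list(
    stats::setNames(ds_xy, c("gene_id", "dS_XY")),
    stats::setNames(ds_xog, c("gene_id", "dS_X_OG")),
    stats::setNames(om_x, c("gene_id", "omega_X")),
    stats::setNames(om_y, c("gene_id", "omega_Y"))))
  region_summary <- aggregateRegion(per_gene, gene_region)
  omega_test <- tryCatch(
    pairedOmegaTest(per_gene$omega_X, per_gene$omega_Y),
    error = function(e) NULL)

  # --- genetic map, Marey, segmentation ------------------------------
  log_msg("map", "genetic map, Marey fit and segmentation")
  gm <- do.call(simulateGeneticMap, config$map)
  anchors <- anchorMarkers(gm$hits)
  marey <- buildMareyMap(anchors, gm$markers, sex = "female")
  profile <- recombinationRate(marey, config$marey$window,
                               config$marey$step,
                               chrom_length = config$map$chrom_length)
  seg <- segmentRegions(profile, config$marey$threshold,
                        config$marey$min_run,
                        chrom_length = config$map$chrom_length,
                        marey = marey)

  # --- expression ----------------------------------------------------
  log_msg("expression", "allele-specific expression")
  genes_df <- data.frame(gene_id = names(gene_region),
                         region = unname(gene_region))
  y_deg <- vapply(config$regions, function(p) p$y_expression, 0)
  expr <- do.call(simulateExpression,
                  c(list(genes = genes_df, y_degeneration = y_deg),
                    config$expression))
  bias <- biasSummary(expr$records, gene_region)
  xy_test <- xyExpressionTest(expr$records)
  bias_cmp <- tryCatch(regionBiasCompare(bias), error = function(e) NULL,
                       warning = function(w) NULL)

  # --- genome scan ---------------------------------------------------
  log_msg("scan", "gene-density windows")
  iv <- segmentIntervals(seg)
  dens <- ifelse(iv$label == "pericentromeric",
                 config$scan$gene_density_peri,
                 config$scan$gene_density_distal)
  gene_pos <- simulateFeaturePositions(
    data.frame(start = iv$start, end = iv$end, density = dens))
  track <- densityWindows(gene_pos, config$map$chrom_length,
                          config$scan$window, config$scan$step,
                          mode = "count_per_mb", chrom = seg@chrom)

  # --- outputs + manifest --------------------------------------------
  wt <- function(d, f) {
    utils::write.table(d, file.path(outdir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    wt(cross$pedigree, "pedigree.tsv"),
    wt(sites, "diagnostic_sites.tsv"),
    wt(assign, "read_assignment.tsv"),
    wt(est, "divergence_estimates.tsv"),
    wt(branches, "branch_estimates.tsv"),
    wt(region_summary, "region_summary.tsv"),
    wt(anchors, "anchors.tsv"),
    wt(mareyPoints(marey), "marey_points.tsv"),
    wt(profileWindows(profile), "recombination_profile.tsv"),
    wt(segmentIntervals(seg), "segmentation.tsv"),
    wt(bias, "expression_bias.tsv"),
    if (!is.null(bias_cmp)) wt(bias_cmp, "region_bias_tests.tsv"),
    wt(track, "gene_density_track.tsv"))
  cons_fa <- file.path(outdir, "y_consensus.fasta")
  writeLines(unlist(lapply(consensuses, function(cc)
    c(paste0(">", cc$gene_id), cc$sequence))), cons_fa)
  files <- c(files, "y_consensus.fasta")

  recovered <- list(
    mean_dS_XY_by_region = as.list(stats::setNames(
      region_summary$mean[region_summary$statistic == "dS_XY"],
      region_summary$region[region_summary$statistic == "dS_XY"])),
    pericentromeric_mb = with(segmentIntervals(seg),
                              sum(end[label == "pericentromeric"] -
                                    start[label == "pericentromeric"]) / 1e6),
    distal_rate = regionRateMean(profile, seg),
    site_precision = validation$site_precision,
    site_recall = validation$site_recall,
    xy_expression_p = xy_test$p,
    omega_y_gt_x_p = if (!is.null(omega_test)) omega_test$p else NA)
  truth <- list(
    dS_XY_target = vapply(config$regions, `[[`, 0, "dS_XY"),
    boundaries_bp = c(config$map$distal_p_length,
                      config$map$chrom_length - config$map$distal_q_length),
    rate_distal = config$map$rate_distal)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sexchromr")),
    seed = seed, config = config,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(recovered = recovered, truth = truth),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(divergence = est, branches = branches,
                 region_summary = region_summary, segmentation = seg,
                 profile = profile, expression = bias, scan = track,
                 validation = validation, manifest = manifest))
}
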