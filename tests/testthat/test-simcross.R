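# Forward simulators: gametolog triplets, sequenced cross, genetic map,
# expression counts.

test_that("zero-divergence branch target leaves sequences identical", {
  set.seed(1)
  trip <- simulateGametologTriplets(3, 20, dS_XY = 0, dS_X_OG = 0.1,
                                    omega_X = 0.3, omega_Y = 0.3)
  expect_identical(as.character(trip$x), as.character(trip$y))
  expect_equal(trip$truth$dS_realized[trip$truth$branch %in% c("X", "Y")],
               rep(0, 6))
})

test_that("omega 0 on the Y branch changes only synonymous sites", {
  set.seed(2)
  trip <- simulateGametologTriplets(5, 50, dS_XY = 0.1, dS_X_OG = 0.1,
                                    omega_X = 0.3, omega_Y = 0)
  pep <- function(s) as.character(Biostrings::translate(s))
  expect_identical(pep(trip$y), pep(trip$anc))
  expect_equal(sum(trip$truth$nonsyn_events[trip$truth$branch == "Y"]), 0)
})

test_that("no emitted coding sequence contains an internal stop codon", {
  set.seed(3)
  trip <- simulateGametologTriplets(10, 40, dS_XY = 0.15, dS_X_OG = 0.25,
                                    omega_X = 0.8, omega_Y = 0.8)
  for (dss in trip[c("x", "y", "og", "anc")]) {
    aa <- as.character(Biostrings::translate(dss))
    expect_false(any(grepl("\\*", aa)))
  }
})

test_that("realized synonymous divergence matches the event-log oracle and the target", {
  set.seed(4)
  trip <- simulateGametologTriplets(100, 500, dS_XY = 0.063,
                                    dS_X_OG = 0.12,
                                    omega_X = 0.3, omega_Y = 0.3)
  tr <- trip$truth
  # oracle: realized events per synonymous site, straight from the
  # simulator's event log
  per_gene_xy <- tapply(tr$syn_events / tr$S_sites,
                        list(tr$gene_id, tr$branch), identity)
  realized <- mean(per_gene_xy[, "X"] + per_gene_xy[, "Y"])
  expect_lt(abs(realized - 0.063), 0.007)
  expect_equal(tr$dS_realized, tr$syn_events / tr$S_sites)
})

test_that("realized mean dS converges to target within 5% at 500 genes", {
  set.seed(5)
  trip <- simulateGametologTriplets(500, 100, dS_XY = 0.08,
                                    dS_X_OG = 0.16,
                                    omega_X = 0.4, omega_Y = 0.4)
  tr <- trip$truth
  xy <- tapply(tr$dS_realized, list(tr$gene_id, tr$branch), identity)
  realized <- mean(xy[, "X"] + xy[, "Y"])
  expect_lt(abs(realized - 0.08) / 0.08, 0.05)
})

test_that("invalid triplet configurations are rejected", {
  expect_error(simulateGametologTriplets(2, 5, 0.1, 0.2, 0.3, 0.3),
               "codons")
  expect_error(simulateGametologTriplets(2, 20, 0.1, 0.2, -1, 0.3),
               "finite")
  expect_error(simulateGametologTriplets(2, 20, 0.2, 0.05, 0.3, 0.3),
               "dS_X_OG")
})

test_that("the same seed reproduces the cross byte for byte", {
  c1 <- smallCross(seed = 7)
  c2 <- smallCross(seed = 7)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$observations, c2$observations)
  expect_identical(c1$read_errors, c2$read_errors)
  d1 <- tempfile(); d2 <- tempfile()
  writeCrossFastq(c1, d1, samples = "father")
  writeCrossFastq(c2, d2, samples = "father")
  f1 <- file.path(d1, "father_R1.fastq"); f2 <- file.path(d2, "father_R1.fastq")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("true Y-SNPs never appear in the mother or daughters", {
  cross <- smallCross(seed = 8, n_genes = 6, error_rate = 0)
  obs <- merge(cross$observations, cross$pedigree[, c("sample_id", "sex", "role")])
  for (i in seq_len(nrow(cross$truth_sites))) {
    ts <- cross$truth_sites[i, ]
    o <- obs[obs$gene_id == ts$gene_id & obs$pos == ts$pos &
               (obs$sex == "F"), ]
    expect_equal(sum(o[[ts$y_allele]]), 0, info = paste(ts$gene_id, ts$pos))
  }
})

test_that("every offspring allele at every site is present in a parent", {
  cross <- smallCross(seed = 9, n_genes = 5, error_rate = 0)
  obs <- merge(cross$observations, cross$pedigree[, c("sample_id", "role")])
  bases <- c("A", "C", "G", "T")
  parent <- obs[obs$role != "offspring", ]
  child <- obs[obs$role == "offspring", ]
  key <- function(d) paste(d$gene_id, d$pos)
  for (k in unique(key(child))) {
    ch <- child[key(child) == k, ]
    pa <- parent[key(parent) == k, ]
    child_alleles <- bases[colSums(ch[, bases, drop = FALSE]) > 0]
    parent_alleles <- bases[colSums(pa[, bases, drop = FALSE]) > 0]
    expect_true(all(child_alleles %in% parent_alleles), info = k)
  }
})

test_that("mean per-site depth matches the Lander-Waterman expectation", {
  # oracle: expected depth = coverage, computed on the simulator's own
  # read table; gene 1500 bp at 20x
  set.seed(10)
  trip <- simulateGametologTriplets(2, 500, dS_XY = 0.06, dS_X_OG = 0.12,
                                    omega_X = 0.3, omega_Y = 0.3)
  cross <- simulateCross(trip, n_sons_rna = 0, n_daughters_rna = 0,
                         coverage_genomic = 20, read_length = 150)
  rd <- cross$reads[cross$reads$sample_id == "father", ]
  mean_depth <- sum(rd$end - rd$start + 1) / (2 * 1500)
  expect_lt(abs(mean_depth - 20) / 20, 0.15)
})

test_that("RNA progeny Y-allele depth scales with Y expression", {
  set.seed(11)
  trip <- simulateGametologTriplets(4, 100, dS_XY = 0.08, dS_X_OG = 0.12,
                                    omega_X = 0.3, omega_Y = 0.3)
  cross <- simulateCross(trip, n_sons_genomic = 2, n_daughters_genomic = 2,
                         n_sons_rna = 10, n_daughters_rna = 2,
                         y_expression = 0, error_rate = 0)
  rd <- cross$reads
  ped <- cross$pedigree
  rna_sons <- ped$sample_id[ped$datatype == "rna" & ped$sex == "M"]
  expect_equal(sum(rd$hap == "y" & rd$sample_id %in% rna_sons), 0)
  gen_sons <- ped$sample_id[ped$datatype == "genomic" & ped$sex == "M" &
                              ped$role == "offspring"]
  expect_gt(sum(rd$hap == "y" & rd$sample_id %in% gen_sons), 0)
})

test_that("a cross without progeny of one sex is rejected", {
  set.seed(1)
  trip <- simulateGametologTriplets(2, 20, 0.06, 0.12, 0.3, 0.3)
  expect_error(simulateCross(trip, n_sons_genomic = 0, n_sons_rna = 0),
               "son")
})

test_that("simulated map cM is the integral of the rate function", {
  set.seed(1)
  # closed form: 2 * 25.6 + 0 + 2 * 15 = 81.2 cM
  gm <- simulateGeneticMap(370.6e6, 25.6e6, 15e6, 2, 0,
                           n_markers = 200, noise_cm = 0)
  expect_equal(gm$truth$total_cm, 81.2, tolerance = 1e-9)
  expect_equal(gm$map_function(0), 0)
  expect_equal(gm$map_function(370.6e6), 81.2, tolerance = 1e-9)
  # linear piece: two points 10 Mb apart in a 2 cM/Mb segment differ by 20
  expect_equal(gm$map_function(10e6) - gm$map_function(0), 20,
               tolerance = 1e-9)
  # zero-rate centre: one shared cM value before noise
  expect_equal(gm$map_function(100e6), gm$map_function(300e6))
})

test_that("noiseless marker cM equals the map function at the marker position", {
  set.seed(2)
  gm <- simulateGeneticMap(1e8, 1e7, 5e6, 2, 0, n_markers = 100,
                           noise_cm = 0)
  expect_equal(gm$markers$cm_female,
               unname(round(gm$map_function(gm$truth$marker_bp), 3)))
})

test_that("map simulation rejects too few markers", {
  expect_error(simulateGeneticMap(1e8, 1e7, 5e6, 2, 0, n_markers = 5),
               "n_markers")
})

test_that("expression simulation matches analytic female:male ratios", {
  set.seed(12)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:150),
                      region = rep(c("qXdr", "PAR", "autosome"), each = 50))
  ex <- simulateExpression(genes, y_degeneration = c(qXdr = 0.5, PAR = 1,
                                                     autosome = 1),
                           n_males = 50, n_females = 50)
  b <- biasSummary(ex$records, stats::setNames(genes$region, genes$gene_id))
  # delta = 0.5: expected log2(female/male) = log2(2/1.5)
  expect_lt(abs(mean(b$log2_bias[b$region == "qXdr"]) - log2(2 / 1.5)), 0.1)
  # delta = 1: symmetric means, bias converges to 0
  expect_lt(abs(mean(b$log2_bias[b$region == "PAR"])), 0.1)
  expect_lt(abs(mean(b$log2_bias[b$region == "autosome"])), 0.1)
})

test_that("expression counts are negative binomial with the requested dispersion", {
  set.seed(13)
  genes <- data.frame(gene_id = "g1", region = "autosome")
  # small dispersion: variance approaches the Poisson limit (= mean)
  ex <- simulateExpression(genes, n_males = 4000, n_females = 0,
                           dispersion = 1e-4, gene_sd = 0)
  cx <- ex$records$counts_x  # two copies of mean 100
  expect_lt(abs(mean(cx) - 200) / 200, 0.05)
  expect_lt(var(cx) / mean(cx), 1.3)
  expect_error(simulateExpression(genes, dispersion = 0), "dispersion")
})

test_that("feature placement honours per-interval densities", {
  set.seed(14)
  pos <- simulateFeaturePositions(data.frame(
    start = c(0, 1e7), end = c(1e7, 3e7), density = c(10, 2)))
  expect_equal(sum(pos < 1e7), 100)
  expect_equal(sum(pos >= 1e7), 40)
})

test_that("simulated VCF round-trips through a standard VCF reader", {
  skip_if_not_installed("vcfR")
  cross <- smallCross(seed = 15, n_genes = 2)
  f <- tempfile(fileext = ".vcf")
  writeCrossVcf(cross, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(nrow(v@fix), nrow(cross$variants))
  gt <- vcfR::extract.gt(v, "GT")
  expect_equal(ncol(gt), nrow(cross$pedigree))
  # fathers are het at true Y-SNP rows
  ts <- cross$truth_sites[1, ]
  row_id <- which(v@fix[, "CHROM"] == ts$gene_id &
                    as.integer(v@fix[, "POS"]) == ts$pos)
  expect_equal(unname(gt[row_id, "father"]), "0/1")
})
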