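# Y-diagnostic SNP classification, read partitioning and consensus
# building.

test_that("the canonical father-to-sons-never-to-daughters site is called Y-linked", {
  obs <- siteObs(list(father = c(A = 11, G = 9), mother = c(A = 20),
                      son1 = c(A = 6, G = 5), son2 = c(A = 5, G = 6),
                      dau1 = c(A = 12), dau2 = c(A = 10)))
  ped <- pedigreeOf(sons = 2, daughters = 2)
  s <- classifySites(obs, ped)
  expect_equal(s$status, "Y_linked")
  expect_equal(s$y_allele, "G")
  expect_equal(s$x_allele, "A")
  expect_equal(s$n_sons_support, 2L)
  expect_equal(s$n_daughters_checked, 2L)
})

test_that("a daughter carrying the candidate Y allele is a hard reject", {
  obs <- siteObs(list(father = c(A = 11, G = 9), mother = c(A = 20),
                      son1 = c(A = 6, G = 5), son2 = c(A = 5, G = 6),
                      dau1 = c(A = 8, G = 4), dau2 = c(A = 10)))
  s <- classifySites(obs, pedigreeOf(2, 2))
  expect_equal(s$status, "rejected")
  expect_equal(s$reject_reason, "daughter_carries_y")
})

test_that("a heterozygous mother makes the site untraceable", {
  obs <- siteObs(list(father = c(A = 11, G = 9), mother = c(A = 10, G = 10),
                      son1 = c(G = 10), son2 = c(G = 10),
                      dau1 = c(A = 10), dau2 = c(A = 10)))
  s <- classifySites(obs, pedigreeOf(2, 2))
  expect_equal(s$status, "rejected")
  expect_equal(s$reject_reason, "mother_heterozygous")
})

test_that("a genomic son without the Y allele rejects the site", {
  obs <- siteObs(list(father = c(A = 11, G = 9), mother = c(A = 20),
                      son1 = c(A = 6, G = 5), son2 = c(A = 11),
                      dau1 = c(A = 12), dau2 = c(A = 10)))
  s <- classifySites(obs, pedigreeOf(2, 2))
  expect_equal(s$status, "rejected")
  expect_equal(s$reject_reason, "genomic_son_lacks_y")
})

test_that("RNA sons tolerate bounded Y dropout, genomic sons none", {
  mk <- function(n_lack, datatype, tol = 0.2) {
    sons <- lapply(seq_len(5), function(i)
      if (i <= n_lack) c(A = 10) else c(A = 5, G = 5))
    names(sons) <- paste0("son", 1:5)
    obs <- siteObs(c(list(father = c(A = 11, G = 9), mother = c(A = 20),
                          dau1 = c(A = 10)), sons))
    ped <- rbind(pedigreeOf(0, 1),
                 data.frame(sample_id = paste0("son", 1:5), family = "fam1",
                            sex = "M", role = "offspring",
                            datatype = datatype))
    classifySites(obs, ped, rna_son_dropout_tolerance = tol)
  }
  expect_equal(mk(1, "rna")$status, "Y_linked")     # 4/5 carry, tol 0.2
  expect_equal(mk(2, "rna")$status, "rejected")     # 3/5 below 0.8
  expect_equal(mk(1, "genomic")$status, "rejected") # no tolerance
})

test_that("low-depth individuals are uninformative and gate the call", {
  # all daughters below min_depth: informative fraction 3/5 + sons only
  obs <- siteObs(list(father = c(A = 11, G = 9), mother = c(A = 20),
                      son1 = c(A = 6, G = 5), son2 = c(A = 5, G = 6),
                      son3 = c(A = 4, G = 5),
                      dau1 = c(A = 2), dau2 = c(A = 3)))
  s <- classifySites(obs, pedigreeOf(3, 2), min_informative_fraction = 0.8)
  expect_equal(s$status, "rejected")
  expect_equal(s$reject_reason, "insufficient_informative_progeny")
})

test_that("classification recovers simulated Y-SNPs with high precision and recall", {
  set.seed(31)
  trip <- simulateGametologTriplets(25, 300, dS_XY = 0.063,
                                    dS_X_OG = 0.12,
                                    omega_X = 0.3, omega_Y = 0.6)
  cross <- simulateCross(trip, n_sons_rna = 0, n_daughters_rna = 0)
  sites <- classifySites(cross$observations, cross$pedigree)
  v <- validateAgainstTruth(sites, cross$truth_sites)
  expect_gte(v$site_precision, 0.95)
  expect_gte(v$site_recall, 0.8)
})

test_that("an RNA-heavy design still recovers Y-SNPs under Y silencing", {
  set.seed(32)
  trip <- simulateGametologTriplets(10, 300, dS_XY = 0.09,
                                    dS_X_OG = 0.12,
                                    omega_X = 0.3, omega_Y = 0.4)
  cross <- simulateCross(trip, n_sons_genomic = 5, n_daughters_genomic = 5,
                         n_sons_rna = 25, n_daughters_rna = 25,
                         y_expression = 0.5)
  sites <- classifySites(cross$observations, cross$pedigree)
  v <- validateAgainstTruth(sites, cross$truth_sites)
  expect_gte(v$site_precision, 0.95)
  expect_gte(v$site_recall, 0.8)
})

test_that("raising min_depth never increases the number of Y-linked calls", {
  cross <- smallCross(seed = 33, n_genes = 8, n_codons = 120,
                      error_rate = 0)
  n_calls <- vapply(c(3L, 5L, 8L, 12L), function(md) {
    s <- classifySites(cross$observations, cross$pedigree, min_depth = md)
    sum(s$status == "Y_linked")
  }, 0L)
  expect_true(all(diff(n_calls) <= 0L))
})

test_that("read pairs partition exhaustively and exclusively", {
  cross <- smallCross(seed = 34, n_genes = 4)
  sites <- classifySites(cross$observations, cross$pedigree)
  males <- cross$pedigree$sample_id[cross$pedigree$sex == "M"]
  asn <- partitionReads(cross$overlaps, sites, reads = cross$reads,
                        sample_ids = males)
  male_pairs <- unique(cross$reads$pair_id[
    cross$reads$sample_id %in% males])
  expect_setequal(asn$pair_id, male_pairs)
  expect_equal(anyDuplicated(asn$pair_id), 0L)
  expect_true(all(asn$bin %in% c("Y", "X", "ambiguous", "uninformative")))
  expect_true(all(asn$supporting_sites[asn$bin %in% c("Y", "X")] >= 1L))
})

test_that("hand-built pairs bin by the conflict rules", {
  sites <- data.frame(gene_id = "g1", pos = c(10L, 50L),
                      x_allele = c("A", "C"), y_allele = c("G", "T"),
                      status = "Y_linked")
  ov <- data.frame(
    gene_id = "g1",
    pos     = c(10L, 10L, 50L, 10L),
    read_id = c(1L, 3L, 4L, 5L),
    pair_id = c(1L, 2L, 2L, 3L),
    sample_id = "father",
    base    = c("G", "G", "C", "C"))
  reads <- data.frame(read_id = 1:8, pair_id = rep(1:4, each = 2),
                      sample_id = "father")
  asn <- partitionReads(ov, sites, reads = reads)
  # pair 1: one Y site, mate without overlap -> Y
  expect_equal(asn$bin[asn$pair_id == 1], "Y")
  # pair 2: one site showing Y, another showing X -> ambiguous
  expect_equal(asn$bin[asn$pair_id == 2], "ambiguous")
  # pair 3: third allele at a diagnostic site -> ambiguous
  expect_equal(asn$bin[asn$pair_id == 3], "ambiguous")
  # pair 4: no overlap -> uninformative
  expect_equal(asn$bin[asn$pair_id == 4], "uninformative")
})

test_that("consensus calling follows depth, majority and tie rules", {
  # hand-built micro-case: 1 gene of 9 bp, reads all from the y
  # haplotype, depth profile controlled by read placement
  haps <- list(g1 = c(xp = "AAAAAAAAA", y = "AAAGAAAAA",
                      xm1 = "AAAAAAAAA", xm2 = "AAAAAAAAA"))
  reads <- data.frame(read_id = 1:10, pair_id = rep(1:5, each = 2),
                      sample_id = "father", gene_id = "g1", hap = "y",
                      start = c(1, 5, 1, 5, 1, 5, 1, 5, 1, 5),
                      end   = c(4, 9, 4, 9, 4, 9, 4, 9, 4, 9))
  errs <- data.frame(read_id = integer(), pos = integer(),
                     obs_base = character())
  asn <- data.frame(pair_id = 1:5, bin = "Y", supporting_sites = 1L)
  cons <- buildConsensus(reads, errs, haps, asn, "g1", min_depth = 3L)
  expect_equal(cons$sequence, "AAAGAAAAA")
  expect_equal(cons$fraction_called, 1)
  # below min_depth: only 2 reads -> N everywhere
  cons2 <- buildConsensus(reads[1:2, ], errs, haps,
                          data.frame(pair_id = 1L, bin = "Y",
                                     supporting_sites = 1L),
                          "g1", min_depth = 3L)
  expect_equal(cons2$sequence, strrep("N", 9))
  # tie: 2 reads say A (errors), 2 say G at position 4, min_depth 2
  errs3 <- data.frame(read_id = c(1L, 3L), pos = c(4L, 4L),
                      obs_base = c("A", "A"))
  cons3 <- buildConsensus(reads[c(1, 3, 5, 7), ], errs3, haps,
                          data.frame(pair_id = 1:4, bin = "Y",
                                     supporting_sites = 1L),
                          "g1", min_depth = 2L)
  expect_equal(substr(cons3$sequence, 4, 4), "N")
  # empty Y bin: all-N with a warning
  expect_warning(
    cons4 <- buildConsensus(reads, errs, haps,
                            data.frame(pair_id = 1:5, bin = "X",
                                       supporting_sites = 1L), "g1"),
    "no Y-assigned reads")
  expect_equal(cons4$fraction_called, 0)
})

test_that("on error-free data the consensus equals the true Y haplotype at called positions", {
  cross <- smallCross(seed = 35, n_genes = 5, n_codons = 150,
                      error_rate = 0)
  sites <- classifySites(cross$observations, cross$pedigree)
  males <- cross$pedigree$sample_id[cross$pedigree$sex == "M"]
  asn <- partitionReads(cross$overlaps, sites, reads = cross$reads,
                        sample_ids = males)
  for (g in names(cross$haplotypes)) {
    cons <- buildConsensus(cross$reads, cross$read_errors,
                           cross$haplotypes, asn, g)
    truth <- strsplit(cross$haplotypes[[g]][["y"]], "")[[1]]
    called <- strsplit(cons$sequence, "")[[1]]
    ok <- called != "N"
    expect_true(all(called[ok] == truth[ok]), info = g)
  }
})

test_that("no Y-linked call coexists with a carrying informative daughter", {
  cross <- smallCross(seed = 36, n_genes = 6)
  sites <- classifySites(cross$observations, cross$pedigree)
  ped <- cross$pedigree
  daughters <- ped$sample_id[ped$sex == "F" & ped$role == "offspring"]
  obs <- cross$observations
  ylinked <- sites[sites$status == "Y_linked", ]
  for (i in seq_len(nrow(ylinked))) {
    s <- ylinked[i, ]
    o <- obs[obs$gene_id == s$gene_id & obs$pos == s$pos &
               obs$sample_id %in% daughters & obs$depth >= 5, ]
    carrier <- o[[s$y_allele]] >= 2 & o[[s$y_allele]] / o$depth >= 0.05
    expect_false(any(carrier), info = paste(s$gene_id, s$pos))
  }
})

test_that("truth equal to calls gives perfect validation scores", {
  truth <- data.frame(gene_id = "g1", pos = c(5L, 9L),
                      x_allele = "A", y_allele = c("G", "T"))
  calls <- data.frame(gene_id = "g1", pos = c(5L, 9L),
                      x_allele = "A", y_allele = c("G", "T"),
                      status = "Y_linked")
  v <- validateAgainstTruth(calls, truth)
  expect_equal(v$site_precision, 1)
  expect_equal(v$site_recall, 1)
  # empty calls: zero recall
  v0 <- validateAgainstTruth(calls[0, ], truth)
  expect_equal(v0$site_recall, 0)
})
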