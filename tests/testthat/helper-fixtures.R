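# Shared fixtures, built in code.

# Tiny deterministic cross used by several classification tests.
smallCross <- function(seed = 1, n_genes = 4, n_codons = 60,
                       error_rate = 0.002, ...) {
  set.seed(seed)
  trip <- simulateGametologTriplets(n_genes, n_codons, dS_XY = 0.06,
                                    dS_X_OG = 0.12, omega_X = 0.3,
                                    omega_Y = 0.6)
  simulateCross(trip, n_sons_rna = 0, n_daughters_rna = 0,
                error_rate = error_rate, ...)
}

# Hand-built observation table: one site, explicit allele depths.
# depths: named list sample_id -> c(A=, C=, G=, T=)
siteObs <- function(depths, gene = "g1", pos = 10L) {
  rows <- lapply(names(depths), function(s) {
    d <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    d[names(depths[[s]])] <- depths[[s]]
    data.frame(gene_id = gene, pos = pos, sample_id = s,
               A = d[["A"]], C = d[["C"]], G = d[["G"]], T = d[["T"]],
               depth = sum(d))
  })
  do.call(rbind, rows)
}

pedigreeOf <- function(sons = 2, daughters = 2, datatype = "genomic") {
  rbind(
    data.frame(sample_id = "father", family = "fam1", sex = "M",
               role = "father", datatype = "genomic"),
    data.frame(sample_id = "mother", family = "fam1", sex = "F",
               role = "mother", datatype = "genomic"),
    if (sons) data.frame(sample_id = paste0("son", seq_len(sons)),
                         family = "fam1", sex = "M", role = "offspring",
                         datatype = datatype),
    if (daughters) data.frame(sample_id = paste0("dau", seq_len(daughters)),
                              family = "fam1", sex = "F",
                              role = "offspring", datatype = datatype))
}

# A RecombinationProfile built directly from a rate vector, one window
# per step (non-overlapping), for segmentation unit tests.
profileFromRates <- function(rates, width = 1e6) {
  n <- length(rates)
  new("RecombinationProfile", chrom = "chrT", sex = "female",
      windows = data.frame(start = (seq_len(n) - 1) * width,
                           end = seq_len(n) * width,
                           rate = rates,
                           n_markers = rep(10L, n)),
      window = width, step = width)
}
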