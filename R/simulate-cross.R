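#' Simulate a sequenced two-generation cross segregating a Y haplotype
#'
#' Builds a family from a set of gametolog pairs: the father carries one X
#' haplotype (the reference) and the Y haplotype; the mother carries two X
#' haplotypes, one of which bears additional neutral heterozygous SNPs.
#' Sons inherit the Y plus one maternal X; daughters inherit the paternal X
#' plus one maternal X.  Paired-end reads with a flat per-base error rate
#' are drawn from every individual's haplotypes, and per-site allele-depth
#' observations and a read-site overlap table are derived from those same
#' reads, so the downstream pipeline is exercised without an external
#' aligner (alignment is by construction).
#'
#' Genomic-datatype individuals are sequenced at `coverage_genomic` per
#' diploid genome (half per haplotype).  RNA-datatype individuals get
#' allele depths scaled by expression: each X copy at `coverage_rna / 2`
#' and the Y copy at `y_expression * coverage_rna / 2`, so Y-silenced genes
#' can drop Y alleles in transcriptome sons.
#'
#' @param triplets Output of [simulateGametologTriplets()], or any list
#'   with `x` and `y` [Biostrings::DNAStringSet]s of equal names/lengths.
#' @param n_sons_genomic,n_daughters_genomic Genome-sequenced F1 progeny
#'   counts.
#' @param n_sons_rna,n_daughters_rna Transcriptome-sequenced F2 progeny
#'   counts (may be 0 for a genomic-only design).
#' @param coverage_genomic,coverage_rna Fold coverage per individual.
#' @param read_length,insert_size Read and fragment lengths in bp.
#' @param error_rate Flat per-base sequencing error probability.
#' @param maternal_het_rate Per-bp rate of extra neutral heterozygous SNPs
#'   on one maternal haplotype.
#' @param y_expression Y-copy expression as a fraction of one X copy in
#'   RNA samples; scalar or per-gene named vector.
#' @return list of class `sim_cross`: `pedigree`, `haplotypes` (per-gene
#'   named character vectors `xp`, `y`, `xm1`, `xm2`), `variants`,
#'   `truth_sites` (true Y-diagnostic SNPs), `reads`, `read_errors`,
#'   `overlaps` (read x variant-site observations), `observations`
#'   (per-site allele depths per sample) and `params`.
#' @examples
#' set.seed(1)
#' trip <- simulateGametologTriplets(2, 40, 0.06, 0.12, 0.3, 0.6)
#' cross <- simulateCross(trip, n_sons_rna = 0, n_daughters_rna = 0)
#' @export
simulateCross <- function(triplets,
                          n_sons_genomic = 5L, n_daughters_genomic = 5L,
                          n_sons_rna = 25L, n_daughters_rna = 25L,
                          coverage_genomic = 20, coverage_rna = 20,
                          read_length = 150L, insert_size = 400L,
                          error_rate = 0.002, maternal_het_rate = 0.002,
                          y_expression = 1) {
  n_sons <- n_sons_genomic + n_sons_rna
  n_daughters <- n_daughters_genomic + n_daughters_rna
  if (n_sons < 1L || n_daughters < 1L)
    stop("at least one son and one daughter are required; ",
         "Y-SNP classification is undefined otherwise")
  if (coverage_genomic <= 0 || coverage_rna < 0)
    stop("coverage must be positive")
  genes <- names(triplets$x)
  if (is.null(genes) || !identical(genes, names(triplets$y)))
    stop("triplets$x and triplets$y must share gene names")
  x_chr <- as.character(triplets$x)
  y_chr <- as.character(triplets$y)
  if (length(y_expression) == 1L && is.null(names(y_expression)))
    y_expression <- stats::setNames(rep(y_expression, length(genes)), genes)

  pedigree <- .makePedigree(n_sons_genomic, n_daughters_genomic,
                            n_sons_rna, n_daughters_rna)

  # haplotypes: xm1 carries extra neutral het SNPs
  haplotypes <- lapply(seq_along(genes), function(g) {
    x <- unname(x_chr[g])
    xm1 <- .addNeutralSnps(x, maternal_het_rate)
    c(xp = x, y = unname(y_chr[g]), xm1 = xm1, xm2 = x)
  })
  names(haplotypes) <- genes

  variants <- data.table::rbindlist(lapply(genes, function(g) {
    h <- haplotypes[[g]]
    m <- do.call(rbind, strsplit(h, ""))
    pos <- which(m["y", ] != m["xp", ] | m["xm1", ] != m["xp", ])
    if (!length(pos)) return(NULL)
    data.table::data.table(gene_id = g, pos = pos,
                           ref = m["xp", pos], y = m["y", pos],
                           xm1 = m["xm1", pos], xm2 = m["xm2", pos])
  }))
  truth_sites <- variants[variants$y != variants$ref &
                            variants$y != variants$xm1 &
                            variants$y != variants$xm2, ]
  truth_sites <- data.table::data.table(
    gene_id = truth_sites$gene_id, pos = truth_sites$pos,
    x_allele = truth_sites$ref, y_allele = truth_sites$y)

  reads <- .drawReads(pedigree, genes, nchar(x_chr), coverage_genomic,
                      coverage_rna, read_length, insert_size, y_expression)
  read_errors <- .drawErrors(reads, error_rate)
  overlaps <- .overlapReadsSites(reads, read_errors, variants, haplotypes)
  observations <- .depthTable(overlaps, pedigree)

  structure(list(pedigree = as.data.frame(pedigree),
                 haplotypes = haplotypes,
                 variants = as.data.frame(variants),
                 truth_sites = as.data.frame(truth_sites),
                 reads = reads, read_errors = read_errors,
                 overlaps = overlaps, observations = observations,
                 params = list(coverage_genomic = coverage_genomic,
                               coverage_rna = coverage_rna,
                               read_length = read_length,
                               insert_size = insert_size,
                               error_rate = error_rate,
                               maternal_het_rate = maternal_het_rate,
                               y_expression = y_expression)),
            class = "sim_cross")
}

.makePedigree <- function(nsg, ndg, nsr, ndr) {
  kid <- function(prefix, n, sex, gen, datatype) {
    if (n < 1L) return(NULL)
    data.table::data.table(
      sample_id = sprintf("%s%02d", prefix, seq_len(n)),
      family = "fam1", father = "father", mother = "mother",
      sex = sex, role = "offspring", generation = gen, datatype = datatype)
  }
  data.table::rbindlist(list(
    data.table::data.table(sample_id = "father", family = "fam1",
                           father = NA_character_, mother = NA_character_,
                           sex = "M", role = "father", generation = "P",
                           datatype = "genomic"),
    data.table::data.table(sample_id = "mother", family = "fam1",
                           father = NA_character_, mother = NA_character_,
                           sex = "F", role = "mother", generation = "P",
                           datatype = "genomic"),
    kid("son_g", nsg, "M", "F1", "genomic"),
    kid("dau_g", ndg, "F", "F1", "genomic"),
    kid("son_r", nsr, "M", "F2", "rna"),
    kid("dau_r", ndr, "F", "F2", "rna")))
}

.addNeutralSnps <- function(x, rate) {
  if (rate <= 0) return(x)
  L <- nchar(x)
  n <- stats::rbinom(1L, L, rate)
  if (n == 0L) return(x)
  pos <- sample.int(L, n)
  s <- strsplit(x, "")[[1]]
  for (p in pos) s[p] <- sample(setdiff(.BASES, s[p]), 1L)
  paste(s, collapse = "")
}

# Which haplotypes an individual carries, with per-haplotype coverage.
.sampleHaps <- function(ped_row, maternal_hap, cov_g, cov_r, y_expr_gene) {
  dtype <- ped_row$datatype
  half <- if (dtype == "genomic") cov_g / 2 else cov_r / 2
  if (ped_row$role == "father") {
    data.frame(hap = c("xp", "y"), cov = c(half, half))
  } else if (ped_row$role == "mother") {
    data.frame(hap = c("xm1", "xm2"), cov = c(half, half))
  } else if (ped_row$sex == "M") {
    ycov <- if (dtype == "rna") half * y_expr_gene else half
    data.frame(hap = c("y", maternal_hap), cov = c(ycov, half))
  } else {
    data.frame(hap = c("xp", maternal_hap), cov = c(half, half))
  }
}

.drawReads <- function(pedigree, genes, gene_len, cov_g, cov_r,
                       read_length, insert_size, y_expression) {
  ped <- as.data.frame(pedigree)
  # one maternal haplotype per child, fixed across genes (no recombination
  # within the simulated gene set)
  maternal <- stats::setNames(
    sample(c("xm1", "xm2"), nrow(ped), replace = TRUE), ped$sample_id)
  out <- vector("list", nrow(ped) * length(genes))
  k <- 0L
  next_id <- 0L
  for (i in seq_len(nrow(ped))) {
    for (g in seq_along(genes)) {
      L <- gene_len[g]
      ins <- min(insert_size, L)
      rl <- min(read_length, ins)
      haps <- .sampleHaps(ped[i, ], maternal[[ped$sample_id[i]]],
                          cov_g, cov_r, y_expression[[genes[g]]])
      for (h in seq_len(nrow(haps))) {
        # fragments may start in the flanking sequence (genes sit inside
        # a chromosome); reads are clipped to the CDS, so coverage is
        # uniform across the gene rather than tapering at its edges
        span <- L + ins - 1L
        mu <- span * haps$cov[h] / (2 * rl)
        n_pairs <- stats::rpois(1L, mu)
        if (n_pairs == 0L) next
        s <- sample.int(span, n_pairs, replace = TRUE) - (ins - 1L)
        pair_id <- next_id + seq_len(n_pairs)
        next_id <- next_id + n_pairs
        st <- c(s, s + ins - rl)
        en <- c(s + rl - 1L, s + ins - 1L)
        dt <- data.table::data.table(
          pair_id = rep(pair_id, 2L),
          mate = rep(1:2, each = n_pairs),
          sample_id = ped$sample_id[i], gene_id = genes[g],
          hap = haps$hap[h],
          start = pmax(st, 1L),
          end = pmin(en, L))
        dt <- dt[dt$start <= dt$end]
        if (nrow(dt)) { k <- k + 1L; out[[k]] <- dt }
      }
    }
  }
  reads <- data.table::rbindlist(out[seq_len(k)])
  if (nrow(reads)) {
    data.table::setorder(reads, pair_id, mate)
    reads[, read_id := .I]
  } else reads[, read_id := integer()]
  reads[]
}

.drawErrors <- function(reads, error_rate) {
  if (!nrow(reads) || error_rate <= 0)
    return(data.table::data.table(read_id = integer(), pos = integer(),
                                  obs_base = character()))
  width <- reads$end - reads$start + 1L
  n_err <- stats::rbinom(nrow(reads), width, error_rate)
  idx <- which(n_err > 0L)
  if (!length(idx))
    return(data.table::data.table(read_id = integer(), pos = integer(),
                                  obs_base = character()))
  err <- data.table::rbindlist(lapply(idx, function(i) {
    offs <- sample.int(width[i], n_err[i])
    data.table::data.table(read_id = reads$read_id[i],
                           pos = reads$start[i] + offs - 1L)
  }))
  err[, obs_base := sample(.BASES, .N, replace = TRUE)]
  err
}

.overlapReadsSites <- function(reads, read_errors, variants, haplotypes) {
  empty <- data.table::data.table(
    gene_id = character(), pos = integer(), read_id = integer(),
    pair_id = integer(), sample_id = character(), base = character())
  if (!nrow(reads) || !nrow(variants)) return(empty)
  sites <- variants[, c("gene_id", "pos")]
  rd <- data.table::copy(reads)
  rd[, `:=`(lo = start, hi = end)]
  ov <- rd[sites, on = list(gene_id, lo <= pos, hi >= pos),
           allow.cartesian = TRUE, nomatch = NULL,
           list(gene_id, pos = lo, read_id, pair_id, sample_id, hap)]
  if (!nrow(ov)) return(empty)
  # base carried by the read at the site = haplotype base, unless a
  # sequencing error hit that read position
  hap_key <- paste0(ov$gene_id, ".", ov$hap)
  hap_strings <- unlist(haplotypes)  # names like gene.hap
  ov[, base := substr(hap_strings[hap_key], pos, pos)]
  if (nrow(read_errors)) {
    ov[read_errors, on = list(read_id, pos), base := i.obs_base]
  }
  ov[, hap := NULL]
  ov[]
}

.depthTable <- function(overlaps, pedigree) {
  if (!nrow(overlaps))
    return(data.frame(gene_id = character(), pos = integer(),
                      sample_id = character(), A = integer(), C = integer(),
                      G = integer(), T = integer(), depth = integer()))
  counts <- overlaps[, list(n = .N),
                     by = list(gene_id, pos, sample_id, base)]
  wide <- data.table::dcast(counts, gene_id + pos + sample_id ~ base,
                            value.var = "n", fill = 0L)
  for (b in .BASES) if (!b %in% names(wide)) wide[, (b) := 0L]
  data.table::setcolorder(wide, c("gene_id", "pos", "sample_id", .BASES))
  wide[, depth := A + C + G + T]
  data.table::setorder(wide, gene_id, pos, sample_id)
  as.data.frame(wide)
}
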