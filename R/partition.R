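#' Partition read pairs by diagnostic alleles
#'
#' Assigns each read pair to the Y or X haplotype: a pair is `Y` when
#' every diagnostic site it overlaps (at least one) shows the Y allele,
#' `X` when every overlapped site shows the X allele, `ambiguous` when
#' sites conflict or show a third allele, and `uninformative` when the
#' pair overlaps no diagnostic site.  A mate without site overlap
#' inherits its pair's bin, mirroring the practice of carrying paired
#' reads along with Y-SNP-bearing reads.
#'
#' @param overlaps Read-site overlap table with columns `gene_id`, `pos`,
#'   `read_id`, `pair_id`, `base` (one row per read x overlapped variant
#'   site), e.g. the `overlaps` element of [simulateCross()].
#' @param sites Diagnostic sites from [classifySites()]; only rows with
#'   `status == "Y_linked"` are used.
#' @param reads Optional read table (`read_id`, `pair_id`, ...) listing
#'   all pairs, so pairs without any site overlap are reported as
#'   `uninformative`; defaults to the pairs present in `overlaps`.
#' @param sample_ids Optional samples to restrict to.
#' @return data.frame with one row per read pair: `pair_id`, `bin`
#'   (`Y`, `X`, `ambiguous`, `uninformative`) and `supporting_sites`.
#'   Every input pair appears in exactly one bin.
#' @export
partitionReads <- function(overlaps, sites, reads = NULL,
                           sample_ids = NULL) {
  ov <- data.table::as.data.table(overlaps)
  if (!is.null(sample_ids) && "sample_id" %in% names(ov))
    ov <- ov[sample_id %in% sample_ids]
  ysites <- data.table::as.data.table(sites)
  ysites <- ysites[status == "Y_linked",
                   c("gene_id", "pos", "x_allele", "y_allele")]
  all_pairs <- if (!is.null(reads)) {
    rd <- data.table::as.data.table(reads)
    if (!is.null(sample_ids) && "sample_id" %in% names(rd))
      rd <- rd[sample_id %in% sample_ids]
    unique(rd$pair_id)
  } else unique(ov$pair_id)

  hit <- ov[ysites, on = c("gene_id", "pos"), nomatch = NULL]
  per_pair <- if (nrow(hit)) {
    hit[, `:=`(is_y = base == y_allele, is_x = base == x_allele)]
    hit[, list(n_sites = .N, n_y = sum(is_y), n_x = sum(is_x)),
        by = pair_id]
  } else data.table::data.table(pair_id = integer(), n_sites = integer(),
                                n_y = integer(), n_x = integer())
  per_pair[, bin := data.table::fcase(
    n_y == n_sites, "Y",
    n_x == n_sites, "X",
    default = "ambiguous")]
  out <- data.table::data.table(pair_id = all_pairs)
  out <- merge(out, per_pair[, c("pair_id", "bin", "n_sites")],
               by = "pair_id", all.x = TRUE)
  out[is.na(bin), bin := "uninformative"]
  out[is.na(n_sites), n_sites := 0L]
  data.table::setnames(out, "n_sites", "supporting_sites")
  data.table::setorder(out, pair_id)
  as.data.frame(out)
}

#' Build a Y-consensus coding sequence from partitioned reads
#'
#' Piles up the reads of Y-assigned pairs over the coding sequence of one
#' gene and calls, per position, the majority base when depth reaches
#' `min_depth` and the majority fraction exceeds 0.5; positions below
#' depth, and ties, are written `N`.
#'
#' @param reads Read table (`read_id`, `pair_id`, `gene_id`, `hap`,
#'   `start`, `end`).
#' @param read_errors Sequencing-error table (`read_id`, `pos`,
#'   `obs_base`); may be empty.
#' @param haplotypes Named per-gene haplotype strings (as in
#'   [simulateCross()]), used to reconstitute read bases.
#' @param assignment Pair assignment from [partitionReads()].
#' @param gene_id Gene to build the consensus for.
#' @param cds_length CDS length in bp (defaults to the haplotype length).
#' @param min_depth Minimum Y-read depth to call a base.
#' @return list of class `y_consensus`: `gene_id`, `sequence` (character,
#'   length `cds_length`, `N` where uncalled), `depth` (integer vector)
#'   and `fraction_called`.
#' @export
buildConsensus <- function(reads, read_errors, haplotypes, assignment,
                           gene_id, cds_length = NULL, min_depth = 3L) {
  haps <- haplotypes[[gene_id]]
  if (is.null(cds_length)) cds_length <- nchar(haps[[1]])
  rd <- data.table::as.data.table(reads)
  rd <- rd[rd$gene_id == gene_id]
  asn <- data.table::as.data.table(assignment)
  ypairs <- asn[bin == "Y", pair_id]
  rd <- rd[pair_id %in% ypairs]
  counts <- matrix(0L, nrow = 4L, ncol = cds_length,
                   dimnames = list(.BASES, NULL))
  if (nrow(rd)) {
    # per haplotype of origin, read coverage contributes the haplotype
    # base at each covered position; sequencing errors are then moved
    # from the haplotype base to the observed base
    for (h in unique(rd$hap)) {
      rh <- rd[hap == h]
      cov <- IRanges::coverage(IRanges::IRanges(rh$start, rh$end),
                               width = cds_length)
      cov <- as.integer(cov)
      hb <- match(strsplit(haps[[h]], "")[[1]], .BASES)
      idx <- cbind(hb, seq_len(cds_length))
      counts[idx] <- counts[idx] + cov
    }
    err <- data.table::as.data.table(read_errors)
    if (nrow(err)) {
      err <- err[rd, on = "read_id", nomatch = NULL]
      err <- err[pos >= start & pos <= end]
      if (nrow(err)) {
        true_b <- vapply(seq_len(nrow(err)), function(k)
          substr(haps[[err$hap[k]]], err$pos[k], err$pos[k]), "")
        for (k in seq_len(nrow(err))) {
          counts[true_b[k], err$pos[k]] <- counts[true_b[k], err$pos[k]] - 1L
          counts[err$obs_base[k], err$pos[k]] <-
            counts[err$obs_base[k], err$pos[k]] + 1L
        }
      }
    }
  } else {
    warning("no Y-assigned reads for ", gene_id, "; all-N consensus")
  }
  depth <- colSums(counts)
  top <- apply(counts, 2L, max)
  top_base <- .BASES[apply(counts, 2L, which.max)]
  tie <- apply(counts, 2L, function(x) sum(x == max(x)) > 1L) & depth > 0L
  call <- depth >= min_depth & top / pmax(depth, 1L) > 0.5 & !tie
  seq_out <- ifelse(call, top_base, "N")
  structure(list(gene_id = gene_id,
                 sequence = paste(seq_out, collapse = ""),
                 depth = as.integer(depth),
                 fraction_called = mean(call)),
            class = "y_consensus")
}

#' Validate diagnostic-site calls and consensus sequences against
#' simulation truth
#'
#' @param sites Diagnostic sites from [classifySites()].
#' @param truth_sites True Y-SNP table (`gene_id`, `pos`, `y_allele`),
#'   e.g. the `truth_sites` element of [simulateCross()].
#' @param consensuses Optional list of `y_consensus` objects.
#' @param y_truth Optional [Biostrings::DNAStringSet] (or named character
#'   vector) of true Y haplotype sequences per gene.
#' @return list with `site_precision`, `site_recall`, `n_called`,
#'   `n_truth`, and — when consensuses are supplied — `base_accuracy`
#'   (over called, non-N positions) and `fraction_called`.
#' @export
validateAgainstTruth <- function(sites, truth_sites, consensuses = NULL,
                                 y_truth = NULL) {
  called <- sites[sites$status == "Y_linked", c("gene_id", "pos", "y_allele")]
  key <- function(d) paste(d$gene_id, d$pos, d$y_allele)
  tp <- sum(key(called) %in% key(truth_sites))
  precision <- if (nrow(called)) tp / nrow(called) else NA_real_
  recall <- if (nrow(truth_sites)) tp / nrow(truth_sites) else NA_real_
  out <- list(site_precision = precision, site_recall = recall,
              n_called = nrow(called), n_truth = nrow(truth_sites))
  if (!is.null(consensuses)) {
    y_truth <- stats::setNames(as.character(y_truth), names(y_truth))
    match_n <- 0L; called_n <- 0L; frac <- numeric()
    for (cons in consensuses) {
      tr <- y_truth[[cons$gene_id]]
      s <- strsplit(cons$sequence, "")[[1]]
      t_ <- strsplit(tr, "")[[1]]
      ok <- s != "N"
      match_n <- match_n + sum(s[ok] == t_[ok])
      called_n <- called_n + sum(ok)
      frac <- c(frac, cons$fraction_called)
    }
    out$base_accuracy <- if (called_n) match_n / called_n else NA_real_
    out$fraction_called <- mean(frac)
  }
  out
}
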