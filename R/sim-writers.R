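# Plain-text writers for simulated data.  All writers are deterministic
# functions of the sim objects, so byte-identical inputs give
# byte-identical files.

#' Write simulated reads as paired FASTQ files
#'
#' Read sequences are reconstituted from the haplotype strings with
#' sequencing errors applied; mate 2 is written reverse-complemented.
#' Base qualities are constant Phred+33 'I'.
#'
#' @param cross A `sim_cross` object.
#' @param dir Output directory (created if needed).
#' @param samples Samples to write (default: all).
#' @return Invisibly, the paths written.
#' @export
writeCrossFastq <- function(cross, dir, samples = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reads <- data.table::as.data.table(cross$reads)
  if (is.null(samples)) samples <- unique(reads$sample_id)
  err <- data.table::as.data.table(cross$read_errors)
  hap_strings <- unlist(cross$haplotypes)
  paths <- character()
  for (s in samples) {
    rs <- reads[sample_id == s]
    seqs <- substr(hap_strings[paste0(rs$gene_id, ".", rs$hap)],
                   rs$start, rs$end)
    if (nrow(err)) {
      re <- err[rs, on = "read_id", nomatch = NULL]
      if (nrow(re)) {
        re[, row := match(read_id, rs$read_id)]
        for (k in seq_len(nrow(re))) {
          off <- re$pos[k] - rs$start[re$row[k]] + 1L
          substr(seqs[re$row[k]], off, off) <- re$obs_base[k]
        }
      }
    }
    rc <- rs$mate == 2L
    seqs[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
    for (m in 1:2) {
      sel <- rs$mate == m
      f <- file.path(dir, sprintf("%s_R%d.fastq", s, m))
      rec <- paste0("@pair", rs$pair_id[sel], "/", m, "\n", seqs[sel],
                    "\n+\n", strrep("I", nchar(seqs[sel])))
      writeLines(rec, f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' Write called-style genotypes for a simulated cross as minimal VCF v4.2
#'
#' One biallelic row per simulated variant site; genotypes are called from
#' the per-sample allele depths (an allele is present with >= 2 supporting
#' reads and >= 10% of site depth).  FORMAT is `GT:AD:DP`.
#'
#' @param cross A `sim_cross` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeCrossVcf <- function(cross, path) {
  obs <- data.table::as.data.table(cross$observations)
  variants <- cross$variants
  samples <- cross$pedigree$sample_id
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sexchromr_simulateCross",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    alts <- setdiff(unique(c(v$y, v$xm1, v$xm2)), v$ref)
    alt <- if (length(alts)) alts[1] else "."
    site_obs <- obs[gene_id == v$gene_id & pos == v$pos]
    gts <- vapply(samples, function(s) {
      o <- site_obs[sample_id == s]
      if (!nrow(o) || o$depth == 0L) return("./.:0,0:0")
      ad_ref <- o[[v$ref]]
      ad_alt <- if (alt == ".") 0L else o[[alt]]
      present <- function(ad) ad >= 2L && ad / o$depth >= 0.1
      gt <- if (present(ad_ref) && present(ad_alt)) "0/1"
        else if (present(ad_alt)) "1/1"
        else if (present(ad_ref)) "0/0" else "./."
      sprintf("%s:%d,%d:%d", gt, ad_ref, ad_alt, o$depth)
    }, character(1))
    rows[i] <- paste(c(v$gene_id, v$pos, ".", v$ref, alt, ".", "PASS", ".",
                       "GT:AD:DP", gts), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write the pedigree as a tab-separated table
#' @param cross A `sim_cross` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writePedigree <- function(cross, path) {
  utils::write.table(cross$pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular alignment hit file (`-outfmt 6` dialect)
#'
#' @param path Path to a tab-separated hit file without header.
#' @return data.frame with the standard 12 columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`).
#' @export
readBlastHits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  utils::read.table(path, sep = "\t", col.names = cols,
                    colClasses = c("character", "character", rep("numeric", 10)),
                    comment.char = "")
}
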