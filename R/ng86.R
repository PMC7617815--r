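#' Nei-Gojobori (1986) pairwise synonymous and nonsynonymous divergence
#'
#' Estimates dS and dN between two aligned, in-frame coding sequences using
#' the unweighted pathway method: synonymous and nonsynonymous sites are
#' counted per codon (averaged over the two sequences, with changes to stop
#' codons counted as nonsynonymous so sites sum to three per codon), observed
#' differences in multiply-substituted codons are averaged over all minimal
#' mutational pathways that avoid stop codons, and the resulting proportions
#' are corrected for multiple hits with the Jukes-Cantor formula
#' d = -3/4 * log(1 - 4p/3).
#'
#' Codons containing gaps, `N` or any non-ACGT character in either sequence
#' are masked from counting, as are stop codons.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length divisible
#'   by 3 (character or [Biostrings::DNAString]).
#' @return A list with elements `dS`, `dN`, `omega` (NA when `dS` is 0),
#'   `pS`, `pN`, `S_sites`, `N_sites`, `syn_diffs`, `nonsyn_diffs` and
#'   `codons` (countable codons).
#' @details When an observed proportion reaches the Jukes-Cantor domain
#'   boundary (p >= 3/4) a saturation error is raised.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @examples
#' ng86(strrep("TTT", 10), paste0("TTC", strrep("TTT", 9)))
#' @export
ng86 <- function(seq_a, seq_b) {
  a <- as.character(seq_a)
  b <- as.character(seq_b)
  if (nchar(a) != nchar(b))
    stop("sequences must be aligned to equal length")
  tab <- codonTables()
  ca <- codonStringToIndex(a)[[1]]
  cb <- codonStringToIndex(b)[[1]]
  ok <- !is.na(ca) & !is.na(cb) & !tab$is_stop[ca] & !tab$is_stop[cb]
  ca <- ca[ok]; cb <- cb[ok]
  n_codon <- length(ca)
  if (n_codon < 1L) stop("no countable codons in alignment")

  S <- (sum(tab$s_sites[ca]) + sum(tab$s_sites[cb])) / 2
  N <- 3 * n_codon - S

  diff <- which(ca != cb)
  sd_ <- 0; nd_ <- 0
  if (length(diff)) {
    pairs <- unique(cbind(ca[diff], cb[diff]))
    counts <- apply(pairs, 1L, function(pr) .pathwayCount(pr[1], pr[2]))
    key <- paste0(ca[diff], "_", cb[diff])
    pkey <- paste0(pairs[, 1], "_", pairs[, 2])
    m <- match(key, pkey)
    sd_ <- sum(counts["syn", m])
    nd_ <- sum(counts["nonsyn", m])
  }
  pS <- sd_ / S
  pN <- nd_ / N
  dS <- jukesCantor(pS, "synonymous")
  dN <- jukesCantor(pN, "nonsynonymous")
  list(dS = dS, dN = dN,
       omega = if (dS > 0) dN / dS else NA_real_,
       pS = pS, pN = pN, S_sites = S, N_sites = N,
       syn_diffs = sd_, nonsyn_diffs = nd_, codons = n_codon)
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p Observed proportion of differences per site.
#' @param what Label used in the saturation error message.
#' @return Corrected distance in substitutions per site.
#' @export
jukesCantor <- function(p, what = "site") {
  if (p >= 0.75)
    stop("saturation: observed ", what, " proportion ", signif(p, 3),
         " is at or beyond the Jukes-Cantor domain boundary (3/4)",
         call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise divergence estimates for a gametolog triplet
#'
#' Runs [ng86()] on the X:Y, X:outgroup and Y:outgroup pairs of an aligned
#' triplet.  Pairs involving a missing sequence, or pairs whose estimate
#' saturates, are returned as NA rows.
#'
#' @param x_cds,y_cds,og_cds Aligned coding sequences (equal length;
#'   `y_cds`/`og_cds` may be `NULL` or `NA`).
#' @param gene_id Optional gene identifier carried into the output.
#' @return data.frame with one row per pair (`XY`, `X_OG`, `Y_OG`) and
#'   columns `gene_id`, `pair`, `dS`, `dN`, `omega`, `S_sites`, `N_sites`,
#'   `codons`.
#' @export
tripletDivergence <- function(x_cds, y_cds = NULL, og_cds = NULL,
                              gene_id = NA_character_) {
  one <- function(label, a, b) {
    if (is.null(a) || is.null(b) || is.na(a[1]) || is.na(b[1]))
      return(data.frame(gene_id = gene_id, pair = label, dS = NA_real_,
                        dN = NA_real_, omega = NA_real_, S_sites = NA_real_,
                        N_sites = NA_real_, codons = NA_integer_))
    est <- tryCatch(ng86(a, b), error = function(e) NULL)
    if (is.null(est))
      return(data.frame(gene_id = gene_id, pair = label, dS = NA_real_,
                        dN = NA_real_, omega = NA_real_, S_sites = NA_real_,
                        N_sites = NA_real_, codons = NA_integer_))
    data.frame(gene_id = gene_id, pair = label, dS = est$dS, dN = est$dN,
               omega = est$omega, S_sites = est$S_sites,
               N_sites = est$N_sites, codons = est$codons)
  }
  rbind(one("XY", x_cds, y_cds),
        one("X_OG", x_cds, og_cds),
        one("Y_OG", y_cds, og_cds))
}
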