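#' Codon-aware alignment of a gametolog triplet
#'
#' Aligns coding sequences in a frame-preserving way: each sequence is
#' translated, the peptides are globally aligned pairwise against the X
#' peptide (Needleman-Wunsch, BLOSUM62, affine gap penalties), and the
#' peptide alignments are back-threaded onto codons.  Gap codons are
#' written as `---` and are masked (together with codons containing `N`)
#' by downstream counting in [ng86()].
#'
#' @param x_cds Reference (X) coding sequence, in frame from position 1.
#' @param y_cds,og_cds Optional coding sequences to align against
#'   `x_cds`; `NULL`, `NA` or all-`N` sequences yield `NA` slots.
#' @param gene_id Optional identifier.
#' @param region Optional region label (`PAR`, `Xpr`, `qXdr`,
#'   `autosome`).
#' @param gapOpening,gapExtension Affine gap penalties passed to
#'   [Biostrings::pairwiseAlignment()].
#' @return list of class `gametolog_triplet` with elements `gene_id`,
#'   `region`, `x`, `y`, `og` (aligned nucleotide strings over a common
#'   codon coordinate system) and `codons` (aligned length in codons).
#' @details Sequences whose translation contains an internal stop codon in
#'   frame 0 cannot be aligned and raise an error; the caller is expected
#'   to skip and log such genes.
#' @export
codonAlign <- function(x_cds, y_cds = NULL, og_cds = NULL,
                       gene_id = NA_character_, region = NA_character_,
                       gapOpening = 10, gapExtension = 0.5) {
  x <- .cleanCds(x_cds, "x_cds", required = TRUE)
  y <- .cleanCds(y_cds, "y_cds")
  og <- .cleanCds(og_cds, "og_cds")

  ax <- x; ay <- y; aog <- og
  if (!is.na(y)) {
    al <- .peptideAlignPair(x, y, gapOpening, gapExtension)
    ax <- al$a; ay <- al$b
  }
  if (!is.na(og)) {
    al <- .peptideAlignPair(x, og, gapOpening, gapExtension)
    # merge onto a common X coordinate system: project both alignments
    # through the (possibly gapped) X sequence
    merged <- .mergeOnReference(ax, if (is.na(y)) NULL else ay,
                                al$a, al$b)
    ax <- merged$ref; ay <- merged$s1; aog <- merged$s2
  }
  structure(list(gene_id = gene_id, region = region,
                 x = ax, y = if (is.na(y)) NA_character_ else ay,
                 og = if (is.na(og)) NA_character_ else aog,
                 codons = nchar(ax) / 3),
            class = "gametolog_triplet")
}

.cleanCds <- function(s, what, required = FALSE) {
  if (is.null(s) || (length(s) == 1L && is.na(s))) {
    if (required) stop(what, " is required")
    return(NA_character_)
  }
  s <- toupper(as.character(s))
  if (nchar(s) %% 3L != 0L) stop(what, ": length not divisible by 3")
  if (grepl("^N*$", s)) {
    if (required) stop(what, " is all-N")
    return(NA_character_)
  }
  pep <- .translateMasked(s)
  if (grepl("\\*", substr(pep, 1L, nchar(pep) - 1L)))
    stop(what, ": internal stop codon in frame")
  s
}

.translateMasked <- function(s) {
  tab <- codonTables()
  ci <- codonStringToIndex(s)[[1]]
  aa <- ifelse(is.na(ci), "X", tab$aa[ci])
  paste(aa, collapse = "")
}

.peptideAlignPair <- function(a, b, gapOpening, gapExtension) {
  pa <- gsub("\\*$", "", .translateMasked(a))
  pb <- gsub("\\*$", "", .translateMasked(b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gapOpening, gapExtension = gapExtension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  list(a = .backThread(a, pat), b = .backThread(b, sub))
}

.backThread <- function(nt, aligned_pep) {
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  out <- character(length(aligned_pep))
  k <- 0L
  for (i in seq_along(aligned_pep)) {
    if (aligned_pep[i] == "-") out[i] <- "---"
    else { k <- k + 1L; out[i] <- codons[k] }
  }
  # trailing stop codon (if the CDS carried one) is dropped by the peptide
  # trim; append remaining codons only if they are a terminal stop
  paste(out, collapse = "")
}

# Merge two pairwise alignments (ref vs s1, ref vs s2) onto a shared
# gapped reference, codon-wise.
.mergeOnReference <- function(ref1, s1, ref2, s2) {
  split3 <- function(s) substring(s, seq(1L, nchar(s), 3L),
                                  seq(3L, nchar(s), 3L))
  r1 <- split3(ref1); r2 <- split3(ref2)
  a1 <- if (is.null(s1)) NULL else split3(s1)
  a2 <- split3(s2)
  i <- 1L; j <- 1L
  ref_out <- character(); s1_out <- character(); s2_out <- character()
  while (i <= length(r1) || j <= length(r2)) {
    g1 <- i <= length(r1) && r1[i] == "---"
    g2 <- j <= length(r2) && r2[j] == "---"
    if (g1) {
      ref_out <- c(ref_out, "---")
      s1_out <- c(s1_out, if (is.null(a1)) "---" else a1[i])
      s2_out <- c(s2_out, "---")
      i <- i + 1L
    } else if (g2) {
      ref_out <- c(ref_out, "---")
      s1_out <- c(s1_out, "---")
      s2_out <- c(s2_out, a2[j])
      j <- j + 1L
    } else {
      ref_out <- c(ref_out, if (i <= length(r1)) r1[i] else r2[j])
      s1_out <- c(s1_out, if (is.null(a1) || i > length(a1)) "---" else a1[i])
      s2_out <- c(s2_out, if (j <= length(a2)) a2[j] else "---")
      i <- i + 1L; j <- j + 1L
    }
  }
  list(ref = paste(ref_out, collapse = ""),
       s1 = if (is.null(a1)) NULL else paste(s1_out, collapse = ""),
       s2 = paste(s2_out, collapse = ""))
}
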