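# Internal genetic-code machinery shared by the forward simulator and the
# NG86 estimator.  Codons are indexed 1..64 as 16*(b1-1) + 4*(b2-1) + b3
# with bases ordered A,C,G,T.  All tables are built once per session.

.BASES <- c("A", "C", "G", "T")

.codon_cache <- new.env(parent = emptyenv())

codonIndex <- function(b1, b2, b3) 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3

#' @noRd
codonTables <- function() {
  tab <- .codon_cache$tables
  if (!is.null(tab)) return(tab)

  idx <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)[, 3:1]
  codons <- paste0(.BASES[idx$b1], .BASES[idx$b2], .BASES[idx$b3])
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[codons])
  is_stop <- aa == "*"

  # neighbour[i, p, b]: consequence of changing position p of codon i to
  # base b.  0 same base, 1 synonymous, 2 nonsynonymous, 3 creates a stop.
  neighbour <- array(0L, dim = c(64L, 3L, 4L))
  neighbour_idx <- array(0L, dim = c(64L, 3L, 4L))
  base_of <- cbind(idx$b1, idx$b2, idx$b3)
  for (i in 1:64) {
    for (p in 1:3) {
      for (b in 1:4) {
        if (b == base_of[i, p]) next
        bb <- base_of[i, ]
        bb[p] <- b
        j <- codonIndex(bb[1], bb[2], bb[3])
        neighbour_idx[i, p, b] <- j
        neighbour[i, p, b] <-
          if (is_stop[j]) 3L else if (aa[j] == aa[i]) 1L else 2L
      }
    }
  }

  # NG86 synonymous site count per codon: per position, (number of
  # synonymous single-base changes)/3; changes to stops count as
  # nonsynonymous so that S + N = 3 per codon.
  s_sites <- numeric(64)
  for (i in 1:64) {
    s_sites[i] <- sum(neighbour[i, , ] == 1L) / 3
  }
  s_sites[is_stop] <- NA_real_

  .codon_cache$tables <- list(
    codons = codons, aa = aa, is_stop = is_stop,
    sense = which(!is_stop),
    base_of = base_of,
    neighbour = neighbour, neighbour_idx = neighbour_idx,
    s_sites = s_sites
  )
  .codon_cache$tables
}

#' @noRd
codonStringToIndex <- function(x) {
  # x: character vector of nucleotide strings (length divisible by 3).
  # Returns a list of integer codon vectors; codons containing anything
  # outside ACGT map to NA.
  lapply(x, function(s) {
    nt <- match(strsplit(toupper(s), "")[[1]], .BASES)
    if (length(nt) %% 3L != 0L)
      stop("sequence length not divisible by 3")
    m <- matrix(nt, nrow = 3L)
    ok <- colSums(is.na(m)) == 0L
    out <- rep(NA_integer_, ncol(m))
    out[ok] <- codonIndex(m[1, ok], m[2, ok], m[3, ok])
    out
  })
}

#' @noRd
indexToCodonString <- function(ci) {
  tab <- codonTables()
  paste(tab$codons[ci], collapse = "")
}

# Pathway-averaged synonymous/nonsynonymous difference counts for a codon
# pair: enumerate every ordering of the differing positions, drop pathways
# that traverse a stop codon, and average the per-step classifications over
# the remaining pathways.  If every pathway traverses a stop, average over
# all pathways with stop-creating steps counted as nonsynonymous.
.pathwayCount <- function(i, j) {
  key <- paste0(i, "_", j)
  hit <- .codon_cache$paths[[key]]
  if (!is.null(hit)) return(hit)
  tab <- codonTables()
  diff_pos <- which(tab$base_of[i, ] != tab$base_of[j, ])
  d <- length(diff_pos)
  if (d == 0L) {
    res <- c(syn = 0, nonsyn = 0)
  } else {
    perms <- if (d == 1L) list(diff_pos) else {
      if (d == 2L) list(diff_pos, rev(diff_pos)) else {
        p <- list()
        for (a in 1:3) for (b in 1:3) for (cc in 1:3)
          if (length(unique(c(a, b, cc))) == 3L)
            p[[length(p) + 1L]] <- diff_pos[c(a, b, cc)]
        p
      }
    }
    walk <- function(order) {
      cur <- i
      syn <- 0L; nonsyn <- 0L; through_stop <- FALSE
      for (p in order) {
        target_base <- tab$base_of[j, p]
        step <- tab$neighbour[cur, p, target_base]
        nxt <- tab$neighbour_idx[cur, p, target_base]
        if (step == 1L) syn <- syn + 1L
        else nonsyn <- nonsyn + 1L          # stop-creating steps: nonsyn
        if (step == 3L && nxt != j) through_stop <- TRUE
        if (tab$is_stop[nxt] && nxt != j) through_stop <- TRUE
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn, bad = as.integer(through_stop))
    }
    res_all <- vapply(perms, walk, numeric(3))
    keep <- res_all["bad", ] == 0
    if (!any(keep)) keep <- rep(TRUE, ncol(res_all))
    res <- c(syn = mean(res_all["syn", keep]),
             nonsyn = mean(res_all["nonsyn", keep]))
  }
  if (is.null(.codon_cache$paths))
    .codon_cache$paths <- new.env(parent = emptyenv())
  .codon_cache$paths[[key]] <- res
  res
}

#' Pathway-averaged substitution counts between two codons
#'
#' Averages the number of synonymous and nonsynonymous single-nucleotide
#' steps over all minimal mutational pathways between two sense codons,
#' excluding pathways that pass through a stop codon.
#'
#' @param codon_a,codon_b Three-letter codon strings (ACGT alphabet).
#' @return Named numeric vector with elements `syn` and `nonsyn`.
#' @examples
#' codonPathwayCounts("TTT", "TTC")  # one synonymous step
#' @export
codonPathwayCounts <- function(codon_a, codon_b) {
  ia <- codonStringToIndex(codon_a)[[1]]
  ib <- codonStringToIndex(codon_b)[[1]]
  if (anyNA(c(ia, ib))) stop("codons must be unambiguous ACGT triplets")
  .pathwayCount(ia, ib)
}
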