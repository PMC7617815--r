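#' Simulate X/Y/outgroup gametolog triplets with known branch parameters
#'
#' Generates, per gene, a random ancestral coding sequence (uniform over
#' sense codons, no stops) and evolves it along the fixed topology
#' ((X,Y),OG) with a simple continuous-time substitution process: a
#' proposal picks a uniform random site and a uniform random alternative
#' base and is accepted with relative rate 1 if synonymous, omega if
#' nonsynonymous, and 0 if it would create a stop codon.  The number of
#' proposals per branch is tuned analytically so that the expected number
#' of accepted synonymous events equals the target synonymous divergence
#' times the ancestral NG86 synonymous site count, keeping per-gene
#' divergence stochastic.
#'
#' The X and Y branches each receive half of the X:Y synonymous target;
#' the outgroup branch receives `dS_X_OG - dS_XY/2` (all root-to-outgroup
#' divergence is placed on the outgroup branch).
#'
#' @param n_genes Number of gametolog triplets to simulate.
#' @param n_codons Codons per gene (>= 10).
#' @param dS_XY Target X:Y synonymous divergence (substitutions per
#'   synonymous site); e.g. 0.063 for an old stratum, 0.091 for a young
#'   actively recombining one.
#' @param dS_X_OG Target X:outgroup synonymous divergence (must be >=
#'   `dS_XY/2`).
#' @param omega_X,omega_Y,omega_OG dN/dS acceptance ratios per branch
#'   (>= 0; `omega_OG` defaults to `omega_X`).
#' @param region Region label stored with each gene.
#' @param gene_prefix Prefix for generated gene identifiers.
#' @return list with elements `x`, `y`, `og`, `anc`
#'   ([Biostrings::DNAStringSet] of length `n_genes`) and `truth`, a
#'   data.frame of realized per-gene, per-branch event counts and rates
#'   (`gene_id`, `region`, `branch`, `syn_events`, `nonsyn_events`,
#'   `S_sites`, `N_sites`, `dS_realized`, `dN_realized`).
#' @examples
#' set.seed(1)
#' trip <- simulateGametologTriplets(3, 50, dS_XY = 0.06, dS_X_OG = 0.12,
#'                                   omega_X = 0.3, omega_Y = 0.6)
#' @export
simulateGametologTriplets <- function(n_genes, n_codons, dS_XY, dS_X_OG,
                                      omega_X, omega_Y,
                                      omega_OG = omega_X,
                                      region = "Xpr",
                                      gene_prefix = paste0("g", region)) {
  if (n_codons < 10L) stop("n_codons must be >= 10")
  for (v in c(dS_XY, dS_X_OG, omega_X, omega_Y, omega_OG))
    if (!is.finite(v) || v < 0) stop("branch targets must be finite and >= 0")
  if (dS_X_OG < dS_XY / 2)
    stop("dS_X_OG must be at least dS_XY/2 on topology ((X,Y),OG)")
  tab <- codonTables()
  genes <- sprintf("%s_%04d", gene_prefix, seq_len(n_genes))
  x <- y <- og <- anc <- character(n_genes)
  truth <- vector("list", n_genes)
  branch_len <- c(X = dS_XY / 2, Y = dS_XY / 2, OG = dS_X_OG - dS_XY / 2)
  branch_om <- c(X = omega_X, Y = omega_Y, OG = omega_OG)
  for (g in seq_len(n_genes)) {
    anc_ci <- sample(tab$sense, n_codons, replace = TRUE)
    nt <- as.vector(t(tab$base_of[anc_ci, , drop = FALSE]))
    S_anc <- sum(tab$s_sites[anc_ci])
    N_anc <- 3 * n_codons - S_anc
    res <- lapply(names(branch_len), function(br) {
      evolveCds(nt, target_syn = branch_len[[br]] * S_anc,
                omega = branch_om[[br]])
    })
    names(res) <- names(branch_len)
    x[g] <- .ntToString(res$X$seq)
    y[g] <- .ntToString(res$Y$seq)
    og[g] <- .ntToString(res$OG$seq)
    anc[g] <- .ntToString(nt)
    truth[[g]] <- data.frame(
      gene_id = genes[g], region = region,
      branch = names(branch_len),
      syn_events = vapply(res, `[[`, 0L, "syn_events"),
      nonsyn_events = vapply(res, `[[`, 0L, "nonsyn_events"),
      S_sites = S_anc, N_sites = N_anc,
      dS_realized = vapply(res, `[[`, 0L, "syn_events") / S_anc,
      dN_realized = vapply(res, `[[`, 0L, "nonsyn_events") / N_anc,
      row.names = NULL)
  }
  list(x = .namedDss(x, genes), y = .namedDss(y, genes),
       og = .namedDss(og, genes), anc = .namedDss(anc, genes),
       truth = do.call(rbind, truth))
}

.namedDss <- function(x, nm) {
  s <- Biostrings::DNAStringSet(x)
  names(s) <- nm
  s
}

.ntToString <- function(nt) paste(.BASES[nt], collapse = "")

#' Evolve a coding sequence by the accept/reject proposal process
#'
#' @param nt Integer nucleotide vector (1=A..4=T), length divisible by 3,
#'   encoding a stop-free CDS.
#' @param target_syn Expected number of accepted synonymous events.
#' @param omega Acceptance probability for nonsynonymous proposals.
#' @return list with `seq` (evolved integer vector), `syn_events`,
#'   `nonsyn_events`, `proposals`.
#' @keywords internal
evolveCds <- function(nt, target_syn, omega) {
  tab <- codonTables()
  L <- length(nt)
  if (target_syn <= 0)
    return(list(seq = nt, syn_events = 0L, nonsyn_events = 0L,
                proposals = 0L))
  # probability that a uniform (site, alternative-base) proposal is
  # synonymous, computed on the input sequence
  ci <- codonIndex(nt[seq(1L, L, 3L)], nt[seq(2L, L, 3L)], nt[seq(3L, L, 3L)])
  n_syn_changes <- sum(tab$s_sites[ci]) * 3   # number of syn single-nt changes
  p_syn <- n_syn_changes / (3 * L)
  n_prop <- max(1L, as.integer(round(target_syn / p_syn)))
  syn <- 0L; nonsyn <- 0L
  sites <- sample.int(L, n_prop, replace = TRUE)
  alts <- sample.int(3L, n_prop, replace = TRUE)
  accept_u <- stats::runif(n_prop)
  for (k in seq_len(n_prop)) {
    s <- sites[k]
    cpos <- ((s - 1L) %% 3L) + 1L
    c0 <- s - cpos + 1L
    cod <- codonIndex(nt[c0], nt[c0 + 1L], nt[c0 + 2L])
    b <- setdiff(1:4, nt[s])[alts[k]]
    type <- tab$neighbour[cod, cpos, b]
    if (type == 1L) {
      nt[s] <- b; syn <- syn + 1L
    } else if (type == 2L && accept_u[k] < omega) {
      nt[s] <- b; nonsyn <- nonsyn + 1L
    }
  }
  list(seq = nt, syn_events = syn, nonsyn_events = nonsyn,
       proposals = n_prop)
}
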