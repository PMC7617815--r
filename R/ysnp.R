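#' Classify Y-diagnostic SNPs from cross segregation
#'
#' A site is called Y-linked when its segregation is exactly that of a
#' male-specific Y allele: the mother is homozygous; the father carries a
#' second allele B absent from the mother; every genome-sequenced son with
#' sufficient depth carries B; at least `1 - rna_son_dropout_tolerance` of
#' informative transcriptome-sequenced sons carry B (Y copies may be
#' weakly expressed); and no daughter of any datatype with sufficient
#' depth carries B — a single carrying daughter is a hard reject.  With
#' several families the rule must hold in every family where the site is
#' informative.
#'
#' An allele is deemed *carried* when it has at least `allele_min_count`
#' supporting reads making up at least `allele_min_frac` of the site
#' depth, which keeps isolated sequencing errors from toggling calls.
#'
#' @param observations data.frame of per-site allele depths with columns
#'   `gene_id` (or `chrom`), `pos`, `sample_id`, `A`, `C`, `G`, `T`,
#'   `depth`.
#' @param pedigree data.frame with `sample_id`, `family`, `sex`, `role`,
#'   `datatype` columns.
#' @param min_depth Minimum site depth for an individual to be
#'   informative.
#' @param min_informative_fraction Minimum fraction of progeny that must
#'   be informative at the site.
#' @param rna_son_dropout_tolerance Tolerated fraction of informative RNA
#'   sons without the Y allele.
#' @param mother_impurity_max Maximum minor-allele fraction for the
#'   mother to count as homozygous.
#' @param allele_min_count,allele_min_frac Allele presence thresholds.
#' @return data.frame of class `diagnostic_sites`: one row per tested
#'   site with `gene_id`, `pos`, `x_allele`, `y_allele`,
#'   `n_sons_support`, `n_sons_informative`, `n_daughters_checked`,
#'   `status` (`Y_linked` / `rejected`) and `reject_reason`.
#' @export
classifySites <- function(observations, pedigree, min_depth = 5L,
                          min_informative_fraction = 0.8,
                          rna_son_dropout_tolerance = 0.2,
                          mother_impurity_max = 0.1,
                          allele_min_count = 2L, allele_min_frac = 0.05) {
  obs <- data.table::as.data.table(observations)
  if ("chrom" %in% names(obs) && !"gene_id" %in% names(obs))
    data.table::setnames(obs, "chrom", "gene_id")
  ped <- data.table::as.data.table(pedigree)
  if (!"family" %in% names(ped)) ped[, family := "fam1"]
  need_sons <- ped[sex == "M" & role == "offspring", .N]
  need_dau <- ped[sex == "F" & role == "offspring", .N]
  if (need_sons < 1L || need_dau < 1L)
    stop("classification needs at least one son and one daughter")
  obs <- merge(obs, ped[, c("sample_id", "family", "sex", "role", "datatype")],
               by = "sample_id")
  all_zero <- obs[, list(tot = sum(depth)), by = list(gene_id, pos)][tot == 0L]
  if (nrow(all_zero))
    message(nrow(all_zero), " sites with all-zero depth skipped")

  carried <- function(count, depth)
    count >= allele_min_count & count / pmax(depth, 1L) >= allele_min_frac

  classify_family <- function(d) {
    # d: observations of one family at one site
    mo <- d[role == "mother"]
    fa <- d[role == "father"]
    res <- list(x_allele = NA_character_, y_allele = NA_character_,
                n_sons_support = 0L, n_sons_informative = 0L,
                n_daughters_checked = 0L, status = "rejected",
                reject_reason = NA_character_, informative = TRUE)
    if (nrow(mo) != 1L || mo$depth < min_depth) {
      res$reject_reason <- "mother_uninformative"; res$informative <- FALSE
      return(res)
    }
    mc <- unlist(mo[, .BASES, with = FALSE])
    m_major <- .BASES[which.max(mc)]
    if ((mo$depth - max(mc)) / mo$depth >= mother_impurity_max ||
        sum(carried(mc, mo$depth)) > 1L) {
      res$reject_reason <- "mother_heterozygous"
      return(res)
    }
    if (nrow(fa) != 1L || fa$depth < min_depth) {
      res$reject_reason <- "father_uninformative"; res$informative <- FALSE
      return(res)
    }
    fc <- unlist(fa[, .BASES, with = FALSE])
    cand <- .BASES[carried(fc, fa$depth)]
    cand <- setdiff(cand, m_major)
    # B must also be absent from the mother
    cand <- cand[!carried(mc[cand], mo$depth)]
    if (!length(cand)) {
      res$reject_reason <- "father_lacks_second_allele"
      return(res)
    }
    b <- cand[which.max(fc[cand])]
    res$x_allele <- m_major
    res$y_allele <- b

    prog <- d[role == "offspring"]
    informative <- prog$depth >= min_depth
    res_frac <- if (nrow(prog)) mean(informative) else 0
    sons <- prog[sex == "M" & depth >= min_depth]
    daughters <- prog[sex == "F" & depth >= min_depth]
    res$n_sons_informative <- nrow(sons)
    res$n_daughters_checked <- nrow(daughters)
    if (nrow(daughters)) {
      dau_carry <- carried(daughters[[b]], daughters$depth)
      if (any(dau_carry)) {
        res$reject_reason <- "daughter_carries_y"
        return(res)
      }
    }
    if (!nrow(sons)) {
      res$reject_reason <- "no_informative_sons"; res$informative <- FALSE
      return(res)
    }
    son_carry <- carried(sons[[b]], sons$depth)
    res$n_sons_support <- sum(son_carry)
    g_sons <- sons$datatype == "genomic"
    if (any(g_sons & !son_carry)) {
      res$reject_reason <- "genomic_son_lacks_y"
      return(res)
    }
    r_sons <- !g_sons
    if (any(r_sons) &&
        mean(son_carry[r_sons]) < 1 - rna_son_dropout_tolerance) {
      res$reject_reason <- "rna_son_dropout_excess"
      return(res)
    }
    if (res_frac < min_informative_fraction) {
      res$reject_reason <- "insufficient_informative_progeny"
      return(res)
    }
    res$status <- "Y_linked"
    res
  }

  out <- obs[, {
    fams <- split(.SD, family)
    per_fam <- lapply(fams, classify_family)
    inf <- vapply(per_fam, `[[`, TRUE, "informative")
    use <- if (any(inf)) per_fam[inf] else per_fam
    statuses <- vapply(use, `[[`, "", "status")
    ok <- all(statuses == "Y_linked") && any(inf)
    first_bad <- which(statuses != "Y_linked")
    pick <- if (ok) use[[1L]] else use[[first_bad[1L]]]
    list(x_allele = pick$x_allele, y_allele = pick$y_allele,
         n_sons_support = sum(vapply(use, `[[`, 0L, "n_sons_support")),
         n_sons_informative = sum(vapply(use, `[[`, 0L, "n_sons_informative")),
         n_daughters_checked = sum(vapply(use, `[[`, 0L, "n_daughters_checked")),
         status = if (ok) "Y_linked" else "rejected",
         reject_reason = if (ok) NA_character_ else pick$reject_reason)
  }, by = list(gene_id, pos)]
  data.table::setorder(out, gene_id, pos)
  out <- as.data.frame(out)
  class(out) <- c("diagnostic_sites", class(out))
  out
}
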