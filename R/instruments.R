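# cis-eQTL instrument selection: druggable-genome overlap, transcription
# start site window, FDR filter, confounder blocklist, greedy LD clumping.
# The TSS window boundary is inclusive (|pos - tss| <= window_bp); the FDR
# boundary is strict (fdr < threshold). Clumping uses an explicit LD matrix
# input, making the reference panel a swappable asset.

#' Restrict eQTL records to druggable genes
#'
#' Keeps only records whose gene appears in the annotation panel with a
#' non-missing druggable tier, and splits them per gene.
#'
#' @param eqtl_records eQTL summary-statistics data frame.
#' @param gene_panel gene annotation data frame (`symbol`, `chrom`, `tss`,
#'   `druggable_tier`).
#' @return named list mapping gene symbol to its eQTL records, with
#'   attribute `n_genes` holding the retained-gene count.
#' @export
overlap_druggable <- function(eqtl_records, gene_panel) {
  druggable <- gene_panel$symbol[!is.na(gene_panel$druggable_tier)]
  kept <- eqtl_records[eqtl_records$gene %in% druggable, , drop = FALSE]
  out <- split(kept, factor(kept$gene, levels = unique(kept$gene)))
  attr(out, "n_genes") <- length(out)
  out
}

#' Select cis-window instrument candidates for one gene
#'
#' Keeps SNPs with `|pos - tss| <= window_bp` (boundary inclusive) and
#' `fdr < fdr_threshold` (strict), attaching the signed distance to the TSS
#' and the instrument-strength F statistic `(beta/se)^2`. No automatic F
#' filter is applied; see `f_min` in [select_instruments()].
#'
#' @param records eQTL records for the gene.
#' @param gene one-row gene annotation (needs `symbol` and `tss`).
#' @param window_bp cis-window half-width in base pairs.
#' @param fdr_threshold strict per-record FDR cutoff.
#' @return candidate data frame with `distance_to_tss` and `f_statistic`.
#' @export
select_cis_window <- function(records, gene, window_bp = 100000L,
                              fdr_threshold = 0.05) {
  if (is.null(gene$tss) || !length(gene$tss) || is.na(gene$tss)) {
    dgmr_abort(sprintf("gene %s has no annotated TSS",
                       gene$symbol %||% "<unknown>"),
               "dgmr_annotation_error")
  }
  dist <- records$pos - gene$tss
  keep <- abs(dist) <= window_bp & records$fdr < fdr_threshold
  out <- records[keep, , drop = FALSE]
  out$distance_to_tss <- dist[keep]
  out$f_statistic <- (out$beta / out$se)^2
  out
}

#' Remove confounder-associated SNPs from a candidate set
#'
#' @param candidates instrument-candidate data frame.
#' @param blocklist character vector of SNP ids associated with confounders
#'   (e.g. adiposity or diabetes traits) to exclude.
#' @return list with `kept` and `removed` data frames; removed rows carry
#'   `reason = "confounder-associated"`.
#' @export
apply_blocklist <- function(candidates, blocklist) {
  hit <- candidates$snp_id %in% blocklist
  removed <- candidates[hit, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "confounder-associated"
  list(kept = candidates[!hit, , drop = FALSE], removed = removed)
}

#' Greedy LD clumping of instrument candidates
#'
#' Sorts candidates by eQTL p-value (ties broken by larger F statistic, then
#' lexicographic SNP id, so output is independent of input order), then
#' repeatedly keeps the best remaining SNP and discards all others with
#' `r^2 >= r2_threshold` to it. Retained SNPs are pairwise below the
#' threshold and every discarded SNP indexes a better-ranked retained one.
#'
#' @param candidates instrument-candidate data frame.
#' @param ld LD correlation matrix covering every candidate SNP.
#' @param r2_threshold clumping threshold on squared correlation.
#' @return the retained subset of `candidates`, in rank order.
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001) {
  if (!nrow(candidates)) return(candidates)
  missing <- setdiff(candidates$snp_id, rownames(ld))
  if (length(missing)) {
    dgmr_abort(sprintf("SNP(s) absent from LD matrix: %s",
                       paste(missing, collapse = ", ")),
               "dgmr_coverage_error")
  }
  f <- candidates$f_statistic %||% (candidates$beta / candidates$se)^2
  rank <- order(candidates$pval, -f, candidates$snp_id)
  ranked <- candidates[rank, , drop = FALSE]
  r2 <- ld[ranked$snp_id, ranked$snp_id, drop = FALSE]^2
  alive <- rep(TRUE, nrow(ranked))
  keep <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[r2[i, ] >= r2_threshold] <- FALSE
  }
  ranked[keep, , drop = FALSE]
}

#' Full instrument selection across a gene panel
#'
#' Applies, in order: druggable-genome overlap, per-gene cis-window and FDR
#' filtering, confounder blocklist, and greedy LD clumping. Returns one row
#' per retained instrument with selection metadata, plus a funnel of counts
#' (attribute `funnel`) mirroring how instrument attrition is reported.
#'
#' @param eqtl eQTL summary statistics (all genes).
#' @param gene_panel gene annotation data frame.
#' @param ld named list of per-gene LD matrices.
#' @param blocklist character vector of confounder SNP ids.
#' @param window_bp,fdr_threshold,clump_r2 selection parameters.
#' @param f_min optional minimum F statistic (default `NULL`: report F but
#'   do not filter).
#' @return instruments data frame (gene, snp_id, alleles, eaf, beta, se,
#'   pval, fdr, n, distance_to_tss, f_statistic).
#' @export
select_instruments <- function(eqtl, gene_panel, ld, blocklist = character(0),
                               window_bp = 100000L, fdr_threshold = 0.05,
                               clump_r2 = 0.001, f_min = NULL) {
  per_gene <- overlap_druggable(eqtl, gene_panel)
  out <- vector("list", length(per_gene))
  n_candidates <- 0L
  n_blocked <- 0L
  for (i in seq_along(per_gene)) {
    g <- names(per_gene)[i]
    ann <- gene_panel[gene_panel$symbol == g, , drop = FALSE]
    cand <- select_cis_window(per_gene[[i]], ann, window_bp, fdr_threshold)
    n_candidates <- n_candidates + nrow(cand)
    bl <- apply_blocklist(cand, blocklist)
    n_blocked <- n_blocked + nrow(bl$removed)
    cand <- bl$kept
    if (!is.null(f_min)) {
      cand <- cand[cand$f_statistic >= f_min, , drop = FALSE]
    }
    if (!nrow(cand)) next
    if (is.null(ld[[g]])) {
      dgmr_abort(sprintf("no LD matrix supplied for gene %s", g),
                 "dgmr_coverage_error")
    }
    out[[i]] <- clump(cand, ld[[g]], clump_r2)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) {
    res <- cbind(validate_summary_stats(
      data.frame(snp_id = character(0), chrom = character(0),
                 pos = integer(0), effect_allele = character(0),
                 other_allele = character(0), eaf = numeric(0),
                 beta = numeric(0), se = numeric(0), pval = numeric(0),
                 n = numeric(0), gene = character(0), fdr = numeric(0)),
      "eqtl"),
      data.frame(distance_to_tss = integer(0), f_statistic = numeric(0)))
  }
  rownames(res) <- NULL
  attr(res, "funnel") <- c(genes_in = length(unique(eqtl$gene)),
                           genes_druggable = length(per_gene),
                           candidates_cis = n_candidates,
                           candidates_blocked = n_blocked,
                           instruments = nrow(res),
                           genes_with_instruments =
                             length(unique(res$gene)))
  res
}
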