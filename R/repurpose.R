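# Drug-repurposing triage: intersect MR-significant genes with colocalized
# genes, derive the risk direction, and pass each gene's drug candidates
# through the three-level inclusion rubric plus a direction-of-effect
# concordance check. Safety/approval judgments are curated booleans in the
# drug table, not live database calls, which makes the rubric explicit and
# reproducible.

ACTION_VOCAB <- c("inhibitor", "antagonist", "antibody", "agonist",
                  "activator", "cofactor", "other")
LOWERING_ACTIONS <- c("inhibitor", "antagonist", "antibody")
RAISING_ACTIONS <- c("agonist", "activator", "cofactor")

#' Intersect MR-significant and colocalized genes
#'
#' A gene is prioritized when its MR q-value is below `fdr` and its
#' colocalization PP4 exceeds `pp4` (strict). The risk direction follows the
#' sign of the MR effect (positive log-odds per SD expression =
#' risk-increasing). Output is sorted by gene so it is invariant to input
#' order.
#'
#' @param mr_results `MrResult` data frame (needs `qval`).
#' @param coloc_results `ColocResult` data frame.
#' @param fdr MR significance threshold on the q-value.
#' @param pp4 colocalization threshold (strict).
#' @param tissue optional tissue label attached to every row.
#' @return `PrioritizedTarget` data frame: gene, tissue, method, nsnp, beta,
#'   qval, or_point, ci_low, ci_high, pp4, risk_direction.
#' @export
prioritize_targets <- function(mr_results, coloc_results, fdr = 0.05,
                               pp4 = 0.75, tissue = NA_character_) {
  orphan <- setdiff(coloc_results$gene, mr_results$gene)
  if (length(orphan)) {
    dgmr_abort(sprintf("gene(s) present in colocalization but absent from MR: %s",
                       paste(orphan, collapse = ", ")),
               "dgmr_consistency_error")
  }
  merged <- merge(mr_results, coloc_results[, c("gene", "n_snps", "pp4")],
                  by = "gene")
  keep <- merged$qval < fdr & is_colocalized(merged$pp4, pp4)
  out <- merged[keep, , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  data.frame(gene = out$gene, tissue = rep(tissue, nrow(out)),
             method = out$method,
             nsnp = out$nsnp, beta = out$beta, qval = out$qval,
             or_point = out$or_point, ci_low = out$ci_low,
             ci_high = out$ci_high, pp4 = out$pp4,
             risk_direction = ifelse(out$beta > 0, "risk_increasing",
                                     "protective"),
             stringsAsFactors = FALSE)
}

#' Apply the three-level drug inclusion criteria
#'
#' Level I requires a specific (non-broad-spectrum) action; Level II
#' established safety and efficacy; Level III regulatory approval.
#' `level_passed` is the highest level reached: 0 for broad-spectrum
#' agents, 1 for specific agents of uncertain safety, 2 for safe and
#' efficacious but unapproved agents, 3 for approved drugs. Rows are sorted
#' by descending level, then drug name.
#'
#' @param candidates drug-candidate data frame.
#' @return the same table with `level_passed` populated and sorted.
#' @export
apply_inclusion_criteria <- function(candidates) {
  level <- ifelse(candidates$broad_spectrum, 0L,
                  ifelse(!candidates$safety_established, 1L,
                         ifelse(!candidates$approved, 2L, 3L)))
  candidates$level_passed <- level
  out <- candidates[order(-candidates$level_passed, candidates$drug_name), ,
                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direction-of-effect concordance between a target and a drug
#'
#' A risk-increasing gene (expression raises disease odds) is concordant
#' with expression/activity-lowering actions (inhibitor, antagonist,
#' antibody); a protective gene with raising actions (agonist, activator,
#' cofactor); the opposite pairings are discordant; action type `other` is
#' indeterminate.
#'
#' @param risk_direction `"risk_increasing"` or `"protective"` (vectorized).
#' @param action_type drug action from the controlled vocabulary.
#' @return character vector: `"concordant"`, `"discordant"` or
#'   `"indeterminate"`.
#' @export
direction_concordance <- function(risk_direction, action_type) {
  bad <- setdiff(unique(action_type), ACTION_VOCAB)
  if (length(bad)) {
    dgmr_abort(sprintf("unknown action_type %s; allowed: %s",
                       paste(bad, collapse = ", "),
                       paste(ACTION_VOCAB, collapse = ", ")),
               "dgmr_vocabulary_error")
  }
  if (!all(risk_direction %in% c("risk_increasing", "protective"))) {
    dgmr_abort("risk_direction must be 'risk_increasing' or 'protective'",
               "dgmr_vocabulary_error")
  }
  out <- rep("indeterminate", length(action_type))
  lowering <- action_type %in% LOWERING_ACTIONS
  raising <- action_type %in% RAISING_ACTIONS
  risk <- risk_direction == "risk_increasing"
  out[risk & lowering] <- "concordant"
  out[risk & raising] <- "discordant"
  out[!risk & raising] <- "concordant"
  out[!risk & lowering] <- "discordant"
  out
}

#' Join prioritized targets with their drug candidates
#'
#' Attaches each prioritized gene's candidates, applies the inclusion
#' criteria and the direction-concordance check. Genes without candidates
#' are retained with NA drug columns so the target list stays complete.
#'
#' @param targets output of [prioritize_targets()].
#' @param drug_table drug-candidate data frame.
#' @return prioritization table, one row per target-drug pair, sorted by
#'   gene then descending `level_passed`.
#' @export
repurposing_table <- function(targets, drug_table) {
  if (!nrow(targets)) {
    return(data.frame(gene = character(0), tissue = character(0),
                      risk_direction = character(0), qval = numeric(0),
                      pp4 = numeric(0), or_point = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      drug_name = character(0), action_type = character(0),
                      max_phase = character(0), level_passed = integer(0),
                      concordance = character(0), stringsAsFactors = FALSE))
  }
  scored <- apply_inclusion_criteria(drug_table)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, , drop = FALSE]
    cand <- scored[which(scored$gene == tg$gene), , drop = FALSE]
    if (!nrow(cand)) {
      return(data.frame(gene = tg$gene, tissue = tg$tissue,
                        risk_direction = tg$risk_direction, qval = tg$qval,
                        pp4 = tg$pp4, or_point = tg$or_point,
                        ci_low = tg$ci_low, ci_high = tg$ci_high,
                        drug_name = NA_character_,
                        action_type = NA_character_,
                        max_phase = NA_character_,
                        level_passed = NA_integer_,
                        concordance = NA_character_,
                        stringsAsFactors = FALSE))
    }
    data.frame(gene = tg$gene, tissue = tg$tissue,
               risk_direction = tg$risk_direction, qval = tg$qval,
               pp4 = tg$pp4, or_point = tg$or_point, ci_low = tg$ci_low,
               ci_high = tg$ci_high, drug_name = cand$drug_name,
               action_type = cand$action_type, max_phase = cand$max_phase,
               level_passed = cand$level_passed,
               concordance = direction_concordance(
                 rep(tg$risk_direction, nrow(cand)), cand$action_type),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, -ifelse(is.na(out$level_passed), -1L,
                                     out$level_passed)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
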