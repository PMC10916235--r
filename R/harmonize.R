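# Allele harmonization: align exposure and outcome summary statistics to a
# common effect allele per SNP, resolving swapped alleles and strand flips
# and dropping ambiguous palindromic SNPs. Every decision is recorded in an
# auditable per-SNP ledger (`action`, `drop_reason`).

HARMONIZE_ACTIONS <- c("none", "swap", "strand_flip", "swap_and_flip",
                       "dropped")

#' Harmonize one exposure/outcome SNP pair
#'
#' Rules, applied in order:
#' * identical allele pair: action `none`;
#' * swapped alleles: outcome beta negated, `eaf_out := 1 - eaf_out`,
#'   action `swap`;
#' * complementary alleles: outcome relabelled to the opposite strand and
#'   compared again (`strand_flip` / `swap_and_flip`);
#' * palindromic SNPs (A/T or C/G): nominal allele matching is applied
#'   first, then the pair is kept only when both allele frequencies are on
#'   the same side of 0.5 and both outside
#'   `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`; otherwise dropped
#'   (`palindromic-ambiguous`, or `palindromic-no-frequency` when the
#'   outcome frequency is missing);
#' * incompatible allele sets: dropped (`allele-mismatch`);
#' * matched non-palindromic SNPs whose frequencies disagree by more than
#'   `freq_tolerance` are dropped (`frequency-discordant`) - this catches
#'   genome-build or population mismatches.
#'
#' @param exposure,outcome one-row summary-statistics data frames for the
#'   same SNP.
#' @param palindrome_eaf_limit ambiguity band half-width for palindromic
#'   SNPs (default 0.42, the community convention).
#' @param freq_tolerance maximum allowed |eaf_exp - eaf_out| after alignment
#'   for non-palindromic SNPs.
#' @return a one-row `Instrument` data frame: `snp_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `n_exp`, `n_out`,
#'   `action`, `drop_reason` (plus `gene` when the exposure carries one).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                      freq_tolerance = 0.2) {
  if (!identical(as.character(exposure$snp_id),
                 as.character(outcome$snp_id))) {
    dgmr_abort("exposure and outcome rows refer to different SNPs",
               "dgmr_usage_error")
  }
  e1 <- toupper(exposure$effect_allele); e2 <- toupper(exposure$other_allele)
  o1 <- toupper(outcome$effect_allele); o2 <- toupper(outcome$other_allele)
  beta_out <- outcome$beta
  eaf_out <- outcome$eaf
  action <- NA_character_
  reason <- NA_character_

  swap_out <- function() {
    beta_out <<- -beta_out
    if (!is.na(eaf_out)) eaf_out <<- 1 - eaf_out
  }

  if (is_palindromic(e1, e2)) {
    if (setequal(c(o1, o2), c(e1, e2))) {
      if (o1 == e2) swap_out()
      lim <- palindrome_eaf_limit
      if (is.na(eaf_out)) {
        action <- "dropped"; reason <- "palindromic-no-frequency"
      } else if (is.na(exposure$eaf)) {
        action <- "dropped"; reason <- "palindromic-no-frequency"
      } else {
        unambiguous <- (exposure$eaf < lim & eaf_out < lim) |
          (exposure$eaf > 1 - lim & eaf_out > 1 - lim)
        if (unambiguous) {
          action <- if (o1 == e2) "swap" else "none"
        } else {
          action <- "dropped"; reason <- "palindromic-ambiguous"
        }
      }
    } else {
      action <- "dropped"; reason <- "allele-mismatch"
    }
  } else if (setequal(c(o1, o2), c(e1, e2))) {
    if (o1 == e1) action <- "none" else { swap_out(); action <- "swap" }
  } else if (setequal(c(COMPLEMENT[o1], COMPLEMENT[o2]), c(e1, e2))) {
    if (COMPLEMENT[[o1]] == e1) action <- "strand_flip"
    else { swap_out(); action <- "swap_and_flip" }
  } else {
    action <- "dropped"; reason <- "allele-mismatch"
  }

  if (action != "dropped" && !is_palindromic(e1, e2) &&
      !is.na(exposure$eaf) && !is.na(eaf_out) &&
      abs(exposure$eaf - eaf_out) > freq_tolerance) {
    action <- "dropped"; reason <- "frequency-discordant"
  }

  data.frame(gene = exposure$gene %||% NA_character_,
             snp_id = as.character(exposure$snp_id),
             effect_allele = e1, other_allele = e2,
             beta_exp = exposure$beta, se_exp = exposure$se,
             beta_out = beta_out, se_out = outcome$se,
             eaf_exp = exposure$eaf, eaf_out = eaf_out,
             n_exp = exposure$n, n_out = outcome$n,
             pval_exp = exposure$pval, pval_out = outcome$pval,
             action = action, drop_reason = reason,
             stringsAsFactors = FALSE)
}

#' Harmonize an exposure table against an outcome table
#'
#' Joins by `snp_id` and applies [harmonize()] per shared SNP. SNPs absent
#' from the outcome are reported as dropped with reason
#' `"missing-from-outcome"` (no proxy substitution is attempted).
#'
#' @param exposure exposure summary statistics (e.g. selected instruments).
#' @param outcome outcome summary statistics.
#' @inheritParams harmonize
#' @return the harmonization ledger: one row per exposure SNP. Rows with
#'   `action != "dropped"` are usable instruments.
#' @export
harmonize_tables <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                             freq_tolerance = 0.2) {
  idx <- match(exposure$snp_id, outcome$snp_id)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    e <- exposure[i, , drop = FALSE]
    if (is.na(idx[i])) {
      rows[[i]] <- data.frame(gene = e$gene %||% NA_character_,
                              snp_id = as.character(e$snp_id),
                              effect_allele = e$effect_allele,
                              other_allele = e$other_allele,
                              beta_exp = e$beta, se_exp = e$se,
                              beta_out = NA_real_, se_out = NA_real_,
                              eaf_exp = e$eaf, eaf_out = NA_real_,
                              n_exp = e$n, n_out = NA_real_,
                              pval_exp = e$pval, pval_out = NA_real_,
                              action = "dropped",
                              drop_reason = "missing-from-outcome",
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- harmonize(e, outcome[idx[i], , drop = FALSE],
                             palindrome_eaf_limit, freq_tolerance)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), snp_id = character(0),
                      effect_allele = character(0), other_allele = character(0),
                      beta_exp = numeric(0), se_exp = numeric(0),
                      beta_out = numeric(0), se_out = numeric(0),
                      eaf_exp = numeric(0), eaf_out = numeric(0),
                      n_exp = numeric(0), n_out = numeric(0),
                      pval_exp = numeric(0), pval_out = numeric(0),
                      action = character(0), drop_reason = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Keep only usable rows of a harmonization ledger
#' @param ledger output of [harmonize_tables()].
#' @return rows with `action != "dropped"`.
#' @export
harmonized_instruments <- function(ledger) {
  ledger[ledger$action != "dropped", , drop = FALSE]
}
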