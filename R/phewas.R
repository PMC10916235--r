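# Phenome-wide MR: repeat the MR of one gene's instrument(s) across a panel
# of non-disease-of-interest outcomes as an on-target safety screen, with
# one BH family across the whole panel.

#' Phenome-wide MR scan of one gene's instruments
#'
#' For each trait in the panel the gene's instruments are harmonized against
#' that trait's summary statistics and routed through [run_gene_mr()] (Wald
#' ratio for one instrument, IVW for several) - per-trait estimates are
#' identical to calling the MR core directly. Benjamini-Hochberg adjustment
#' spans all testable traits as a single family. Traits in which no
#' instrument SNP is present (or all are dropped at harmonization) are
#' reported with `testable = FALSE` rather than silently skipped, and are
#' excluded from the BH family size.
#'
#' @param instruments instruments data frame for one gene.
#' @param panel either a long-format data frame of GWAS-kind records with
#'   additional `trait_id` (and optionally `trait_label`) columns, or a list
#'   of `list(trait_id, trait_label, records)` entries.
#' @param config options forwarded to [run_gene_mr()] and harmonization.
#' @return data frame, one row per trait: `trait_id`, `trait_label`,
#'   `testable`, `method`, `nsnp`, `beta`, `se`, `pval`, `qval`,
#'   `or_point`, `ci_low`, `ci_high`, ordered by `qval`.
#' @export
phenome_scan <- function(instruments, panel, config = list()) {
  if (is.data.frame(panel)) {
    require_columns(panel, c("trait_id"), "<panel>")
    if (!"trait_label" %in% names(panel)) panel$trait_label <- panel$trait_id
    ids <- unique(panel$trait_id)
    panel <- lapply(ids, function(id) {
      sub <- panel[panel$trait_id == id, , drop = FALSE]
      list(trait_id = id, trait_label = sub$trait_label[1L],
           records = sub)
    })
  }
  if (!length(panel)) {
    dgmr_abort("empty phenome panel", "dgmr_usage_error")
  }
  rows <- lapply(seq_along(panel), function(i) {
    trait <- panel[[i]]
    ledger <- harmonize_tables(instruments, trait$records,
                               config$palindrome_eaf_limit %||% 0.42,
                               config$freq_tolerance %||% 0.2)
    ivs <- harmonized_instruments(ledger)
    base <- data.frame(trait_id = trait$trait_id,
                       trait_label = trait$trait_label %||% trait$trait_id,
                       testable = nrow(ivs) > 0L, method = NA_character_,
                       nsnp = 0L, beta = NA_real_, se = NA_real_,
                       pval = NA_real_, qval = NA_real_,
                       or_point = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, stringsAsFactors = FALSE)
    if (!nrow(ivs)) return(base)
    cfg <- config
    cfg$seed <- child_seed(config$seed %||% 1L, i)
    est <- run_gene_mr(ivs, cfg)
    base$method <- est$method
    base$nsnp <- est$nsnp
    base$beta <- est$beta
    base$se <- est$se
    base$pval <- est$pval
    base$or_point <- est$or_point
    base$ci_low <- est$ci_low
    base$ci_high <- est$ci_high
    base
  })
  out <- do.call(rbind, rows)
  testable <- out$testable
  if (any(testable)) out$qval[testable] <- bh_fdr(out$pval[testable])
  out[order(!out$testable, out$qval), , drop = FALSE]
}

#' Simulate a phenome outcome panel for one gene's region
#'
#' Null traits draw outcome effects of zero at every SNP; an optional set of
#' implanted traits receives a true mediated effect `theta`. Schema matches
#' the long-format input of [phenome_scan()].
#'
#' @param region region from [simulate_region()].
#' @param truth truth from [simulate_truth()] (eQTL side of the gene).
#' @param n_traits panel size.
#' @param implant integer indices of traits given a true effect.
#' @param theta true effect for implanted traits.
#' @param n_cases,n_controls per-trait GWAS sample sizes.
#' @param seed RNG seed.
#' @return long-format data frame with `trait_id`, `trait_label` plus
#'   GWAS-kind summary-statistic columns.
#' @export
simulate_phenome_panel <- function(region, truth, n_traits = 200L,
                                   implant = integer(0), theta = 0.3,
                                   n_cases = 5000L, n_controls = 50000L,
                                   seed = 1L) {
  rows <- lapply(seq_len(n_traits), function(i) {
    tr <- truth
    if (i %in% implant) {
      tr$scenario <- "causal_shared"
      tr$theta <- theta
    } else {
      tr$scenario <- "null"
      tr$theta <- 0
    }
    rec <- simulate_gwas_summary(region, tr, n_cases, n_controls,
                                 seed = child_seed(seed, i))
    rec$trait_id <- sprintf("trait%04d", i)
    rec$trait_label <- sprintf("synthetic trait %d", i)
    rec
  })
  do.call(rbind, rows)
}
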