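# Ground-truth summary-statistics simulator. Simulation happens directly at
# the summary-statistic level: marginal effects are the LD-propagated true
# effects (b_marg = R %*% b_true) and estimates are drawn from the sampling
# distribution implied by allele frequency and sample size. No
# individual-level genotypes are generated; that is sufficient for every
# pipeline stage and orders of magnitude faster.

#' Simulate an LD region around a gene
#'
#' Builds a block-diagonal AR(1) LD structure: within a block
#' `r(i, j) = rho^|i-j|`, across blocks `r = 0`. Block boundaries double as
#' ground-truth "independent region" markers for clumping and for the
#' distinct-causal-variant colocalization scenario. SNP positions are
#' strictly increasing within +/-100 kb of the nominal transcription start
#' site; allele pairs are non-palindromic unless `palindromic_fraction > 0`.
#'
#' @param n_snps number of SNPs (>= 1).
#' @param block_size SNPs per LD block (>= 1).
#' @param rho within-block AR(1) correlation, in \[0, 1).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param seed RNG seed.
#' @param chrom chromosome label.
#' @param tss nominal transcription start site (bp).
#' @param snp_prefix prefix for generated SNP ids (keep unique across genes).
#' @param palindromic_fraction fraction of SNPs given A/T or C/G allele pairs.
#' @return a list with elements `ld` (correlation matrix with SNP-id
#'   dimnames), `snp_ids`, `maf`, `pos`, `block` (block index per SNP),
#'   `effect_allele`, `other_allele`, `chrom`, `tss`.
#' @export
simulate_region <- function(n_snps, block_size = 10L, rho = 0.8,
                            maf_range = c(0.05, 0.5), seed = 1L,
                            chrom = "1", tss = 1000000L,
                            snp_prefix = "rs", palindromic_fraction = 0) {
  if (n_snps < 1L || block_size < 1L) {
    dgmr_abort("`n_snps` and `block_size` must be >= 1", "dgmr_parameter_error")
  }
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    dgmr_abort("`rho` must lie in [0, 1)", "dgmr_parameter_error")
  }
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L]) {
    dgmr_abort("`maf_range` must be an increasing pair within (0, 0.5]",
               "dgmr_parameter_error")
  }
  with_seed(seed, {
    block <- rep(seq_len(ceiling(n_snps / block_size)),
                 each = block_size)[seq_len(n_snps)]
    idx <- seq_len(n_snps)
    ld <- rho ^ abs(outer(idx, idx, "-"))
    ld[outer(block, block, "!=")] <- 0
    snp_ids <- sprintf("%s%d", snp_prefix, idx)
    dimnames(ld) <- list(snp_ids, snp_ids)
    maf <- stats::runif(n_snps, maf_range[1L], maf_range[2L])
    window <- max(100000L, n_snps + 1L)
    pos <- sort(sample.int(2L * window, n_snps)) + as.integer(tss) - window
    pos <- pmax(pos, 1L)
    # ordered non-palindromic pairs (effect, other); complements excluded
    pairs <- expand.grid(effect = ALLELES, other = ALLELES,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$effect != pairs$other, ]
    nonpal <- pairs[COMPLEMENT[pairs$effect] != pairs$other, ]
    pal <- pairs[COMPLEMENT[pairs$effect] == pairs$other, ]
    take_pal <- stats::runif(n_snps) < palindromic_fraction
    pick_np <- sample.int(nrow(nonpal), n_snps, replace = TRUE)
    pick_p <- sample.int(nrow(pal), n_snps, replace = TRUE)
    effect_allele <- ifelse(take_pal, pal$effect[pick_p], nonpal$effect[pick_np])
    other_allele <- ifelse(take_pal, pal$other[pick_p], nonpal$other[pick_np])
    list(ld = ld, snp_ids = snp_ids, maf = maf, pos = pos, block = block,
         effect_allele = effect_allele, other_allele = other_allele,
         chrom = as.character(chrom), tss = as.integer(tss))
  })
}

#' Define the generative truth for one gene
#'
#' @param gene gene symbol.
#' @param region region as returned by [simulate_region()].
#' @param scenario one of `"null"` (expression has eQTLs but no effect on the
#'   outcome), `"causal_shared"` (outcome effects are `theta` times the
#'   marginal eQTL effects, so the causal variants coincide),
#'   `"causal_distinct"` (outcome signal sits on SNPs in LD blocks disjoint
#'   from the eQTL causal block), `"pleiotropic"` (adds direct SNP-outcome
#'   effects on top of the mediated path).
#' @param theta true causal effect of expression on the outcome, log-odds per
#'   SD of expression. Must be 0 for the null scenario.
#' @param eqtl_beta true cis-eQTL effect at each causal SNP (SD units).
#' @param n_causal number of eQTL causal SNPs.
#' @param seed RNG seed for causal-SNP placement.
#' @return a `SimulationTruth` list: `gene`, `scenario`, `theta`,
#'   `causal_snp_ids`, `outcome_snp_ids`, `eqtl_betas` (named, full region),
#'   `seed`.
#' @export
simulate_truth <- function(gene, region,
                           scenario = c("null", "causal_shared",
                                        "causal_distinct", "pleiotropic"),
                           theta = 0, eqtl_beta = 0.345, n_causal = 1L,
                           seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "null" && theta != 0) {
    dgmr_abort("null scenario requires theta = 0", "dgmr_parameter_error")
  }
  with_seed(seed, {
    ids <- region$snp_ids
    causal <- sample(ids, min(n_causal, length(ids)))
    betas <- stats::setNames(numeric(length(ids)), ids)
    betas[causal] <- eqtl_beta
    outcome_ids <- character(0L)
    if (scenario == "causal_distinct") {
      causal_blocks <- unique(region$block[match(causal, ids)])
      free <- ids[!(region$block %in% causal_blocks)]
      if (!length(free)) {
        dgmr_abort("causal_distinct needs at least one LD block free of eQTL causal SNPs",
                   "dgmr_parameter_error")
      }
      outcome_ids <- sample(free, min(n_causal, length(free)))
    } else if (scenario %in% c("causal_shared", "pleiotropic")) {
      outcome_ids <- causal
    }
    list(gene = gene, scenario = scenario, theta = theta,
         causal_snp_ids = causal, outcome_snp_ids = outcome_ids,
         eqtl_betas = betas, seed = as.integer(seed))
  })
}

#' Simulate cis-eQTL summary statistics for a region
#'
#' Marginal true effects are `R %*% b_true`; each estimate adds independent
#' Normal noise with sd equal to its standard error
#' `1 / sqrt(2 * maf * (1 - maf) * n_eqtl)` (expression standardized to SD
#' 1). Two-sided z p-values; per-region Benjamini-Hochberg FDR, emulating a
#' "significant cis-eQTL" release.
#'
#' @param region region from [simulate_region()].
#' @param truth truth from [simulate_truth()].
#' @param n_eqtl eQTL study sample size (>= 2).
#' @param seed RNG seed.
#' @return eQTL-kind summary-statistics data frame.
#' @export
simulate_eqtl_summary <- function(region, truth, n_eqtl = 31684L, seed = 1L) {
  if (n_eqtl < 2L) {
    dgmr_abort("`n_eqtl` must be >= 2", "dgmr_parameter_error")
  }
  with_seed(seed, {
    b_marg <- as.vector(region$ld %*% truth$eqtl_betas[region$snp_ids])
    se <- 1 / sqrt(2 * region$maf * (1 - region$maf) * n_eqtl)
    beta <- b_marg + stats::rnorm(length(se)) * se
    z <- beta / se
    pval <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    data.frame(snp_id = region$snp_ids, chrom = region$chrom,
               pos = region$pos, effect_allele = region$effect_allele,
               other_allele = region$other_allele, eaf = region$maf,
               beta = beta, se = se, pval = pval, n = n_eqtl,
               gene = truth$gene, fdr = stats::p.adjust(pval, "BH"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate case-control GWAS summary statistics for a region
#'
#' Under `causal_shared` the per-SNP true outcome effect is `theta` times the
#' marginal eQTL true effect; under `causal_distinct` a direct effect `theta`
#' sits on the disjoint outcome SNP set and is propagated through LD; the
#' `pleiotropic` scenario adds Normal(0, `pleiotropy_sd`) direct effects.
#' Standard errors use the binary-trait approximation
#' `1 / sqrt(2 * maf * (1 - maf) * n_eff)` with effective sample size
#' `n_eff = 4 / (1/n_cases + 1/n_controls)` and unit phenotype-variance
#' proxy (a documented approximation, not an estimand). A configurable
#' fraction of rows has alleles swapped (beta negated, eaf reflected) and/or
#' strand-flipped to exercise harmonization.
#'
#' @param region region from [simulate_region()].
#' @param truth truth from [simulate_truth()].
#' @param n_cases,n_controls case and control counts.
#' @param pleiotropy_sd sd of direct pleiotropic effects (log-odds).
#' @param flip_fraction fraction of rows with effect/other alleles swapped.
#' @param strand_fraction fraction of rows reported on the opposite strand.
#' @param seed RNG seed.
#' @return GWAS-kind summary-statistics data frame (column `n` holds
#'   `n_cases + n_controls`).
#' @export
simulate_gwas_summary <- function(region, truth, n_cases = 27205L,
                                  n_controls = 110881L, pleiotropy_sd = 0,
                                  flip_fraction = 0, strand_fraction = 0,
                                  seed = 1L) {
  if (n_cases < 1L || n_controls < 1L) {
    dgmr_abort("`n_cases` and `n_controls` must be >= 1", "dgmr_parameter_error")
  }
  stopifnot_scalar_prob(flip_fraction, "flip_fraction")
  stopifnot_scalar_prob(strand_fraction, "strand_fraction")
  with_seed(seed, {
    ids <- region$snp_ids
    b_marg_eqtl <- as.vector(region$ld %*% truth$eqtl_betas[ids])
    b_out <- switch(truth$scenario,
      null = numeric(length(ids)),
      causal_shared = truth$theta * b_marg_eqtl,
      pleiotropic = truth$theta * b_marg_eqtl,
      causal_distinct = {
        direct <- stats::setNames(numeric(length(ids)), ids)
        direct[truth$outcome_snp_ids] <- truth$theta
        as.vector(region$ld %*% direct)
      })
    if (truth$scenario == "pleiotropic" && pleiotropy_sd > 0) {
      b_out <- b_out +
        as.vector(region$ld %*% stats::rnorm(length(ids), 0, pleiotropy_sd))
    }
    n_eff <- 4 / (1 / n_cases + 1 / n_controls)
    se <- 1 / sqrt(2 * region$maf * (1 - region$maf) * n_eff)
    beta <- b_out + stats::rnorm(length(se)) * se
    pval <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
    out <- data.frame(snp_id = ids, chrom = region$chrom, pos = region$pos,
                      effect_allele = region$effect_allele,
                      other_allele = region$other_allele, eaf = region$maf,
                      beta = beta, se = se, pval = pval,
                      n = n_cases + n_controls, stringsAsFactors = FALSE)
    swap <- stats::runif(nrow(out)) < flip_fraction
    if (any(swap)) {
      tmp <- out$effect_allele[swap]
      out$effect_allele[swap] <- out$other_allele[swap]
      out$other_allele[swap] <- tmp
      out$beta[swap] <- -out$beta[swap]
      out$eaf[swap] <- 1 - out$eaf[swap]
    }
    flip <- stats::runif(nrow(out)) < strand_fraction
    if (any(flip)) {
      out$effect_allele[flip] <- unname(COMPLEMENT[out$effect_allele[flip]])
      out$other_allele[flip] <- unname(COMPLEMENT[out$other_allele[flip]])
    }
    out
  })
}

#' Curated drug-candidate table for the TBK1/TNFSF12/GPX3 case study
#'
#' Hand-coded replica of the published candidate set for these three Tier-1
#' druggable genes: two approved specific TBK1 inhibitors (fostamatinib,
#' amlexanox), two anti-TNFSF12 antibodies still in phase 1-2 trials with
#' unestablished safety (BIIB-023, RG-7212), and the phase-3 broad-spectrum
#' cofactor glutathione for GPX3.
#'
#' @return drug-candidate data frame.
#' @export
example_drug_table <- function() {
  data.frame(
    gene = c("TBK1", "TBK1", "TNFSF12", "TNFSF12", "GPX3"),
    drug_name = c("fostamatinib", "amlexanox", "BIIB-023", "RG-7212",
                  "glutathione"),
    action_type = c("inhibitor", "inhibitor", "antibody", "antibody",
                    "cofactor"),
    max_phase = c("approved", "approved", "2", "1", "3"),
    broad_spectrum = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    safety_established = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    approved = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    level_passed = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Archetypes with known expected inclusion levels.
DRUG_ARCHETYPES <- data.frame(
  action_type = c("inhibitor", "antibody", "cofactor", "agonist", "activator"),
  max_phase = c("approved", "2", "3", "3", "1"),
  broad_spectrum = c(FALSE, FALSE, TRUE, FALSE, FALSE),
  safety_established = c(TRUE, FALSE, TRUE, TRUE, FALSE),
  approved = c(TRUE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Simulate a gene-to-drug candidate table
#'
#' Each gene receives one or two candidates drawn from archetypes spanning
#' the inclusion lattice (approved specific inhibitors, uncertain-safety
#' antibodies, broad-spectrum cofactors, ...), so expected Level I-III
#' outcomes are known by construction. Combine with [example_drug_table()]
#' for the curated case-study rows.
#'
#' @param genes character vector of gene symbols (may be empty).
#' @param seed RNG seed.
#' @return drug-candidate data frame (header-only when `genes` is empty).
#' @export
simulate_drug_table <- function(genes, seed = 1L) {
  empty <- example_drug_table()[0L, ]
  if (!length(genes)) return(empty)
  with_seed(seed, {
    rows <- lapply(seq_along(genes), function(i) {
      k <- sample.int(2L, 1L)
      arch <- DRUG_ARCHETYPES[sample.int(nrow(DRUG_ARCHETYPES), k), ,
                              drop = FALSE]
      data.frame(gene = genes[i],
                 drug_name = sprintf("cmpd-%s-%d", genes[i], seq_len(k)),
                 arch, level_passed = NA_integer_, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a full input bundle with known ground truth
#'
#' Generates, for `n_genes` genes each with its own LD region, the complete
#' set of pipeline inputs: gene annotation (druggable tiers), eQTL and GWAS
#' summary statistics, per-gene LD matrices, a drug-candidate table (curated
#' case-study rows plus simulated rows), an empty-by-default confounder
#' blocklist, and the truth table. The first `n_causal` genes follow
#' `causal_scenario` with effect `theta`; the remainder are null genes whose
#' expression still has a real cis-eQTL (so instruments exist) but no effect
#' on the outcome.
#'
#' Defaults mirror the emulated study: eQTL n = 31,684 (blood), GWAS 27,205
#' cases / 110,881 controls, one causal cis-SNP per gene with effect 0.345
#' SD (about 5% expression variance explained at typical MAF).
#'
#' @param n_genes number of genes.
#' @param n_causal number of non-null genes (placed first, named after the
#'   case-study genes when possible).
#' @param causal_scenario scenario for the non-null genes.
#' @param theta causal effect for non-null genes (log-odds per SD).
#' @param n_snps,block_size,rho region shape parameters.
#' @param eqtl_beta true causal cis-eQTL effect.
#' @param n_eqtl,n_cases,n_controls sample sizes.
#' @param flip_fraction,strand_fraction GWAS allele-representation noise.
#' @param pleiotropy_sd direct-effect sd for `pleiotropic` genes.
#' @param tissue tissue label recorded on outputs.
#' @param seed RNG seed (every per-gene draw derives from it).
#' @param out_dir optional directory; when given, all inputs are written as
#'   the TSV bundle consumed by [run_pipeline()].
#' @return invisible list with elements `genes`, `eqtl`, `gwas`, `ld`
#'   (named list of matrices), `drugs`, `blocklist`, `truth`, `tissue`.
#' @export
simulate_study <- function(n_genes = 50L, n_causal = 5L,
                           causal_scenario = "causal_shared", theta = 0.25,
                           n_snps = 20L, block_size = 5L, rho = 0.8,
                           eqtl_beta = 0.345, n_eqtl = 31684L,
                           n_cases = 27205L, n_controls = 110881L,
                           flip_fraction = 0, strand_fraction = 0,
                           pleiotropy_sd = 0, tissue = "blood", seed = 1L,
                           out_dir = NULL) {
  if (n_causal > n_genes) {
    dgmr_abort("`n_causal` cannot exceed `n_genes`", "dgmr_parameter_error")
  }
  case_genes <- c("TBK1", "TNFSF12", "GPX3", "RESP18", "CD68")
  genes <- sprintf("SYNG%04d", seq_len(n_genes))
  if (n_causal > 0L) {
    genes[seq_len(min(n_causal, length(case_genes)))] <-
      case_genes[seq_len(min(n_causal, length(case_genes)))]
  }
  tiers <- with_seed(child_seed(seed, 0L), {
    t <- sample(c(1L, 2L, 3L, NA_integer_), n_genes, replace = TRUE,
                prob = c(0.4, 0.3, 0.2, 0.1))
    t[seq_len(n_causal)] <- 1L
    t
  })
  eqtl <- vector("list", n_genes)
  gwas <- vector("list", n_genes)
  ld <- vector("list", n_genes)
  truth_rows <- vector("list", n_genes)
  ann <- data.frame(symbol = genes,
                    chrom = as.character(rep_len(1:22, n_genes)),
                    tss = as.integer(1000000 + 2000000 * (seq_len(n_genes) - 1)),
                    druggable_tier = tiers, stringsAsFactors = FALSE)
  for (i in seq_len(n_genes)) {
    gseed <- child_seed(seed, i)
    region <- simulate_region(n_snps, block_size, rho, seed = gseed,
                              chrom = ann$chrom[i], tss = ann$tss[i],
                              snp_prefix = sprintf("rs%d_", i))
    scenario <- if (i <= n_causal) causal_scenario else "null"
    truth <- simulate_truth(genes[i], region, scenario,
                            theta = if (i <= n_causal) theta else 0,
                            eqtl_beta = eqtl_beta, seed = gseed + 1L)
    eqtl[[i]] <- simulate_eqtl_summary(region, truth, n_eqtl,
                                       seed = gseed + 2L)
    gwas[[i]] <- simulate_gwas_summary(region, truth, n_cases, n_controls,
                                       pleiotropy_sd = pleiotropy_sd,
                                       flip_fraction = flip_fraction,
                                       strand_fraction = strand_fraction,
                                       seed = gseed + 3L)
    ld[[i]] <- region$ld
    truth_rows[[i]] <- data.frame(
      gene = genes[i], scenario = scenario, theta = truth$theta,
      causal_snp_ids = paste(truth$causal_snp_ids, collapse = ","),
      outcome_snp_ids = paste(truth$outcome_snp_ids, collapse = ","),
      seed = gseed, stringsAsFactors = FALSE)
  }
  names(ld) <- genes
  drugs <- rbind(example_drug_table(),
                 simulate_drug_table(utils::head(setdiff(genes, case_genes),
                                                 10L),
                   seed = child_seed(seed, n_genes + 1L)))
  bundle <- list(genes = ann, eqtl = do.call(rbind, eqtl),
                 gwas = do.call(rbind, gwas), ld = ld, drugs = drugs,
                 blocklist = character(0L),
                 truth = do.call(rbind, truth_rows), tissue = tissue)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

#' Write a simulated input bundle as the on-disk TSV layout
#' @param bundle list from [simulate_study()].
#' @param out_dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(file.path(out_dir, "ld"), recursive = TRUE, showWarnings = FALSE)
  write_gene_annotation(bundle$genes, file.path(out_dir, "genes.tsv"))
  write_summary_stats(bundle$eqtl, file.path(out_dir, "eqtl.tsv"))
  write_summary_stats(bundle$gwas, file.path(out_dir, "gwas.tsv"))
  for (g in names(bundle$ld)) {
    write_ld_matrix(bundle$ld[[g]], file.path(out_dir, "ld",
                                              paste0(g, ".tsv")))
  }
  utils::write.table(bundle$drugs[, c(DRUG_TABLE_COLS)],
                     file.path(out_dir, "drugs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_blocklist(bundle$blocklist, file.path(out_dir, "blocklist.txt"))
  utils::write.table(bundle$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Read an input bundle from its on-disk TSV layout
#' @param dir directory written by [write_bundle()].
#' @return bundle list as produced by [simulate_study()].
#' @export
read_bundle <- function(dir) {
  genes <- read_gene_annotation(file.path(dir, "genes.tsv"))
  ld_files <- list.files(file.path(dir, "ld"), pattern = "\\.tsv$",
                         full.names = TRUE)
  ld <- lapply(ld_files, read_ld_matrix)
  names(ld) <- sub("\\.tsv$", "", basename(ld_files))
  truth_path <- file.path(dir, "truth.tsv")
  list(genes = genes,
       eqtl = read_summary_stats(file.path(dir, "eqtl.tsv"), "eqtl"),
       gwas = read_summary_stats(file.path(dir, "gwas.tsv"), "gwas"),
       ld = ld,
       drugs = read_drug_table(file.path(dir, "drugs.tsv")),
       blocklist = read_blocklist(file.path(dir, "blocklist.txt")),
       truth = if (file.exists(truth_path)) read_tsv_raw(truth_path) else NULL,
       tissue = NULL)
}
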