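# Shared fixtures and independent oracles. Oracles are deliberately written
# as plodding second routes (lm fits, explicit enumerations, hand loops) so
# they never share arithmetic with the implementation under test.

make_sumstat <- function(n = 3L, snp_id = sprintf("rs%d", seq_len(n)),
                         chrom = "1", pos = seq_len(n) * 1000L,
                         effect_allele = rep_len(c("A", "C", "G"), n),
                         other_allele = rep_len(c("G", "T", "A"), n),
                         eaf = rep_len(0.3, n), beta = rep_len(0.1, n),
                         se = rep_len(0.05, n), pval = rep_len(0.04, n),
                         nsamp = rep_len(10000, n), gene = NULL,
                         fdr = NULL) {
  df <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                   effect_allele = effect_allele,
                   other_allele = other_allele, eaf = eaf, beta = beta,
                   se = se, pval = pval, n = nsamp,
                   stringsAsFactors = FALSE)
  if (!is.null(gene)) {
    df$gene <- gene
    df$fdr <- fdr %||% pval
  }
  df
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Agreement to 1e-12 on a scale-aware footing (absolute near zero,
# relative otherwise), avoiding relative-error blowups at near-zero truths.
expect_close <- function(actual, expected, tol = 1e-12) {
  expect_lt(abs(actual - expected), tol * max(1, abs(expected)))
}

random_ivs <- function(n, seed) {
  set.seed(seed)
  data.frame(gene = "g",
             beta_exp = sample(c(-1, 1), n, TRUE) * runif(n, 0.1, 0.6),
             se_exp = runif(n, 0.01, 0.08),
             beta_out = rnorm(n, 0, 0.1),
             se_out = runif(n, 0.01, 0.08),
             n_exp = 30000, n_out = 130000,
             stringsAsFactors = FALSE)
}

# BH step-up by the textbook definition, written independently of p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Weighted median by explicit cumulative-weight walk and interpolation.
oracle_weighted_median <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  cum <- numeric(length(w))
  run <- 0
  for (i in seq_along(w)) {
    cum[i] <- run + w[i] / 2
    run <- run + w[i]
  }
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(cum)] <= 0.5) return(b[length(b)])
  i <- 1L
  while (cum[i + 1L] < 0.5) i <- i + 1L
  b[i] + (b[i + 1L] - b[i]) * (0.5 - cum[i]) / (cum[i + 1L] - cum[i])
}

# Exhaustive enumeration over all single-causal-variant configurations:
# trait 1 causal at i (or nowhere), trait 2 at j (or nowhere).
oracle_coloc <- function(l1, l2, p1, p2, p12) {
  n <- length(l1)
  s0 <- 1
  s1 <- 0; s2 <- 0; s3 <- 0; s4 <- 0
  for (i in seq_len(n)) s1 <- s1 + p1 * exp(l1[i])
  for (j in seq_len(n)) s2 <- s2 + p2 * exp(l2[j])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) s3 <- s3 + p1 * p2 * exp(l1[i] + l2[j])
    }
  }
  for (i in seq_len(n)) s4 <- s4 + p12 * exp(l1[i] + l2[i])
  tot <- s0 + s1 + s2 + s3 + s4
  c(pp0 = s0, pp1 = s1, pp2 = s2, pp3 = s3, pp4 = s4) / tot
}

# Greedy clump by p-ranked insertion, written as a plain loop over the
# candidate list: a SNP enters iff its r^2 with every previously accepted
# SNP is below threshold.
oracle_clump <- function(candidates, ld, r2_threshold) {
  f <- (candidates$beta / candidates$se)^2
  ranked <- candidates[order(candidates$pval, -f, candidates$snp_id), ]
  accepted <- character(0)
  for (i in seq_len(nrow(ranked))) {
    id <- ranked$snp_id[i]
    ok <- TRUE
    for (a in accepted) {
      if (ld[id, a]^2 >= r2_threshold) ok <- FALSE
    }
    if (ok) accepted <- c(accepted, id)
  }
  accepted
}

# Steiger from the Fisher-z textbook formula, recomputed from scratch.
oracle_steiger <- function(z_exp, z_out, n_exp, n_out) {
  r_exp <- sqrt(z_exp^2 / (z_exp^2 + n_exp - 2))
  r_out <- sqrt(z_out^2 / (z_out^2 + n_out - 2))
  stat <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(correct = r_exp > r_out, pval = 2 * pnorm(-abs(stat)))
}

# Simulate one gene end to end (region, eQTL, GWAS) and return its
# harmonized instruments after the standard selection path.
simulate_gene_instruments <- function(seed, theta = 0.25, n_snps = 5L,
                                      block_size = 5L, eqtl_beta = 0.345,
                                      scenario = "causal_shared",
                                      n_eqtl = 31684L, n_cases = 27205L,
                                      n_controls = 110881L) {
  region <- simulate_region(n_snps, block_size, rho = 0.8, seed = seed,
                            snp_prefix = sprintf("rs%d_", seed))
  truth <- simulate_truth("g", region, scenario, theta = theta,
                          eqtl_beta = eqtl_beta, seed = seed + 1L)
  eqtl <- simulate_eqtl_summary(region, truth, n_eqtl, seed = seed + 2L)
  gwas <- simulate_gwas_summary(region, truth, n_cases, n_controls,
                                seed = seed + 3L)
  gene <- data.frame(symbol = "g", chrom = "1", tss = region$tss,
                     druggable_tier = 1L, stringsAsFactors = FALSE)
  cand <- select_cis_window(eqtl, gene)
  if (!nrow(cand)) return(NULL)
  picked <- clump(cand, region$ld)
  harmonized_instruments(harmonize_tables(picked, gwas))
}
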