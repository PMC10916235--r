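exp_row <- function(ea = "A", oa = "G", beta = 0.3, eaf = 0.3, snp = "rs1") {
  make_sumstat(1L, snp_id = snp, effect_allele = ea, other_allele = oa,
               beta = beta, eaf = eaf, gene = "G", fdr = 0.01)
}
out_row <- function(ea = "A", oa = "G", beta = -0.2, eaf = 0.3,
                    snp = "rs1") {
  make_sumstat(1L, snp_id = snp, effect_allele = ea, other_allele = oa,
               beta = beta, eaf = eaf)
}

test_that("allele alignment follows the sign and frequency conventions", {
  # swapped alleles: beta negated, eaf reflected
  h <- harmonize(exp_row("A", "G", 0.3), out_row("G", "A", -0.2, eaf = 0.7))
  expect_identical(h$action, "swap")
  expect_equal(h$beta_out, 0.2)
  expect_equal(h$eaf_out, 0.3)
  # identical alleles: untouched
  h2 <- harmonize(exp_row(), out_row())
  expect_identical(h2$action, "none")
  expect_equal(h2$beta_out, -0.2)
  # complementary strand: relabelled
  h3 <- harmonize(exp_row("A", "G"), out_row("T", "C"))
  expect_identical(h3$action, "strand_flip")
  expect_equal(h3$beta_out, -0.2)
  h4 <- harmonize(exp_row("A", "G"), out_row("C", "T", -0.2, eaf = 0.7))
  expect_identical(h4$action, "swap_and_flip")
  expect_equal(h4$beta_out, 0.2)
  # incompatible allele sets
  h5 <- harmonize(exp_row("A", "G"), out_row("A", "C"))
  expect_identical(h5$action, "dropped")
  expect_identical(h5$drop_reason, "allele-mismatch")
  expect_error(harmonize(exp_row(snp = "rs1"), out_row(snp = "rs2")),
               class = "dgmr_usage_error")
})

test_that("palindromic SNPs are kept only when frequencies are decisive", {
  # both frequencies below the ambiguity band: kept
  h <- harmonize(exp_row("A", "T", eaf = 0.10), out_row("A", "T", eaf = 0.12))
  expect_identical(h$action, "none")
  # ambiguous frequency: dropped
  h2 <- harmonize(exp_row("A", "T", eaf = 0.48), out_row("A", "T", eaf = 0.48))
  expect_identical(h2$drop_reason, "palindromic-ambiguous")
  # opposite sides of 0.5: dropped
  h3 <- harmonize(exp_row("C", "G", eaf = 0.1), out_row("C", "G", eaf = 0.9))
  expect_identical(h3$drop_reason, "palindromic-ambiguous")
  # missing outcome frequency on a palindrome: conservative drop
  h4 <- harmonize(exp_row("A", "T", eaf = 0.1), out_row("A", "T", eaf = NA))
  expect_identical(h4$drop_reason, "palindromic-no-frequency")
})

test_that("discordant frequencies on matched SNPs are dropped", {
  h <- harmonize(exp_row("A", "G", eaf = 0.1), out_row("A", "G", eaf = 0.45))
  expect_identical(h$drop_reason, "frequency-discordant")
  # missing GWAS frequency on a non-palindrome is tolerated
  h2 <- harmonize(exp_row("A", "G", eaf = 0.1), out_row("A", "G", eaf = NA))
  expect_identical(h2$action, "none")
})

test_that("harmonization is an involution and idempotent on random configs", {
  set.seed(42)
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                c("A", "T"), c("C", "G"))
  n_checked <- 0L
  for (i in 1:400) {
    ep <- pairs[[sample.int(6L, 1L)]]
    if (runif(1) < 0.5) ep <- rev(ep)
    rep_mode <- sample(c("same", "swap", "flip", "swapflip"), 1L)
    eaf_e <- runif(1, 0.02, 0.98)
    eaf_o <- min(max(eaf_e + rnorm(1, 0, 0.03), 0.01), 0.99)
    op <- switch(rep_mode, same = ep, swap = rev(ep),
                 flip = unname(c(T = "A", A = "T", C = "G", G = "C")[ep]),
                 swapflip = rev(unname(c(T = "A", A = "T", C = "G",
                                         G = "C")[ep])))
    eaf_o2 <- if (rep_mode %in% c("swap", "swapflip")) 1 - eaf_o else eaf_o
    beta_o <- rnorm(1, 0, 0.2)
    beta_o2 <- if (rep_mode %in% c("swap", "swapflip")) -beta_o else beta_o
    e <- exp_row(ep[1], ep[2], beta = rnorm(1, 0.3, 0.1), eaf = eaf_e)
    o <- out_row(op[1], op[2], beta = beta_o2, eaf = eaf_o2)
    h1 <- harmonize(e, o)
    # involution: swapping the outcome representation changes nothing
    o_sw <- o
    o_sw$effect_allele <- o$other_allele
    o_sw$other_allele <- o$effect_allele
    o_sw$beta <- -o$beta
    o_sw$eaf <- 1 - o$eaf
    h2 <- harmonize(e, o_sw)
    if (h1$action != "dropped" && h2$action != "dropped") {
      n_checked <- n_checked + 1L
      expect_equal(h1$beta_exp, h2$beta_exp)
      expect_equal(h1$beta_out, h2$beta_out, tolerance = 1e-12)
      # idempotence: re-harmonizing the harmonized convention is a no-op
      o_h <- out_row(h1$effect_allele, h1$other_allele, beta = h1$beta_out,
                     eaf = h1$eaf_out)
      h3 <- harmonize(e, o_h)
      expect_identical(h3$action %in% c("none", "swap", "strand_flip",
                                        "swap_and_flip"), TRUE)
      expect_equal(h3$beta_out, h1$beta_out, tolerance = 1e-12)
    }
  }
  expect_gt(n_checked, 200L)
})

test_that("flip fractions are recovered from the harmonization ledger", {
  region <- simulate_region(1500L, block_size = 10L, rho = 0.8, seed = 8)
  truth <- simulate_truth("G", region, "null", eqtl_beta = 0, seed = 9)
  eqtl <- simulate_eqtl_summary(region, truth, seed = 10)
  gwas <- simulate_gwas_summary(region, truth, flip_fraction = 0.3,
                                strand_fraction = 0.2, seed = 11)
  ledger <- harmonize_tables(eqtl, gwas)
  kept <- harmonized_instruments(ledger)
  frac_swap <- mean(kept$action %in% c("swap", "swap_and_flip"))
  half <- 2.576 * sqrt(0.3 * 0.7 / nrow(kept))
  expect_gt(frac_swap, 0.3 - half)
  expect_lt(frac_swap, 0.3 + half)
  frac_strand <- mean(kept$action %in% c("strand_flip", "swap_and_flip"))
  half2 <- 2.576 * sqrt(0.2 * 0.8 / nrow(kept))
  expect_gt(frac_strand, 0.2 - half2)
  expect_lt(frac_strand, 0.2 + half2)
  # instruments missing from the outcome are ledgered, not lost
  ledger2 <- harmonize_tables(eqtl[1:5, ], gwas[-(1:5), ])
  expect_identical(unique(ledger2$drop_reason), "missing-from-outcome")
})
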