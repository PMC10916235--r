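test_that("simulated LD regions follow the block AR(1) construction", {
  region <- simulate_region(4L, block_size = 2L, rho = 0.9, seed = 1)
  expect_equal(region$ld[1, 2], 0.9)
  expect_equal(region$ld[1, 3], 0)
  expect_equal(diag(region$ld), rep(1, 4), ignore_attr = TRUE)
  # rho = 0 gives identity LD
  r0 <- simulate_region(5L, block_size = 5L, rho = 0, seed = 1)
  expect_equal(unname(r0$ld), diag(5))
  expect_error(simulate_region(4L, 2L, rho = 1), class = "dgmr_parameter_error")
  # positions strictly increasing, PSD structure
  r <- simulate_region(50L, block_size = 10L, rho = 0.8, seed = 3)
  expect_true(all(diff(r$pos) > 0))
  expect_gte(min(eigen(r$ld, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("eQTL generator is deterministic and unbiased through LD", {
  region <- simulate_region(6L, block_size = 3L, rho = 0.6, seed = 2)
  truth <- simulate_truth("g", region, "causal_shared", theta = 0.2,
                          eqtl_beta = 0.3, seed = 5)
  a <- simulate_eqtl_summary(region, truth, 30000L, seed = 9)
  b <- simulate_eqtl_summary(region, truth, 30000L, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_eqtl_summary(region, truth, 1L),
               class = "dgmr_parameter_error")

  # with identity LD the causal SNP's expected beta equals its true effect;
  # empirical mean over replicates within 3 Monte Carlo SEs
  r1 <- simulate_region(4L, block_size = 1L, rho = 0, seed = 3)
  t1 <- simulate_truth("g", r1, "causal_shared", theta = 0, eqtl_beta = 0.3,
                       seed = 4)
  causal <- t1$causal_snp_ids
  reps <- vapply(seq_len(500L), function(i) {
    sim <- simulate_eqtl_summary(r1, t1, 20000L, seed = 100 + i)
    sim$beta[sim$snp_id == causal]
  }, numeric(1))
  mcse <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.3), 3 * mcse)

  # marginal effects propagate through LD: b_marg = R %*% b_true
  reps2 <- sapply(seq_len(500L), function(i) {
    simulate_eqtl_summary(region, truth, 20000L, seed = 2000 + i)$beta
  })
  expected <- as.vector(region$ld %*% truth$eqtl_betas[region$snp_ids])
  mcse2 <- apply(reps2, 1, sd) / sqrt(ncol(reps2))
  expect_true(all(abs(rowMeans(reps2) - expected) < 3 * mcse2))
})

test_that("null eQTL p-values behave like uniforms", {
  pvals <- unlist(lapply(1:4, function(k) {
    region <- simulate_region(500L, block_size = 1L, rho = 0, seed = 50 + k)
    truth <- simulate_truth("g", region, "null", theta = 0, eqtl_beta = 0,
                            seed = 60 + k)
    simulate_eqtl_summary(region, truth, 30000L, seed = 70 + k)$pval
  }))
  expect_gt(mean(pvals < 0.05), 0.03)
  expect_lt(mean(pvals < 0.05), 0.07)
})

test_that("null GWAS p-values pass a Kolmogorov-Smirnov uniformity check", {
  pvals <- unlist(lapply(1:10, function(k) {
    region <- simulate_region(500L, block_size = 10L, rho = 0.8,
                              seed = 300 + k)
    truth <- simulate_truth("g", region, "null", theta = 0, eqtl_beta = 0.3,
                            seed = 400 + k)
    simulate_gwas_summary(region, truth, seed = 500 + k)$pval
  }))
  expect_length(pvals, 5000L)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("GWAS generator honours scenarios and allele flips", {
  region <- simulate_region(8L, block_size = 4L, rho = 0.7, seed = 11)
  shared <- simulate_truth("g", region, "causal_shared", theta = 0.25,
                           eqtl_beta = 0.345, seed = 12)
  # flip fraction 1: every row swapped and negated relative to the eQTL file
  ref <- simulate_gwas_summary(region, shared, seed = 13, flip_fraction = 0)
  flip <- simulate_gwas_summary(region, shared, seed = 13, flip_fraction = 1)
  expect_identical(flip$effect_allele, ref$other_allele)
  expect_identical(flip$other_allele, ref$effect_allele)
  expect_equal(flip$beta, -ref$beta)
  expect_equal(flip$eaf, 1 - ref$eaf)

  # distinct scenario puts the outcome signal in a block disjoint from the
  # eQTL causal block
  distinct <- simulate_truth("g", region, "causal_distinct", theta = 0.3,
                             eqtl_beta = 0.345, seed = 14)
  eqtl_block <- region$block[match(distinct$causal_snp_ids, region$snp_ids)]
  out_block <- region$block[match(distinct$outcome_snp_ids, region$snp_ids)]
  expect_false(any(out_block %in% eqtl_block))

  # Wald ratios over many null genes center on zero
  ratios <- vapply(1:300, function(k) {
    r <- simulate_region(1L, 1L, rho = 0, seed = 700 + k)
    t <- simulate_truth("g", r, "null", theta = 0, eqtl_beta = 0.345,
                        seed = 800 + k)
    e <- simulate_eqtl_summary(r, t, seed = 900 + k)
    g <- simulate_gwas_summary(r, t, seed = 1000 + k)
    g$beta / e$beta
  }, numeric(1))
  expect_lt(abs(mean(ratios)), 3 * sd(ratios) / sqrt(length(ratios)))
})

test_that("drug-table generator covers the curated case study", {
  ex <- example_drug_table()
  fosta <- ex[ex$drug_name == "fostamatinib", ]
  expect_identical(fosta$action_type, "inhibitor")
  expect_identical(fosta$max_phase, "approved")
  glut <- ex[ex$drug_name == "glutathione", ]
  expect_identical(glut$max_phase, "3")
  expect_true(glut$broad_spectrum)
  expect_identical(nrow(simulate_drug_table(character(0))), 0L)
  sim <- simulate_drug_table(c("A1", "B2"), seed = 3)
  expect_true(all(sim$gene %in% c("A1", "B2")))
  expect_identical(sim, simulate_drug_table(c("A1", "B2"), seed = 3))
})

test_that("study bundles are reproducible and write a readable layout", {
  b1 <- simulate_study(n_genes = 6L, n_causal = 2L, seed = 77)
  b2 <- simulate_study(n_genes = 6L, n_causal = 2L, seed = 77)
  expect_identical(b1$eqtl, b2$eqtl)
  expect_identical(b1$gwas, b2$gwas)
  dir <- withr::local_tempdir()
  write_bundle(b1, dir)
  back <- read_bundle(dir)
  expect_equal(back$genes, b1$genes)
  expect_equal(back$eqtl$beta, b1$eqtl$beta, tolerance = 1e-12)
  expect_identical(names(back$ld), sort(names(b1$ld)))
})
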