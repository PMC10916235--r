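iv1 <- function(beta_exp = 0.5, se_exp = 0.05, beta_out = 0.13,
                se_out = 0.04) {
  data.frame(gene = "G", beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out, n_exp = 30000,
             n_out = 130000, stringsAsFactors = FALSE)
}

test_that("Wald ratio follows the delta method", {
  est <- wald_ratio(iv1())
  expect_equal(est$beta, 0.26)
  expect_equal(est$se, 0.08)
  expect_identical(est$method, "wald_ratio")
  # identity case
  expect_equal(wald_ratio(iv1(0.4, 0.05, 0.4, 0.05))$beta, 1)
  expect_error(wald_ratio(iv1(beta_exp = 0)), class = "dgmr_degenerate_error")
  # second-order adds the exposure-uncertainty term
  so <- wald_ratio(iv1(), second_order = TRUE)
  expect_equal(so$se, sqrt(0.04^2 / 0.5^2 + 0.13^2 * 0.05^2 / 0.5^4))
  expect_gt(so$se, est$se)
})

test_that("IVW equals weighted least squares through the origin", {
  # equal exposure effects and outcome SEs: mean of the two Wald ratios
  ivs <- rbind(iv1(0.5, 0.05, 0.10, 0.04), iv1(0.5, 0.05, 0.20, 0.04))
  est <- ivw(ivs)
  expect_equal(est$beta, mean(c(0.10, 0.20) / 0.5))
  expect_error(ivw(iv1()), class = "dgmr_usage_error")
  # against the lm() normal-equations route, 1e-12
  for (seed in 1:25) {
    ivs <- random_ivs(sample(2:8, 1), seed)
    fit <- lm(beta_out ~ 0 + beta_exp, data = ivs,
              weights = 1 / ivs$se_out^2)
    est <- ivw(ivs)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
    expect_equal(est$se,
                 summary(fit)$coefficients[1, 2] / summary(fit)$sigma,
                 tolerance = 1e-12)
  }
  # duplicated instrument pair collapses to its Wald ratio
  dup <- rbind(iv1(), iv1())
  expect_equal(ivw(dup)$beta, wald_ratio(iv1())$beta)
  # random-effects inflation never shrinks the SE
  het <- rbind(iv1(0.5, 0.05, 0.3, 0.02), iv1(0.5, 0.05, -0.3, 0.02),
               iv1(0.5, 0.05, 0.05, 0.02))
  expect_gte(ivw(het, "random")$se, ivw(het, "fixed")$se)
})

test_that("MR-Egger matches weighted regression with intercept", {
  for (seed in 1:25) {
    ivs <- random_ivs(sample(3:10, 1), seed + 100)
    s <- ifelse(ivs$beta_exp < 0, -1, 1)
    d <- data.frame(x = ivs$beta_exp * s, y = ivs$beta_out * s)
    fit <- lm(y ~ x, data = d, weights = 1 / ivs$se_out^2)
    co <- summary(fit)$coefficients
    est <- mr_egger(ivs)
    expect_close(est$slope$beta, unname(co["x", 1]))
    expect_close(est$slope$se, unname(co["x", 2]))
    expect_close(est$intercept$beta, unname(co["(Intercept)", 1]))
    expect_close(est$intercept$pval, unname(co["(Intercept)", 4]))
  }
  expect_error(mr_egger(rbind(iv1(), iv1())),
               class = "dgmr_insufficient_instruments_error")
  collinear <- rbind(iv1(0.5), iv1(0.5), iv1(0.5))
  expect_error(mr_egger(collinear), class = "dgmr_degenerate_error")
})

test_that("Egger intercept is centered on zero without pleiotropy", {
  intercepts <- vapply(1:200, function(k) {
    set.seed(3000 + k)
    n <- 10L
    be <- runif(n, 0.2, 0.6)
    se_out <- runif(n, 0.02, 0.05)
    bo <- 0.25 * be + rnorm(n, 0, se_out)
    ivs <- data.frame(gene = "G", beta_exp = be, se_exp = 0.01,
                      beta_out = bo, se_out = se_out, n_exp = 3e4,
                      n_out = 1e5)
    mr_egger(ivs)$intercept$beta
  }, numeric(1))
  mcse <- sd(intercepts) / sqrt(length(intercepts))
  expect_lt(abs(mean(intercepts)), 3 * mcse)
})

test_that("weighted median interpolates the cumulative weight function", {
  # equal weights, ratios (0.1, 0.2, 0.9): plain median
  ivs <- rbind(iv1(1, 0.01, 0.1, 0.05), iv1(1, 0.01, 0.2, 0.05),
               iv1(1, 0.01, 0.9, 0.05))
  expect_equal(weighted_median(ivs, n_boot = 50, seed = 1)$beta, 0.2)
  # all ratios equal: estimate is that constant, bootstrap SE small
  same <- rbind(iv1(1, 0.001, 0.3, 0.001), iv1(0.8, 0.001, 0.24, 0.001),
                iv1(1.2, 0.001, 0.36, 0.001))
  wm <- weighted_median(same, n_boot = 200, seed = 2)
  expect_equal(wm$beta, 0.3, tolerance = 1e-9)
  expect_lt(wm$se, 0.01)
  # unequal weights match the brute-force oracle to 1e-12
  for (seed in 1:25) {
    ivs <- random_ivs(7L, seed + 200)
    est <- weighted_median(ivs, n_boot = 10, seed = 3)
    expect_equal(est$beta,
                 oracle_weighted_median(ivs$beta_out / ivs$beta_exp,
                                        ivs$beta_exp^2 / ivs$se_out^2),
                 tolerance = 1e-12)
  }
  expect_error(weighted_median(rbind(iv1(), iv1())),
               class = "dgmr_insufficient_instruments_error")
  # seed-controlled bootstrap is reproducible
  expect_identical(weighted_median(ivs, n_boot = 100, seed = 9)$se,
                   weighted_median(ivs, n_boot = 100, seed = 9)$se)
})

test_that("Steiger directionality agrees with the Fisher-z formula", {
  strong <- iv1(0.3, 0.01, 0.03, 0.01)  # z_exp = 30, z_out = 3
  st <- steiger_test(strong, 30000, 30000)
  expect_true(st$direction_correct)
  # symmetric case: no direction, p = 1
  sym <- iv1(0.3, 0.01, 0.3, 0.01)
  st2 <- steiger_test(sym, 20000, 20000)
  expect_false(st2$direction_correct)
  expect_equal(st2$pval, 1)
  expect_error(steiger_test(strong, 3, 1000), class = "dgmr_parameter_error")
  for (seed in 1:30) {
    set.seed(seed + 400)
    iv <- iv1(rnorm(1, 0.3, 0.1), runif(1, 0.01, 0.05),
              rnorm(1, 0.1, 0.05), runif(1, 0.01, 0.05))
    n1 <- sample(1000:50000, 1)
    n2 <- sample(1000:50000, 1)
    st <- steiger_test(iv, n1, n2)
    orc <- oracle_steiger(iv$beta_exp / iv$se_exp, iv$beta_out / iv$se_out,
                          n1, n2)
    expect_identical(st$direction_correct, orc$correct)
    expect_equal(st$pval, orc$pval, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand step-up and preserves order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 0)), class = "dgmr_validation_error")
  for (seed in 1:50) {
    set.seed(seed)
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone when input sorted; q >= p always
  p <- sort(runif(30))
  q <- bh_fdr(p)
  expect_true(all(diff(q) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("odds-ratio reporting exponentiates the 95% bounds", {
  orci <- to_or_ci(0.2624, 0.0451)
  expect_equal(orci$or_point, 1.30, tolerance = 0.005)
  expect_equal(orci$ci_low, 1.19, tolerance = 0.005)
  expect_equal(orci$ci_high, 1.42, tolerance = 0.005)
  z <- to_or_ci(0, 0.1)
  expect_equal(z$or_point, 1)
  expect_equal(z$ci_low, exp(-1.96 * 0.1))
  degenerate <- to_or_ci(0.5, 0)
  expect_equal(degenerate$ci_low, degenerate$or_point)
  expect_error(to_or_ci(0, -1), class = "dgmr_parameter_error")
})

test_that("gene-level routing picks the method by instrument count", {
  one <- run_gene_mr(iv1())
  expect_identical(one$method, "wald_ratio")
  expect_true(is.na(one$egger_beta))
  two <- run_gene_mr(rbind(iv1(), iv1(0.4, 0.04, 0.1, 0.05)))
  expect_identical(two$method, "ivw")
  expect_true(is.na(two$egger_beta) && is.na(two$wm_beta))
  expect_false(is.na(two$q_stat))
  five <- run_gene_mr(random_ivs(5L, 7), config = list(wm_boot = 50))
  expect_identical(five$method, "ivw")
  expect_false(is.na(five$egger_beta) || is.na(five$wm_beta))
  expect_true(five$ci_low <= five$or_point & five$or_point <= five$ci_high)
  expect_error(run_gene_mr(iv1()[0, ]), class = "dgmr_usage_error")
})

test_that("estimators are equivariant under joint exposure sign flips", {
  for (seed in 1:10) {
    ivs <- random_ivs(5L, seed + 600)
    flipped <- ivs
    flipped$beta_exp <- -flipped$beta_exp
    flipped$beta_out <- -flipped$beta_out
    expect_equal(ivw(ivs)$beta, ivw(flipped)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(ivs)$slope$beta, mr_egger(flipped)$slope$beta,
                 tolerance = 1e-12)
    expect_equal(weighted_median(ivs, 10, 1)$beta,
                 weighted_median(flipped, 10, 1)$beta, tolerance = 1e-12)
  }
})

test_that("family-level MR attaches BH q-values and a ledger", {
  bundle <- simulate_study(n_genes = 10L, n_causal = 3L, seed = 31)
  ins <- select_instruments(bundle$eqtl, bundle$genes, bundle$ld)
  res <- mr_all_genes(ins, bundle$gwas, config = list(seed = 1))
  expect_true(all(res$qval >= res$pval))
  expect_equal(res$qval, bh_fdr(res$pval))
  expect_s3_class(attr(res, "ledger"), "data.frame")
  expect_true(all(res$or_point > 0))
})
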