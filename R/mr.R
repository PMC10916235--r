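# Two-sample MR estimators over harmonized instruments: Wald ratio for a
# single instrument, inverse-variance weighted for two or more, MR-Egger and
# weighted median as sensitivity analyses from three instruments up, Steiger
# directionality, BH-FDR across genes, and odds-ratio reporting. All
# estimator arithmetic is written out explicitly (normal equations, weighted
# quantile interpolation) so each has an independent oracle in the tests.

method_estimate <- function(method, beta, se, pval, nsnp, extra = list()) {
  c(list(method = method, beta = beta, se = se, pval = pval, nsnp = nsnp),
    extra)
}

z_pval <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

#' Wald ratio causal estimate from a single instrument
#'
#' `beta = beta_out / beta_exp`; first-order delta-method standard error
#' `se_out / |beta_exp|` by default, with the second-order term
#' `beta_out^2 * se_exp^2 / beta_exp^4` added when `second_order = TRUE`
#' (recommended when exposure and outcome precisions are comparable, where
#' first-order intervals undercover). Two-sided Normal p-value.
#'
#' @param iv one-row harmonized instrument (`beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`).
#' @param second_order include the exposure-uncertainty variance term.
#' @return a `MethodEstimate` list (`method`, `beta`, `se`, `pval`, `nsnp`).
#' @export
wald_ratio <- function(iv, second_order = FALSE) {
  if (iv$beta_exp == 0) {
    dgmr_abort("degenerate instrument: beta_exp = 0", "dgmr_degenerate_error")
  }
  beta <- iv$beta_out / iv$beta_exp
  var1 <- iv$se_out^2 / iv$beta_exp^2
  se <- if (second_order) {
    sqrt(var1 + iv$beta_out^2 * iv$se_exp^2 / iv$beta_exp^4)
  } else {
    sqrt(var1)
  }
  method_estimate("wald_ratio", beta, se, z_pval(beta, se), 1L)
}

#' Inverse-variance weighted causal estimate
#'
#' Weighted mean of per-instrument Wald ratios with weights
#' `w_i = beta_exp_i^2 / se_out_i^2` - equivalently the weighted regression
#' of outcome on exposure effects through the origin. Fixed-effect by
#' default; the multiplicative random-effects model inflates the standard
#' error by `max(1, sqrt(Q / (n - 1)))`. Cochran's Q is always reported.
#'
#' @param ivs harmonized instruments (>= 2 rows).
#' @param model `"fixed"` or `"random"`.
#' @return a `MethodEstimate` list with `q_stat` and `q_pval` extras.
#' @export
ivw <- function(ivs, model = c("fixed", "random")) {
  model <- match.arg(model)
  n <- nrow(ivs)
  if (n < 2L) {
    dgmr_abort("IVW needs >= 2 instruments; route single instruments to wald_ratio",
               "dgmr_usage_error")
  }
  ratio <- ivs$beta_out / ivs$beta_exp
  w <- ivs$beta_exp^2 / ivs$se_out^2
  beta <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (ratio - beta)^2)
  if (model == "random") se <- se * max(1, sqrt(q / (n - 1)))
  method_estimate("ivw", beta, se, z_pval(beta, se), n,
                  list(q_stat = q,
                       q_pval = stats::pchisq(q, n - 1, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Instruments are first oriented so that `beta_exp >= 0` (flipping the
#' sign of each pair), then outcome effects are regressed on exposure
#' effects with an intercept, weights `1 / se_out^2`. The slope is the
#' causal estimate; a nonzero intercept flags directional pleiotropy.
#' Standard errors come from the weighted normal equations with a
#' t-reference on `n - 2` degrees of freedom.
#'
#' @param ivs harmonized instruments (>= 3 rows).
#' @return list with `slope` and `intercept` `MethodEstimate`s.
#' @export
mr_egger <- function(ivs) {
  n <- nrow(ivs)
  if (n < 3L) {
    dgmr_abort("MR-Egger needs >= 3 instruments",
               "dgmr_insufficient_instruments_error")
  }
  s <- ifelse(ivs$beta_exp < 0, -1, 1)
  x <- ivs$beta_exp * s
  y <- ivs$beta_out * s
  w <- 1 / ivs$se_out^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x * x); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (!is.finite(det) || det <= .Machine$double.eps * sw * swxx) {
    dgmr_abort("MR-Egger design is singular (exposure effects collinear)",
               "dgmr_degenerate_error")
  }
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (n - 2)
  se_slope <- sqrt(sigma2 * sw / det)
  se_int <- sqrt(sigma2 * swxx / det)
  t_p <- function(b, se) 2 * stats::pt(-abs(b / se), df = n - 2)
  list(slope = method_estimate("mr_egger", slope, se_slope,
                               t_p(slope, se_slope), n),
       intercept = method_estimate("mr_egger_intercept", intercept, se_int,
                                   t_p(intercept, se_int), n))
}

# Weighted median by linear interpolation of the cumulative weight function
# at 0.5 (weights pre-normalized, order statistics bracketing).
weighted_median_point <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - 0.5 * w
  if (s[1L] >= 0.5) return(v[1L])
  if (s[length(s)] <= 0.5) return(v[length(v)])
  below <- max(which(s < 0.5))
  v[below] + (v[below + 1L] - v[below]) *
    (0.5 - s[below]) / (s[below + 1L] - s[below])
}

#' Weighted median causal estimate
#'
#' Weighted median of the per-instrument Wald ratios with weights
#' `beta_exp^2 / se_out^2`, interpolated at cumulative weight 0.5. The
#' standard error comes from a seed-controlled parametric bootstrap:
#' exposure and outcome effects are resampled from their Normal sampling
#' distributions and the weighted median recomputed.
#'
#' @param ivs harmonized instruments (>= 3 rows).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return a `MethodEstimate` list with `n_boot` extra.
#' @export
weighted_median <- function(ivs, n_boot = 1000L, seed = 1L) {
  n <- nrow(ivs)
  if (n < 3L) {
    dgmr_abort("weighted median needs >= 3 instruments",
               "dgmr_insufficient_instruments_error")
  }
  est <- weighted_median_point(ivs$beta_out / ivs$beta_exp,
                               ivs$beta_exp^2 / ivs$se_out^2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      be <- stats::rnorm(n, ivs$beta_exp, ivs$se_exp)
      bo <- stats::rnorm(n, ivs$beta_out, ivs$se_out)
      weighted_median_point(bo / be, be^2 / ivs$se_out^2)
    }, numeric(1L))
  })
  se <- stats::sd(boots)
  method_estimate("weighted_median", est, se, z_pval(est, se), n,
                  list(n_boot = n_boot))
}

#' Steiger directionality test
#'
#' Compares the variance in exposure versus outcome explained by an
#' instrument: `r2 = z^2 / (z^2 + n - 2)` on each side. The orientation is
#' deemed correct when `r2_exp > r2_out`; the p-value compares the Fisher
#' z-transformed |r| values scaled by
#' `sqrt(1/(n_exp - 3) + 1/(n_out - 3))`.
#'
#' @param iv one-row harmonized instrument.
#' @param n_exp,n_out sample sizes (both > 3).
#' @return list with `direction_correct`, `pval`, `r2_exp`, `r2_out`.
#' @export
steiger_test <- function(iv, n_exp = iv$n_exp, n_out = iv$n_out) {
  if (is.na(n_exp) || is.na(n_out) || n_exp <= 3 || n_out <= 3) {
    dgmr_abort("Steiger test needs sample sizes > 3", "dgmr_parameter_error")
  }
  z_exp <- iv$beta_exp / iv$se_exp
  z_out <- iv$beta_out / iv$se_out
  r2_exp <- z_exp^2 / (z_exp^2 + n_exp - 2)
  r2_out <- z_out^2 / (z_out^2 + n_out - 2)
  fz <- atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))
  stat <- fz / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(direction_correct = r2_exp > r2_out,
       pval = 2 * stats::pnorm(-abs(stat)),
       r2_exp = r2_exp, r2_out = r2_out)
}

# Gene-level Steiger over several (approximately independent, post-clumping)
# instruments: variance explained sums across instruments.
steiger_gene <- function(ivs) {
  n_exp <- stats::median(ivs$n_exp)
  n_out <- stats::median(ivs$n_out)
  if (is.na(n_exp) || is.na(n_out) || n_exp <= 3 || n_out <= 3) {
    return(list(direction_correct = NA, pval = NA_real_))
  }
  z_exp <- ivs$beta_exp / ivs$se_exp
  z_out <- ivs$beta_out / ivs$se_out
  r2_exp <- min(sum(z_exp^2 / (z_exp^2 + n_exp - 2)), 0.999999)
  r2_out <- min(sum(z_out^2 / (z_out^2 + n_out - 2)), 0.999999)
  fz <- atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))
  stat <- fz / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(direction_correct = r2_exp > r2_out,
       pval = 2 * stats::pnorm(-abs(stat)))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1,
#' input order preserved (delegates to [stats::p.adjust()] after
#' validation).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    dgmr_abort("p-values must lie in (0, 1]", "dgmr_validation_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Odds ratio with 95% confidence interval from a log-odds estimate
#'
#' @param beta log-odds estimate.
#' @param se standard error (>= 0).
#' @return list with `or_point`, `ci_low`, `ci_high` (`exp(beta -+
#'   1.96*se)`).
#' @export
to_or_ci <- function(beta, se) {
  if (any(se < 0)) {
    dgmr_abort("`se` must be >= 0", "dgmr_parameter_error")
  }
  list(or_point = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se))
}

#' Per-gene MR with method routing and sensitivity analyses
#'
#' One instrument routes to the Wald ratio; two or more to IVW; with three
#' or more, MR-Egger and the weighted median are additionally recorded as
#' sensitivity columns. The Steiger directionality flag is attached from the
#' instruments' sample sizes.
#'
#' @param ivs harmonized, non-dropped instruments for one gene.
#' @param config list of options: `wald_second_order` (FALSE),
#'   `ivw_model` ("fixed"), `wm_boot` (1000), `seed` (1).
#' @return one-row data frame in the `MrResult` schema (without `qval`,
#'   which is a family-level quantity; see [mr_all_genes()]).
#' @export
run_gene_mr <- function(ivs, config = list()) {
  if (!nrow(ivs)) {
    dgmr_abort("no instruments supplied", "dgmr_usage_error")
  }
  n <- nrow(ivs)
  primary <- if (n == 1L) {
    wald_ratio(ivs, second_order = isTRUE(config$wald_second_order))
  } else {
    ivw(ivs, model = config$ivw_model %||% "fixed")
  }
  sens <- list(q_stat = NA_real_, q_pval = NA_real_,
               egger_beta = NA_real_, egger_se = NA_real_,
               egger_pval = NA_real_, egger_intercept = NA_real_,
               egger_intercept_se = NA_real_, egger_intercept_pval = NA_real_,
               wm_beta = NA_real_, wm_se = NA_real_, wm_pval = NA_real_)
  if (n >= 2L) {
    sens$q_stat <- primary$q_stat
    sens$q_pval <- primary$q_pval
  }
  if (n >= 3L) {
    egger <- tryCatch(mr_egger(ivs), dgmr_error = function(e) NULL)
    if (!is.null(egger)) {
      sens$egger_beta <- egger$slope$beta
      sens$egger_se <- egger$slope$se
      sens$egger_pval <- egger$slope$pval
      sens$egger_intercept <- egger$intercept$beta
      sens$egger_intercept_se <- egger$intercept$se
      sens$egger_intercept_pval <- egger$intercept$pval
    }
    wm <- weighted_median(ivs, n_boot = config$wm_boot %||% 1000L,
                          seed = config$seed %||% 1L)
    sens$wm_beta <- wm$beta
    sens$wm_se <- wm$se
    sens$wm_pval <- wm$pval
  }
  steiger <- steiger_gene(ivs)
  orci <- to_or_ci(primary$beta, primary$se)
  data.frame(gene = ivs$gene[1L] %||% NA_character_,
             method = primary$method, nsnp = n,
             beta = primary$beta, se = primary$se, pval = primary$pval,
             qval = NA_real_, or_point = orci$or_point,
             ci_low = orci$ci_low, ci_high = orci$ci_high,
             steiger_correct = steiger$direction_correct,
             steiger_pval = steiger$pval,
             as.data.frame(sens), stringsAsFactors = FALSE)
}

#' MR across all genes with family-level FDR
#'
#' Harmonizes each gene's instruments against the outcome GWAS, runs
#' [run_gene_mr()] per gene, and applies Benjamini-Hochberg adjustment
#' across the tested genes (one family per exposure-dataset-by-outcome
#' analysis). Genes whose instruments are all dropped at harmonization are
#' skipped and listed in the `skipped` attribute.
#'
#' @param instruments instruments data frame from [select_instruments()].
#' @param gwas outcome GWAS summary statistics.
#' @param config options passed to [run_gene_mr()] plus
#'   `palindrome_eaf_limit` and `freq_tolerance` for harmonization.
#' @return `MrResult` data frame, one row per tested gene, with attributes
#'   `ledger` (full harmonization ledger) and `skipped`.
#' @export
mr_all_genes <- function(instruments, gwas, config = list()) {
  ledger <- harmonize_tables(instruments, gwas,
                             config$palindrome_eaf_limit %||% 0.42,
                             config$freq_tolerance %||% 0.2)
  usable <- harmonized_instruments(ledger)
  genes <- unique(instruments$gene)
  rows <- list()
  skipped <- character(0)
  for (g in genes) {
    ivs <- usable[usable$gene == g, , drop = FALSE]
    if (!nrow(ivs)) {
      skipped <- c(skipped, g)
      next
    }
    cfg <- config
    cfg$seed <- child_seed(config$seed %||% 1L, match(g, genes))
    rows[[g]] <- run_gene_mr(ivs, cfg)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- run_gene_mr(data.frame(gene = "g", beta_exp = 1, se_exp = 1,
                                  beta_out = 0, se_out = 1, n_exp = 10,
                                  n_out = 10))[0L, ]
  } else {
    res$qval <- bh_fdr(res$pval)
  }
  rownames(res) <- NULL
  attr(res, "ledger") <- ledger
  attr(res, "skipped") <- skipped
  res
}
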