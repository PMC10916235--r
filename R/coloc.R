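# Bayesian colocalization of an eQTL and a GWAS signal over a shared SNP
# region, assuming at most one causal variant per trait. Per-SNP evidence
# enters as Wakefield approximate Bayes factors; the five hypothesis
# posteriors (H0 neither trait associated, H1/H2 one trait only, H3 two
# distinct causal variants, H4 one shared causal variant) are accumulated
# on the log scale throughout.

#' Wakefield log approximate Bayes factor for one SNP
#'
#' With shrinkage `r = prior_w / (prior_w + se^2)` and `z = beta / se`,
#' returns `0.5 * log(1 - r) + 0.5 * r * z^2`. Stable for |z| well beyond
#' 50 since everything stays on the log scale.
#'
#' @param beta effect estimate.
#' @param se standard error (> 0).
#' @param prior_w prior variance of the true effect (> 0); convention 0.15^2
#'   for quantitative traits, 0.2^2 for case-control.
#' @return log ABF (vectorized over `beta`/`se`).
#' @export
log_abf <- function(beta, se, prior_w) {
  if (any(!is.finite(se) | se <= 0) || !is.finite(prior_w) || prior_w <= 0) {
    dgmr_abort("`se` and `prior_w` must be positive", "dgmr_parameter_error")
  }
  r <- prior_w / (prior_w + se^2)
  0.5 * log1p(-r) + 0.5 * r * (beta / se)^2
}

#' Build a per-trait region dataset for colocalization
#'
#' @param records summary-statistics data frame for the region.
#' @param trait_type `"quantitative"` (eQTL side) or `"case_control"`
#'   (GWAS side); fixes the default effect-size prior variance.
#' @param prior_w optional override of the prior variance.
#' @return a `RegionDataset` list (`snp_ids`, `beta`, `se`, `trait_type`,
#'   `prior_w`).
#' @export
region_dataset <- function(records, trait_type = c("quantitative",
                                                   "case_control"),
                           prior_w = NULL) {
  trait_type <- match.arg(trait_type)
  prior_w <- prior_w %||% if (trait_type == "quantitative") 0.15^2 else 0.2^2
  list(snp_ids = as.character(records$snp_id), beta = records$beta,
       se = records$se, trait_type = trait_type, prior_w = prior_w)
}

#' Colocalization posteriors for two traits over one region
#'
#' SNPs are intersected by id (allele orientation is irrelevant to the
#' squared-z ABF evidence). With per-SNP log ABFs `l1`, `l2`, the
#' single-causal-variant configuration sums are `S1 = sum_i exp(l1_i)`,
#' `S2 = sum_j exp(l2_j)`, `S4 = sum_i exp(l1_i + l2_i)` and
#' `S3 = sum_{i != j} exp(l1_i + l2_j)` (computed by direct pairwise
#' log-sum-exp, so no catastrophic cancellation of `S1*S2 - S4`), giving
#' unnormalized posteriors proportional to
#' `(1, p1*S1, p2*S2, p1*p2*S3, p12*S4)`.
#'
#' @param d1,d2 `RegionDataset`s from [region_dataset()].
#' @param p1,p2,p12 per-SNP prior probabilities that a SNP associates with
#'   trait 1 only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @return list with `pp` (named numeric, pp0..pp4 summing to 1) and
#'   `n_snps`.
#' @export
coloc_posteriors <- function(d1, d2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (p1 <= 0 || p2 <= 0 || p12 < 0 || p1 + p2 + p12 >= 1) {
    dgmr_abort("priors must satisfy p1 > 0, p2 > 0, p12 >= 0, p1+p2+p12 < 1",
               "dgmr_parameter_error")
  }
  shared <- intersect(d1$snp_ids, d2$snp_ids)
  if (!length(shared)) {
    dgmr_abort("no shared SNPs between the two region datasets",
               "dgmr_coverage_error")
  }
  i1 <- match(shared, d1$snp_ids)
  i2 <- match(shared, d2$snp_ids)
  l1 <- log_abf(d1$beta[i1], d1$se[i1], d1$prior_w)
  l2 <- log_abf(d2$beta[i2], d2$se[i2], d2$prior_w)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls4 <- logsumexp(l1 + l2)
  ls3 <- if (length(shared) == 1L) {
    -Inf
  } else {
    cross <- outer(l1, l2, "+")
    diag(cross) <- -Inf
    logsumexp(as.vector(cross))
  }
  lpost <- c(h0 = 0,
             h1 = log(p1) + ls1,
             h2 = log(p2) + ls2,
             h3 = log(p1) + log(p2) + ls3,
             h4 = if (p12 > 0) log(p12) + ls4 else -Inf)
  pp <- exp(lpost - logsumexp(lpost))
  list(pp = stats::setNames(pp, c("pp0", "pp1", "pp2", "pp3", "pp4")),
       n_snps = length(shared))
}

#' Apply the colocalization decision rule
#' @param pp4 posterior probability of a shared causal variant.
#' @param threshold decision threshold; the verdict is the strict
#'   inequality `pp4 > threshold`.
#' @return logical.
#' @export
is_colocalized <- function(pp4, threshold = 0.75) {
  pp4 > threshold
}

#' Colocalization for a set of genes
#'
#' For each requested gene, intersects its cis-region eQTL records with the
#' GWAS records and computes the five posteriors. The region is the full
#' available cis region per gene (all supplied eQTL SNPs), configurable
#' upstream by subsetting.
#'
#' @param eqtl eQTL summary statistics (all genes).
#' @param gwas outcome GWAS summary statistics.
#' @param genes gene symbols to test.
#' @param p1,p2,p12 colocalization priors.
#' @param pp4_threshold decision threshold for the verdict column.
#' @param prior_w_eqtl,prior_w_gwas effect-size prior variances.
#' @return `ColocResult` data frame (gene, n_snps, pp0..pp4, colocalized).
#' @export
run_coloc <- function(eqtl, gwas, genes, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      pp4_threshold = 0.75, prior_w_eqtl = 0.15^2,
                      prior_w_gwas = 0.2^2) {
  rows <- lapply(genes, function(g) {
    ge <- eqtl[eqtl$gene == g, , drop = FALSE]
    if (!nrow(ge)) {
      dgmr_abort(sprintf("no eQTL records for gene %s", g),
                 "dgmr_coverage_error")
    }
    post <- coloc_posteriors(
      region_dataset(ge, "quantitative", prior_w_eqtl),
      region_dataset(gwas[gwas$snp_id %in% ge$snp_id, , drop = FALSE],
                     "case_control", prior_w_gwas),
      p1, p2, p12)
    data.frame(gene = g, n_snps = post$n_snps,
               pp0 = post$pp[["pp0"]], pp1 = post$pp[["pp1"]],
               pp2 = post$pp[["pp2"]], pp3 = post$pp[["pp3"]],
               pp4 = post$pp[["pp4"]],
               colocalized = is_colocalized(post$pp[["pp4"]], pp4_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), n_snps = integer(0),
                      pp0 = numeric(0), pp1 = numeric(0), pp2 = numeric(0),
                      pp3 = numeric(0), pp4 = numeric(0),
                      colocalized = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
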