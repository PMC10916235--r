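---
title: "Drug-target Mendelian randomization with dgmr: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with dgmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgmr)
```

## The problem and the model

`dgmr` estimates whether the expression level of a druggable gene causally
affects a disease, using only summary statistics. The exposure is gene
expression instrumented by cis-eQTLs; the outcome is a case-control GWAS.
For an instrument SNP with expression effect $\beta_{exp}$ and outcome
effect $\beta_{out}$ (both per effect allele, after harmonization), the
single-instrument causal estimate is the Wald ratio
$\hat\theta = \beta_{out}/\beta_{exp}$, interpreted as log-odds of disease
per standard deviation of expression. With $k \ge 2$ approximately
independent instruments the primary estimate is inverse-variance weighted,

$$\hat\theta_{IVW} = \frac{\sum_i w_i\,\hat\theta_i}{\sum_i w_i},
\qquad w_i = \frac{\beta_{exp,i}^2}{se_{out,i}^2},$$

equivalently a weighted regression of $\beta_{out}$ on $\beta_{exp}$
through the origin. From three instruments up, MR-Egger (weighted
regression with a free intercept; the intercept flags directional
pleiotropy) and the weighted median of the ratios are recorded as
sensitivity analyses. The "more than two variants" gate is read as
$k \ge 3$, which is also the algebraic minimum for both estimators.

The identifying assumptions are the usual instrumental-variable triple:
relevance (the SNP affects expression — the F statistic
$(\beta_{exp}/se_{exp})^2$ is reported for every instrument), independence
from confounders (supported by the cis-window restriction and the
confounder blocklist), and exclusion (no direct SNP-outcome path — probed,
not guaranteed, by Egger's intercept and the weighted median). Steiger's
test guards against reverse causation by comparing the variance explained
in exposure versus outcome, $r^2 = z^2/(z^2+n-2)$ per side, with a
Fisher-z p-value.

A significant MR signal can still be driven by two different causal
variants in linkage disequilibrium. Colocalization resolves this: per-SNP
evidence enters as Wakefield approximate Bayes factors

$$\log ABF = \tfrac12\log(1-r) + \tfrac12 r z^2,
\qquad r = \frac{W}{W + se^2},$$

and the five single-causal-variant hypotheses H0-H4 receive posteriors
from per-SNP priors $p_1, p_2, p_{12}$. H4 (one shared causal variant)
must exceed 0.75 — strictly — for a gene to count as colocalized. Genes
passing both filters are mapped to drug candidates and triaged: Level I
requires a specific (non-broad-spectrum) action, Level II established
safety and efficacy, Level III regulatory approval; a separate concordance
check compares the gene's risk direction with the drug's action type
(risk-increasing expression pairs with inhibitors, antagonists and
antibodies; protective expression with agonists, activators, cofactors).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_bp` | 100000 | bp | cis-window half-width around the TSS; the boundary is **inclusive** (the prose convention "within ±100 kb" does not specify; inclusivity is chosen once and frozen in tests) |
| `fdr_threshold` | 0.05 | — | **strict** (`< 0.05`) both for instrument eQTL FDR and for MR q-values |
| `clump_r2` | 0.001 | — | greedy clumping threshold; deliberately stringent, so most genes keep a single instrument |
| `p1`, `p2`, `p12` | 1e-4, 1e-4, 1e-5 | per SNP | standard colocalization priors |
| `pp4_threshold` | 0.75 | — | strict colocalization decision bound |
| `palindrome_eaf_limit` | 0.42 | frequency | palindromic SNPs are kept only when both allele frequencies fall on the same side of 0.5 and outside [0.42, 0.58]; community convention, since the emulated analyses do not discuss palindromes |
| `freq_tolerance` | 0.2 | frequency | maximum exposure/outcome allele-frequency discrepancy before a SNP is dropped as `frequency-discordant`; exposed as a parameter because public releases do not document how frequency conflicts were reconciled |
| `ivw_model` | `"fixed"` | — | fixed-effect IVW primary; multiplicative random-effects inflation `max(1, sqrt(Q/(n-1)))` by flag — with mostly single-SNP instruments the choice is rarely exercised |
| `wald_second_order` | `FALSE` | — | see *Numerical choices* |
| `wm_boot` | 1000 | draws | parametric bootstrap for the weighted-median SE; parametric (resampling effects from their Normal sampling distributions) chosen for determinism given summary statistics |
| `f_min` | `NULL` | — | no automatic weak-instrument filter; set `f_min = 10` to enforce the conventional F ≥ 10 |

## What the simulator emulates — and what it does not

The generator works at the summary-statistic level. Marginal effects are
the LD-propagated true effects, $b_{marg} = R\,b_{true}$, and estimates
add independent Normal noise with standard deviation equal to the standard
error $1/\sqrt{2\,maf(1-maf)\,n}$ (for case-control outcomes, the
effective sample size $n_{eff} = 4/(1/n_{cases} + 1/n_{controls})$ with a
unit phenotype-variance proxy — an approximation, not an estimand). LD is
block-diagonal AR(1): within a block $r_{ij} = \rho^{|i-j|}$, zero across
blocks, so block boundaries double as ground truth for clumping and for
the distinct-causal-variant scenario. Scenarios: `null` (real eQTLs,
$\theta = 0$), `causal_shared` (outcome effects $\theta$ times the
marginal eQTL effects), `causal_distinct` (outcome signal in a disjoint LD
block), `pleiotropic` (direct SNP-outcome effects on top).

Defaults mirror the emulated study conditions: eQTL n = 31,684 (blood),
GWAS 27,205 cases / 110,881 controls, one causal cis-SNP per gene with
effect 0.345 SD — about 5% of expression variance explained at typical
minor-allele frequencies, i.e. a strong instrument (F in the hundreds).
Causal genes default to $\theta = 0.25$ (odds ratio ≈ 1.28 per SD), the
magnitude scale of the blood-tissue case-study genes.

Deliberately **not** modelled: realistic minor-allele-frequency spectra,
case-control ascertainment, individual-level genotypes, sampling
correlation between neighbouring SNPs' estimation errors (noise is
independent per SNP given the marginal means), cross-tissue sharing, and
winner's-curse selection (available as a significance-conditioned
resampling switch in concept but off by default, since no validation
quantity depends on it). Passing tests therefore demonstrate correctness
of the estimators and decision logic under these generative assumptions —
not robustness to the messier error structure of real consortium data.

## Numerical choices

* **First- vs second-order Wald SE.** The default SE is
  $se_{out}/|\beta_{exp}|$, the dominant reporting convention. That
  first-order form ignores the exposure-side term
  $\beta_{out}^2 se_{exp}^2/\beta_{exp}^4$; when exposure and outcome
  standard errors are comparable — as with an eQTL study of ~32k against a
  GWAS with effective n near 90k — the ignored term is a noticeable
  fraction of the ratio variance and first-order intervals undercover
  slightly *regardless of instrument strength*. For coverage-calibrated
  intervals the package exposes `wald_second_order = TRUE`, and the
  package's own coverage validation uses it.
* **Clumping determinism.** Ties on p-value break by larger F statistic,
  then lexicographic SNP id, so output is invariant to input order.
* **Colocalization stability.** Everything stays on the log scale; the
  cross-configuration sum S3 is computed by direct pairwise log-sum-exp
  with the diagonal removed rather than as $S_1 S_2 - S_4$, avoiding
  catastrophic cancellation when one SNP dominates both traits. Stable for
  |z| well past 50.
* **Degenerate inputs.** `beta_exp = 0` is a degenerate-instrument error;
  collinear exposure effects make the Egger design singular (classed
  error); genes whose instruments are all dropped at harmonization are
  skipped with a logged reason, never silently.
* **Harmonization of palindromes.** Nominal allele matching is applied
  first, then the frequency-decisiveness rule; a palindromic SNP with a
  missing outcome frequency is dropped (conservative), reason
  `palindromic-no-frequency`. Whether the emulated analyses kept or
  dropped palindromic instruments is unstated; these defaults are
  assumptions, and flagged as such.
* **FDR families.** One BH family per exposure-dataset-by-outcome analysis
  (e.g. blood and brain separately), and one family across the whole
  phenome panel; traits whose instrument is absent are excluded from the
  family size `m` and reported as not-testable.
* **Colocalization region.** The full available cis region supplied per
  gene (all of its eQTL SNPs intersected with the GWAS), not just the
  clumped instrument window; configurable upstream by subsetting.

## Validation problem sizes

The package's statistical checks run at sizes chosen to make Monte Carlo
error small relative to the tolerances while staying quick on one CPU:
1,000 random instrument sets against weighted-least-squares oracles
(agreement to 1e-12, scale-aware); colocalization posteriors against an
exhaustive single-causal-configuration enumeration on regions of up to 10
SNPs (1e-9); parameter recovery over 500 causal genes (mean within 3 Monte
Carlo SEs of the truth, 95% CI coverage within [0.93, 0.97]); error
control over 20 replicate null panels of 500 genes (average realized false
discovery proportion at q < 0.05 at most 0.075 — the binomial slack over
the nominal 0.05 for 20 panels); Steiger orientation over 300 strong
instrument genes (≥ 99% correct); and colocalization discrimination over
200 regions per scenario (median PP4 > 0.75 shared; median PP3 > 0.75 and
PP4 < 0.25 distinct). `scripts/acceptance.R` recomputes all of these from
scratch for any seed.

## Known limitations

* Single-causal-variant colocalization only; no SuSiE-style multi-causal
  extension and no more-than-two-trait analysis.
* No proxy-SNP substitution when an instrument is missing from the
  outcome study, and no trans-eQTL instruments.
* Level II/III drug judgments are curated input booleans; the package
  makes the rubric explicit but does not source it. "Broad spectrum" has
  no operational definition and is likewise a curated flag.
* With clumping at $r^2 < 0.001$ most genes retain one instrument, so
  pleiotropy-robust sensitivity estimators are rarely available — a
  power/bias trade-off inherited from the design being emulated.
* Opposite risk directions for the same gene in different tissues are
  preserved per tissue and never reconciled; concordance is evaluated per
  tissue row.
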