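---
title: "Methods: paired EWAS for disease-discordant monozygotic twins"
author: "twinewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired EWAS for disease-discordant monozygotic twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinewas)
```

## The problem

Monozygotic twins discordant for a disease are a natural matched design:
genome, sex, ancestry and shared birth factors are controlled, so
DNA-methylation differences measured at birth (archived neonatal blood
spots on a genome-wide beta-value array) can be tested for association
with the later onset of disease in one twin but not the other. The
package implements the full analysis chain for such a cohort: quality
control of a normalized probes-by-subjects beta matrix, reference-based
deconvolution of nucleated blood-cell proportions, within-pair delta-beta
statistics, per-probe conditional logistic regression, spatially informed
region detection, and stratification of the resulting effect-direction
bias by genomic context (CpG-island relation, gene model position,
regulatory features, repeat classes, and any user-supplied interval
tracks). Because twin registry data of this kind are legally restricted,
the package ships a synthetic cohort generator with full ground truth;
every downstream stage is exercised and tested against it.

## Per-probe model

Beta values $\beta \in [0,1]$ are transformed to M-values
$M = \log_2(\beta/(1-\beta))$ (betas clipped to $[10^{-6},1-10^{-6}]$),
the variance-stabilized scale standard for array regression. For a 1:1
matched pair the conditional logistic likelihood depends only on the
within-pair covariate difference $d = x_{\mathrm{case}} -
x_{\mathrm{control}}$ and reduces to

$$\ell(b) = \sum_{\text{pairs } i} -\log\!\left(1 + e^{-d_i^\top b}\right),$$

an intercept-free binary regression on differences with the outcome fixed
to one. The design per probe is the M-value difference plus shared
covariate differences: array plate as one-hot indicator differences and
cell-type proportions as differences of six of the seven estimated types
(granulocytes act as the reference type, which avoids the
sum-to-one collinearity). Pair-constant covariates such as sex difference
to identically zero columns and are dropped with a log message — in a
same-sex twin design sex cannot contribute to a conditional likelihood.
Covariate columns are scaled to unit variance; the methylation
coefficient and its test are invariant to this.

`fit_conditional_logistic()` maximizes $\ell$ by Newton–Raphson with
step-halving (score norm below $10^{-8}$, at most 50 iterations; the
per-probe loop is compiled C++). Probes whose methylation differences are
all zero are flagged `degenerate`. Separation needs care in this design:
with tens of pairs and several covariates, a direction in the joint
covariate space that puts every pair difference on one side of a
hyperplane often exists once the methylation effect is substantial, and
the likelihood then has no interior maximum. Any coefficient escaping
past $|b| > 15$ therefore flags the probe (`separated` when the
methylation differences are sign-monotone, `not_converged` otherwise) and
its Wald inference is withheld; the independent matched-pair
implementation in the survival package returns infinite or missing
coefficients on the same inputs.

### Finite-sample calibration

Wald standard errors from the inverse observed information are
anti-conservative when eight parameters are fitted on forty pairs: on
null synthetic cohorts the genomic-inflation factor
$\lambda = \mathrm{median}\,\chi^2_{\mathrm{obs}} / 0.4549$ reaches
1.3–1.45. `run_ewas()` therefore inflates standard errors by the
degrees-of-freedom factor $\sqrt{n/(n-p)}$ by default
(`small_sample = TRUE`), which brings null cohorts to
$\lambda \approx 1.03$. A Student-$t$ reference on $n - p$ degrees of
freedom was evaluated as a further correction and rejected: it
over-penalizes exactly the tail that regional detection integrates,
halving the power to recover planted regions while improving $\lambda$
by less than 0.03. Benjamini–Hochberg FDR is computed over probes with
status `ok` only; untestable probes carry no p-value.

## Region detection

Regions are detected from the per-probe p-values in the comb-p style:

1. `estimate_acf()` estimates the spatial autocorrelation of
   probit-transformed p-values $z = \Phi^{-1}(1-p)$ in 50-bp distance
   bins up to 750 bp, pooled across chromosomes (bins with fewer than 10
   pairs fall back to zero).
2. `slk_correct()` replaces each probe's p by the Stouffer–Liptak–Kechris
   combination of all probes within ±750 bp:
   $z_{\mathrm{comb}} = \sum_j z_j / \sqrt{k + 2\sum_{j<l}\sigma(d_{jl})}$,
   with $\sigma(\cdot)$ read from the autocorrelation table. Isolated
   probes are unchanged; a non-positive variance falls back to
   independence for that probe.
3. `find_regions()` seeds regions at probes with corrected $p < 0.01$ and
   extends across sub-threshold probes while inter-probe gaps stay within
   750 bp; runs of fewer than two probes are discarded.
4. `score_region()` combines the member probes' raw p-values by the same
   correlation-adjusted Stouffer–Liptak formula and applies the regional
   Šidák correction $1-(1-p)^{T/w}$, where $w$ is the region width and
   $T$ the total assayed bases, taken as the per-chromosome span of
   analyzed probes summed over chromosomes — a reproducible proxy, since
   no convention for "bases assayed" is universal.

All four parameters (window/gap 750 bp, seed p 0.01, bin size 50 bp) are
configurable and echoed into every run report; results should always be
read alongside them. Effect direction is carried separately as the
string of member-coefficient signs in genomic order (e.g. `- - +`), and
a region is conventionally called direction-consistent when all signs
agree. An optional genomic-control rescaling of the input chi-squares
(`gc_correct`) exists for data with residual technical inflation; it is
off by default because genomic control cannot distinguish artifact from
pervasive genuine signal and discounts real regions when many probes
carry small true effects.

## Cell-type deconvolution

`estimate_proportions()` performs reference-based deconvolution by
constrained projection: per subject, minimize $\|y - Rp\|^2$ subject to
$p \ge 0$ and $\sum p \le 1$, where $R$ holds purified cell-type beta
profiles (B, CD4T, CD8T, monocytes, granulocytes, NK, nucleated red
blood cells) at the informative probes. The non-negative least-squares
step is Lawson–Hanson; when the unconstrained-sum solution exceeds one,
the sum constraint is activated as an equality through a heavily
weighted augmentation row. The unexplained fraction $1-\sum p$ and the
residual norm are reported as diagnostics and no rescaling is applied.
Estimated proportions feed the regression covariates; cases and
controls are also compared per cell type by a paired Wilcoxon
signed-rank test with FDR across the seven types.

## Exact tests

Three small inferential tools are implemented from first principles
because their exact behavior is load-bearing downstream and is verified
against enumeration in the test suite:

* `binom_two_sided()` — point-probability-ordering exact binomial test
  with log-space tail summation, so whole-array sign tallies (hundreds
  of thousands of trials) are computed without underflow.
* `wilcoxon_signed_rank()` — one-sample signed-rank test; exact null
  distribution by convolution of the rank generating function for up to
  25 nonzero, untied values, normal approximation with continuity and
  tie correction otherwise.
* `bh_fdr()` — Benjamini–Hochberg step-up with enforced monotonicity and
  missing-value propagation; FDR families follow the analysis groupings
  (one family per annotation axis, sign tests and delta-beta tests
  corrected separately).

## The synthetic cohort generator

`generate_cohort()` simulates
$\mathrm{logit}(\beta_{js}) = a_j + u_{j,\mathrm{pair}(s)} +
b_{j,\mathrm{plate}(s)} + \mathbb{1}[s\ \mathrm{case}]\,\delta_j +
(\text{cell term})_{js} + \varepsilon_{js}$, clipped to $\pm 12$ before
the inverse logit. Its defaults define the study conditions used
throughout the tests:

* **Baselines** $a_j$ are drawn per island-relation context (open sea
  mean logit 2.2, islands −2.5, shores 0, shelves 1.5), reproducing the
  bimodal marginal distribution of array betas with hypomethylated
  islands and methylated open sea.
* **Noise** is heteroscedastic: the individual and plate components are
  scaled by $\min(1.3,\ 0.25/(\beta_0(1-\beta_0)))$, making measurement
  noise approximately uniform on the beta scale as on real arrays.
  Magnitudes (individual 0.085, plate 0.04, pair 0.35 on the logit
  scale at mid-methylation) are set so that (a) per-pair Spearman
  correlations of betas fall at the top of the published
  monozygotic-twin range (≈0.995, inside the tested band 0.95–0.999)
  and (b) an absolute delta-beta of 0.15 — the recurrence screen's
  threshold — essentially never arises from noise alone, so the
  recurrent set is empty under the null. Real twin cohorts report
  thousands of recurrently variable probes; those reflect heavy-tailed
  biological variability (metastable epialleles, local genetic effects)
  that this Gaussian generator deliberately does not emulate, so a
  passing recurrence screen here demonstrates thresholds and counting,
  not biology.
* **Case effects** $\delta_j$ are drawn per context with negative means
  for open sea, shore and shelf (−0.008 to −0.007 logit) and zero mean
  for islands, random sign per probe. This yields ≈59% negative
  coefficients in open sea versus ≈50% in islands and ≈58% over the full
  array, per-pair median delta-beta of order $-10^{-3}$ in open sea, and
  overall $\lambda \approx 1.1$. These three published summaries cannot
  be matched simultaneously to their printed values under any Gaussian
  choice — the printed per-context delta-beta medians, sign
  percentages, and $\lambda$ over-determine the effect scale — so the
  defaults privilege the sign-bias pattern and calibration.
* **Planted regions** occupy isolated dense probe clusters: 10–12
  consecutive probes spanning ≤800 bp with ≥750 bp of empty flank on
  both sides, so the called region coincides spatially with the planted
  one. The shared beta-scale effect (−0.02) is converted to the logit
  scale at each probe's baseline slope (floored at 0.25/1.3, matching
  the noise cap) so the planted effect is uniform relative to local
  noise at roughly 0.65 noise-SD per pair per probe. Regional power is
  deliberately built from member count rather than per-probe effect
  size: the per-probe Wald z of this design saturates near 3 at 40
  pairs (larger shifts push probes into joint separation and lose them
  entirely), so an 8-probe region at z ≈ 2.2 is detectable where a
  3-probe region at any effect size is not.
* **Cell mixtures** are Dirichlet(6, 12, 12, 10, 55, 3, 2) over
  (B, CD4T, CD8T, Mono, Gran, NK, nRBC) — a plausible cord-blood
  composition — drawn at the pair level and individually perturbed on
  the log scale (sd 0.07), reflecting largely shared intrauterine
  hematopoiesis. 400 informative probes carry per-cell-type logit
  offsets N(0, 1.5²) and near-0.5 baselines; the bundled reference
  matrix is the inverse-logit of baseline plus offset. All other probes
  are cell-invariant.
* **Plates**: two plates, case and control of every pair on different
  plates, chips of eight subjects within plate; the plate effect is an
  independent N(0, 0.045²·scale) draw per probe and plate.
* **Determinism**: one integer seed; each component (manifest, cohort,
  region planting, tracks) derives its own stream by a fixed offset, so
  identical configurations are bitwise reproducible and components can
  be regenerated independently.

Synthetic annotation tracks (repeat classes, CoRSIV-like regions, cCRE
classes, TF motifs) are random intervals anchored on probe positions,
written as 0-based half-open BED; they exercise the overlap engine and
the per-track FDR families, not any biological enrichment.

## Problem sizes and degenerate inputs

The shipped study conditions are 40 pairs × 20,000 probes with 5 planted
regions; the test suite exercises 20 such cohorts plus 20 matched null
cohorts, and smaller cohorts (10–15 pairs, 600–8,000 probes) for unit
tests. Degenerate inputs are handled explicitly: probes with all-zero
differences (degenerate status), separated likelihoods (flagged, not
reported), constant beta vectors in correlations (missing with a
warning), empty strata (row omitted), strata with no informative pairs
(p missing), empty autocorrelation bins (zero with a warning),
non-positive combination variances (independence fallback), and
missing detection-p input (no-op with a warning).

## Known limitations

* The generator's Gaussian tails understate real within-pair
  variability; recurrence-screen results on synthetic data say nothing
  about the biological recurrent set.
* Conditional-logistic Wald inference at ≤40 pairs is power-limited
  (per-probe z saturates near 3); single-probe discoveries at
  array-wide FDR essentially require more pairs, consistent with the
  pipeline's emphasis on regional and sign-bias analyses.
* The Šidák total-bases convention (probe-span per chromosome) is one of
  several in circulation; regional p-values are comparable only under a
  fixed convention, which the run report records.
* IDAT-level normalization, probe cross-reactivity masking, and
  gene-set enrichment are out of scope; the pipeline starts at a
  normalized beta matrix.
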