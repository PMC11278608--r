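---
title: "Methods: two-sample, multivariable and two-step mediation MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample, multivariable and two-step mediation MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables. For variant $j$, let $\hat\gamma_j$ (SE $\sigma_{Xj}$) be its
association with the exposure and $\hat\Gamma_j$ (SE $\sigma_{Yj}$) its
association with the outcome, estimated in non-overlapping samples. If the
variant is a valid instrument — associated with the exposure, independent of
confounders, and affecting the outcome only through the exposure — then
$\Gamma_j = \beta\,\gamma_j$ and each Wald ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ estimates the causal effect
$\beta$. For a binary outcome the betas are log-odds, so $e^\beta$ is an odds
ratio.

The package implements the analysis design of a two-stage study: stage 1 is
bidirectional univariable MR between a binary exposure (the motivating case
is type 2 diabetes) and a binary outcome (calcific aortic valve stenosis),
with a multivariable adjustment for adiposity covariates; stage 2 screens a
panel of candidate mediators (circulating metabolites, blood pressure) with
two-step MR and decomposes the total effect.

## Instrument processing

* **Selection**: variants with exposure $p <$ `p_threshold` (default
  $5\times10^{-8}$, the conventional genome-wide threshold).
* **Clumping**: greedy, in ascending p-value order with lexicographic
  tie-break on the variant id; a variant is kept iff its LD $r^2$ with every
  already-kept variant within `window_kb` (default 10\,000 kb, i.e. a
  $\pm$10 Mb window, 1-based positions) on the same chromosome is below
  `r2_threshold` (default 0.001). The LD matrix is caller-supplied: computing
  LD from a reference panel is out of scope, and the synthetic generator
  emits its own.
* **Harmonization** (in order, each counted in an audit that sums to
  input $-$ retained): instruments missing from the outcome GWAS; palindromic
  variants (A/T, C/G) regardless of allele frequency — the strictest reading
  of "palindromic variants were removed", with no frequency rescue; variants
  with outcome $p <$ `outcome_p_exclude` (default $5\times10^{-8}$);
  variants whose outcome alleles match neither orientation. Flipped
  orientation negates the outcome beta and reflects the outcome allele
  frequency.
* **Instrument strength**: per-variant explained variance
  $r^2_j = 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\hat\gamma_j^2$ (unit-variance
  phenotype — the only definition computable from summary data alone), summed
  to $R^2$, and $F = R^2(N-K-1)/[K(1-R^2)]$ with the conventional weak-
  instrument flag at $F \le 10$. Exposure-side allele frequencies are used.

Row validation drops hard invariant violations (non-positive SE, p outside
$(0,1]$, malformed alleles, duplicated ids) with a logged count. A p-value
that disagrees with $2\Phi(-|\hat\beta/\mathrm{se}|)$ by more than 10% on the
z scale only sets the `zp_flag` column: published tables round both fields,
and discarding such rows would throw away usable data.

## Estimators

All estimators report $\hat\beta$, its SE, the 95% normal interval
$\hat\beta \pm 1.96\,\mathrm{se}$, a two-sided normal p-value, and (for
binary outcomes) the exponentiated odds-ratio scale. The definitions are the
standard ones implemented by the tooling this design is normally run with:

* **IVW** (primary): weighted regression of $\hat\Gamma$ on $\hat\gamma$
  through the origin, weights $1/\sigma_{Yj}^2$ — equivalently the
  inverse-variance meta-analysis of the Wald ratios. Multiplicative random
  effects: the fixed-effect SE is scaled by
  $\hat\phi = \max\!\big(1, \sqrt{Q/(J-1)}\big)$, so heterogeneity widens the
  interval and under-dispersion falls back to the fixed-effect SE.
* **MR-Egger**: the same weighted regression with an intercept, fitted after
  orienting all exposure betas non-negative. The intercept estimates the
  average directional pleiotropic effect; the slope is the
  pleiotropy-adjusted causal effect under the InSIDE assumption. Both
  coefficients share the inflation $\max(1,\sqrt{\mathrm{RSS}_w/(J-2)})$.
* **Weighted median**: the weighted median of the Wald ratios with weights
  $\hat\gamma_j^2/\sigma_{Yj}^2$ (each ratio's inverse variance), linear
  interpolation at cumulative weight 0.5; consistent when valid instruments
  carry $>$50% of the weight. SE by seeded parametric bootstrap
  (default 1000 draws) resampling both betas.
* **Simple and weighted mode**: Gaussian-kernel density over the ratios with
  Silverman bandwidth $\phi\cdot1.06\cdot\min(\mathrm{SD},
  \mathrm{IQR}/1.34)\cdot J^{-1/5}$ ($\phi = 1$ by default), argmax on a
  512-point grid spanning the ratios $\pm3$ bandwidths; uniform or
  inverse-variance weights. If every ratio coincides the common ratio is
  returned directly.

Wald-ratio SEs are first order ($\sigma_{Yj}/|\hat\gamma_j|$); second-order
exposure-error terms are deliberately omitted and this is a documented
limitation — with the strong instruments the pipeline enforces ($F > 10$) the
attenuation is well under 1%.

## Sensitivity diagnostics

* **Cochran's Q** on the Wald ratios with weights
  $(\hat\gamma_j/\sigma_{Yj})^2$, $\chi^2_{J-1}$ reference.
* **Egger intercept test**: intercept $= 0$ is the no-directional-pleiotropy
  null.
* **MR-PRESSO**: leave-one-out expected values
  $\hat\Gamma^{(-j)} = \hat\beta_{\mathrm{IVW}(-j)}\hat\gamma_j$; observed
  residual sum of squares compared against `n_sim` (default 1000) parametric
  simulations under the null; +1-smoothed empirical p-values (floor
  $1/(n_\mathrm{sim}+1)$); per-variant outlier calls Bonferroni-corrected
  over $J$ at `signif` (default 0.05); corrected estimate = IVW on unflagged
  variants; distortion test against 1000 random same-size removals. Fully
  seeded and bit-reproducible.
* **Leave-one-out**: $J$ IVW refits, each equal to an independent IVW call on
  the $J-1$ subset.

## Multivariable MR

Instruments are the union of each exposure's selected (and clumped)
instruments; cross-exposure betas are looked up for all union members, and a
variant missing from any exposure GWAS is dropped and audited rather than
imputed as zero (conservative). The fit is weighted multiple regression of
the outcome betas on the exposure-beta matrix without intercept, weights
$1/\sigma_{Yj}^2$, inflation floored at 1 with df $J-E$. A rank-deficient
design raises an error naming the offending exposures — note that an
exposure whose betas are all zero is itself rank-deficient, so the
"secondary exposure contributes nothing" limit is exercised through the
single-exposure reduction, which reproduces univariable IVW exactly.

## Two-step mediation

Step 1 estimates $\beta_1$ (exposure $\to$ mediator) per mediator from the
exposure's instruments; step 2 estimates $\beta_2$ (mediator $\to$ outcome)
from each mediator's own instruments, by *univariable* MR — the two effects
are reported separately and the product formula uses the raw $\beta_2$, a
deliberate reading documented here. Benjamini–Hochberg adjustment is applied
across the full panel separately per step; "significant" means $p < 0.05$
and adjusted $p < 0.05$, "suggestive" means $p < 0.05$ only. A mediator with
no surviving instruments is recorded as failed, never silently dropped.

The indirect effect is $\beta_1\beta_2$ with the first-order delta-method SE
$\sqrt{\beta_1^2\mathrm{se}_2^2 + \beta_2^2\mathrm{se}_1^2}$ — the
cross-covariance term is dropped because the two estimates come from
non-overlapping samples (limitation: with overlapping GWAS panels the SE is
optimistic). The proportion mediated is $100\,\beta_1\beta_2/\beta$ with
$\beta$ the univariable IVW total effect on the log-odds scale (the only
scale on which the ratio is dimensionless). The headline table keeps
mediators significant in both steps whose indirect effect shares the sign of
the total effect; proportions are reported as-is and never renormalized to
sum to 100%.

`table1_fixture()` ships the 69-row published reference table (rounded point
estimates, CI bounds and proportions, with per-cell printed precision) used
by the regression tests; the total effect attached to it is
$\log(1.153)$.

## The synthetic GWAS generator

`scenario_spec()` + `simulate_scenario()` encode the structural model the
analysis assumes: instruments act on the exposure with effects
$\gamma_j \sim N(0.08, 0.03^2)$ per allele; the exposure carries
$\beta_\mathrm{total}$ (default $\log 1.153$) onto the outcome; each mediator
sits on an $a\cdot b$ path and has its own instrument set so $\beta_2$ is
estimable; optional outcome-side instruments carry a reverse effect (default
0) so reverse-direction MR is estimable; optional pleiotropy acts on the
outcome associations only (InSIDE holds unless directional mode is chosen).
Observed betas are truth plus normal noise with
$\mathrm{se} = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ for continuous
traits and the case-fraction-scaled analogue
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n\,v(1-v)}$ for binary traits —
the standard summary-level approximation, avoiding individual-level
simulation. P-values come from the normal approximation, floored at the
smallest positive double so extreme hits cannot underflow to an invalid
$p = 0$. LD blocks replicate each exposure instrument into proxies with
effects attenuated by $\sqrt{r^2}$ and a block-constant LD matrix.

Default sample sizes mirror the motivating study's scale: a ~659k binary
exposure GWAS (9.5% cases), a ~392k binary outcome GWAS (2.3% cases), ~115k
continuous mediator GWAS, and 120 post-clumping instruments.

What the generator does **not** emulate: realistic LD beyond block
structure, allele-frequency/effect-size coupling, winner's curse beyond what
selection induces, sample overlap between GWAS, population stratification,
or non-normal effect distributions. A green test therefore establishes that
the estimators and pipeline are correct *under the stated structural model*,
not that the published real-data estimates are reproduced — those require
the original GWAS downloads and are out of scope.

## Numerical choices and degenerate inputs

* 95% intervals use 1.96 exactly; p-values are two-sided normal and floored
  at the smallest positive double.
* The IVW/Egger/MVMR SE inflation is floored at 1; this makes the Egger
  intercept test mildly conservative (empirical size ~4.6% at $J = 50$ over
  5000 null replicates).
* Clumping ties break lexicographically on variant id, so results are
  invariant to input row order.
* All-identical ratios: the weighted median and modes return the common
  ratio; zero KDE bandwidth is handled explicitly.
* `wald_ratio` with a zero exposure beta, IVW with fewer than 2 variants,
  Egger/median/mode with fewer than 3, MR-PRESSO with fewer than 4, and an
  empty harmonized set are errors, not silent results.
* Every stochastic SE (bootstraps, MR-PRESSO) takes an explicit seed and
  restores the caller's RNG state.

## Design choices where the design was open

* **MR-PRESSO spike-in world.** The outlier-correction claim ("the corrected
  estimate is closer to the truth than the uncorrected one in $\ge$95% of
  replicates") concerns the regime where the pleiotropic bias dominates
  estimator noise. A 10-SE offset on an average-weight instrument in a
  25-instrument panel shifts IVW by only ~1.9 estimator SEs, so sampling
  noise favours the *uncorrected* estimate ~17% of the time and no correct
  implementation can reach 95%. The shipped spike-in world therefore uses a
  10-instrument panel whose spiked instrument is strong
  ($\gamma_1 = 0.15$): the induced bias is ~5 estimator SEs and the claim is
  a property of the method rather than of luck.
* **Self-mediation check.** Screening a mediator identical to the exposure
  requires disabling the outcome-significance exclusion
  (`outcome_p_exclude = 0`): every instrument is genome-wide significant for
  itself by construction.
* **Calibration replicates.** The calibration check runs 2000 replicates
  (above the 500 floor) because the conservative Egger size (~4.6%) sits
  near the lower edge of the [3%, 7%] acceptance band and 500-replicate
  Monte-Carlo noise (±0.9%) would make the outcome a coin flip on the seed.
* **Recovery experiment.** The 23%-proportion recovery scenario omits null
  and outcome-side variants (irrelevant to the mediation path) to stay
  within the test-time budget; instrument count stays at the default 120.

## A caveat the generator makes visible

Step-2 instruments are selected from each mediator's GWAS with no filtering
beyond the harmonization rules (the analyzed design uses no Steiger
filtering). When the exposure's effect on a mediator is strong enough that
*exposure* instruments reach genome-wide significance in the mediator GWAS
(in the synthetic world: $a\cdot\bar\gamma$ more than ~5.5 mediator-GWAS
SEs), those variants enter the step-2 instrument set, and their Wald ratios
estimate $\beta_\mathrm{total}/a$ rather than $\beta_2$ — inflating
$\hat\beta_2$ and the mediation proportion. The generator reproduces this
faithfully: a blood-pressure-like mediator with $a = 0.54$ shows it, while
metabolite-scale effects ($a \approx 0.05$–$0.1$) do not. This is a known
structural caveat of two-step MR with naive instrument selection, inherited
from the analyzed design rather than introduced by the implementation.

## Known limitations

First-order Wald SEs; no cross-covariance in the delta method; no MVMR-Egger
or conditional F statistics; no MR-RAPS/contamination-mixture/CAUSE
estimators; no Steiger filtering or Radial MR; no reference-panel LD, no
liftover, no download clients. Mediators are analyzed one at a time — no
joint multi-mediator decomposition — so proportions across correlated
mediators can legitimately sum past 100%.
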