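# mrmediate

Two-sample, multivariable and two-step mediation Mendelian randomization
(MR) from GWAS summary statistics — for epidemiologists asking whether an
exposure causes an outcome, whether the effect survives adjustment for
correlated traits, and how much of it flows through candidate mediators,
using only published per-variant association tables.

Genetic variants serve as instrumental variables: for variant *j* with
exposure association γ̂ⱼ and outcome association Γ̂ⱼ (SE σⱼ), a valid
instrument satisfies Γⱼ = β·γⱼ, and the inverse-variance-weighted (IVW)
estimate pools the Wald ratios Γ̂ⱼ/γ̂ⱼ:

    β̂_IVW = Σ wⱼ γ̂ⱼ Γ̂ⱼ / Σ wⱼ γ̂ⱼ²,   wⱼ = 1/σⱼ²

with multiplicative random-effects SEs (inflation max(1, √(Q/(J−1)))).
MR-Egger, weighted-median and mode estimators guard against pleiotropy;
Cochran's Q, the Egger intercept, MR-PRESSO and leave-one-out probe the
assumptions. Two-step mediation estimates β₁ (exposure→mediator) and β₂
(mediator→outcome), the indirect effect β₁β₂ with a delta-method SE
√(β₁²se₂² + β₂²se₁²), and the proportion mediated 100·β₁β₂/β, with
Benjamini–Hochberg screening across the mediator panel. A synthetic GWAS
generator with a full structural model (instruments → exposure → mediators →
outcome, optional pleiotropy, LD blocks, reverse effects) makes every stage
testable without downloading real GWAS data.

## Worked example

Simulate a study with a true total effect of log(1.153) (an odds ratio of
1.153 per unit of genetic liability) and two true mediators, then run the
full pipeline:

```r
library(mrmediate)

spec <- scenario_spec(
  seed = 42,
  beta_total = log(1.153),   # total exposure -> outcome effect (OR 1.153)
  mediators = data.frame(name = c("bcaa", "tyr", "null_trait"),
                         a = c(0.075, 0.051, 0),     # exposure -> mediator
                         b = c(0.437, 0.271, 0)))    # mediator -> outcome
sc <- simulate_scenario(spec)

instruments <- clump(select_instruments(sc$exposure), sc$ld)
h <- harmonize(instruments, sc$outcome)
f_statistics(instruments, spec$n_exposure)
#> Instrument strength: R2 = 0.2965 over 108 variants (n = 659316), F = 2573.13

to_odds_ratio(ivw(h))
#> MR estimate [ivw]: beta = 0.126 (se 0.01944), 95% CI [0.08789, 0.1641], p = 9.08e-11, 108 SNPs
#>   OR 1.134 (95% CI 1.092-1.178)

mr_all_methods(h, seed = 1)[, 1:7]
#>            method nsnp   beta     se   ci_low ci_high     pval
#> 1             ivw  108 0.1260 0.0194  0.08789   0.164 9.08e-11
#> 2     egger_slope  108 0.1578 0.0616  0.03715   0.279 1.04e-02
#> 3 weighted_median  108 0.1167 0.0295  0.05884   0.175 7.71e-05
#> 4     simple_mode  108 0.1076 0.0565 -0.00308   0.218 5.67e-02
#> 5   weighted_mode  108 0.0962 0.0465  0.00508   0.187 3.85e-02
```

The IVW odds ratio 1.134 (CI 1.092–1.178) recovers the generative 1.153
within sampling error, and the four supplementary estimators agree.
Diagnostics show no heterogeneity or directional pleiotropy (none was
simulated):

```r
cochran_q(h)           # Q = 100.81 (df 107, p = 0.650)
egger_intercept_test(h) # b = -0.0028 (p = 0.586)
```

Two-step mediation screens the panel and keeps mediators significant in both
steps with direction-consistent indirect effects:

```r
cfg <- screen_config()
s1 <- screen_step1(sc$exposure, sc$mediators, cfg)
s2 <- screen_step2(sc$mediators, sc$outcome, cfg)
med <- run_mediation(ivw(h), s1, s2)
med$headline[, c("mediator", "beta1", "beta2", "indirect", "proportion_pct")]
#>   mediator  beta1 beta2 indirect proportion_pct
#> 1     bcaa 0.0749 0.442   0.0331           26.3
#> 2      tyr 0.0492 0.290   0.0143           11.3
```

The null mediator is screened out; the recovered proportions (26.3%, 11.3%)
sit near the generative values (23.0%, 9.7% of the total effect) within
Monte-Carlo error of a single replicate.

## File-based pipeline and CLI

`run_stage1()` (bidirectional univariable MR + sensitivity battery +
multivariable adjustment) and `run_stage2()` (two-step mediation) consume a
JSON `run_config()` pointing at summary-statistics TSVs (columns `SNP, chr,
pos, effect_allele, other_allele, eaf, beta, se, pval, n`; foreign headers
adapt via a dialect map) and write tidy report tables. The same machinery is
scriptable:

```sh
Rscript -e 'mrmediate::mr_cli()' simulate --out sim_dir --seed 42
Rscript -e 'mrmediate::mr_cli()' stage1 --config sim_dir/config.json --out reports
Rscript -e 'mrmediate::mr_cli()' stage2 --config sim_dir/config.json --out reports
```

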