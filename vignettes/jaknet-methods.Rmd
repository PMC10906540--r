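---
title: "Methods: arm-based Bayesian network meta-analysis in jaknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arm-based Bayesian network meta-analysis in jaknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jaknet)
```

## The problem

Four JAK inhibitors — tofacitinib 5 mg, baricitinib 4 mg, upadacitinib
15 mg, and filgotinib 200 mg — have each been compared to methotrexate
(MTX) monotherapy in randomized trials of DMARD-naive rheumatoid
arthritis, but never to each other. Ranking them on remission
(DAS28-CRP < 2.6) and low disease activity (DAS28-CRP ≤ 3.2) therefore
requires a network meta-analysis (NMA): the four trials form a *star*
network around the common MTX comparator, and every JAK-vs-JAK contrast
is estimated indirectly through MTX.

The packaged evidence network (`jak_network()`) carries the four trials —
2,185 patients in eight arms. The source publications report arm sizes and
response *percentages*, not counts, so `reconstruct_event_count()` recovers
integer events as `round(n * pct / 100)` with exact halves rounded up (no
half case occurs in the packaged data, so any deterministic tie rule gives
the same counts; the rule is fixed anyway so the reconstruction is
platform-independent). One caveat inherited from the source analysis: the
baricitinib trial defined remission by DAS28-ESR < 2.6 rather than
DAS28-CRP < 2.6; its arms are pooled with the others unchanged, and
`?jak_network` flags this.

## Model

For arm $k$ of study $i$ with $n_{ik}$ patients and $r_{ik}$ responders,

$$ r_{ik} \sim \mathrm{Binomial}(n_{ik}, p_{ik}), \qquad
   \mathrm{logit}(p_{ik}) = \mu_i + \Delta_{ik}, $$

where $\mu_i$ is the study baseline logit (its baseline arm $b_i$ is the
study's lowest-indexed treatment, MTX in every packaged trial) and
$\Delta_{ik}$ is the arm's effect relative to that baseline:

* **fixed effects** — $\Delta_{ik} = d_{t_{ik}} - d_{b_i}$, with $d_k$ the
  *basic parameter* (log odds ratio of treatment $k$ versus the reference,
  $d_{\mathrm{ref}} \equiv 0$);
* **random effects** — $\Delta_{ik} = \delta_{ik}$ with
  $\delta_i \sim \mathrm{MVN}\!\left(X_i d,\; \tau^2
  (\tfrac12 I + \tfrac12 J)\right)$: trial-specific effects with common
  between-study SD $\tau$ and correlation $1/2$ between effects sharing a
  study (the standard homogeneous-variance multi-arm structure; for the
  packaged two-arm trials it reduces to independent
  $N(d_t - d_b, \tau^2)$ effects).

Every contrast is a difference of basic parameters
($d_{AB} = d_B - d_A$), so indirect estimates are consistent by
construction. The unrelated-mean-effects (UME) variant used by the
inconsistency diagnostic replaces $d_{t} - d_{b}$ with one free parameter
per observed design pair; both variants are expressed through the same
arm-level design matrix.

### Priors

The analysis that this package reconstructs was run on tooling whose
prior settings are unpublished; `jaknet` therefore uses explicit vague
defaults, all configurable in `nma_config()`:

| parameter | prior | default | scale |
|---|---|---|---|
| $d_k$ | $N(0, \sigma_d^2)$ | $\sigma_d = 100$ | log-odds |
| $\mu_i$ | $N(0, \sigma_\mu^2)$ | $\sigma_\mu = 100$ | log-odds |
| $\tau$ | $\mathrm{Uniform}(0, u)$ | $u = 2$ | log-odds SD |

With eight informative arms the likelihood dominates: refitting with
$\sigma_d = \sigma_\mu = 15$ moves every fixture OR by well under 5%
(asserted in the test suite). A between-study SD of 2 on the log-odds
scale is far above anything plausible for this outcome, so the uniform
upper bound is not binding.

## Posterior computation

`sample_posterior()` runs an adaptive random-walk
Metropolis-within-Gibbs sampler written in C++:

* one Gaussian random-walk update per scalar parameter per iteration,
  with per-parameter proposal scales tuned toward 0.44 acceptance by
  Robbins–Monro adaptation during burn-in and frozen afterwards;
* one *joint* move per effect parameter along the posterior's dominant
  ridge — for fixed effects, $d_j$ up and its studies' baselines down
  (the two are strongly anticorrelated within a study); for random
  effects, $d_j$ together with the $\delta$'s centred on it. The second
  variant is what keeps the random-effects chain mixing as
  $\tau \to 0$, where scalar updates alone stall in the funnel;
* defaults of 4 chains, 10,000 burn-in and 10,000 monitoring iterations
  per chain (thin 1), matching the run lengths of the reconstructed
  analysis; chain $c$ draws from an independent RNG stream seeded with
  `seed + c`, so results are bit-reproducible for fixed inputs.

Convergence is gated on split-$\hat R$ ($< 1.05$) of every effect
parameter; a failing run raises an error carrying the diagnostics rather
than returning silently. $\hat R$ for $\tau$ is reported but not gated: on
networks with one study per comparison $\tau$ is prior-dominated and mixes
slowly without being wrong, and gating it would reject valid fits.

Point estimates are posterior **medians** with central 95% credible
intervals, and all quantiles are computed on the log-OR scale and then
exponentiated. On the log scale the empirical quantile function is exactly
antisymmetric under negation, which is what makes league-table
reciprocity exact: `median(A vs B) * median(B vs A) = 1` to machine
precision, and CrI endpoints swap and invert across the diagonal. A
comparison is declared significant when its 95% CrI excludes 1.

## Ranking

`rank_probabilities()` ranks the treatments within each retained draw
(larger $d$ = better for efficacy outcomes; a `direction` flag reverses
this for harms), giving the matrix $P[j, r]$ = probability that treatment
$j$ has rank $r$. Tied draws — impossible for continuous posteriors,
possible for constructed integer draws — spread their mass uniformly over
the tied rank positions, which preserves double stochasticity and equals
averaging over tie-break orders. SUCRA is the normalised area under the
cumulative ranking curve,

$$ \mathrm{SUCRA}_j = \frac{1}{a-1} \sum_{r=1}^{a-1} \sum_{s \le r} P[j, s], $$

equal to 1 for a certain winner, 0 for a certain loser, and summing to
$a/2$ exactly. SUCRA is reported as a fraction in $[0,1]$ (the convention
of the table being reconstructed) to three decimals. `league_table()`
orders treatments by descending SUCRA, so the top-left cell belongs to the
best-ranked treatment and upper-triangle ORs $> 1$ favour the row.

## Diagnostics

* **Monte-Carlo error** (`mc_error_check()`): batch-means MCSE per chain
  (batch size $\approx \sqrt{N}$), pooled across chains, compared to the
  posterior SD; the run passes when every ratio is below 5%. A degenerate
  constant chain is reported as ratio 0. At the default run lengths the
  fixture fits pass with ratios around 0.01.
* **Residual deviance** (`arm_deviance()`): posterior mean saturated-model
  binomial deviance per study arm ($0 \log 0 \equiv 0$); a well-fitting
  model contributes about 1 per arm. pD and DIC are derived from the
  deviance at the posterior-mean fit and reported alongside.
* **Inconsistency** (`inconsistency_comparison()`): per-arm deviances
  under the consistency and UME fits, paired — the data behind the usual
  inconsistency scatterplot. On a loop-free star network the two models
  are structurally identical, so the report states that no closed loops
  exist and the pairs coincide up to Monte-Carlo noise; the machinery is
  only informative on networks with cycles, which the synthetic `loop3`
  scenario exercises by injecting direct/indirect conflict.
* **Sensitivity** (`sensitivity_compare()`): side-by-side FE and RE OR
  summaries with an agreement flag (same significance classification and
  medians within 25% by default). On the packaged star network the FE and
  RE *medians* agree closely, but $\tau$ is essentially unidentified from
  four single-comparison trials: under the vague $U(0,2)$ prior its
  posterior tracks the prior, RE intervals become very wide, and the
  significance classifications are not comparable. This is a property of
  the evidence structure, not of the sampler, and is the main reason the
  fixed-effects model is the primary analysis here.

## Synthetic-data validation

`synthetic_truth()` / `simulate_network()` generate trial networks from
known parameters: study baselines $\mu_i \sim N(m, s^2)$, trial effects
$\delta \sim N(d_t - d_b, \tau^2)$, events binomial. Each study draws
from a deterministic substream of the global seed, so appending studies
never perturbs earlier ones. Three presets cover the cases the tests
need: `star4` (the packaged geometry — four two-arm trials against a
common reference with true ORs 2.12/1.95/4.13/1.79 and ~17% baseline
response), `loop3` (a closed three-treatment loop for inconsistency
checks), and `hetero` (`star4` with $\tau = 0.5$).

`recovery_harness()` repeats simulate → fit → summarise, reporting
per-parameter bias, 95% CrI coverage, and how often the truly best
treatment tops the SUCRA ranking. Over 20 replicates of `star4` at the
default run lengths, coverage sits at its nominal level within binomial
noise and the top treatment is identified essentially always.

What the generator emulates is exactly the model's assumed data-generating
process. Passing recovery therefore validates the inference machinery —
likelihood, priors, sampler, ranking — but says nothing about model
misspecification on real trials: no non-collapsibility effects, no
covariate imbalance, no selective reporting, no dose heterogeneity within
a treatment label. Those caveats apply to any NMA of this design and are
not testable from four trials.

## Numerical choices and degenerate inputs

* Event reconstruction rounds half up (`floor(x + 0.5)`), clamped to
  $[0, n]$.
* Medians rather than means: reciprocity then holds exactly (means of
  reciprocal lognormal-ish draws do not multiply to 1).
* Chain starts: baselines at empirical logits with SD-0.5 jitter, effects
  jittered around zero — overdispersed enough for split-$\hat R$ to mean
  something, close enough to converge within the default burn-in.
* Zero-event networks: with no events anywhere, the binomial likelihood
  decreases monotonically in every logit, so vs-reference ORs are pulled
  *below* 1 in proportion to the prior SD — the prior centres contrasts
  between exchangeable arms, not contrasts against the baseline-anchored
  reference. The tests assert the symmetric contrast; users fitting
  all-zero data should expect this behaviour, which is inherent to the
  arm-based model, and consider continuity corrections upstream.
* Simulated probabilities that underflow to 0/1 warn rather than error
  (such arms are legal but carry no effect information).

## Problem sizes

Unit tests run reduced chains (2 × 2,000 + 2,000) — enough for the
distributional assertions they make at their stated tolerances — while the
end-to-end checks of the published numbers run the full 4 × 10,000 +
10,000 configuration; a fixture fit takes well under a second either way.
The recovery harness in the test suite uses 20 replicates of the `star4`
scenario.

## Known limitations

* The exact CrI endpoints of the reconstructed analysis are not
  reproducible to the second decimal because its prior and initialisation
  settings are unpublished; point estimates and significance calls
  reproduce comfortably. (One published filgotinib interval is itself
  internally inconsistent between summary and table — 1.27–3.53 vs
  1.27–2.53 — so only the point estimate is meaningful there.)
* $\tau$ is unidentifiable from one study per comparison; random-effects
  results on such networks are prior-driven by necessity.
* No contrast-based likelihood, no meta-regression, no node-splitting
  inconsistency method, and no P-score analogue — outside the package's
  scope.
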