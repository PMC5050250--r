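---
title: "Methods: Bayesian analysis of internal replication and independent replication success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian analysis of internal replication and independent replication success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesrep)
```

# The question and the two competing accounts

A study-level replication dataset pairs each original effect with the
outcome of an independent, direct replication attempt. Some original
publications also contained *internal, conceptual* replications — the
same theory shown again under a varied design. If internal replication
marks robust phenomena (the *unknown moderator* account), internally
replicated effects should replicate independently more often. If
internal replications are largely a by-product of questionable research
practices (the *QRP* account: optional stopping, publication bias,
HARKing), they carry no such information, and the null model of equal
replication-success proportions should be supported.

`bayesrep` implements both halves of that argument: the Bayesian
comparison machinery, and generative QRP simulations showing how easily
null effects acquire internal replications.

# Contingency-table Bayes factors

The primary comparison is a 2×2 table: successes (replication *p* < .05,
strict) out of fixed group totals for the internally replicated and
internally unreplicated groups. We use the Dirichlet-multinomial
(Gunel–Dickey family) test under the independent-multinomial sampling
plan, since the group sizes are the margin fixed by the design:

* **Null**: one success probability shared by both groups, prior
  Beta(*a*, *a*);
* **Alternative**: independent per-group probabilities, each Beta(*a*, *a*).

Both marginal likelihoods are closed-form Beta functions
(`dm_log_evidence()`); binomial coefficients cancel and are omitted
consistently. The prior concentration defaults to *a* = 1 (uniform), the
conventional default for a designed two-group comparison; larger *a*
pulls both models toward ½ and, on tables with a real difference,
monotonically erodes the alternative's advantage.

The reported hypotheses are one-sided (the moderator account asserts a
*direction*), obtained by posterior restriction:

$$\mathrm{BF}_{+0} = \mathrm{BF}_{10} \times
  \frac{P(\text{direction} \mid \text{data, alt})}{1/2},$$

with the direction probability computed from the two independent Beta
posteriors. Sampling (default, 100,000 draws, seeded) matches the
reference behavior of contingency Bayes factor software; a deterministic
1-D integration is available (`method = "integration"`) and is used
where speed and exactness matter (e.g. the world-discrimination sweep).
Sampled ties (`p1 == p2`) count one half; the event has measure zero and
the rule exists only for bit-level reproducibility.

Estimation draws both probabilities from their Beta posteriors and
summarizes the **log odds ratio** or **proportion difference** by the
posterior median and an equal-tailed (percentile) 95% credible interval
— percentile rather than HDI, matching the convention of contingency
samplers; HDI is reserved for the robust module below. The contrast is
always signed toward the directional alternative, so a positive median
supports the moderator account. Both estimands are computed and reported
for contingency rows because the emulated analysis mixes the two scales
across its table rows; reports carry a note flagging this rather than
guessing intent.

Directional conventions for the predictor rows are declarative and
overridable (`default_predictor_directions()`). The general rule —
"reproducibility-favoring levels are more common among internally
unreplicated effects" — sets most rows (e.g. main effects more common in
the unreplicated group; social-psychology membership more common in the
replicated group). The formal-power-analysis row is the one exception:
its published convention treats *presence in the internally replicated
group* as the alternative, and the default follows that table
convention.

# JZS Bayes factor and robust estimation for continuous predictors

Continuous predictors are compared with the default Bayesian two-sample
test: δ ~ Cauchy(0, √2/2) ("medium"; the reference default at the time
of the emulated analysis). We evaluate

$$\mathrm{BF}_{10} =
  \frac{\int f_{t,\nu}\!\left(t \mid \mathrm{ncp} = \delta\sqrt{n_\mathrm{eff}}\right)
        \pi(\delta)\, d\delta}{f_{t,\nu}(t \mid 0)},
  \qquad n_\mathrm{eff} = \frac{n_1 n_2}{n_1 + n_2},$$

a 1-D adaptive quadrature over the Cauchy prior using the exact
noncentral-t likelihood of the t statistic; the test suite cross-checks
it against a dense-grid integration of the equivalent g-mixture
representation. Directional versions restrict the posterior of δ, as
above. Raw values are analyzed except where the emulated analysis
documents a transform: original sample size is taken to the natural log,
with the one unusually large study (N = 230,025) flagged excluded — a
flag, never a deletion, and the exclusion count is echoed in the report
row.

Estimation of group differences uses the robust model (the BEST family):
observations in group *j* are t-distributed with location μ_j, scale
σ_j, and a shared normality parameter ν. Priors are deliberately vague:
μ_j ~ Normal(pooled mean, (1000·pooled sd)²), σ_j uniform over (pooled
sd/1000, pooled sd·1000), ν − 1 ~ Exponential with mean 29 (ν averages
about 30 — near-normal — but can drop toward 1 when the data demand
heavy tails). Sampling is single-chain Metropolis-within-Gibbs on the
scale-mixture representation (conjugate updates for the latent weights,
locations and truncated inverse-gamma scales; a log-scale random walk
for ν), which is ample at desk scale; a split-chain scale-reduction
diagnostic is computed on the retained draws and *flagged* in the result
if above 1.1, never silently ignored. Intervals are 95% HDIs by
convention for this module (percentile available). The default of
100,000 retained draws matches the estimation budget of the emulated
analysis; tests and sweeps use smaller, stated budgets (3,000–30,000)
because the posterior for two groups of ~50 observations is effectively
exact well below the default.

# QRP simulators

Observations are unit normal and every test is a standard two-sided
pooled-variance t test with closed-form p-values — the convention of the
simulation literature this module follows.

* **Optional stopping** (`simulate_optional_stopping()`): peek at per-group
  sizes n_min, n_min+step, …, n_max and stop at the first *p* < α. The
  default schedule — peek after every added observation from 10 to 50
  per group — echoes the cited designs and pushes the false-positive
  rate to roughly 0.2 (vs the nominal .05); all observations are drawn
  before peeking, so designs sharing a seed differ *only* in their peek
  schedule (common random numbers), making monotonicity-in-peeking
  comparisons sharp.
* **Publication bias** (`apply_publication_bias()`): significant results
  always survive; non-significant ones with probability
  `prob_report_nonsignificant` (default 0, a total file drawer).
  Selection for significance inflates mean published |d| above the
  unconditional mean.
* **HARKing** (`apply_harking()`): reported effects are sign-aligned with
  the post-hoc hypothesis, i.e. absolute values, order preserved.
* **Publication records** (`simulate_publication_record()`): a lab runs
  `n_candidates` studies on one effect under the enabled QRPs; an effect
  is *internally replicated* when at least two published significant
  studies exist.

# The synthetic world generator

`generate_dataset()` emulates a 100-study reproducibility-project-style
table under either account. Per effect:

1. A latent replication-relevant effect: null with probability
   `null_fraction` (default .5), otherwise |r| ~ Normal(.4, .1) on the
   correlation scale, converted by d = 2r/√(1 − r²) (equal groups;
   unit-tested inverse `d_to_r()`).
2. **The lab record is pure QRP machinery.** Candidate internal studies
   test a signal *uncorrelated* with the replication-relevant effect
   (the QRP account's formalization: conceptual-replication success is
   driven by the practices, not the phenomenon). Every candidate runs
   optional stopping; only significant results are published; published
   effects are HARKed. Labs that pursue internal replication (fraction
   .44) keep running candidates until their target count — drawn from
   the documented 20:10:9:5 marginal over 1–4 — is published, a
   study-level form of sampling-until-success squarely in the QRP
   spirit. This construction makes the two groups' success proportions
   equal *in expectation* in `qrp_world`, which is the point of the
   account.
3. The replication runs cleanly: a single two-sample t test at a size
   powered at .92 against the original's claimed effect (so the
   `replication_power` column averages ≈ .92). Its true effect is the
   latent effect attenuated by `attenuation` (default .5); in
   `moderator_world` internally replicated effects are attenuated less,
   by the factor (1 − coupling), with coupling = 1 ("strong") by
   default. Setting coupling = 0 makes the worlds identical draw for
   draw.

Defaults were fixed once by closed-form power arithmetic: with half the
effects null and attenuation .5, overall success lands near one third
(between the two groups' documented 29% and 41%), while strong coupling
opens a success-proportion margin of roughly 0.15 at n = 2000 — enough
for `world_discrimination_check()` to support the null in `qrp_world`
(BF₀₊ > 3) and the alternative in `moderator_world` (BF₊₀ > 10) in the
vast majority of seeded runs.

**What the generator does not emulate**: correlation between covariates
and outcomes (field of study, surprisingness etc. are drawn
independently), per-study heterogeneity in QRP intensity, non-normal raw
data, and any fit to the real per-study dataset. Passing tests on
synthetic tables therefore validate the *pipeline's* correctness and
discrimination, not substantive claims about real data. The packaged
deterministic fixture (`synthetic_osc_fixture()`,
`inst/extdata/synthetic_osc100.csv`) is a different object: it
reconstructs the *documented categorical marginals* exactly (success
counts 12/42 and 22/54, field 13/29 vs 29/25 with their subgroup
successes, effect type 20/36 vs 29/50, power analysis 0/42 vs 2/54, the
N = 230,025 outlier, and 4 missing replication outcomes), with
deterministic plausible sequences for continuous columns. Contingency
results on the fixture are therefore exactly the documented ones;
continuous-row results are not, and are validated by property-based
tests instead.

# Numerical choices and degenerate inputs

* Closed-form evidences are validated against composite-Simpson
  quadrature on a dense grid, exhaustively for all 2×2 tables with
  entries ≤ 5.
* The one-sided correction at a perfectly balanced table returns
  direction probability ½ exactly (integration) or within Monte-Carlo
  error (sampling).
* Zero cells are handled by the prior: with *a* = 1 a 0-of-n row has
  evidence 1/(n + 1) and posterior Beta(1, n + 1); nothing special-cases.
* Zero pooled variance is a degenerate-data error for the JZS test;
  groups with fewer than 2 usable values make a report row
  "insufficient", with no Bayes factor emitted.
* Missing values: empty CSV fields, never sentinels; missingness is
  confined to replication outcomes, ratings and effect type (the
  documented effect-type group totals imply missing classifications) and
  survives I/O round trips. Predictor groups are formed among studies
  with usable replication outcomes, matching the documented group sizes
  (42/54).
* Reports derive per-row seeds from the master seed, so a fixed seed
  makes the entire report byte-identical across runs.

# Problem sizes used by the test suite

Deterministic checks run at the documented table sizes. Stochastic
checks use sizes chosen for tight Monte-Carlo error at desk scale:
100,000 direction-probability draws where documented values are
reproduced (tolerance ±5% relative); 200 synthetic datasets of 50 + 50
observations for interval calibration (±4 percentage points); 20 seeded
runs per world at n = 2000 studies for discrimination; 4,000–20,000
simulated studies for the QRP rate checks (2–3 Monte-Carlo standard
errors).

# Known limitations

* Only 2×2 tables and the independent-multinomial plan are implemented;
  Poisson, joint-multinomial and hypergeometric variants of the
  Gunel–Dickey family are out of scope.
* The robust sampler is single-chain; the split-chain diagnostic detects
  slow mixing but not multimodality (irrelevant for this unimodal
  posterior family).
* The moderator account has no canonical generative model; the
  attenuation-coupling formalization here is this package's own, and
  conclusions from `moderator_world` runs are conditional on it.
* Continuous-predictor rows of a real analysis depend on per-study raw
  values; with only documented summaries available, those paths are
  validated by recovery and calibration studies on synthetic data.
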