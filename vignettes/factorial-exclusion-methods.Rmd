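---
title: "Simulating and analysing multi-site factorial consumer-exclusion experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing multi-site factorial consumer-exclusion experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factex)
```

## The experiment and its model

`factex` supports the design and analysis of distributed field experiments
in which three groups of plant consumers — insects, mollusks, and foliar
fungal pathogens — are suppressed with biocides in a full 2^3 factorial.
Every site holds randomized complete blocks (three by default) of all
eight treatment combinations, 24 plots per site, so every block is a
miniature of the whole experiment and absorbs local environmental
variation.

Plot biomass is modelled hierarchically:

$$y_{sbp} = \beta_0 + \beta_i I + \beta_f F + \beta_m M
  + \beta_{fm} FM + \beta_{im} IM + \beta_{if} IF + \beta_{ifm} IFM
  + u_s + v_{sb} + e_{sbp},$$

with $I, F, M \in \{0, 1\}$ indicator-coded biocide applications and
independent Gaussian site, block-within-site, and plot-within-block
effects. The default standard deviations — 372.7 g between sites, 7.82 g
between blocks, 15.33 g between plots, around a 100 g baseline — are the
network's baseline-data estimates; they are the study conditions, not
tuning knobs. With one observation per plot the plot-level draw *is* the
residual, so `sd_plot` doubles as the residual SD in fitting.

Three effect families map onto the coefficients
(`effect_scenario()`), with $\delta$ = `effect_pct`% of the baseline:

* **main_only** — $\beta_i = \beta_f = \beta_m = \delta$, no interactions:
  each biocide alone raises biomass.
* **superadditive** — mains as above plus $\beta_{fm} = \delta$: combining
  fungicide and molluscicide yields more than the sum of their parts. The
  synergy is injected on the fungicide x molluscicide pair; set
  `all_pairs = TRUE` to put it on all three pairs for sensitivity work.
* **compensatory** — mains as above with $\beta_{\text{pair}} = -2\delta$
  for all three pairs and $\beta_{ifm} = +3\delta$, so *every* multi-biocide
  cell sits exactly at the baseline: one consumer group fully compensates
  for another. The three-way value is the unique choice that extends
  "no increase for combined application" to the triple cell.

Effects are additive in grams on the common baseline rather than
multiplicative on site-specific means: the generating equation is additive,
and an additive reading keeps the scenario families exactly orthogonal to
the variance components. Random draws are Gaussian at every level; the
generator makes no further distributional claims.

## Monte-Carlo power analysis

`estimate_power()` asks: if the experiment were run afresh, how often
would a given term be detected? Each of `n_sim` replicates redraws *all*
random effects (sites, blocks, plots) and the analysis is run exactly as
it would be on field data:

1. fit the full factorial mixed model
   `biomass ~ insecticide * fungicide * molluscicide + (1 | site) +
   (1 | block-within-site)` by maximum likelihood, indicator coding;
2. refit without the tested term and compare by a likelihood-ratio test
   (one degree of freedom, statistic clamped at zero);
3. count p < 0.05.

The rejection count is reported with its exact Clopper–Pearson interval
(`clopper_pearson()`, beta-quantile form), the appropriate interval for a
binomial count at the extremes where power is near 0 or 1.

Design choices worth making explicit:

* **Full factorial fixed effects in every scenario.** Interactions are kept
  in the model even when truly zero, because the interaction scenarios need
  them and a pre-registered analysis would not switch models by scenario.
* **Indicator coding and the meaning of a "main effect" test.** Dropping a
  main-effect column from a model that retains its interactions tests, under
  indicator coding, the effect of that biocide in the stratum where the
  other two are absent (the reduced model equates the single-biocide cell
  with the control and leaves every other cell free). Under effect (±1)
  coding the same deletion would test the *marginal* main effect averaged
  over the other treatments, which on a balanced design is estimated from
  all plots and therefore detected with more power. The simulator's
  generating equation is written in 0/1 coding, so the power engine fits in
  0/1 coding; the coding choice is exposed in `fit_lmm()` for users who want
  the marginal version.
* **Likelihood-ratio rather than Wald tests** for power, so the tested
  quantity is "does removing this term significantly reduce model
  likelihood", matching the package's model-simplification procedure. At
  these sample sizes the two are nearly indistinguishable.
* **Replicate seeds are counter-based** substreams of the master seed,
  so runs are reproducible, rows are independent, and no call site draws
  from an unseeded source. A replicate whose fit raises a convergence
  warning is redrawn once and otherwise counted as a non-rejection (and
  tallied), a conservative disposition that cannot inflate power.
* **Speed.** Within a power run the design matrix never changes, so both
  template models are fitted once and replicates only swap the response in
  (`lme4::refit`); a full 300-replicate row on the 35-site design takes
  seconds rather than minutes. A test verifies the refit path agrees with
  a from-scratch fit.

On this design the noncentrality of the main-effect test is
$\delta\sqrt{n_{\text{cell}}/2}/\sigma_{\text{plot}}$ with
$n_\text{cell} = 105$ plots per cell, and the interaction test uses the
four cells of the double-control stratum; power is therefore high (≥ 95%)
for main effects of ≈ 7.5% of baseline and for superadditive interactions
of ≈ 15%, while compensatory interactions — whose pairwise coefficients are
twice the nominal effect — are detectable already at 5%. Those analytic
expectations agree with the package's own Monte-Carlo output (see the
acceptance script), which is the package's account of what this procedure
yields under these study conditions.

## Within-block permutation calibration

`false_positive_analysis()` answers a different question: with eight terms
tested per model, how often is *something* significant by chance? It
shuffles the response within every block (preserving each block's multiset
of values exactly, hence the design structure), refits the ±1-coded
factorial mixed model, and counts per-term Wald significances over
thousands of iterations. Because permutation destroys any
treatment–response association, every non-intercept term should come up
significant in a fraction α of iterations *regardless of what the input
data contain* — the package tests this on data with strong true effects,
not just on nulls. Effect coding is used here because the counts are read
from the model summary, and ±1 coding makes the summary's main-effect rows
marginal means rather than simple effects.

The analysis scale deserves care. Field biomass is positive and
right-skewed, and the reference analysis logs it. Synthetic data drawn
with a *gram-scale* site SD (372.7 g) around a 100 g baseline necessarily
contain negative values, so the log model cannot be applied as-is;
`false_positive_analysis()` then instructs the user to supply an `offset`
or use the identity scale. Both remedies were examined:

* **Identity scale:** the per-term rates sit inside the exact binomial
  band around α. The intercept, however, is not "significant in every
  iteration" the way a logged field dataset's intercept is, because the
  between-site SD dwarfs the 100 g mean.
* **Offset-then-log:** the intercept proportion becomes 1.0, but the
  per-term rates run slightly *below* α (typically 3–4.5% at α = 5%),
  robustly across offset sizes and seeds. The mechanism: when the SD
  exceeds the mean, any shifted log is dominated by the lowest-baseline
  site, whose blocks contribute most of the residual variance; the
  randomization distribution of a contrast built from a few bounded
  block-level permutation distributions is platykurtic, and a
  normal-reference Wald test under-rejects against light tails.

This is an artifact of forcing a log model onto data whose dispersion
exceeds their level — on positive, log-homoscedastic data the logged
analysis calibrates at α, as the test suite shows on smaller-variance
generators. The package therefore treats the identity-scale run as the
calibration benchmark for gram-scale synthetic data, and keeps the
log-with-offset route available (with the smallest-value-to-1 convention)
for data that are merely shifted, not scale-pathological. With multi-year
input only each plot's most recent record is analysed.

## The pre-registered analysis pipeline

The modelling surface mirrors how the network pre-registered its
analyses, all through `fit_lmm()` (lme4 underneath; OLS when no random
intercepts are requested):

* `fit_site_model()` — per-site factorial with block as a categorical
  covariate; with several years, the longitudinal variant with calendar-year
  and plot random intercepts. Block enters as a fixed factor in the
  single-year model because with three blocks a variance component is
  poorly identified; the mixed alternative is available through
  `fit_lmm()` directly.
* `fit_overall_model()` — cross-site model with year-since-start (0 at
  each site's baseline, so the intercept is the baseline control mean)
  crossed with the factorial, and random intercepts for site,
  block-within-site, plot-within-block, and calendar-year-within-site.
  Degenerate inputs degrade explicitly: single-year data drop the year
  terms and the calendar-year intercept with a warning rather than
  failing or silently absorbing them.
* `fit_context_model()` — a per-site driver (climate, soil, control
  richness or productivity), centred and scaled, interacting with the
  treatments. Standardization is an affine reparameterization (the
  likelihood is unchanged — tested), but it makes the driver main effect
  and interactions readable in SD units. A driver that is constant across
  sites is refused rather than silently dropped.
* Community responses: `shannon()` (nats), `richness()`, `group_cover()`
  (percent of total cover, unmapped species pooled into "other"), and
  `n_groups_recode()` for the 0–3 excluded-groups recoding.

`simplify_model()` implements backward elimination of interactions by
likelihood-ratio test: highest order first, within an order the largest
p-value first (the procedure is specified only as "stepwise", so the
least-defensible term goes first), main effects never removed, and a term
is protected while a retained higher-order interaction contains it. All
comparisons refit by ML. Two consequences are worth knowing. First,
elimination stops at an order as soon as its worst term is significant, so
a significant three-way freezes the model (marginality). Second, under a
global null the *three-way* is retained at rate α, but each two-way is
retained at approximately α + (1−α)α ≈ 0.0975 at α = 0.05, because it
survives either on its own test or under a retained three-way; the test
suite asserts both rates at their derived values. No multiplicity
correction is applied along the elimination path, matching the
pre-registered procedure; full-model summaries remain available alongside.

## The synthetic generators: what they do and do not emulate

`simulate_experiment()` reproduces the hierarchical structure (sites,
blocks, plots), the factorial treatment effects, and the variance
components; optionally persistent plot effects, linear year trends, and
calendar-year shocks for longitudinal testing. `simulate_community()`
emulates cover sheets: log-normal species abundances from per-site pools,
multiplicative consumer effects on the dominant or most subordinate
species applied where consumers are present (plots *without* insecticide),
covers reported to 0.1% minimum so totals can exceed 100%.

Deliberately not emulated: non-Gaussian biomass, temporal autocorrelation
beyond independent year effects, spatial structure within sites,
treatment-by-site interaction variance (random slopes), damage scores,
traits, and soil covariates. Green tests therefore certify the machinery —
estimators recover what this generator encodes, tests hold their nominal
size under this null — not that field data satisfy the generator's
assumptions; in particular the power numbers inherit the additive-Gaussian
reading of the effect scenarios.

## Numerical conventions

* α = 0.05 two-sided throughout; Wald p-values use the standard normal
  reference (no Satterthwaite or Kenward–Roger degrees-of-freedom
  corrections — at 840 observations per fit they would be cosmetic).
* A zero standard error reports p = 0 for a nonzero estimate and p = 1
  for a zero estimate; identical models compare with statistic 0 and
  p = 1.
* LRT statistics are clamped at zero (REML/optimizer noise can produce
  tiny negative differences); degrees of freedom are counted as the
  difference in fixed-effect coefficients; term labels are compared
  order-invariantly ("a:b" equals "b:a").
* Perfect collinearity among fixed-effect columns is an error naming the
  aliased columns, never a silent drop. Singular variance components are
  flagged, not hidden.
* Every public function that draws randomness takes a seed, restores the
  caller's RNG state, and derives any substreams deterministically;
  designs built with the same seed are identical and extending a design
  never reshuffles existing blocks.

Problem sizes used by the test suite are chosen to make each property
sharp but cheap: the full 35-site design (300 replicates per row) for the
power table, 29 sites and 1,000 iterations for permutation calibration,
200 sites for variance-component recovery, 12 sites and 200 simulations
for the elimination study, and 10,000-draw checks for distributional
properties of the generators.

## Known limitations

Only Gaussian responses are fitted (percentage damage and other
non-normal responses would need a GLMM backend); permutation p-values for
*observed* effects are out of scope (permutation is used for calibration
only); structural equation modelling of mechanisms is not implemented; and
the power presets parameterize the 35-site network layout — other layouts
are reachable through `n_sites`/`n_blocks` but ship without presets.
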