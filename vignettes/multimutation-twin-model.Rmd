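---
title: "The multimutation onset model and twin concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multimutation onset model and twin concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtwin)
```

## The model

`mmtwin` implements a genetic multimutation model of age of onset for
autism spectrum disorder (ASD). The model assumes that a *susceptible*
child is born carrying the predisposition, and that the full disorder
manifests once `m = m1 + 1` mutation events have accumulated: `m1`
interchangeable steps, each occurring at rate `k1` per month, plus one
step at rate `k2` per month. Because the `m1` steps can occur in any
order, the probability that a susceptible individual has developed the
disorder by age `t` months is

$$P_s(t) = \left(1 - e^{-k_1 t}\right)^{m_1}\left(1 - e^{-k_2 t}\right),$$

a proper CDF on ages: $P_s(0) = 0$, nondecreasing, with limit 1 — every
susceptible individual eventually develops the disorder;
non-susceptible individuals never do. Its derivative
$\mathrm{IR}_s(t) = dP_s/dt$ is the incidence-rate density of onset
ages, which integrates to one.

The shipped parameter library (`param_library()`) carries the sets
fitted to 2014 IAN registry cumulative age-of-first-diagnosis counts —
`asd_male` (`k1 = 0.12605`, `k2 = 0.030207`, `m1 = 17`) and `asd_female`
(`k1 = 0.12532`, `k2 = 0.031716`, `m1 = 17`), rates per month — plus a
schizophrenia set whose published per-year rates are divided by 12 on
load. Months are the package's single internal time unit.

```{r landmarks}
pf <- param_library("asd_female")
onset_quantile(0.5, pf)        # median onset, ~33 months
susceptible_prevalence(124, pf) # 98% of susceptibles by ~10.3 years
peak_incidence_age(pf)          # incidence density peaks near 25.6 months
```

### Which parameter set reproduces which printed value

The male and female curves never differ by more than 0.015 in
probability, and the source analysis treats them as interchangeable.
They are not numerically identical, though: the illustrative landmark
values (median 33 months, 98% at 124 months, the 40-month twin-state
triple, 50% concordance at 42 months, 96% at 123 months, the 55-month
effective cohort age) are reproduced by the **female** set, while the
clock-rate calibrations (0.865 for a 39-month median, 0.613 for a
55-month median) require the **male** set. The package exposes both and
every analysis names its set explicitly rather than guessing a single
intended set. With the female set the peak incidence age computes to
25.66 months (the male set gives 25.62); published discussion rounds
this to 25.6.

## Twin concordance

Identical (monozygote, MZ) twins are assumed either both susceptible or
both not; co-susceptible twins acquire mutations *independently*, so
their onset ages are independent draws from $P_s$. For a susceptible MZ
pair the states "both affected / exactly one / neither" at age $t$ have
probabilities $P_s^2$, $2P_s(1-P_s)$, $(1-P_s)^2$.

Registries ascertain a pair only when at least one twin is diagnosed.
The package therefore works throughout with **pairwise** concordance —
concordant pairs over pairs with at least one affected twin:

$$C_M(t) = \frac{P_s^2}{P_s^2 + 2P_s(1-P_s)} = \frac{P_s(t)}{2 - P_s(t)},$$

which climbs monotonically to 100%. This convention is chosen because
its inversion $P_s = 2c/(1+c)$ reproduces the published identity
$c = 41/60 \mapsto P_s = 82/101$ exactly; probandwise concordance is
deliberately not implemented.

For fraternal (dizygote, DZ) pairs the model conditions on a
susceptible index twin and gives the co-twin inherited susceptibility
$S_\mathrm{inher} \in [0,1]$. Under the same pairwise convention,

$$C_D(t) = \frac{s\,P_s(t)}{1 + s\,(1 - P_s(t))}, \qquad s = S_\mathrm{inher},$$

which saturates at $s$, not at 100% — the model's signature separating
zygosities. The published account does not print its DZ curve formula;
this form is *derived here* from the stated assumptions (co-twin
susceptible with probability $s$, independent onsets, pairwise
convention). A consequence worth knowing: at the 2014 registry's
effective prevalence (0.812), a true $s = 0.188$ would yield
$C_D \approx 0.147$, not the observed 0.188. Assigning
$S_\mathrm{inher} = 0.188$ from the observed rate therefore treats the
cohort as saturated. `s_inher_from_observed()` exposes both readings:
the default `"saturation"` mode reproduces the published assignment;
`"model-inverse"` solves the curve at a stated prevalence (giving
0.242 here). No intent is guessed.

### Expected concordance over a cohort age distribution

A real cohort has many ages; the expected pairwise concordance is the
age-distribution-weighted average of $C_M$
(`expected_mz_concordance_discrete()`). When the cohort's age
distribution *is* the onset distribution truncated at $t_o$ — observe
one twin of each pair as it develops the disorder — the average has the
closed form

$$\langle C_M\rangle = -1 - \frac{2}{P_s(t_o)}\ln\!\Big(1 - \frac{P_s(t_o)}{2}\Big)
 \;\xrightarrow{t_o \to \infty}\; 2\ln 2 - 1 = 0.38629.$$

The untruncated limit is distribution-free: substituting $u = P_s(t)$
turns the average into $\int_0^1 u/(2-u)\,du$ for *any* continuous onset
CDF. The quadrature cross-check in
`expected_mz_concordance_onset_weighted(..., method = "quadrature")`
evaluates exactly that substituted integral adaptively (tolerance
1e-10, absolute tolerance 0 so small truncation ages stay accurate); the
substitution avoids integrating over an unbounded age domain.

### Clock-rate calibration

Regional cohorts differ in onset timing. The generalization
$P_s(t; r) = (1-e^{-k_1 r t})^{m_1}(1-e^{-k_2 r t})$ multiplies both
rates by a dimensionless *biological clock rate* `r`, so
$P_s(t; r) = P_s(rt; 1)$ identically. A cohort median of $t^\*$ months
therefore maps to $r = \mathrm{median}(r{=}1)/t^\*$
(`clock_rate_for_median()`). With the male shape, 39- and 55-month
medians give $r = 0.864$ and $0.613$; by the scaling law their ratio is
exactly $39/55 = 0.709$ regardless of shape parameters (a published
ratio of 0.720 is inconsistent with its own rate values, and the
package computes 0.709).

## Numerical choices

- **Quantiles.** `onset_quantile()` brackets $[0, t_{hi}]$ with
  doubling until $P_s(t_{hi}) > q$, then runs safeguarded Newton
  iteration (bisection fallback, log-spaced interpolated start) to
  $|P_s(t) - q| < 10^{-10}$, vectorized over `q`. Whole-month published
  landmarks ("33 months", "42 months", "55 months") are reproduced by
  exact root-solving followed by rounding to the nearest month.
- **Peak incidence.** Golden-section search on the analytic density
  (`optimize`, tol 1e-10) over $[0, q_{0.999}]$; the density is
  unimodal throughout the published parameter ranges. Tests and the
  reproduction script cross-check against a 0.001-month grid.
- **Fitting.** `fit_onset_curve()` scans the integer exponent `m1`
  exhaustively (default 1–40; how the published exponent was selected
  is not stated, so an explicit deterministic grid is used) with
  Levenberg-Marquardt (`minpack.lm::nlsLM`, ftol/ptol 1e-10, up to 1e4
  evaluations) nested inside. Starting values come from the data
  (half-maximum age for `k1`, tail rate for `k2`, the inflated last
  count for `N_b`) with a fixed three-point multi-start fallback. The
  objective is unweighted least squares on cumulative counts, matching
  the conventional procedure for this model; cumulative counts are
  serially correlated, so this is curve fitting, not maximum
  likelihood — documented, not corrected, to stay comparable.
  `fit_clock_rate()`'s table mode optimizes `r` alone on a log scale
  with the pool size concentrated out linearly at each candidate.
- **Degenerate inputs.** Negative ages, probabilities outside their
  ranges, empty or non-monotone count tables, and infeasible
  inherited-susceptibility inversions all raise located errors rather
  than returning silently wrong numbers.

## The synthetic cohort generator

The registry data behind the published analysis is not public, so
`generate_twin_cohort()` emulates its structure and serves as the test
bed for every analytic curve: MZ pairs both susceptible with
independent onset draws (the assumption that makes $P_{ss} = P_s^2$);
DZ pairs with a designated susceptible index twin A and co-twin B
susceptible with probability `s_inher` (the generator mirrors the
model's conditioning on an index twin rather than symmetrizing);
never-onset twins carry an explicit `NA` sentinel, not a large number;
diagnosis means onset at or before the observation age; ascertainment
keeps pairs with at least one diagnosis. Onset ages come from
inverse-transform sampling through `onset_quantile()`, and all
randomness flows from the single config seed — identical config and
seed give byte-identical tables.

Defaults mirror the study conditions: a fixed observation age (the
age-cohort idealization of a registry snapshot, 60 months unless
stated), `s_inher = 0.188` as assigned from the observed 49/260 DZ
rate, and no reporting bias. The `reporting_bias` knob models the
registry's documented tendency to under-report concordant pairs (extra
paperwork for a second affected twin): both-diagnosed pairs are
retained with the given probability at generation time. Simulation
confirms the qualitative claim that this bias lowers the measured
concordance — it works against, not for, the genetic hypothesis.

Two idealizations to keep in mind when reading passing tests: onset
equals diagnosis (no diagnostic-delay distribution — none is
specified), and co-susceptible twins share no within-pair onset-age
correlation beyond susceptibility itself. Real registry data would
violate both to some degree, so simulation/theory agreement here
validates the implementation, not the biology. Problem sizes were
chosen so every check is decisive at desk scale: 1e5–1e6 pairs for
binomial comparisons (3-standard-error bands), 50 replicates of a
300-susceptible cohort for parameter recovery, 20 replicates in the
fast unit suite.

A sampling note: the empirical pairwise concordance rate of a finite
cohort is *not* path-wise monotone in age even though diagnoses only
accumulate — a newly ascertained discordant pair lowers the ratio
momentarily. The concordant and ascertained *counts* are monotone;
tests assert exact monotonicity on the counts and monotonicity within
binomial fluctuation on the rate.

What the trajectory test shows: once every observation age clears the
onset distribution's upper reach, MZ concordance exceeds 99% (the
analytic curve passes 96% near 124 months and 99% only past the ~99.9%
onset quantile, around 229 months for the male set), while DZ
concordance flattens at `s_inher`. This is the model's proposed
critical test: follow a real MZ cohort past age ten and watch whether
concordance keeps climbing toward 100%.

## Known limitations

- The model is sex-symmetric; the observed ~4:1 male:female prevalence
  disparity is outside its scope (the near-identity of male and female
  onset curves is what motivates treating it as ascertainment or
  gender-bias driven, not mechanism driven).
- No confidence intervals accompany observed concordance rates or the
  fitted intrinsic parameters (none are published to compare against);
  the parameter-recovery simulations quantify fitting noise instead.
- The ordered-mutation variant of the model (steps constrained to a
  fixed order) is not implemented.
- The published cohort-average concordance of 0.755 used the
  unpublished individual ages of 60 registry MZ pairs and is therefore
  not reproducible; `expected_mz_concordance_discrete()` provides the
  estimator for anyone holding such data.
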