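---
title: "Methods: patch density models, robust-design demography, and immigrant estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch density models, robust-design demography, and immigrant estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchdemog)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the defaults and why they were chosen, the numerical
decisions, and what the synthetic-data tests do and do not establish about
field data.

## 1. The scientific setting

Forest-specialist small mammals living in habitat patches are expected to
show a *patch-area effect* on density — higher density in larger patches —
only below a landscape-scale threshold of remaining habitat, because
immigration from neighboring patches (the rescue effect) equalizes
densities where the landscape is still well connected. The package
implements the two analyses that test this mechanism: a model-selection
analysis of density against patch area across landscape contexts, and a
capture–recapture analysis that turns demographic parameter estimates into
an explicit count of immigrants per patch and interval.

## 2. Density: the eight-model candidate set

Each candidate model assembles per-landscape **component functions** of the
density index (distinct individuals captured per standardized patch
survey):

* `constant_nb` — no area effect; counts are negative binomial with mean
  `exp(a)` and dispersion `k` (variance `m + m²/k`). The negative binomial
  absorbs the strong overdispersion of patch counts that a constant
  Poisson could not.
* `linear_pois` — counts are Poisson with `log mean = a + b·log10(area)`.
  Areas enter as base-10 logarithms; the link is the natural log.

The set spans no structure (D1), a global area effect (D2), landscape
structure without/with area effects everywhere (D3, D4), and area effects
restricted to particular landscape combinations (D5–D8, with D8 the
"area effect only at intermediate cover" hypothesis). Components never
share parameters — a deliberate reading of "model log-likelihood = sum of
component log-likelihoods": each constant component carries its own
dispersion, each linear component its own slope. This makes `K` auditable:
2 per component, so 2 for D1–D2 and 6 for D3–D8. The exact per-model `K`
convention is declared here rather than inherited, since published
candidate tables often leave the dispersion accounting implicit.

Fitting is exact: Poisson components via IRLS (`stats::glm`), the
negative-binomial mean via its closed form (the sample mean), and `k` by
one-dimensional likelihood maximization on the log scale, capped at `1e6`.
Underdispersed or degenerate data hit the cap and the fit is flagged as a
boundary fit rather than failing; all-zero data yield a `-Inf` intercept
boundary fit with log-likelihood 0, which keeps empty landscapes (a real
feature of heavily deforested landscapes) inside the model set. AICc uses
`n` = number of patches entering the model (50 under the default design).

## 3. Demography: the joint robust-design likelihood

Capture histories follow a robust design: `T` primary sessions assumed
closed, each with `K` secondary occasions, open intervals between. The
joint log-likelihood of a fit is the sum of two conditionally independent
parts.

**Within sessions (Huggins).** An individual first caught at occasion `j`
of a session contributes
`(1-p)^(j-1) · p · ∏_{m>j} c^{h_m}(1-c)^{1-h_m} / p*`, with
`p* = 1-(1-p)^K`. Conditioning on capture removes abundance from the
likelihood; `N̂ = M/p̂*` is recovered afterwards with a delta-method SE
(binomial sampling of `M` plus detection-parameter uncertainty) and a 95%
CI lognormal on `f0 = N̂ - M`, so the lower bound can never fall below the
number of animals actually caught. The `p ≠ c` distinction models the
behavioral response induced by trapping (trap-happiness with baited
traps); the response resets at each primary session, matching the
closed-population semantics of `p` and `c` within sessions.

**Between sessions (Pradel-style growth).** Collapsed histories (detected
/ not per session, detection `p*_t` tied to the same capture rates) follow
an entry–exit process: entries follow the per-capita entry distribution
implied by survival and growth, `β ∝ (1, λ-φ, λ(λ-φ), …, λ^{T-2}(λ-φ))`;
an animal present survives each interval with probability `φ`; the
likelihood conditions on detection at least once. Two checks pin this
construction down exactly: conditional probabilities over all `2^T - 1`
observable histories sum to 1, and `φ → 1, λ = 1` degenerates to the
closed-population Bernoulli model.

**Parameter structures.** φ (logit link) and λ (log link) are constant,
landscape-specific, or patch-specific; `p` and `c` are additive in patch
and session on the logit scale (the conventional reading of "p(pa+t)").
φ and λ are time-constant within a model, as in the candidate structures
this set mirrors. `K` counts 1 / #landscapes / #patches per factor plus
`1 + (G-1) + (T-1)` per detection block — reproducing 22…32 for I1…I9 on
the six-patch, five-session layout.

**Numerical decisions.**

* Optimization: `nlminb` box-constrained quasi-Newton on the link scale
  (bounds ±12 keep probabilities away from exact 0/1), from a null start
  plus optional seeded random starts; in `fit_rd_set` later structures are
  warm-started from the first structure's solution. Relative tolerance
  `1e-9`; variance from the inverse observed information (`optimHess`),
  with SEs reported as unavailable when the information is singular.
* `λ < φ` would imply negative recruitment; raw entries are floored at
  zero and a smooth squared-violation penalty (weight 100) steers the
  optimizer back rather than failing a hard constraint.
* AICc effective sample size = total number of captured individuals. MARK
  uses a different ESS convention, so absolute AICc values are not
  comparable across programs; Δ, ω and K are. Deviance is reported as
  `-2·logL` without a saturated-model constant for the same reason.
* Non-converged structures are dropped, with a warning, before Akaike
  weights are normalized.

## 4. The immigrant-number estimator

For interval `t → t+1` of each patch,
`Î = N̂_adult(t+1) − φ̂ · N̂(t)`:
the adults present at `t+1` minus the expected survivors of everyone
present at `t`. `N̂(t)` uses complete histories (young included — they are
part of the surviving population); `N̂_adult(t+1)` uses reduced histories
from which every capture made while the animal was classified young (by
tooth eruption: third upper molar not yet erupted) is removed. Since young
are recruited in situ, an animal maturing between sessions appears in the
survivor term, not the immigrant term, and the estimator's expectation is
exactly the adult immigration rate — even with in-situ recruitment.

The default reduction removes young *encounters* and keeps later adult
captures of the same animal: an animal first caught young was born in the
patch, so its adult reappearance must not count as immigration.
`drop_ever_young = TRUE` offers the stricter alternative (drop such
animals entirely), for sensitivity analysis.

Negative `Î` is possible (estimation noise around small populations) and
is kept by default, flagged; flooring at zero would bias landscape means
upward. `φ̂` is the patch's model-averaged, time-constant estimate, and
all abundance inputs are model-averaged with unconditional SEs.

**Between-landscape comparison.** With three patches per landscape a
mixed-model significance test has essentially no replication; instead the
package uses an exact permutation test on the patch-level mean `Î`:
difference of landscape means, null distribution over all
`choose(6,3) = 20` patch-to-landscape assignments. This is exact and
assumption-free, but its smallest attainable two-sided p is
`2/20 = 0.1` — a documented floor, not a bug. Designs with more patches
get exhaustive enumeration up to `1e4` arrangements and Monte Carlo
beyond.

## 5. The synthetic-data generator

The generator is the package's ground truth, emulating the field design:
six 2-ha grids (three per landscape, 121 Sherman + 55 pitfall stations
each), five 5-day sessions at 20-day intervals — 26400 trap nights — and
small populations.

* **Density truth** (defaults): 50% cover — constant, mean 12.9,
  `k = 2.1` (matching a mean ± SD of 12.9 ± 9.6); 30% — linear with slope
  0.9 per decade of area, passing through 8.9 at the geometric-mean area
  of its 2–374 ha range; 10% — structural absence. Areas are log-uniform
  within each landscape's observed range; 15/20/15 patches.
* **Demographic truth** (defaults): per-patch initial adults 6 (50%) / 4
  (30%); apparent survival 0.62 / 0.50; Poisson adult immigration 2.2 /
  1.5 per interval and Poisson in-situ young recruitment 0.5 per session
  (maturing after one surviving interval), chosen so the emergent growth
  rate λ is ≈ 1.04 / 0.93; detection `p = 0.35`, `c = 0.45` per occasion
  (recapture above capture, as baited traps induce; `p* ≈ 0.88`).
  Immigration and birth are Poisson arrivals — the minimal-assumption
  generative choice, which also makes truth recovery analytic.
* λ is *emergent* in simulation (from φ, immigration and recruitment)
  while the estimation side parameterizes λ directly; the generator
  reports realized per-interval λ so recovery tests compare like with
  like. The roster satisfies the accounting identity
  `adults(t+1) = survivors(t) + matured(t) + immigrants(t→t+1)` exactly
  on every replicate, not just in expectation.

What the generator does **not** emulate: spatially explicit movement
(immigration is a rate, not a walk through a matrix), density dependence,
seasonality within the trapping window, tag loss, and age-dependent
detection. Passing recovery tests therefore demonstrates the estimators'
internal consistency under the stated generative assumptions — not
robustness to the full messiness of field data.

## 6. Problem sizes used in the validation suite

The shipped tests validate, among others: exact normalization of both
conditional likelihoods over 100 randomized parameter draws; recovery of
φ and λ within 2 SE (100 replicates, 6 patches × 40 individuals,
`p = c = 0.4`) and of Huggins abundance within 2% (500 closed sessions,
N = 50); retention of the generating density model D8 in the ΔAICc ≤ 2 set
(100 replicates, 50 patches); detection of landscape-structured survival
0.62 vs 0.50 over I1 (30 replicates at 130 initial adults per patch); and
recovery of a known Poisson immigration rate of 2 per interval through the
full two-dataset pipeline (30 replicates). These sizes were chosen so each
experiment has enough replication for its binomial or Monte-Carlo margin
while the whole suite stays convenient to run routinely.

## 7. Known limitations

* Absolute AICc values are not comparable to MARK output (ESS convention);
  use Δ and ω.
* With three patches per landscape the permutation floor is p = 0.1;
  significance claims below that require more patches, not more
  permutations.
* The Huggins variance ignores the covariance between `M` and `p̂*`
  (standard, slightly conservative).
* The open process assumes no temporary emigration (no γ parameters) and
  time-constant φ and λ; violations alias into apparent survival exactly
  as in any Pradel-type analysis.
* `.inp` interchange encodes ages in a structured comment; other software
  reading the file sees plain encounter histories and group (patch)
  frequency columns.
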