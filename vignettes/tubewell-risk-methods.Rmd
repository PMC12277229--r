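---
title: "Methods: tubewell water quality, children's health risk, and safe intake limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tubewell water quality, children's health risk, and safe intake limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubewellrisk)
```

## The assessment problem

Shallow alluvial aquifers in south-western Bangladesh carry geogenic iron
and arsenic, and school tubewells draw from them untreated. The package
implements the standard deterministic exposure chain for a school-age
receptor — guideline compliance, chronic daily intake (CDI), hazard
quotient (HQ) and hazard index (HI) — and inverts it into a safe daily
water-intake limit, then adds a learned surrogate of that limit with
feature attribution. Everything is seeded and reproducible end to end.

## Exposure model and parameter sets

For concentration $C$ (mg/L):

$$\mathrm{CDI} = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT}, \qquad
\mathrm{HQ} = \frac{\mathrm{CDI}}{RfD}, \qquad
\mathrm{HI} = \mathrm{HQ}_{As} + \mathrm{HQ}_{Fe}.$$

All shipped parameter sets use IR = 1.0 L/day (intake during school
hours only), EF = 230 school days/year, ED = 5 years and AT = EF·ED =
1150 days, so CDI reduces to $C \cdot IR / BW$.

Two bodies of numbers circulate for the remaining constants and they are
mutually inconsistent:

* **stated** — body weights of 20 kg (girls) / 24.68 kg (boys) and an
  iron oral reference dose of 0.7 mg/kg/day;
* **table-consistent** — BW = 15 kg and RfD$_{Fe}$ = 0.007 mg/kg/day
  (arsenic RfD 0.0003 in both), obtained by solving
  $HQ \cdot BW \cdot RfD = C$ over the published per-union HQ extremes;
  this set reproduces every printed HQ and HI value exactly
  (e.g. `compute_hq(0.175, "as", exposure_params("table-consistent"))`
  = `r round(compute_hq(0.175, "as", exposure_params("table-consistent")), 2)`).

Neither set is declared the "intended" one: both ship, the
table-consistent set is the default because it is the only one checkable
against printed output, and reported HQs round half-up to two decimals
with trailing zeros stripped (`format_hq()`), matching how the tables
print values like 25.9.

## Safe intake at THQ = 1

Setting HQ = 1 and solving for the ingestion rate gives
$FIR = BW \cdot RfD \cdot AT / (EF \cdot ED \cdot C)$ in L/day. Some
statements of this formula carry a $10^3$ factor; that factor is a
µg-to-mg unit conversion, and with $C$ already in mg/L it must be
omitted — dimensional analysis (kg · mg/kg/day ÷ mg/L = L/day) and the
published limits (0.06 L/day at $C_{As}$ = 0.075 mg/L with BW 15 kg)
both require this. The HI = 1 extension
$FIR = BW \cdot AT / (EF \cdot ED \, (C_{As}/RfD_{As} + C_{Fe}/RfD_{Fe}))$
combines the single-analyte limits harmonically, so it is always
dominated by each of them. A concentration of zero imposes no limit;
the package reports `Inf` rather than inventing a cap (an optional cap
is available in `safe_intake_table()`). The duality tests verify that
evaluating HQ (or HI) at an ingestion rate equal to the computed limit
returns exactly 1.

## Guideline accounting conventions

The shipped registry carries the WHO, US EPA and Bangladesh (BDWS/ECR)
limits for pH, EC, TDS, Fe and As. Three conventions are deliberate and
documented rather than silent:

* **pH** — the published accounting reports zero pH exceedances even
  though the sample minimum (6.12) lies below the 6.5–8.5 range. The
  default follows that accounting (only values above 8.5 count);
  `strict_ph = TRUE` applies the range rule literally.
* **BDWS iron 0.3–1.0 mg/L** — counted as an exceedance only above
  1.0 mg/L, which reproduces the published 32% (vs 68% at the plain 0.3
  limits).
* **WHO TDS 600–1000 mg/L** — counted above 1000 mg/L. The published
  TDS counts are internally inconsistent (a 600–1000 rule cannot exceed
  more often than a 500 rule on the same data); no test or target is
  built on them.

Percentages round half-up to one decimal, matching printed values such
as 97.3 and 26.7.

## The synthetic cohort generator

No per-sample table is distributed with the package, so the generator is
a first-class, tested module that emulates the study conditions: n = 75
schools allocated 29/14/17/15 to the Bagoan/Dariapur/Mohajanpur/Monakhali
unions, the published marginal moments (pH 6.85 ± 0.24 on 6.12–7.8, EC
900.27 ± 290.48 µS/cm, TDS 460.50 ± 144.30 mg/L, Fe 0.94 ± 0.92 mg/L, As
0.03 ± 0.05 mg/L, depth 311.20 ± 126.14 ft on 100–560 ft) and the
published pairwise correlations (TDS–EC 0.92, TDS–salinity 0.70,
As–depth −0.71, Fe–depth −0.34, Fe–As 0.22). Salinity (0.45 ± 0.15
practical units, consistent with TDS ≈ 460 mg/L) and temperature
(26.5 ± 0.8 °C, typical of shallow Bangladeshi groundwater) have no
published moments and were fixed once at those field-realistic values.

The scheme is a latent Gaussian copula: a standard multivariate normal is
transformed to lognormal margins for EC, TDS, salinity and Fe, truncated
normals for depth and pH, and a censored normal for As built with an
explicit negative linear dependence on the depth latent. Iron is clipped
to the colorimeter's 0–5 mg/L range and rounded to its 0.01 mg/L display
resolution; arsenic is clipped to the kit's 0–0.5 mg/L range and snapped
to the kit read-out grid {0, 0.005, 0.01, 0.025, 0.035, 0.05, 0.075,
0.1, 0.175, 0.25, 0.5} mg/L (a modeling choice: the published per-union
extremes sit on these levels), with exact midpoints snapping to the lower
level so quantization is deterministic.

Because clipping, quantization and nonlinear margins attenuate Pearson
correlations, the latent correlations are **de-attenuated analytically**
from the configured output targets: exact inversion for
lognormal–lognormal pairs, and first-order Hermite factors
($\sigma m / s$ for a lognormal margin,
$\sigma_0 \Phi(\mu_0/\sigma_0)/s$ for the censored-normal As margin, a
numerically integrated linearity factor for the truncated-normal depth
transform). The censored-normal pre-clip parameters are themselves solved
numerically so the *post*-clip mean and sd match the configured 0.03 ±
0.05. Targets that de-attenuate beyond |ρ| ≥ 1, or that make the latent
matrix indefinite, raise an error naming the offending pair. At n = 5000
the realized correlations sit within ±0.05 of all five targets
(tolerance ±0.08 in the tests, averaged over 10 seeds).

What the generator does **not** emulate: spatial autocorrelation
(coordinates are uniform in the study bounding box, plumbing only),
seasonal variation, the physically implausible EC/TDS minima present in
the field records (available behind `include_outliers`), and marginal
shape beyond two moments — in particular the field data's excess of
low-iron wells, so synthetic exceedance fractions (e.g. ~85% of samples
above the 0.3 mg/L iron limit at these moments) differ from the field
figure (~68%). Tests passing on synthetic data therefore certify the
arithmetic and the statistical machinery, not the field distributions.

## Association diagnostics

The Pearson matrix uses pairwise-complete observations (the pair counts
are attached to the result); zero-variance variables yield `NA` entries
with a warning. Depth regressions are ordinary least squares of
concentration on depth via `lm()`. PCA is computed on the **correlation**
matrix — the indicators mix µS/cm, mg/L, feet and pH units — of
log10-scaled variables; since Fe = 0 and As = 0 occur, each variable is
transformed as $\log_{10}(x + \varepsilon)$ with $\varepsilon$ = half
the smallest positive observed value of that variable. Components carry a
deterministic sign convention (the largest-magnitude loading of each
component is positive) so outputs are stable. Published PC1/PC2 loadings
depend on unstated preprocessing and are treated as reference values
only; no rotation is applied.

## The surrogate model

The surrogate learns the safe-intake limit from the encoded feature table
(union integer code, depth, Fe, As, pH, EC, TDS, plus WHO/BDWS binary
exceedance flags for both analytes — 11 features). Design choices where
the design was genuinely open:

* **Target**: $\log(FIR_{combined})$ — the limit has a heavy right tail;
  unbounded (zero-concentration) rows are excluded before training.
* **Architecture**: two hidden layers of 16 and 8 rectified units — a
  small tabular problem; configurable.
* **Update rule**: plain mini-batch gradient descent,
  $w \leftarrow w - \eta\,(\alpha\,\partial R/\partial w +
  \partial Loss/\partial w)$ with $R(w) = \tfrac12\|w\|^2$ over the
  connection weights (biases carry no penalty, the usual convention) and
  a half mean-squared-error batch loss. A step with α = 0 is exactly a
  plain gradient step (tested to 1e−10). Defaults η = 0.02, 400 epochs,
  batch 32; non-finite loss aborts with a suggestion to reduce η.
* **Scaling**: features and target are centered/unit-scaled from the
  training split only (no leakage); the 90/10 split is seeded and
  stratified by union.
* **Validation**: seeded ten-fold cross-validation over the half-decade
  regularization grid α ∈ 10^(−1,−0.5,0,0.5,1); every row validates
  exactly once per α. On a low-noise target the largest α measurably
  degrades the fit, which the tests assert as the expected
  over-regularization behaviour.

On 500-row synthetic cohorts the surrogate reaches held-out R² ≈ 0.96
against the analytic combined limit (the tests require a 10-seed median
≥ 0.85 and held-out correlation ≥ 0.92); a published "87% accuracy" for
a comparable model is ambiguous about split and target and is treated as
a qualitative band, not a reproduction target.

**Shapley attribution** is exact for ≤ 12 features: coalition values are
the mean model prediction over a background table with present features
taken from the explained row (interventional convention), enumerated over
all $2^p$ coalitions, so the efficiency axiom
$\text{baseline} + \sum_i \phi_i = \text{prediction}$ holds to machine
precision (baseline = mean background prediction). Above 12 features a
seeded Monte-Carlo permutation estimator is used; on 8 features it agrees
with enumeration within 3 Monte-Carlo standard errors. For a model linear
over the evaluation region, $\phi_i = w_i (x_i - \bar{b}_i)$, which the
tests verify against the enumeration.

The **two-group diagnostic** (`alpha_cluster_report()`) partitions
samples by seeded two-means clustering of (prediction, residual) per α
and reports group sizes and co-assignment agreement against the first α.
It is a documented, reproducible descriptive analogue of a published
per-α clustering whose exact procedure is not recoverable; it does not
claim to reproduce those confidence figures.

## Numerical conventions and degenerate inputs

* Rounding in reported tables is half-up (not banker's): 26.65 → 26.7.
* Quantization midpoints snap downward; clipping precedes quantization.
* Unbounded safe limits are `Inf` in memory and `null` in GeoJSON.
* Empty datasets: validation reports n = 0 with zero violations;
  statistics and risk tables refuse with clear errors.
* Constant targets: R² is undefined and reported as `NA`, never 0 or 1.
* An arsenic reading in (0.5, 5] mg/L exceeds the kit's nominal
  detection limit but not its extended read-out; it is flagged, not
  rejected (the kit's two ranges are described inconsistently).

## Problem sizes

The shipped tests and examples use the study-sized cohort (n = 75) for
end-to-end runs, 500-row cohorts over 10 seeds for surrogate performance,
n = 5000 over 10 seeds for generator correlation recovery, 1000 random
concentration pairs for the FIR/HQ duality, and 50 random datasets for
the compliance oracle — sizes chosen so the full suite completes in a few
minutes on one CPU while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

Deterministic exposure only (no Monte-Carlo exposure distributions, no
carcinogenic slope-factor risk); two analytes; no spatial statistics or
map rendering (GeoJSON/CSV export replaces cartography); the generator's
copula captures pairwise linear dependence only; and the published
stated-vs-tabulated exposure-constant conflict is surfaced, not resolved.
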