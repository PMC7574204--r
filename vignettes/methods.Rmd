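---
title: "Methods: from FAME composition and batch kinetics to biodiesel quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from FAME composition and batch kinetics to biodiesel quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleofuel)
```

oleofuel implements the computational chain of a single-cell-oil (SCO)
workflow: screening oleaginous yeasts by Nile-red fluorescence, batch
fermentation kinetics on lignocellulosic hydrolysate, hydrolysate nutrient
accounting, and estimation of biodiesel fuel quality from the fatty-acid
methyl-ester (FAME) composition of the extracted lipid. This vignette
documents the models, the parameters that matter, the synthetic-data
generators, and the design decisions taken where the underlying empirical
conventions are genuinely open.

## FAME composition and its summaries

A lipid sample transesterified and resolved by GC yields a weight-percent
composition $N_i$ over fatty-acid species written `Cn:D` (chain length $n$,
double bonds $D$). Published composition tables frequently total less than
100% because trace species are dropped; `fame_profile()` therefore accepts
raw totals up to 100.5% and `normalize_profile()` closes the composition on
request. All property math runs on either form, controlled by a flag that
the report records; the default is the raw, as-printed composition, because
tabulated reference values in this literature are generally computed on the
numbers as printed. A tolerance of 0.05 percentage points absorbs
two-decimal printing wherever a "sums to 100" check applies.

The saturation-class summary partitions the total into saturated (SFA),
monounsaturated (MUFA) and polyunsaturated (PUFA) mass, and derives two
scalar predictors:

* degree of unsaturation, in mass-fraction units,
  $DU = (\mathrm{MUFA} + 2\,\mathrm{PUFA})/100$ — under this convention
  typical biodiesels score 0.5–2;
* long-chain saturation factor
  $LCSF = 0.1\,N_{16:0} + 0.5\,N_{18:0} + 1\,N_{20:0} + 1.5\,N_{22:0} +
  2\,N_{24:0}$.

Odd-chain species (e.g. `C15:0`) are valid inputs; they contribute to SFA
but not to LCSF, whose weights are defined only for the even C16–C24
saturates.

## Fuel-property correlations

The per-species chemical indices are

$$SV = \sum_i \frac{560\,N_i}{M_i}, \qquad
  IV = \sum_i \frac{254\,D_i\,N_i}{M_i},$$

with $M_i$ the methyl-ester molecular weight assembled from atomic masses
($\mathrm{C}_{n+1}\mathrm{H}_{2n+2-2D}\mathrm{O}_2$). Both are linear in
the weight percents, so on a raw profile they scale with the profile total —
one reason raw and normalized inputs give different property values and the
report must say which was used.

The registry then applies (see `fuel_correlations()`):

| property | correlation | units |
|---|---|---|
| CN (per-species) | $46.3 + 5458/SV - 0.225\,IV$ | — |
| CN (DU route) | $62.876 - 6.6684\,DU$ | — |
| HHV | $49.43 - 0.041\,SV - 0.015\,IV$ | MJ/kg |
| KV (40 °C) | $5.2065 - 0.6316\,DU$ | mm²/s |
| density | $0.8726 + 0.0055\,DU$ | g/cm³ |
| CFPP | $3.1417\,LCSF - 16.477$ | °C |

These are standard literature forms; studies in this area typically cite
"previously reported experimental equations" without printing them, and no
single published set exactly regenerates every tabulated property value in
the source material this package emulates (some printed values — e.g. a
FAME density of 0.47 g/cm³ — are outside the physically possible range for
any methyl-ester mixture). The registry is therefore pluggable: pass a
modified coefficient list to any property function to swap equation sets.
Oxidative stability, which has no accepted composition-only correlation of
comparable standing, is excluded from the default report.

Monotonicity is a designed-in property of the registry and is enforced by
tests: CN and KV strictly decrease and density strictly increases in $DU$,
and replacing unsaturated mass by `C16:0` never decreases CFPP.

## Fuel standards

`fuel_standards()` ships two limit sets. The default `"as-printed"` set
transcribes a widely circulated comparison grid (EN 14214 CN ≥ 47,
ASTM D6751 and IS 15607 CN ≥ 51; EN IV ≤ 120; KV and density ranges as
printed). That grid's CN and KV columns conflict with the official standard
documents — the official EN 14214 minimum CN is 51 and ASTM D6751's is 47,
with the KV ranges shifted correspondingly — so a `"literature"` set
carries the official values. The as-printed set is the default so that
published comparisons can be reproduced exactly as printed; the
documentation flags the conflict rather than silently correcting it.

## Batch kinetics and mass accounting

Kinetics are deliberately endpoint-based: biomass productivity
$(X_T - X_0)/T$, lipid productivity $(L_T - L_0)/T$, lipid content
$100\,L_T/X_T$, and per-sugar consumption $(S_0 - S_T)/T$, matching the
120-h convention of batch SCO studies. A `max-slope` variant reports the
maximum rate over adjacent sampling intervals but is not the default. When
a time course lacks a $t=0$ sugar sample, the medium recipe value can be
supplied (`initial_sugars`), e.g. 30 g/L for a 3% glucose medium — which is
exactly how a 0.25 g/L/h glucose consumption rate arises over 120 h.

Hydrolysate panels mix g/L and mg/L; units are carried per analyte and
converted internally to g/L. "Not detected" entries are explicit missing
values, excluded from utilization arithmetic unless a detection-limit
substitution is configured — treating them as zeros would overstate
utilization for analytes that simply fell below the method's floor.

`mass_balance()` chains shell loading (% w/v, so 10× in g/L) → DCW → lipid
→ biodiesel with per-stage yield ratios; the chain is non-increasing past
the loading stage whenever all stage efficiencies are ≤ 1.

## Screening analytics

Strains are ranked by mean relative fluorescence (RFU) with ties broken
lexicographically by strain id — a documented, deterministic rule that
makes ranking reproducible under replicate reordering. The oleaginous call
is a strict 20% lipid-content cutoff (a strain at exactly 20% is not
called). The RFU–gravimetric-lipid agreement is summarized by Pearson
correlation on per-strain replicate means (4 replicates per treatment is
the field's convention; a per-replicate variant is available behind a
flag). Correlation on titres rather than contents is the default because
screening scatter plots in this literature put lipid titre (g/L) on the
gravimetric axis.

## Synthetic-data generators

The generators exist so every stage is testable without measurements; their
defaults are fixed to the study conditions the package emulates and are not
tuning knobs.

**Batch time course.** Logistic biomass
$X(t) = K/(1 + ((K - X_0)/X_0)e^{-\mu t})$ with Luedeking–Piret lipid
formation $L(t) = \alpha(X(t) - X_0) + \beta\int_0^t X\,ds$ (trapezoid rule
on the sampling grid). Defaults $X_0 = 0.1$, $K = 12.58$, $\mu = 0.1$ /h,
$\alpha = 0.418$, $\beta = 0.002$ reproduce a 120-h
alkali-saccharified-hydrolysate batch ending near 12.6 g/L DCW and 7.0 g/L
lipid. Only endpoint data are available in the emulated study, so the
logistic shape between samples is an implementation choice, not an
inference; $\alpha/\beta$ were chosen once to land the 120-h endpoints with
a small non-growth-associated share. Sugars deplete sequentially in the
preference order glucose → xylose → arabinose (the diauxie oleaginous
yeasts show on mixed hydrolysate sugars), each at its own rate while
active; defaults start from 28.05/18.13/0.29 g/L and finish all three
inside 120 h. Measurement noise is additive Gaussian (`noise_sd`, g/L),
clipped at zero, with lipid clipped at DCW. Note the $\beta$ term grows
without bound while $X$ saturates, so over-long horizons with $\beta > 0$
violate $L \le X$ and are rejected as a parameter error rather than
silently clipped.

**FAME profiles.** Dirichlet draws about a normalized mean profile with
precision `concentration` (default 500, giving per-species scatter of
roughly ±2 percentage points on a 50% species — about the reproducibility
of replicate GC runs); infinite precision returns the mean.

**Screening tables.** Strain titres come from a two-component Gaussian
mixture — a non-oleaginous mode at 0.35 ± 0.1 g/L and an oleaginous mode at
1.5 ± 0.3 g/L with weight 0.1, echoing a 57-strain screen in which roughly
six strains stand out and top titres reach ~1.8 g/L at 72 h. RFU is an
affine response (`gain` 1500 RFU per g/L, `offset` 2000 RFU — arbitrary
plate-reader units chosen to keep draws far from the zero floor) plus
replicate noise whose variance is solved in closed form so the correlation
between per-strain mean RFU and titre equals `target_r`:
$\sigma^2_{rep} = k\,g^2\,\widehat{\mathrm{var}}(\text{titre})\,(1/r^2-1)$
for $k$ replicates. The solve uses the *realized* variance of the drawn
titres rather than the mixture's population variance: conditioning on the
draw keeps the calibration from drifting with the binomial split between
modes, and the sample correlation then lands inside the Fisher-z 95%
interval of the target in ~95% of seeds (the suite checks ≥ 93% over 500
seeds at $n = 57$, $r = 0.94$).

**Hydrolysate panels.** Before-cultivation values are truncated normals
about a fixed nutrient-panel mean/SD table; after-cultivation values apply
per-analyte retention fractions, so utilization percentages are exact by
construction regardless of noise — the generator tests the accounting, not
the chemistry. `sd_scale = 0` reproduces the panel means exactly.

All generators draw from R's global RNG after an optional `set.seed(seed)`,
so a single integer seed makes any pipeline run bit-reproducible.

**What the generators do not emulate.** Real screens have
strain-by-staining interactions and plate effects; real fermentations show
lag phases, inhibitor-dependent growth and non-constant sugar rates; real
GC compositions have correlated species errors. Passing tests demonstrate
that the *arithmetic chain* is correct under the stated statistical
structure, not that the generators are faithful simulators of the biology.

## Numerical choices and degenerate inputs

* "Sums to 100" tolerance 0.05 (absolute, percentage points); normalized
  internal results hold to 1e-9.
* All-zero profiles, zero DCW, zero standard peak area, non-positive
  elapsed time and out-of-range efficiencies raise errors rather than
  returning NaN; a final sugar concentration above the initial one warns
  (net production) and returns the signed rate.
* Parameter-recovery assertions at 1e-9 are exact-arithmetic checks (the
  estimator applied to noiseless generator output); stochastic checks are
  aggregate: with `noise_sd = 0.3` g/L and 9 samples, per-seed endpoint
  productivity is a ~4% relative-error quantity, so individual seeds can
  legitimately exceed ±10%; the suite asserts the mean error lies within
  ±10% and that at least 90% of 100 seeds do, which separates a correct
  generator/estimator pair from a mis-scaled one without making the test a
  coin flip.
* Problem sizes in the suite — 1,000 random profiles for the SV/IV oracle,
  100 seeds for noisy recovery, 500 seeds for screening calibration — keep
  the full run in the tens of seconds while leaving the Monte-Carlo margins
  (binomial SE < 1.2 percentage points at 500 draws) well inside the
  asserted bounds.

## Data notes

The shipped input tables under `inst/extdata/` transcribe printed summary
tables from the emulated study (FAME compositions, the hydrolysate nutrient
panel, batch endpoints, the process chain, detoxification totals). Two
provenance footnotes: the hydrolysate-grown FAME table includes the 0.1%
`C15:0` mentioned only in the running text (bringing the column total to
96.70%); and the reference-medium batch endpoint uses the lipid titre
6.65 g/L consistent with the printed 54.24% content at 12.26 g/L DCW (a
companion table prints 6.61 g/L, which implies 53.92%). The batch *time
course* file is labelled synthetic: only its endpoints are printed values,
the intermediate samples are generator output pinned to those endpoints.

## Known limitations

* Property correlations are empirical regressions fit on vegetable-oil
  FAME ranges; extrapolation to unusual compositions (e.g. > 50%
  odd-chain) is unvalidated.
* Reported property values in the emulated study cannot be regenerated
  exactly by any single public equation set; this package documents the
  deviations instead of matching coefficients to outputs.
* Endpoint kinetics ignore lag and stationary phases by construction;
  `max-slope` is a coarse alternative, not a growth-model fit (ODE fitting
  is out of scope).
* Compliance checking covers the numeric limits encoded in the standards
  table only, not the full certification test battery of the standards.
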