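---
title: "Methods: soil heavy-metal risk assessment with soilrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil heavy-metal risk assessment with soilrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
```

## The problem

Soils near mining and mineral-processing operations accumulate potentially
toxic elements — As, Cd, Cr, Ni, Fe, Mn, Mg, Zn, Cu, Pb — that reach people
through incidental soil ingestion, inhalation of resuspended dust, and
dermal contact. The standard USEPA screening framework converts measured
soil concentrations into chronic daily doses per pathway, compares
non-carcinogenic doses to reference doses, and multiplies lifetime-averaged
doses by slope factors to estimate excess cancer risk. `soilrisk`
implements that framework end to end for per-sample concentration tables
(rows = soil samples, columns = metals, mg/kg dry weight), together with
the descriptive and correlation screening that typically precedes it and a
Monte Carlo layer that propagates input uncertainty through the cancer-risk
model.

## Exposure model

For a metal with soil concentration $C_s$ (mg/kg), the chronic daily
intakes in mg/(kg·day) are

$$\mathrm{CDI_{ing}} = \frac{C_s \cdot \mathrm{IngR} \cdot \mathrm{EF}
\cdot \mathrm{ED} \cdot \mathrm{CF}}{\mathrm{BW} \cdot \mathrm{AT}},
\qquad
\mathrm{CDI_{inh}} = \frac{C_s \cdot \mathrm{InhR} \cdot \mathrm{EF}
\cdot \mathrm{ED}}{\mathrm{PEF} \cdot \mathrm{BW} \cdot \mathrm{AT}},
\qquad
\mathrm{CDI_{derm}} = \frac{C_s \cdot \mathrm{SA} \cdot \mathrm{AF}
\cdot \mathrm{ABS} \cdot \mathrm{EF} \cdot \mathrm{ED} \cdot
\mathrm{CF}}{\mathrm{BW} \cdot \mathrm{AT}}.$$

The mass conversion factor $\mathrm{CF} = 10^{-6}$ kg/mg is dimensionally
required in the ingestion and dermal equations (soil concentrations are per
kg of soil while intake rates are in mg of soil); published presentations
of these equations sometimes leave it implicit, but without it the intakes
are $10^6$-fold too large. The inhalation route needs no CF because the
particle emission factor PEF (m³/kg) already performs the soil-to-air
conversion. Then

$$\mathrm{HQ} = \mathrm{CDI}/\mathrm{RfD}, \qquad
\mathrm{THQ}_p = \sum_{\text{metals}} \mathrm{HQ}, \qquad
\mathrm{HI} = \sum_{p \in \{\mathrm{ing,inh,derm}\}} \mathrm{THQ}_p,
\qquad \mathrm{ILCR} = \mathrm{CDI_{ca}} \cdot \mathrm{SF}.$$

HI < 1 is the non-cancer acceptability criterion; cancer risk below
$10^{-6}$ is negligible, between $10^{-6}$ and $10^{-4}$ acceptable
(boundaries inclusive), above $10^{-4}$ high.

Two averaging times are kept separate: non-carcinogenic intakes average
over the exposure period ($\mathrm{AT_{nc}} = \mathrm{ED} \times 365$ d)
while carcinogenic intakes average over a 70-year lifetime
($\mathrm{AT_{ca}} = 70 \times 365$ d), the standard practice when a single
ambiguous "AT" symbol appears in the source equations. Since
$\mathrm{AT_{ca}} \ge \mathrm{AT_{nc}}$, carcinogenic intakes never exceed
non-carcinogenic ones. The cancer route is ingestion-only by default — the
dominant route for soil and the one with established oral slope factors;
dermal and inhalation unit-risk extrapolations are out of scope. A skin
permeability constant appears in some symbol lists for this model but in no
equation; it plays no role here.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| IngRs | 100 | mg/day | adult incidental soil ingestion |
| InhRs | 20 | m³/day | inhalation rate |
| EF | 350 | days/yr | exposure frequency (resident) |
| ED | 30 | yr | exposure duration |
| BW | 70 | kg | body weight |
| AT_nc | ED × 365 | days | non-carcinogenic averaging time |
| AT_ca | 70 × 365 | days | carcinogenic averaging time |
| PEF | 1.36 × 10⁹ | m³/kg | particle emission factor |
| SA | 5700 | cm² | exposed skin area |
| AF | 0.07 | mg/(cm²·day) | soil-to-skin adherence |
| ABS | 0.001 (As 0.03) | – | dermal absorption fraction |
| CF | 10⁻⁶ | kg/mg | mass conversion |

These are USEPA RAGS-style adult-resident screening values. The shipped
RfD/SF table (`inst/extdata/toxicity_defaults.yaml`) holds IRIS-style
screening reference doses per pathway and oral slope factors; it is loaded
at run time, never hard-coded, and any entry can be overridden. Design
choices worth noting:

- **Carcinogen set.** As, Cd, Cr and Pb carry oral slope factors and enter
  the ILCR total. Ni ships with reference doses only: no oral slope factor
  is established for it, and the simulated carcinogens in this class of
  study are typically exactly Cd, Cr, As and Pb.
- **Mg** has no established reference dose and contributes nothing to HI;
  the assessment warns rather than silently scoring zero, and an assessment
  in which *no* metal has a reference dose is an error.
- **Slope-factor units** are (mg/(kg·day))⁻¹ for the soil-ingestion route
  (occasionally misprinted as per-mg/L in the literature).
- Because site-specific exposure and toxicity values behind published
  summary tables are often unprinted, absolute CDI/THQ/ILCR magnitudes
  computed with screening defaults are order-of-magnitude comparable to
  such tables, not exact reproductions. The qualitative conclusions
  (HI < 1; total ILCR above 10⁻⁴) are robust to this, and the package's
  tests assert those, plus the exactly checkable identities (HI equals the
  pathway THQ sum; mean = sum/count; SE = SD/√n; range = max − min).

## Descriptive and correlation screening

`summarize()` reports the spreadsheet-convention statistics: sample SD
(n − 1), adjusted Fisher–Pearson skewness (n ≥ 3) and bias-corrected excess
kurtosis (n ≥ 4; the KURT convention, which yields the negative values
typical of platykurtic field data). Those conventions were chosen because
environmental datasets of this kind are overwhelmingly summarized with
spreadsheet software ("St. Error", "Kurt" row labels), and excess — not raw
— kurtosis is what such tables print. Undefined shape statistics at tiny n
are `NA` and flagged, never zero. The symmetry label follows the common
screening rule that |skewness| ≤ 1 is approximately symmetric. Variance is
computed from unrounded values, so it equals SD² exactly even where a
published table's independently rounded cells disagree in the last digit.

`pearson_matrix()` uses the product-moment coefficient and the four-tier
magnitude categorization (strong ≥ 0.8 > significant ≥ 0.5 > weak ≥ 0.3 >
insignificant). Published tier bounds overlap at 0.5 and 0.8; boundaries
are resolved upward into the stronger tier, the conservative choice when
flagging association. Categorization is by magnitude only — no p-values —
matching the screening practice this mirrors; zero-variance columns yield
flagged-undefined entries.

## Synthetic sites

Raw per-sample data for the two mining fields this package's fixtures
emulate were never deposited; only per-metal summary rows (mean, SD, min,
max, n = 36) are public. `generate_site_samples()` turns such rows into
concrete tables. The default marginal is a truncated normal centred on the
target mean — justified because every published skewness for these sites
lies within ±1 — with a truncated lognormal available for right-skewed
concentration modelling.

A subtlety forced the correction step beyond a single affine rescale: for
most metals at the gold site the printed SD *exceeds the SD of a uniform
distribution on [min, max]* (e.g. As: SD 8.17 vs range 20, uniform SD
5.77). No unimodal bounded density can realize those moments; feasible
samples must concentrate mass near the bounds. The generator therefore
iterates **rescale-and-clip**: affinely restandardize the sample to the
target mean and SD, clip into [min, max], and repeat until both moments
converge (then a final affine step with the largest in-bounds scale
guarantees the bounds exactly). This is the natural closure of a post-hoc
standardize-and-rescale correction and recovers every fixture row to well
under 1% moment error. Feasibility is checked up front:
$\mathrm{sd}^2 \le (\mathrm{mean}-\mathrm{min})(\mathrm{max}-\mathrm{mean})$,
the two-point bound; infeasible rows are rejected.

`generate_correlated_samples()` draws a Gaussian copula (eigendecomposition
of the target correlation matrix, so exactly singular PSD targets such as a
comonotone pair are handled) and pushes uniforms through the truncated
marginal quantile functions. No moment correction is applied there, since
it would distort the dependence; Pearson targets are recovered to about
±0.15 at n = 500 (the copula preserves rank rather than product-moment
correlation, plus sampling noise). The shipped fixture specs default to
independent metals: the published correlation matrices for both sites are
dominated by |R| < 0.3, and whatever structure the raw data had is
unknowable from the summaries.

What passing tests on these synthetic sites shows — and does not. The
generator reproduces the first two moments and the bounds, so everything
downstream that depends on per-metal means (the entire deterministic risk
layer) is exercised under realistic magnitudes. It does not reproduce the
unknown higher moments, spatial autocorrelation, detection-limit censoring
or inter-metal dependence of the real field data, so test results validate
the *machinery*, not site-specific conclusions about the real soils.

Seeds are explicit arguments everywhere; generation restores the caller's
RNG state (`withr::with_seed`), and identical seed means identical table.

## Monte Carlo layer

The uncertain inputs of the ingestion cancer-risk model are the soil
concentration of each carcinogen, the soil ingestion rate, body weight and
the slope factor. Their default distributions, all overridable
`dist_spec()` objects:

- concentration: lognormal with moments matched to the site's sample mean
  and SD, truncated to the sample range (a natural non-negative,
  right-skewed model for concentrations; a constant column degrades to a
  point mass with a warning);
- body weight: normal(70 kg, CV 0.2) truncated to [40, 120] kg;
- ingestion rate: triangular(50, 100, 200) mg/day;
- slope factor: point mass at the configured value.

Published studies of this kind name these four uncertain variables but
rarely their families or parameters, so these were chosen once for
plausibility and are fully exposed in configuration; percentile outputs
depend on them. Sampling is plain Monte Carlo (not Latin hypercube, the
default of the commercial tool this mirrors), variables are drawn
independently (no rank correlation is stated anywhere to calibrate one),
and each family is sampled by inverse CDF on the truncated probability
range, so truncation is exact and a seed fully determines the run. The
default is 10,000 iterations. Quantiles use the linear-interpolation
convention (`stats::quantile` type 7), stated here for bit-reproducibility.
With every input degenerate at its point value the simulation reproduces
the deterministic pipeline to machine precision — a cross-module oracle the
test suite enforces — and Jensen's inequality makes the simulated mean risk
exceed the risk at mean inputs (the model is convex in 1/BW), which is also
tested.

## Numerical choices and degenerate inputs

- Risk quantities are reported in 3-significant-figure scientific notation
  (`3.38E-1`), descriptive statistics to two decimals, matching the field's
  reporting style; computation always uses full precision.
- Statistics need n ≥ 2 (shape statistics n ≥ 3/4); correlation needs
  n ≥ 3 and nonzero variance; all violations are explicit errors or
  flagged `NA`s.
- Concentrations must be finite and ≥ 0; validation errors name the
  offending sample and metal.
- Problem sizes in the tests and the acceptance script — 36 × 10 tables,
  100-seed recovery sweeps, 10⁴–10⁵ Monte Carlo draws — were chosen as the
  sizes the emulated study design itself uses.

## Known limitations

- Single adult-resident receptor: no child scenario, no dermal or
  inhalation cancer routes.
- Exposure-point concentration is the arithmetic mean per metal, not a 95%
  UCL.
- The Monte Carlo layer varies each metal's concentration independently;
  per-iteration totals ignore inter-metal correlation.
- Screening toxicity values are bundled for convenience; site-specific
  regulatory work should override them with jurisdiction-appropriate
  values.
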