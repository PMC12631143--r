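---
title: "Methods: low-dose methotrexate risk assessment in renal impairment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-dose methotrexate risk assessment in renal impairment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxrenal)
```

## What the package computes

Weekly oral methotrexate at doses of 20 mg or less ("low-dose"
methotrexate, LD-MTX) is the anchor therapy of rheumatoid arthritis.
The drug is cleared almost entirely by the kidney — glomerular
filtration of the unbound fraction plus active tubular secretion
through basolateral uptake (OAT3, RFC1) and apical efflux (MRP4, BCRP)
transporters — so declining renal function raises exposure and with it
the risk of hematological, hepatic and pulmonary toxicity. The package
links three quantitative pieces into one assessment:

1. **Pharmacovigilance**: disproportionality statistics (PRR with
   chi-squared, ROR with a Wald interval, and the BCPNN information
   component with its IC025 bound) on spontaneous-report tables in the
   FAERS ASCII dialect, restricted to reports whose indication terms
   fall in the renal-impairment groupings, with a three-way signal rule
   (all three criteria must hold).
2. **Exposure modeling**: a minimal mechanistic pharmacokinetic model
   of oral methotrexate whose renal clearance is decomposed into
   filtration and transporter-mediated secretion, the latter scaled
   across chronic kidney disease (CKD) stages by the intact nephron
   hypothesis; plus a four-knot restricted cubic spline (RCS) linking
   dose to first-dose peak concentration (Cmax) in normal renal
   function.
3. **Risk calculus**: a Cmax risk bound
   `0.16 umol/L x (dose / 2.3 mg) x (eGFR / 90)` evaluated over the
   label regimens (7.5, 10, 15, 20 mg weekly) and CKD stages 1-3b,
   population-level exceedance assessment, and tablet-quantized dose
   reduction per stage.

Every input the pipeline needs is produced by seeded synthetic
generators, so the whole analysis is reproducible offline.

## Disproportionality statistics

For a 2x2 table (a = target drug with target term, b = drug with other
terms, c = other drugs with the term, d = the rest):

* PRR = `(a/(a+b)) / (c/(c+d))`; Pearson chi-squared
  `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without continuity correction —
  the classic rule (count >= 3, PRR >= 2, chi-squared >= 4) predates
  that convention; a Yates-corrected variant sits behind a flag.
* ROR = `ad/bc` with `exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`;
  any zero cell triggers the Haldane-Anscombe +0.5 correction, which is
  reported. Criterion: count >= 3 and lower bound > 1.
* Information component `IC = log2((a+0.5)/(E+0.5))` with
  `E = (a+b)(a+c)/N`, and the closed-form shrinkage bound
  `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2.0 (a+0.5)^{-3/2}`. The closed
  form is tested against a gamma-posterior Monte-Carlo quantile (within
  0.15 bits for a >= 5). Criterion: count >= 3 and IC025 > 0.

The counting unit is the case-term pair by default (each deduplicated
case contributes each of its reaction terms once), configurable to
case-level counting; the comparator is all other drugs within the renal
cohort. Neither choice is forced by the published description; both are
exposed as arguments. No multiplicity adjustment is applied across
terms — the three-way rule is the only control, mirroring practice.

Cohort construction follows the FAERS conventions: merge DEMO / DRUG /
INDI / REAC on the primary id, normalize drug-name variants through a
bundled synonym table (a deterministic stand-in for NLP normalization),
keep one record per case id (the highest primary id is the current
version), restrict to renal-indication cases, purge
non-adverse-reaction term classes (product issues, injuries, poisoning,
procedural terms, social circumstances), and drop cases left with no
reaction term. Unknown fields are never imputed; they are counted.

## The dose-Cmax spline

The published four-knot RCS has coefficients
beta = (0.0636, 0.0139, 0.0542, -0.0912) with knots 5, 7.5, 15,
22.5 mg. Two conventions required a decision:

* **Truncation.** The printed basis formulas omit the positive-part
  operator on the cubic terms. Without truncation the cubic terms
  cancel identically and the basis degenerates to a quadratic, so the
  standard truncated-power form is implemented: each `(M - k)^3` term
  applies only where `M > k`, which makes the curve linear below the
  first and above the last knot (the "restricted" property, verified by
  finite differences in the tests).
* **Scaling.** With the printed coefficient magnitudes, unscaled basis
  evaluation yields peak concentrations above 5 umol/L at 10 mg —
  physiologically impossible for LD-MTX. Under the Harrell convention
  (basis divided by `(k4-k1)^2`) the same coefficients give plausible
  values (e.g. 0.171 umol/L at 7.5 mg), so `harrell_scaled` is the
  default and `unscaled` is retained for sensitivity.

Fitting uses OLS on the design (1, M, f1, f2) with knots at the 0.05 /
0.275 / 0.725 / 0.95 empirical dose quantiles by default (explicit
knots can be fixed, which is what the recovery experiments do, since a
spline with different knots spans a different function space). Model
parsimony is scored as `AIC = n log(RSS/n) + 2 * 4`.

**A recorded discrepancy:** inverting the published spline at
0.16 umol/L gives ~6.85 mg (the linear segment alone gives
(0.16 - 0.0636)/0.0139 = 6.94), not the published baseline dose of
2.3 mg. The 2.3 mg constant evidently came from an unpublished
verification step, so it is carried as a configuration constant used
exactly where the published calculus uses it, and the inversion result
is asserted in a test rather than silently patched.

## The pharmacokinetic model

A deliberately minimal, lumped structure replaces a full-physiology
platform: a gut depot (first-order `ka`, bioavailability `F`), a
central volume `Vc`, one peripheral volume `Vp` with distribution
clearance `Q`, and parallel first-order elimination routes from
central:

* filtration: `fu x GFR_abs`, where eGFR (mL/min/1.73 m2) is converted
  to an absolute GFR by the individual's DuBois body surface area;
* lumped tubular secretion `CL_sec`, scaled in CKD by the transporter
  ratio `eGFR / 106.78` (intact nephron hypothesis). The OAT3 / RFC1 /
  MRP4 / BCRP split is carried as metadata only — at LD-MTX exposures
  (about three orders of magnitude below the reported transporter
  inhibition constants, e.g. 61.5 uM for OAT3) secretion is far from
  saturation, so a linear term is appropriate;
* hepatic (`CL_hep`) and biliary (`CL_bile`) clearance, left unscaled
  in CKD by default (retained non-renal routes; a multiplier argument
  allows scaled scenarios).

Two share constraints are enforced at the healthy reference (30 years,
176 cm, 73 kg, eGFR 106.78): the renal route must carry more than 80%
of total clearance, and secretion must be 60-80% of renal clearance.
The packaged defaults give renal share 0.87 and secretion share 0.70,
with distribution and absorption constants in the range reported for
oral LD-MTX, and were fixed once so that a single 2.3 mg oral dose in
the reference adult peaks at ~0.156 umol/L — the 0.16 umol/L
verification anchor of the risk calculus (within its stated 20% band).

Numerics: the ODE is integrated with `deSolve::lsoda` (relative
tolerance 1e-8, absolute 1e-10) on a 0.05 h output grid over the
168 h week by default; repeated doses enter as instantaneous events.
Mass balance (administered = gut + central + peripheral + eliminated +
unabsorbed loss) is checked to 0.1%; dose linearity to 1e-6 relative;
superposition of weekly doses and the filtration-only closed-form
two-compartment limit are verified in tests. AUC to the last grid point
uses the linear trapezoid — adequate on dense grids.

Calibration minimizes summed squared log10 concentration residuals
with Monte-Carlo multi-start L-BFGS-B on log-parameters. Only a
structurally identifiable subset is fitted by default (`ka`, `Vc`,
`Q`, `CL_sec`): bioavailability is confounded with volume, and the
individual elimination routes enter healthy-subject data only through
their sum, so the minor routes stay at their priors. Share-constraint
violations are penalized. Model evaluation implements the mean
relative deviation with the square root in the exponent (the printed
form without it would not be a fold error; the literal variant is
available), and both the absolute geometric mean fold error (>= 1 by
construction) and its signed variant — the signed form is what a
reported GMFE below 1 implies.

## Virtual populations and the risk calculus

Stage populations draw eGFR uniformly within stage bounds (stage 2:
60-89, 3a: 45-59, 3b: 30-44 mL/min/1.73 m2) with lognormal
morphometrics around the reference adult. Stage 1 (eGFR > 90) is
bounded above by the reference 106.78 rather than pinned at 90: a
stage-1 population sits between the stage boundary and normal renal
function, and pinning everyone at the boundary would make stage 1
uniformly worst-case. The threshold-table and optimization anchors for
stage 1 remain at 90.

The threshold equation is normalized at eGFR 90, not at the reference
106.78 that the published equation names: only 90 reproduces the
published threshold table cell-for-cell (0.16 x 7.5/2.3 = 0.522
requires a unit eGFR ratio at 90). Both constants are implemented; the
mismatch at 106.78 is asserted in a test as a recorded finding. Two
cells of the printed grid (20 mg at eGFR 89 and at 44) differ from the
equation by one unit in the third decimal (1.377 vs 1.376, 0.681 vs
0.680); the tests pin the 26 exactly matching cells and bound the two
divergent ones at 0.001.

**Assessment** simulates each virtual individual's first weekly dose
and compares their Cmax against their own threshold (their eGFR in the
equation at the regimen dose); the regimen verdict is "exceeds" when
more than half the population exceeds (configurable).

**Optimization** reduces the administered dose in 2.5 mg tablet steps
until the simulated Cmax at the stage's anchor eGFR falls under the
risk bound *of the prescribed label regimen*. Holding the bound at the
label dose is the only reading under which stepwise reduction can
work: both the threshold and the model's Cmax are linear in dose, so
re-evaluating the bound at each candidate dose would make the verdict
dose-invariant (either every dose passes or none does). For the same
reason the anchor is the stage-entry eGFR (the first threshold-table
row of each stage: 89, 59, 44) rather than the stage's lower bound —
worst-case anchoring combined with the fixed bound is strictly more
conservative than the published reductions (it gives a two-tablet
reduction for stage 2 from 7.5 mg where the published table gives
one), while entry anchoring reproduces the published stage-2 row
exactly and remains monotone across stages. Lower-bound anchoring is
kept as an option. Exact agreement with the published stage-3a/3b
doses is not attainable from the published information alone — the
stage-2 and stage-3a rows jointly imply exposure ratios no monotone
linear model can satisfy — so the package asserts the qualitative
contracts (optimized dose never above the label dose, never increasing
as the stage worsens, one-tablet reduction for stage 2 from 7.5 mg)
and reports its own, more conservative, table.

## What the synthetic data emulate — and what they do not

The corpus generator plants known drug-event rate ratios over baseline
term frequencies, versioned duplicate reports, drug-name variants, and
a renal-indication fraction; recovery of planted signals (ratio >= 5,
expected count >= 10, detected in >= 95% of seeds) and null
calibration of the ROR are the testable surrogates for the published
signal list, which cannot be reproduced without the real multi-million
report extract. Real spontaneous-report data differ in ways the
generator does not model: reporting is not independent across terms or
drugs, under-reporting is differential, and duplicates are not limited
to clean version chains. Passing these tests therefore demonstrates
correctness of the statistics and plumbing, not real-world
performance. Likewise, the concentration observations are simulated
from the model itself with lognormal noise; calibration recovery shows
identifiability of the fitted subset, not fidelity to digitized
clinical curves, which are out of scope.

Test and pipeline problem sizes (corpora of 5,000-20,000 cases,
20-seed Monte-Carlo sweeps, populations of tens to hundreds of virtual
individuals, 2,000-replicate coverage checks) were chosen as the
smallest sizes at which the binomial/Monte-Carlo error of each check
is comfortably below its asserted tolerance.

## Known limitations

* The lumped model has no kidney intracellular compartment, no
  metabolite kinetics, and no saturable secretion; it is linear by
  construction, which the risk calculus itself assumes.
* Whether non-renal clearance changes in CKD is modeled only as an
  optional multiplier; the default keeps it fixed.
* The bundled term and synonym vocabularies are small synthetic
  stand-ins for MedDRA and RxNorm-based normalization.
* Stage verdicts near the stage-1/stage-2 boundary are sensitive to
  the calibration anchor: the reference adult sits only ~6% above the
  0.16 umol/L bound scaled to eGFR 90, so single-individual
  assessments exactly at 90 are marginal by design.
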