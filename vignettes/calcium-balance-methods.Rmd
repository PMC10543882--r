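---
title: "Methods: peritoneal calcium mass balance, adequacy and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peritoneal calcium mass balance, adequacy and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcalbal)
library(dplyr)
```

## The balance model

For one patient over 24 hours the package computes three nested calcium
balances, all in mmol/day with the sign convention that positive means the
patient gains calcium:

$$B_{\mathrm{perit}} = \sum_{i} V_i\, C_i \;-\; V_{\mathrm{eff}}\, C_{\mathrm{eff}},
\qquad
B_{\mathrm{comb}} = B_{\mathrm{perit}} - \mathrm{Ca}_{\mathrm{urine}},
\qquad
B_{\mathrm{all}} = B_{\mathrm{comb}} + f \cdot \frac{m_{\mathrm{binder}}}{40.08},$$

where $V_i$ is the actual bag volume and $C_i$ the calcium concentration of
exchange $i$, $V_{\mathrm{eff}} C_{\mathrm{eff}}$ the calcium mass in the
pooled 24-h effluent, $m_{\mathrm{binder}}$ the prescribed elemental binder
calcium in mg/day and $f$ the gut absorption fraction (default 0.20).
Glucose dialysates carry 1.25 mmol/L calcium and icodextrin 1.75 mmol/L;
both are configurable in `pd_config()`.

### The flush-before-fill overfill

Manual CAPD bags are overfilled so the line can be flushed into the drain
bag before the fill: a nominal 2.0 L bag contains 2.15 L, and other manual
nominal volumes scale by the same 2.15/2.0 factor. Two accounting
conventions are implemented behind `pd_config(flush_handling = ...)`:

* `overfill_recovered` (default): the full 2.15 L counts as instilled.
  Because the flush (~90 mL) ends up in the same collection bag as the
  drained dwell, its calcium is part of the measured 24-h effluent, so
  using the full bag volume on both sides keeps the identity
  *instilled = effluent mass + peritoneal balance* exact. This is the
  default because it is the only convention under which the measured
  effluent and the instilled side refer to the same physical material.
* `flush_excluded`: the flush volume is subtracted from the instilled side
  of each manual exchange. Appropriate only for units that discard the
  flush before starting the collection.

Cycler (APD/CCPD) exchanges carry no overfill correction; the cycler's
volumetric record is used when present, the nominal fill otherwise.

### Sign classification and units

A balance of exactly zero is classified non-positive, so "positive balance"
counts never include ties. Calcium mass conversions use 40.08 mg/mmol
throughout (0.649 mmol/day ≡ 26.0 mg/day). The default elemental content
table — calcium carbonate 500 mg/tablet, calcium acetate 253 mg/tablet,
calcium/magnesium carbonate 110 mg/tablet — spans the range of marketed
products and is configurable per cohort.

## Adequacy

Daily urea clearance per route is (collection urea × volume)/serum urea;
weekly Kt/V multiplies by 7 and divides by the Watson total-body-water
estimate of the urea distribution volume. Watson was chosen over
alternative anthropometric formulas for determinism and because it is the
conventional choice in PD adequacy software; the formula's sex-specific
coefficients are hard constraints of the method, not tunables. PNA uses
the Bergström PD equation `PNA = 20.1 + 7.50 × UNA` with urea nitrogen
appearance computed from urinary plus peritoneal urea output at
0.028 g N/mmol; the equation identifier is a config field so a different
variant can be registered without touching call sites. PET transporter
bands follow Twardowski — below 0.50 low, to 0.65 (exclusive) low-average,
to 0.81 (inclusive) high-average, above high — and are configurable because
published band edges vary at the third decimal.

## DXA classification

WHO criteria with explicit boundary assignments: T = −1.0 is normal
("no less than −1.0"), T = −2.5 is osteopenia (osteoporosis requires
strictly less than −2.5), and the Z-score criterion (< −2.0) is strict.
Missing scores produce an explicit `unclassified` level rather than any
default. Both per-site and worst-site labels are emitted, since grouped
analyses can reasonably use either.

## The synthetic cohort generator

The generator exists so every downstream stage — balance, adequacy, DXA,
tabulation, screen, regression — can be exercised end to end with no
patient data. Its defaults emulate a contemporary incident PD cohort of
183 adults: modality mix 29/26.8/44.2% APD/CAPD/CCPD, 56.3% male, 30.1%
diabetic, age 59.4 ± 16.4 years, 49.2% prescribed a calcium-containing
binder, icodextrin used by 93.8% of CAPD and 95.1% of CCPD long dwells and
by no APD patient.

### Dwell model

Each exchange is a single-pool, instantly mixed dwell. The drained calcium
concentration relaxes from the fresh dialysate concentration $C_d$ towards
serum ionized calcium $S$ with equilibration fraction
$k = 1 - e^{-t/\tau}$:

$$C_{\mathrm{drain}} = C_d + (S - C_d)\,k, \qquad
V_{\mathrm{drain}} = V_{\mathrm{fill}} + \mathrm{UF}.$$

The time constant defaults to $\tau$ = 12 h: calcium equilibrates far more
slowly than urea, so short cycler dwells (≈2 h) stay near the fresh-bag
concentration while a 14-h icodextrin day dwell reaches roughly 70% of the
serum–dialysate gradient. Serum ionized calcium is drawn around
1.22 mmol/L (SD 0.07), deliberately between the 1.25 mmol/L glucose and
1.75 mmol/L icodextrin levels: glucose exchanges then sit near zero
diffusive gradient (their balance is mostly convective, −UF × C), while
icodextrin dwells load calcium into the patient. This is the simplest
mechanism that reproduces the qualitative structure of interest — balance
falling with ultrafiltration and with serum calcium, rising with
icodextrin use — and it is exactly recoverable: fitting the closed form to
generated drains returns $\tau$ within a few percent at n = 2000.

Per-exchange ultrafiltration is drawn by dwell type (short glucose
0.08 ± 0.10 L, daytime manual glucose 0.08 ± 0.12 L, overnight glucose
−0.05 ± 0.15 L allowing fluid absorption, icodextrin 0.30 ± 0.18 L), and
manual exchanges are simulated with the overfill/flush physically
separated: the flush goes to the drain bag at fresh concentration, the
remaining 2.06 L dwell in the patient. Urine volume is log-normal with
median ≈1.05 L/day and an 8% anuria rate; urinary calcium is log-normal
with median ≈0.45 mmol/day. Serum and effluent urea are linked through a
patient-level D/P urea around 0.62 so that the weekly Kt/V and PNA panels
land in clinically typical ranges (total Kt/V median ≈2.4–2.5,
PNA ≈60–70 g/day).

Randomness uses one root seed to draw per-patient sub-seeds, so a cohort
of n = 20 is the exact prefix of the same-seed cohort of n = 25.

### What the generator does and does not show

The generator reproduces association *signs* and the ordering of
modality-level medians, not the joint distribution of a real unit's
cohort: effluent calcium concentrations are derived from the dwell model
(no published concentration distribution exists to calibrate against),
covariances among serum chemistry, DXA and body composition are mostly
absent, and per-modality medians at realistic group sizes (≈50) carry
sampling noise comparable to the between-modality differences. Passing
tests therefore demonstrate the pipeline's arithmetic and the direction of
its inferences, not distributional fidelity to any particular unit.

## Cohort statistics

* **Tabulation** uses exact integer counts; percentages are 100 k/n rounded
  half-up to one decimal, matching conventional clinical-table style.
* **Spearman screen**: rho on average ranks, two-sided p from the t
  approximation on n − 2 degrees of freedom. The implementation is checked
  against a brute-force rank-formula oracle on exhaustive small cases.
* **Group tests** follow the declared variable type (Welch t / ANOVA;
  Mann–Whitney / Kruskal–Wallis; chi-square without continuity
  correction). With more than two groups the post-hoc is Tukey HSD when a
  Bartlett test does not reject variance homogeneity and Games–Howell
  otherwise (Games–Howell is implemented in-package: Welch t statistics
  against the studentized-range distribution).
* **Backward logistic regression**: candidates are pre-screened at
  p < 0.1 on the Spearman screen; elimination removes the least
  significant variable while its Wald p ≥ 0.05 *and* removal does not
  increase the AIC — "improves model fit" is operationalised as an AIC
  decrease, and a non-significant variable that improves fit is kept.
  Variables declared nonparametric are log-transformed before entry when
  strictly positive with moment skewness > 1. Quasi-separated variables
  (Wald SE > 50) are dropped with a warning rather than reported with
  meaningless intervals. The pseudo-R² is Nagelkerke's; `tidy()` reports
  β, SE, Wald = (β/SE)², OR = e^β and the 95% Wald interval
  e^{β ± 1.96 SE}.

## Numerical choices and degenerate inputs

* The mass-balance identity holds to 1e-9 by construction; conversions
  round-trip to 1e-12 relative tolerance.
* An empty exchange list is a warned dry regimen (instilled = 0), a missing
  effluent collection a hard error (the balance is undefined without it).
* Anuria is encoded as urine volume 0 with zero solute outputs, validated
  on read; renal Kt/V is then exactly 0.
* Drain volumes that would go negative (fluid absorption exceeding the
  fill) are clipped at zero with a warning in the simulator.
* A PET ratio outside [0, 1.2] and a non-positive serum urea are rejected,
  not coerced.

## Problem sizes used in the test-suite

Property suites run on 500–10,000 random records (vectorised, sub-second),
association-structure and τ-recovery checks on generated cohorts of
n = 2000, and model-recovery checks on n = 400–600 with 50 replicate null
fits at n = 1000; these sizes give stable Monte Carlo behaviour for
sign/coverage assertions while keeping the default suite fast.

## Known limitations

Only pooled 24-h collections are supported — no dwell-by-dwell kinetic
modelling. Dietary calcium intake is out of scope, so "overall" balance is
a medication-inclusive, diet-exclusive quantity. The logistic screen
mirrors a univariate-then-backward workflow common in clinical audit; it
inherits that workflow's known instability under collinearity, which the
quasi-separation guard mitigates but does not remove.
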