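---
title: "Boston and Stewart acid-base analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boston and Stewart acid-base analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidbase)
```

## Why two models

The traditional Boston workflow reads an arterial gas through pH, PaCO₂ and
bicarbonate, with compensation formulas bolted on. It is simple, but in
nephrotic syndrome it misleads: albumin is the dominant unmeasured anion,
so severe hypoalbuminemia depresses the anion gap and hides both a
metabolic alkalosis (loss of weak acid) and any superimposed acidosis.

The Stewart (physicochemical) view treats pH as the dependent outcome of
three independent controls — PaCO₂, the total non-volatile weak acid
concentration A_TOT, and the strong ion difference — and therefore makes
the albumin effect explicit. This package implements both workflows over
the same patient records so that their verdicts can be compared row by row.

## The Stewart quantities

For albumin (g/dL), phosphate (mg/dL) and pH, the package's default
("agrafiotis") coefficient set is

$$A_{TOT} = Alb \cdot 10 (0.1204\,pH - 0.625) + P \cdot 0.3229 (0.309\,pH - 0.469),$$

with a "rastegar" alternative retained behind the `dialect` argument for
sensitivity checks; the two differ by far less than analytical error.
Likewise the calculated bicarbonate inside SIDe is
$0.0301 \cdot PaCO_2 \cdot 10^{pH-6.1}$ by default, with the "kellum"
variant $2.46\times 10^{-8} \cdot PaCO_2 \cdot 10^{pH}$ differing by a
constant 2.9% ratio (the rounding of the CO₂ solubility and pK constants).
The defaults are the coefficient sets under which the packaged reference
cohort's values were produced; using one dialect throughout keeps the
construction identities exact:

$$SIDe = HCO_3^{calc} + A_{TOT}, \qquad SIG = SIDa - SIDe,$$

with $SIDa = Na + K - Cl$ (calcium, magnesium and lactate are negligible at
serum concentrations and excluded). SIG is always computed from the
*calculated* bicarbonate, not the analyzer's reported one: the reference
cohort's reported SIDe column is consistent only with the calculated value,
and the identity SIG = SIDa − HCO₃ − A_TOT then holds exactly by
construction (a property the tests exercise).

## Classification parameters

All thresholds live in `reference_ranges()` and can be overridden there or
from a YAML file via `load_config()`.

| parameter | default | units | role |
|---|---|---|---|
| `reference_a_tot` | 14.09 | mEq/L | control mean; ΔA_TOT = 14.09 − A_TOT |
| `reference_sida` | 42.7 | mEq/L | control mean; ΔSIDa = 42.7 − SIDa |
| `sig_threshold` | 7.0 | mEq/L | strict `>` flags increased-AG acidosis |
| `neutral_band` | 0.1 | mEq/L | tie region of the Δ comparison |
| `compensation_band` | 2.0 | mEq/L | adequate-compensation window (Boston) |
| `kellum_acute` / `kellum_chronic` | (0.2, 17) / (0.5, 5) | — | expected-HCO₃ lines |

**The neutral band.** The Δ comparison needs a tie region: reported
verdicts for the reference cohort include "Neutral" at Δ differences of
0.03 and 0.06 mEq/L but directional calls from 0.11 upward. Any band in
[0.06, 0.11) reproduces all 29 verdicts; the default is 0.1 mEq/L, the
round value inside that window. A wider band (e.g. 0.2) would flip the
0.11-difference patient to Neutral; the band is configurable for users who
prefer a more conservative tie region, but changing it invalidates the
reproduction report.

**Boundary conventions.** pH = 7.40 counts as alkalemia, and PaCO₂ = 40.0
Torr does *not* count as "below 40"; both conventions follow the reference
cohort's own counting. Renin/aldosterone reference ranges are inclusive at
both ends.

**Rounding.** Reported derived quantities use half-up rounding
(`round_half_up()`) at one decimal, matching clinical reporting; base R's
`round()` rounds half to even and reproduces some reported cells wrongly.

## Numerical tolerances of the reproduction report

The reference tables print pH to two decimals. A ±0.005 pH rounding error
moves the calculated bicarbonate by a factor $e^{\ln(10)\times 0.005}$,
i.e. ±1.16% — up to ≈0.34 mEq/L at the cohort's highest bicarbonates. The
per-patient tolerance for recomputed SIDe/SIG is therefore set a priori to
0.35 mEq/L; chain *medians* get 0.25 (rounding errors largely cancel
across 29 patients); directly transcribable cells 0.05; deltas 0.01;
counts are exact. The reproduction report (`reproduce_report()`) fails
loudly if any of its 48 checks drifts.

Quantiles are nearest-rank (type 1): the `ceiling(p·n)`-th sorted value.
At n = 29 this reproduces every reported interquartile pair; other quantile
types do not. The convention is deliberately *not* exposed as an option.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` draw each analyte independently from
a scaled Beta(2, 2) on a physiologic range — respecting hard bounds while
concentrating mass mid-range. Nephrotic defaults span the reference
cohort's observed values (albumin 0.8–2.9 g/dL, Cl 103–112 mEq/L, PaCO₂
21.5–44.7 Torr, lactate 0.6–4.2 mmol/L); control defaults centre on the
control summary (albumin 4.4–5.0, PaCO₂ 39.4–41.1, pH 7.39–7.41). Measured
HCO₃ is the Henderson–Hasselbalch value for the drawn pH/PaCO₂ plus
analyzer noise (SD 0.3 mEq/L), so the Boston and Stewart arms see mutually
consistent gases. The default seed is 20170313.

What the generator deliberately does **not** emulate: inter-analyte
correlation within a group (albumin–pathology correlation enters only
through the group ranges, not copulas), treatment effects, and the
measured-vs-true pH rounding structure of real reports. Passing the
recovery tests therefore shows the classifiers respond correctly to clean,
single-disorder physiology — not that they are robust to every real-world
mixture.

`inject_disorder()` perturbs the minimal analyte set for a canonical
disorder (PaCO₂ down; lactate up; Cl up at fixed Na + K; albumin down) and
then re-solves pH from electroneutrality,
$HCO_3(pH, PaCO_2) + A_{TOT}(pH) = SIDa - x_a$, holding the unmeasured
anion load $x_a$ (incremented for the increased-AG route). The root is
bracketed on pH ∈ [6.5, 8.0], where the left side is strictly increasing in
pH, and solved by `uniroot` to 1e−12; the SIG recovered by the pipeline
then rises one-for-one with the injected load to numerical precision.
Recovery checks run 200 control-like records per disorder at default
magnitudes (8 Torr, 6 mmol/L, 8 mEq/L, 2 g/dL) and require ≥95% correct
verdicts.

## Design notes and open choices

* **Boston metabolic-acidosis rule.** An acidemic record is called
  metabolic acidosis when HCO₃ is below 22 mEq/L (the normal floor) or
  below the compensation band; the duration of a respiratory disturbance
  being unknown on a single gas, the acute line is the default comparator
  and the chronic line is always reported alongside.
* **A-aDO₂ is carried, not computed.** The reference cohort's
  alveolar–arterial gradient column does not match the standard alveolar
  gas equation under any conventional constant set, so it is treated as
  recorded analyzer output; `aado2_standard()` is provided as a separate
  utility.
* **Delta references.** ΔA_TOT and ΔSIDa use the control means 14.09 and
  42.7 mEq/L. Published regression shortcuts
  (`estimate_a_tot_from_alb()`, `estimate_sig_from_cag()`,
  `delta_a_tot_from_alb()`) are stored verbatim in `published_fits()` and
  never refitted in place; refitting the albumin–A_TOT relation on the
  29 packaged patients is only property-banded in the tests (slope
  2.2–3.1, R² ≥ 0.8) because the published fit may include control
  subjects whose per-patient values are not available.
* **Lactate partition.** The `lactate_partition()` cut-offs (lactate
  > 1.0 mmol/L; SIG − lactate ≤ 5 mEq/L) are package defaults for a
  qualitative split and are not validated against any published
  patient-level partition.
* **Endocrine boundaries.** With inclusive ranges, the packaged cohort
  yields PRA below/within/above counts of 4/20/5; the published 5/19/5
  split would require counting a boundary 0.3 as below-normal. The
  inclusive rule is kept and the discrepancy documented rather than
  encoded.
* **Problem sizes.** The reproduction report and acceptance script run the
  29-patient packaged cohort; property tests use a few hundred synthetic
  records per case — desk-scale by design, since every published quantity
  derives from printed tables.

## Limitations

The classifiers operate on single time points; they do not model mixed
triple disorders beyond the verdict pairs described, temperature or
hemoglobin corrections, or the full Stewart master equation (pH is an
input, never solved for, except inside the synthetic generator's
electroneutrality solver).
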