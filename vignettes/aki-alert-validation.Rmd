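---
title: "Validating laboratory AKI e-alerts against a central re-implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating laboratory AKI e-alerts against a central re-implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akival)
```

## The problem

Since 2015 every clinical laboratory in England has been required to embed
a standard acute-kidney-injury (AKI) detection algorithm in its laboratory
information management system (LIMS). Each month laboratories send their
AKI alerts, together with the serum-creatinine (SCr) results surrounding
them, to the UK Renal Registry. Because the algorithm's reference syntax
is not distributed as code, every LIMS provider and laboratory encodes it
independently — so the alert stream a registry receives reflects not only
patient physiology but also each laboratory's interpretation of the rules,
its alert-suppression policy, and the completeness of its monthly file
transfers.

`akival` implements the machinery to audit this situation: a deterministic
central re-implementation of the detection algorithm ("what the alert
*should* have been, given the creatinine data"), chance-corrected
agreement between the local and central alert streams, and a synthetic
registry simulator so that the full pipeline — including its failure
modes — is testable without access to any real patient data.

## The detection algorithm

For each index creatinine C1 the engine derives reference values from the
patient's own history at the same laboratory:

* **RV1** — the lowest SCr in the open window (t − 7 days, t);
* **RV2** — the *median* SCr over [t − 365 days, t − 7 days]. The 365-day
  look-back is the distinctive feature of this algorithm; consensus (KDIGO)
  criteria stop at 48 h / 7 days;
* **min~48h~** — the lowest SCr in (t − 48 h, t).

Staging uses the ratio of C1 to reference, by default the larger of
C1/RV1 and C1/RV2:

| rule | condition | stage |
|---|---|---|
| ratio | ratio ≥ 3 | 3 |
| high C1 | ratio ≥ 1.5 and C1 ≥ 354 µmol/L | 3 |
| ratio | 2 ≤ ratio < 3 | 2 |
| ratio | 1.5 ≤ ratio < 2 | 1 |
| 48-h delta | ratio < 1.5 (or no reference) and C1 − min~48h~ > 26 µmol/L | 1 |
| — | otherwise | 0 |

All thresholds live in a single configuration block
(`akival_config()$engine`) so that "in-house variant" algorithms can be
emulated by overriding any of them.

### Decisions where the published description is silent

* **Window boundaries.** The windows are described only as "0–7" and
  "8–365" days. We use (t−7 d, t) and [t−365 d, t−7 d]: half-open at the
  join so a result exactly 7 days old belongs to RV2 and is never counted
  twice. An even-count RV2 median is the mean of the two middle values.
* **Both ratios.** When RV1 and RV2 both exist the engine stages on the
  larger ratio. Stage-1 alerts whose RV1 ratio is below 1.5 are routinely
  observed in registry data, which is only possible if the 8–365-day
  reference is evaluated even when a 0–7-day one exists.
  `ratio_mode = "prefer_rv1"` restores the alternative reading.
* **High-creatinine escalation.** The C1 ≥ 354 µmol/L promotion to stage 3
  comes from the published flowchart rather than the core consensus rules;
  it is on by default but gated by `high_c1_enabled`.
* **Strictness.** The 48-h delta is strict (> 26 µmol/L); the ratio
  boundaries at 1.5, 2 and 3 are inclusive, following convention.
* **Per-laboratory series.** Look-back windows are evaluated within
  (patient, laboratory): a laboratory's algorithm can only see results it
  produced itself.

## Local stages: live dates and alert linkage

Laboratories only transmit stages 1–3. A creatinine result with no alert is
recoded to local stage 0 *provided* the laboratory's algorithm was live —
proxied by the date of its first-ever received alert. Unalerted results
before the live date are not evaluable and are excluded from pairing.

Received alerts are linked to creatinine results by patient and laboratory
within a 24-hour tolerance. The linkage is **alert-to-result**: each alert
claims its single nearest result, and a result keeps the highest stage
among alerts that claimed it. The opposite direction (each result grabbing
the nearest alert) would let a stage-0 result sitting 24 h from a genuine
alert steal that alert's stage, manufacturing disagreement out of nothing —
it breaks the package's own closure property that a corruption-free
simulation must give agreement exactly 1.

## Agreement: weighted Gwet coefficient

Stage 0 dominates every registry stream (over 80% of results), which makes
kappa-type statistics collapse under prevalence effects. The package uses
Gwet's agreement coefficient; with cell proportions $p_{kl}$ (local $k$,
central $l$), weights $w_{kl}$ and marginal means
$\pi_k = (p_{k\cdot} + p_{\cdot k})/2$:

$$
p_a = \sum_{k,l} w_{kl}\, p_{kl}, \qquad
p_e = \frac{\sum_{k,l} w_{kl}}{q(q-1)} \sum_k \pi_k (1 - \pi_k), \qquad
AC = \frac{p_a - p_e}{1 - p_e}.
$$

Ordinal weights give partial credit to near-miss stage disagreements. The
default family is combinatorial,
$w_{kl} = 1 - \binom{|k-l|+1}{2} / \binom{q}{2}$ — for four stages:
5/6, 1/2 and 0 at distances 1, 2, 3. This family was *resolved by brute
force*: among identity, linear, quadratic and combinatorial candidates it
is the only one that reproduces both reference coefficients (0.97 pooled,
0.83 complete-case) from the published national cross-tabulation
(`ukrr_alert_matrix()`); the quadratic family gets the pooled value right
but fails the complete-case one (0.84). The resolution is re-executed in
the acceptance test suite.

Standard errors use Gwet's closed-form two-rater variance with subjects as
independent units, computed from the cell counts; a seeded multinomial
bootstrap (`ci_method = "bootstrap"`) is retained as a cross-check.
Coefficients are labelled with Landis–Koch bands, with ≥ 0.61
("substantial" or better) conventionally acceptable.

## The synthetic registry

`generate_cohort()` draws a stated world, not a tuned one:

* **Baseline creatinine**: log-normal mixture; 15% of patients form a
  CKD sub-population with median 164 µmol/L (sdlog 0.35); the non-CKD
  location is *solved analytically* so the mixture median equals
  77 µmol/L (sdlog 0.474, giving an IQR near 57–108).
* **Age**: `100 − LogNormal(log 27.6, 0.6)`, resampled into [18, 99] —
  median ≈ 72, IQR ≈ 60–82, right-skewed toward old age.
* **Sex**: 47% female.
* **Episodes**: Poisson arrivals at 0.8 per patient-year; severity mix
  63/18/19% over stages 1/2/3; peak C1:baseline ratio uniform on
  (1.55, 1.95) / (2.05, 2.90) / (3.10, 6.00) by stage (consistent with
  observed per-stage ratio distributions); linear rise over 1–5 days, then
  exponential recovery over 3–21 days (time constant one third of the
  recovery span).
* **Sampling**: baseline tests at 1/month (Poisson), in-episode sampling
  every 2 days plus a draw at the peak — testing intensifies when the
  patient is acutely unwell; jittered times, minute resolution.
* **Measurement noise**: multiplicative log-normal, CV 5%.

Testing intensity and episode shape are assumptions — no within-patient
time-course data are published for this population — chosen once and
documented here, not revisited. The generator emulates *marginal* registry
structure; it does not model inter-episode correlation, seasonal testing
patterns, laboratory assay drift, or true registry volumes (a scale knob
exists, but defaults are desk-scale). A green simulation test therefore
establishes the pipeline's internal consistency and the direction of
corruption effects, not any real-world agreement level.

`simulate_lab_alerts()` corrupts the true alert stream in a fixed, logged
order: **miscode → suppress → drop whole months**. All draws come from one
global RNG in canonical (patient, time) order, so with a fixed seed a
higher suppression probability suppresses a superset of alerts — the
common-random-numbers coupling used by the monotonicity tests.

## Sensitivity and subgroup analyses

* **Complete case** drops pairs whose local 0 was merely inferred from
  alert absence (suppression and failed submission are competing
  explanations), keeping all four categories; the empty local-0 row is
  retained rather than collapsing to 3×4, matching the reference
  reproduction.
* **Complete months** keeps only laboratories with both creatinine and
  alert data in every calendar month of their span.
* **Subgroups** stratify on within-sample quantiles: quartiles of baseline
  creatinine (RV2 preferred, else RV1) and quintiles of age — the axes the
  reported results actually use, though both are configurable. Cut-points
  use the standard empirical quantile (type 7); ties at a cut-point fall
  into the lower stratum; empty or degenerate strata warn rather than
  fail.

## Numerical and reporting choices

Timestamps are ISO-8601 at minute resolution with no time-zone arithmetic
(single-country registry). Duplicates are identical
(patient, time, value) triples; same-time different-value rows are both
kept and flagged. Row rejection is logged by reason and escalates to an
error above a 5% rejection rate. Report tables round half-up to 4 decimal
places; comparisons in tests use full precision or 2 decimals where the
reference values are printed at 2. Every analysis is a pure function of
the pair set, so reordering input rows changes nothing, and a fixed seed
makes the entire report bundle byte-identical.

## Known limitations

* Per-laboratory coefficients from the real registry are not reproducible
  without the underlying patient-level data; the package reproduces the
  published pooled surfaces exactly and validates the per-laboratory
  machinery on simulations with known ground truth.
* The live-date proxy under-counts evaluable results for laboratories that
  went live long before their first submitted alert survived transmission.
* Alert linkage assumes alert and specimen timestamps agree within 24 h;
  laboratories that timestamp alerts at file-assembly time would need a
  wider tolerance (`match_tolerance_hours`).
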