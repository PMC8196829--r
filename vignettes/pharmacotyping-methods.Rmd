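---
title: "Organoid pharmacotyping: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organoid pharmacotyping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacotype)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
conventions, and the places where the design was genuinely open and a
choice had to be made.

## The measurement model

A two-step cytotoxicity assay reads each well twice: S1, the luminescence
of a dead-cell protease substrate before lysis, and S2 the total signal
after lysis. The viable signal in a well is S2 − S1, and percent viability
at a concentration is the ratio of the mean viable drug signal to the mean
viable control signal on the same PDO plate, times 100. Assumptions worth
making explicit:

* **Controls are plate-local.** Each PDO plate normalizes against its own
  untreated wells; a control with mean S2 − S1 ≤ 0 is a failed plate
  ("degenerate control") and is an error, not a silent NA.
* **Viability is not capped at 100 %.** A well whose viable signal exceeds
  the control mean (growth stimulation, pipetting variance) keeps its
  value; capping would bias the AUC of flat, insensitive curves downward.
* **Negative net signals clip to 0** (with a warning): S1 > S2 can only be
  noise, and a negative viability has no physical meaning and would
  corrupt the AUC baseline.
* **Replicates are averaged at the viability level** before integration —
  the arithmetic mean, the default treatment of replicate XY data in the
  plate-analysis software this pipeline replaces. Replicate-level values
  are retained on the profile for inspection.

## AUC on the log10-dose axis

The dose-response score is the trapezoidal area under percent viability
versus log10(concentration), baseline 0, with no curve fitting. Two
decisions here were open and are now fixed conventions:

* **Integration abscissa: log10 dose.** The panel spans three orders of
  magnitude in equal log steps (13 nM to 50 µM, ten points). On a linear
  concentration axis the top dose interval would contribute essentially
  all of the area; on the log axis each dilution step contributes equally,
  and the achievable range for a ≤ 100 % curve is 0 – 358.5
  (100 · log10(5·10⁻⁵/1.3·10⁻⁸)), which is the scale on which responder
  cut-offs in the 130–280 range live. AUC on this axis is exactly
  invariant to the concentration unit (a unit change is a constant shift
  in log10 that cancels in differences) — tested to 1e-12.
* **Percent, not fraction.** Viability enters as 0–100, consistent with
  cut-off magnitudes above; using fractions would only rescale every AUC
  by 100 and every break with it.

No IC50/EC50 or Hill fit is attempted: the trapezoidal AUC of the raw
curve is the published score, is defined for non-sigmoidal curves, and
needs no convergence diagnostics.

## Natural-breaks responder classes

Per drug, the library's AUC vector is partitioned into k = 3 contiguous
classes of its sorted order minimizing the total within-class sum of
squared deviations. The implementation is the exact dynamic program
(Fisher's optimal 1-D grouping), not the iterative reallocation heuristic:
for every prefix and class count the optimal cost is computed, and the
partition is reconstructed front-to-back. Conventions:

* **Tie-breaking.** Among equal-cost partitions the lexicographically
  smallest break sequence is chosen (smallest first break, then second).
  This makes the classifier deterministic and input-order independent —
  cost ties do occur with duplicated values.
* **Break values** are reported as the *maximum of the lower class*, so a
  value exactly equal to a break belongs to the lower class. For training
  data, membership is decided by the class assignment itself, never by
  re-thresholding, so equality cases are unambiguous.
* **Scores.** The lowest-AUC class is the high-responder group, score 1;
  intermediate 2; low responder 3. The goodness-of-variance fit
  GVF = 1 − SDCM/SDAM is reported with each model.
* **The n ≥ 25 gate.** Classifying a library below 25 PDOs per drug is
  refused by default but can be overridden with a warning — a hard
  failure would make the pipeline untestable on small fixtures, while a
  silent pass would hide that breaks from a small library are unstable.
* **Frozen vs re-clustered breaks.** A new PDO can be scored against a
  frozen model by interval membership (below the fitted range → high,
  above → low), so a patient's prediction does not change because the
  library grew; re-clustering the grown library is an explicit separate
  call. Whether the original analysis re-ran the clustering per analysis
  date is unknowable from the outside; both modes are provided.

Ki-67 proliferation indices use the same machinery with k = 2, or the
fixed 45 % rule (high iff > 45 %; exactly 45 % is low).

## Regimen prediction

The regimen score is the mean of the component drugs' scores over the
*screened* components only — leucovorin (a biochemical modulator, not a
cytotoxic) and the nab-paclitaxel albumin carrier are never components.
Score ≤ 2 predicts a sensitive regimen, with the boundary inclusive by
the published rule; the score is permutation-invariant and bounded in
[1, 3] (asserted over all 3⁴ component combinations).

The alternative classifier is a hard-margin linear SVM on AUC feature
vectors. Open points fixed here:

* **Features: all five screened drugs** (the full pharmacotype), with a
  flag to restrict to the regimen's components.
* **No feature standardization by default** — the AUCs share one scale;
  z-scoring is available as an option.
* **Hard margin, no slack.** The published model is a perfectly separating
  hyperplane; non-separable training data is an explicit error, never a
  silent soft-margin fallback. The solver is SMO-style pairwise coordinate
  ascent on the dual followed by an exact KKT solve on the detected
  support set; the test suite checks it against a brute-force
  maximum-margin search over support subsets (agreement to 1e-6 on all
  small separable sets).
* **A decision value of exactly 0** is reported as no-response with a
  boundary warning.

## Cohort statistics

* **Tumor control:** CR, PR and SD count as response; PD as no-response;
  missing restaging is excluded from accuracy denominators and the
  exclusion count is always reported.
* **Fisher's exact test** (two-sided) sums hypergeometric probabilities
  over the support of tables at least as improbable as the observed one —
  the standard small-table definition — with a 1e-7 relative tolerance on
  the probability comparison to avoid floating-point under-counting, and
  the total clamped to 1.
* **Mann–Whitney** uses the exact rank-permutation null (full enumeration)
  for combined n ≤ 20 and the tie-corrected normal approximation with
  continuity correction beyond. The continuous-outcome comparisons in the
  evaluated trial did not name their test; a rank test is the conservative
  choice for skewed day counts and is flagged as an assumption.
* **Kaplan–Meier** is the product-limit estimator with censoring at t
  handled after events at t; the median is the first time with
  S(t) ≤ 0.5 and is undefined if never reached. The group comparison is
  the standard 1-df log-rank test (also unnamed in the source analysis).
  A group with zero events warns but still yields a p-value.
* **Percentages are rounded half-up to one decimal** — base R's
  round-half-even would turn e.g. an exact X.X5 the wrong way relative to
  clinical reporting conventions.

## The synthetic generator: what it emulates, what it does not

`generate_plates()` emulates the assay structure: per PDO × drug a
responder archetype is drawn (high / intermediate / low), an IC50 around
the archetype mean, and viability follows a four-parameter logistic in
log10 dose, V(c) = floor + (100 − floor)/(1 + 10^(hill·(log10 c − log10 IC50))),
emitted as S1/S2 well pairs with multiplicative Gaussian replicate noise.
Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| panel | 10 points, 13 nM – 50 µM | the published screen design |
| replicates | 2 | "tested in duplicates" |
| archetype IC50 means | 0.1×, 1×, 10× the panel's geometric mid-dose | one log-unit separation, centred on the panel |
| log10 IC50 sd | 0.25 | within-archetype biological spread; keeps archetypes recoverable but overlapping |
| Hill slope | 1 | typical cytotoxic single-agent steepness |
| floor viability | 5 % | residual resistant fraction / assay background |
| replicate noise | 5 % | duplicate scatter of a well-run luminescence assay |
| label noise (naive / pretreated) | 0.1 / 0.6 | matches ~90 % first-line and ~40 % pretreated prediction accuracy |
| PFS scales (sensitive / resistant) | 141 / 46 days | the published median PFS contrast |
| censoring probability | 0.2 | typical for a short-follow-up advanced-cancer cohort |

The generator does **not** simulate tumor microenvironment effects,
molecular subtype biology, inter-drug correlation within a PDO, plate
position effects, or the pharmacology of extended drug panels. A green
simulation test therefore establishes that the pipeline recovers the
structure the generator puts in (archetypes, label-noise rates, survival
contrast) — not that it would recover the messier structure of real
screens.

Determinism: three decoupled pseudo-random streams (ground truth, plate
noise, clinical outcomes/censoring) are derived from one seed, so the same
configuration is byte-identical and regenerating one artifact leaves the
others unchanged.

## The deterministic fixture

`fixture_cohort()` encodes, exactly, the published trial's aggregate
counts (sample flow, stratum sizes, pharmacotyping successes, per-line
prediction matches, subtype table), so the cohort statistics reproduce the
printed percentages and Fisher p-values without any data download. The
patient-level AUC matrices and survival times were published only
graphically; fixture PFS and Ki-67 fields are therefore synthetic
placeholders, flagged as such, and no test asserts them. The per-patient
composition of the evaluated subgroups (which 5 of 11 first-line patients
went on to second-line evaluation) is likewise an arbitrary but
count-faithful reconstruction.

One reporting discrepancy is preserved deliberately: the first-line
accuracy computes to 90.9 % (10 of 11) from the printed counts, while the
source text prints 91.1 %. The pipeline reports the computed value.

## Known limitations

* The Jenks dynamic program is O(k·n²); fine for libraries up to a few
  thousand PDOs, not for generic large-scale 1-D clustering.
* The SVM solver targets the small, separable training sets of this
  application (tens of PDOs); it is not a general-purpose SVM.
* No multivariable survival modelling, no multiple-testing correction,
  no plate-geometry QC — all deliberately out of scope.
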