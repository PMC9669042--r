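---
title: "Personalized water-intake advice by surrogate inversion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized water-intake advice by surrogate inversion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroadvisor)
```

## The problem

Sustained concentrated urine is linked to chronic kidney and metabolic
disease, and a 24 h urine osmolality (U_Osm) of 500 mOsm/kg is a widely used
marker of optimal hydration. Population guidelines (for example the EFSA
adequate intakes of 2.5 L/day total water for men and 2.0 L/day for women,
of which ~80% comes from fluids) ignore individual physiology. This package
implements a personalized alternative in three steps:

1. **Surrogate.** Fit a gradient-boosted tree regressor
   $\hat y = f(\mathbf{x})$ predicting U_Osm from anthropometrics (age, sex,
   height, weight, BMI) and intake variables (plain water, total fluid
   intake, total water intake, food/nutrient quantities), with error
   measured as $\mathrm{MAE} = \frac{1}{N}\sum_i |y_i - \hat y_i|$.
2. **Inversion.** For each person, hold everything fixed except plain water
   intake $w$ and solve
   $\min_w \,(f(\mathbf{x}(w)) - 500)^2$ subject to
   $375 \le f(\mathbf{x}(w)) \le 625$ and $0 \le w \le 4050$ mL, the band
   constraints entering as augmented-Lagrangian penalties. Raising $w$ by
   $\Delta$ raises total fluid intake and total water intake by the same
   $\Delta$ (the coupling rule), so advice is expressed both as water and as
   total fluid intake.
3. **Evaluation.** Classify each test datapoint by the sign of
   (actual TFI − reference TFI) against the observed U_Osm side of
   500 mOsm/kg: TP (drank at least the reference, well hydrated), FP
   (drank at least the reference, still concentrated — the only harmful
   error), FN (drank less, still dilute), TN (drank less, concentrated).
   Accuracy is (TP+TN)/total; the *acceptable classification* rate
   (TP+FN+TN)/total penalizes only FP. The same rows scored against the
   sex-specific EFSA fluid thresholds (2.0 / 1.6 L) give the guideline
   baseline.

Because the pooled clinical-trial dataset behind this design is not public,
the package ships a mechanistic synthetic cohort generator so every stage is
testable end to end.

## The synthetic cohort generator

The generator emits participant-visit records from an **osmolar-clearance
forward model**:

$$U_{\mathrm{Osm}} = \frac{\text{osmolar load (mOsm/day)}}
{\text{net urine volume (L/day)}},$$

with osmolar load = 10 mOsm/kg/day × body weight plus dietary terms
(2.5 mOsm per g protein, 0.032 mOsm per mg sodium), and net urine volume =
total water intake + 300 mL metabolic water − 900 mL insensible losses,
floored at 300 mL/day (anuria is out of scope). Multiplicative lognormal
noise (SD 0.20 on the log scale) and clipping to 50–1400 mOsm/kg finish the
draw. This is the simplest mechanism that reproduces the inverse, monotone
water → U_Osm relationship the analysis assumes, and it is homogeneous:
doubling the load at fixed volume doubles U_Osm.

Cohort structure emulates a pooled hydration-trial population: ~63% female,
age 19–51 y (right-skewed, mean ≈ 30), BMI 18–30 kg/m², 1–4 visits per
participant (sex and height constant within participant, age/weight drifting
slightly), plain water lognormal over 0–4050 mL, total fluid intake roughly
200–6000 mL, and a participant-level block of missing intake fields
(default 19% of participants) mirroring the retention of
incomplete-intake participants in the motivating analysis. Seeding is
hierarchical (cohort → participant), so enlarging a cohort never perturbs
existing participants. Correlated urine features (24 h urine volume, number
of micturitions ≈ volume / 250 mL voids) are emitted deliberately so the
feature-selection stage has something realistic to discover *and then
exclude*.

Design choices worth flagging:

* **Food water is tied to food quantity, not beverages.** Food moisture is
  drawn proportional to energy intake (≈ 0.24 mL/kcal at the default 20%
  food-water share), independent of fluid intake. An earlier draft scaled it
  with total fluid intake; that made food moisture an unshiftable alias of
  total water intake, which tree ensembles happily exploit — and since the
  advisor can only shift beverage-derived columns, the fitted water slice
  was systematically attenuated and advice overshot. The energy-based
  construction is both more physiological and identifiable.
* **The ceiling accumulates mass.** For very low drinkers the clearance
  ratio exceeds the 1400 mOsm/kg clip bound, so the generated U_Osm
  distribution piles a few percent of records at the ceiling and its mean
  runs above the ~550 mOsm/kg typical of real cohorts. Real kidneys have a
  soft concentrating limit; ours is hard. Passing tests on this generator
  therefore demonstrate pipeline correctness, not that the model will
  reproduce any particular clinical error level.
* What the generator does **not** emulate: thermoregulation, exercise,
  seasonality, pregnancy/lactation physiology, multi-study batch effects,
  and the original 107-variable codebook (only the modelled subset plus the
  urine features is emitted).

## Preprocessing

Eligibility filters: age 18–65 y and BMI 18–30 kg/m² (healthy-adult
conventions, configurable — the motivating analysis prints only its observed
ranges), plasma osmolality ≤ 310 mOsm/kg (above indicates dehydration,
~5% body-weight loss), total fluid intake ≥ 200 mL (below cannot meet
physiological needs), and complete response + anthropometrics. Missing
plasma osmolality or intake never triggers the corresponding filter: records
with missing intake are retained because tree learners route missing values
natively and such records still inform the rest of the model. Each removed
row is attributed to the *first* violated criterion (age, BMI,
incompleteness, plasma osmolality, minimum intake), so the report's counts
always reconcile. Filtering is idempotent.

The train/test split is by **participant** (default 75:25, rounding toward
train): repeated visits of one person are correlated, and row-level splits
would leak that correlation into the test error. The participant list is
sorted before seeded shuffling, so the split is invariant to row order.
Cross-validation folds inside tuning are grouped by participant for the same
reason.

## Surrogate fitting

Feature importance is the **fractional split gain** of a boosted-tree
ensemble (shares summing to 1; a max-normalized column is kept for display
parity with importance plots scaled to the top feature). The default
feature policy excludes 24 h urine volume and micturition count — the two
best predictors, but ones the general population cannot supply — and the
response and participant ID are never allowed. The final allowed list is
configurable, standing in for the deployable subset a production model
would fix.

Tuning is seeded random search (default 50 draws; tests and the acceptance
script use 6–10 draws to keep runtimes proportionate to their cohort sizes)
over depth 3–8, learning rate 0.03–0.3 (log-uniform), 100–600 rounds,
subsample 0.7–1.0, selected by mean grouped-CV MAE and refit on the full
training set. The primary learner is XGBoost, which routes missing values
natively; the random-forest comparator (ranger) receives a documented
missing-as-sentinel encoding (−10⁶, far outside any feature's range) since
forests have no native routing. `compare_learners()` repeats the whole
split + tune + fit + test cycle (default 5 repeats) and reports per-learner
MAE mean and SD as the stability assessment.

## Interpretation: PDP/ICE and ALE

`pdp_ice()` is the standard overwrite construction: ICE curve
$c_i(g) = f(\mathbf{x}_i \text{ with feature} = g)$ and PDP
$= \frac{1}{n}\sum_i c_i(g)$, on a default grid of 28 points over
0–4050 mL (150 mL step — the same axis the optimizer searches). All rows'
ICE curves are computed (no subsampling). Grid points outside the observed
range are allowed but flagged as extrapolation. `ale()` uses ~20 equi-count
quantile bins, per-bin mean prediction differences between bin edges,
cumulative accumulation, and centering so the count-weighted mean of the
per-bin mid-curve values is zero; tied quantiles merge bins.

**A caution about correlated intakes.** Plain water is a component of total
fluid and total water intake. When those aggregates sit next to plain water
in the feature list, trees can express the entire intake effect through
them, and the overwrite-style PDP over plain water alone is nearly flat even
though the model (and the advisor, which shifts the aggregates *with* water)
is perfectly sound. For curve-based inspection of the water effect we
therefore fit an inspection surrogate on the *actionable* feature set —
plain water plus anthropometrics and food variables, without the aggregate
totals. On such a model the PDP over 0–4050 mL descends by roughly
1000 mOsm/kg on noise-free cohorts, and `largest_drop_interval()` (a sliding
window over the PDP, default 300 mL) recovers planted steep segments — e.g.
a cohort whose observed water intake never goes below 1200 mL yields its
steepest descent on [1200, 1500] mL, the hyperbola being steepest at the low
edge of the support.

## Inversion: the advisor

Tree-ensemble responses are piecewise constant, so naive gradient descent is
undefined. `recommend_water()` therefore:

1. caches the raw 1-D water slice on a 5 mL lattice (one batched predict)
   and builds a smoothed slice (moving average, 100 mL kernel);
2. runs an augmented-Lagrangian outer loop (penalty 1.0, ×10 per outer
   iteration, max 8; multipliers updated by the standard max(0, λ+μg) rule)
   whose inner subproblem is solved by safeguarded 1-D Newton steps with
   50 mL finite differences (trust radius 500 mL, backtracking on
   non-descent), converging when band violation < 1 mOsm/kg and water step
   < 1 mL;
3. multi-starts from the original water, 1500 mL, both bounds, and the
   lattice minimizer of the initial smoothed penalized objective (the cached
   slice makes this global initialization free, and tree plateaus make it
   necessary);
4. polishes every candidate against the *raw* penalized objective on the
   lattice within ±250 mL, then picks the candidate with the lowest raw
   objective, breaking ties toward the smallest behavior change
   (least |optimized − original| water).

The reported prediction always comes from the raw model at the returned
water value. If no in-bounds water satisfies the band, the bound-respecting
minimizer of |prediction − 500| is returned with status `"infeasible"`.
The squared (rather than absolute) deviation from target is a deliberate
interpretation — it is smooth at the optimum and makes the penalized
objective a proper least-squares form. `brute_force_invert()` evaluates the
identical objective exhaustively on a coarse grid (default 50 mL) and serves
as the independent oracle in tests. Rows with missing plain water or total
fluid intake are skipped, not imputed: the coupling rule would be undefined.

## Evaluation

`classify_datapoint()` implements the contingency scheme with the tie
Δ = 0 assigned to the "≥ 0" row, exactly as the scheme's row label prints
the inequality. The identity
acceptable − accuracy = FN/total holds for every table and is asserted
property-style. `efsa_reference_tfi()` derives the fluid thresholds as
0.80 × {2500, 2000} mL exactly. Rows with missing observed TFI or U_Osm are
excluded from scoring and counted, never imputed.

## Numerical and degenerate-input choices

* Constant response → feature ranking errors out (`degenerate response`).
* All-missing feature columns are dropped with a warning at fit time.
* Single-participant splits put everything in train with a warning.
* Empty filter input returns an empty table and a zeroed report.
* ALE with fewer distinct values than bins shrinks the bin count; tied
  quantile edges merge bins.
* The config hash canonicalizes (recursively key-sorts) the configuration
  before hashing, so semantically identical configs hash identically.

## Problem sizes used by the tests and acceptance script

Unit tests run cohorts of 50–300 participants with 2–6 tuning draws; the
end-to-end checks use a 600-participant noise-free cohort (≈ 1100 rows,
~320 eligible test rows) with 8 draws / 3-fold grouped CV, PDP/ALE oracle
comparisons on 200 held-out records, solver-vs-grid-oracle comparisons on
220 records, and the closed-loop recovery check (advised water pushed back
through the noise-free forward model must land in [375, 625] mOsm/kg for at
least 90% of records whose band is reachable within the water bounds).
These sizes are the package's own choices, balancing statistical resolution
against proportionate runtimes.

## Known limitations

* The generator's food set (energy, protein, sodium, food moisture) is a
  stand-in; its realism is untested against dietary data.
* The hard osmolality ceiling distorts the upper tail of generated U_Osm.
* PDPs over features with strong aggregates in the model are masked (see
  above); ALE mitigates but does not remove this.
* The advisor modulates plain water only — no beverage reallocation, no
  intra-day timing.
* Synthetic closed-loop success shows the machinery inverts a faithful
  surrogate; it says nothing about surrogate fidelity on real clinical
  data.
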