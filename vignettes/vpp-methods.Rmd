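---
title: "Designing a data-driven ED vertical patient pathway: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a data-driven ED vertical patient pathway: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A vertical patient pathway (VPP) lets an emergency physician assess and
treat selected patients without assigning them a traditional ED bed: the
patient stays "vertical" (seated, waiting-room based), the bed stays free
for someone sicker. The hard question is *who* is safe and efficient to
route vertically, and how that answer should change when the department
saturates. `vppflow` implements an end-to-end, testable replica of a
data-driven design for that decision:

1. a synthetic ED encounter generator with a known ground-truth bed-need
   mechanism (so every later stage can be validated against a planted
   signal);
2. tiered outcome labeling of "requires an ED bed";
3. a random-forest risk score from triage-time features;
4. a two-stream queueing model — the VPP as an M/M/1 queue whose server
   takes exponential *vacations*, the main ED as a plain M/M/1 queue — with
   a misclassification-aware routing cost minimised over the risk
   threshold;
5. a discrete-event simulator that validates the closed forms and compares
   flow designs;
6. distillation of the per-state optimal policy into a shallow decision
   tree usable at a triage desk; and
7. before/after evaluation: descriptive tables, an adjusted log-LOS
   regression, and 72-hour return models.

Everything runs on synthetic data; no clinical data ships with the
package. The numbered drivers under `analysis/` execute the stages in
order and write their tables under `results/`.

## The synthetic cohort and its planted truth

`ed_generator_config()` encodes the study conditions: a 90-day horizon cut
into a pre period (days 0–33), an educational period (34–54) and a post
period (55–89); roughly 159 arrivals/day from a four-shift piecewise
profile (night 2.5/h, morning 8.5/h, afternoon 9/h, evening 6.5/h) with
gamma-distributed day-to-day surges (CV ≈ 0.2); 56 treatment spaces. The
acuity mix is chosen so the ESI marginal has mean 2.88 and SD 0.66
(probabilities 0.010/0.245/0.610/0.125/0.010 over ESI 1–5 — a tertiary
mix, light in ESI 1 and 5). Age is truncated normal (58.9, SD 21). Five
vitals are drawn per patient; each is independently "abnormal" (displaced
in the worrying direction) with an ESI-dependent probability falling from
0.55 at ESI 1 to 0.06 at ESI 5.

The generator's central design choice is a **known bed-need mechanism**:
ESI 1–2 always need a bed; otherwise bed need is Bernoulli with logit
`b_esi(ESI) + b_complaint(category) + 0.9 × (number of abnormal vitals)`.
Skin, urinary and eye complaints carry strongly negative coefficients
(−3.2, −3.0, −3.4), making them the recoverable "safe vertical" signal;
the remaining ESI-3 complaints sit in a deliberately tight band so that
the learned risk score separates into clusters (ESI 4/5 low, ESI-3
skin/urinary/eye mid, other ESI 3 high, ESI 1–2 near 1). Procedures (IV,
CT with/without contrast, X-ray, ultrasound) are drawn conditional on the
truth and on ESI, with a 0.35 multiplier for skin/urinary/eye
presentations (those complaints rarely need imaging or continuous IV
access); their marginal rates land near a tertiary cohort's (IV ~65%,
X-ray ~46%, CT ~25%/20%, US ~12%).

LOS is log-normal conditional on truth, procedures, ESI and disposition.
Patients who truly need no bed have a short scale (median ≈ 85 min, sdlog
0.30) — short enough that the two-hour labeling rule below can find them —
while bed-needing patients are long (scale ≈ 216 min before procedure
effects, sdlog 0.32). The intercepts were calibrated once so the marginal
pre-period mean lands near 258.7 min. One consequence is accepted
deliberately: the bed/no-bed separation that the labeling rules require
inflates the between-group variance, so the marginal LOS SD comes out
near 140 min rather than the ~122 min of the cohort the defaults emulate.
The configured *means* are matched; the SD is documented as approximate.

The post period multiplies LOS by `intervention_effect` (default 0.9585,
i.e. a 4.15% geometric-mean reduction) via `inject_intervention_effect()`
— this is the planted effect the evaluation stage must recover. Returns
within 72 h are generated at ~3.9% (60% of them with admission) with *no*
period effect, so the return models have a true null to hold.

Operational covariates at arrival (patients in treatment, waiting count,
saturation flag) come from a presence-census emulation: each patient
occupies the department from arrival until LOS (plus a boarding interval
of lognormal mean ≈ 310 min for the admitted third), the census is capped
at the bed count, and the excess is the waiting count. This is an
emulation of congestion, not a queueing-consistent service process — it
produces realistic diurnal and surge-driven congestion (a few percent of
arrivals see a saturated department) but no feedback from congestion to
LOS.

What the generator does **not** emulate, and what passing tests therefore
do not establish about real data: free-text complaints (inputs are already
categorical), physician-level practice variation in LOS, time-of-day
service-rate changes, COVID-era regime shifts, inter-hospital transfers,
and any confounding between period and case mix (the default cohort is
unconfounded by construction; a confounded variant is constructed in the
tests to show the adjustment moves estimates the right way).

## Labels, the gold standard, and the risk model

`assign_bed_need_labels()` applies the tiered definition in strict order:

1. **gold** — seen in the VPP and discharged (a bed was demonstrably never
   needed): the only observed labels;
2. **ESI-3 rule** — ESI 3, discharged, no imaging of any modality, no IV
   therapy, LOS strictly under 120 min;
3. **ESI-4/5 rule** — ESI 4 or 5 with no IV medications or fluids;
4. everything else **requires a bed**.

"Imaging" means any of CT with contrast, CT without contrast, X-ray or
ultrasound (the tabulated modalities), and both "IV therapy" and "IV
medications or fluids" map to the single IV flag. The 120-minute boundary
is strict. The rules are a total function: every clean row gets exactly
one tier, and the binary label is `tier == bed`.

The held-out **gold-standard test set** pairs all gold cases (positives
for "no bed") with an equal-size random sample of unambiguous bed cases —
ESI ≤ 2 patients who were admitted. The composition of the negative class
is a deliberate design choice: maximising
label certainty on both sides was preferred over mimicking cohort
prevalence, and the resulting AUC should be read as separability of
certain cases, not calibrated performance on the full case mix.

`fit_bed_need_model()` is a bagged-tree ensemble (random forest via
`ranger`, 200 trees, impurity importance, fixed seed, single-threaded for
reproducibility) on triage-time features only: ESI, complaint category,
age and z-standardised vitals. Procedures, disposition and LOS are
*labels' ingredients*, never predictors. `evaluate_auc_bootstrap()` runs
five bootstrap train/evaluate rounds against the untouched gold set —
"five bootstrap iterations" is read as five resampled fits whose AUCs are
averaged.

## The queueing model and the routing threshold

Patients with risk score ≤ τ go vertical; the rest go to the main ED.
With total arrival rate λ and classifier operating characteristic
`F_bed(τ) = P(score ≤ τ | bed)`, `F_nobed(τ) = P(score ≤ τ | no bed)`
(empirical, from held-out scores), the vertical stream receives
`λ_v = λ (p F_bed + (1−p) F_nobed)` and the main stream the rest.

The vertical server alternates between availability and exponential
vacations of rate θ — the physician is intermittently pulled back to
main-ED duties, and when the vertical queue empties they leave and return
at Exp(θ) intervals until work is waiting ("multiple vacations"). The
classical decomposition result gives the stationary queueing delay

&nbsp;&nbsp;&nbsp;&nbsp;`Wq_vpp = λ_v / (μ_v (μ_v − λ_v)) + 1/θ`,

the plain M/M/1 delay plus the mean residual vacation (for exponential
vacations `E[V²]/(2E[V]) = 1/θ`). The formula is not taken on faith: the
discrete-event simulator checks both queue formulas against long runs on
a 12-point (λ, μ, θ) grid, and a negative control confirms that dropping
the `1/θ` term is detected.

The routing cost, in minutes per patient, is

&nbsp;&nbsp;&nbsp;&nbsp;`share_v · Wq_vpp + share_m · Wq_main + c₁ p F_bed(τ) + c₂ (1−p)(1−F_nobed(τ))`,

where `c₁` (default 30 min) prices a type-I misroute — a bed-needing
patient sent vertical, who consumes a vertical assessment and then
re-queues at the main ED — and `c₂` (default 15 min) prices a type-II
misroute, the opportunity cost of occupying a bed slot with a
vertically dischargeable patient. Both defaults are package choices, not
published values. Unstable splits cost `+∞`.

Because the empirical operating characteristic makes the cost a *step
function* of τ (it changes only when τ crosses an observed score),
`optimal_threshold()` evaluates a 0.001 grid **plus every empirical score
breakpoint**, which makes the minimisation exact over continuous τ; ties
resolve to the smaller τ (fewer vertical routings). A golden-section
refinement was considered and rejected: smooth local search on a step
function can stall one step from the optimum, while breakpoint
enumeration cannot.

Two monotonicities follow from the conventions and are enforced in tests:
raising `c₁` never raises τ*, raising `c₂` never lowers it.

## ED states and the distilled protocol

`enumerate_ed_states()` crosses three axes (4 × 3 × 3 = 36 states):

* **demand** — multiplier {0.8, 1.0, 1.2, 1.45} on the calibrated base
  arrival rate;
* **staffing coverage** — the nominal main-ED utilisation the schedule
  targets, {0.70, 0.75, 0.80} (staffing follows scheduled demand, so the
  service rate scales with the demand axis);
* **congestion** — `quiet` (60% of beds occupied, empty waiting room),
  `busy` (all beds full, waiting ≈ 10% of beds), `crowded` (all beds
  full, waiting ≈ 80% of beds). A waiting backlog inflates the effective
  near-term arrival rate by `1 + n_waiting/n_beds`.

`crowded` states are exactly the ones flagged by the institutional
saturation rule (all beds occupied and strictly more than a quarter of
bed capacity waiting), and their backlog-inflated load exceeds main-ED
capacity: stability alone forces a large share of the flow vertical
there. The vertical assessment itself is quick (μ_v = 16/h, ~4 min) with
10-minute mean vacations (θ = 6/h); both values, like the axes, were
fixed at design time so that the per-state optima reproduce the intended
two-regime behaviour, and frozen before any acceptance checking. The
qualitative result, visible in `analysis/03_queueing_thresholds.R`, is
that unsaturated thresholds sit in the wide score gap *below* the
non-skin/urinary/eye ESI-3 cluster, while crowded thresholds sit *above*
it — eligibility expands under saturation, as the design intends.

`optimal_labels_for_states()` then labels each of the 45 (ESI ×
complaint) strata in each state — `vpp_eligible` iff the stratum's mean
risk score is at or below the state's τ* — and `distill_decision_tree()`
fits an `rpart` classification tree of depth ≤ 4 on (ESI, complaint
category, saturation flag) *only*. The risk score builds the labels but
is deliberately excluded as a tree feature: the protocol must be
executable by triage staff from the chart alone. Leaves with tied counts
resolve to the main ED (conservative). Agreement is measured on
**held-out states** (a third of the grid, split by state) rather than
in-sample — the stricter of the two measurement choices.

One divergence is worth stating plainly. The *deployed* protocol —
exposed verbatim as `protocol_decision()`: ESI 4/5 vertical, ESI 3 with
skin/urinary/eye complaints vertical, and during saturation *everyone*
vertical — goes one step beyond the queue-optimal policy, which expands
eligibility to all ESI-3 patients under saturation but never finds it
optimal to route ESI 1–2 vertically (their type-I cost and near-certain
re-queue dominate any wait relief). The saturation override for the
sickest patients is an institutional simplification of the optimizer's
output, not a consequence of it; the package keeps both objects and the
tests hold each to its own contract.

## The simulator

`simulate_scenario()` draws exponential inter-arrival, service and
vacation times per replication. Single-stream FIFO waits use the Lindley
recursion (vectorised for the plain queue); the vacation queue uses the
exact per-customer recursion in which the first vacation completion after
an arrival to an empty system sits an Exp(θ) residual beyond it (vacation
completions form a Poisson process, so this is exact, not an
approximation). Four designs are implemented: the VPP two-stream design
with type-I re-queues, a fast track (dedicated server restricted to ESI
4/5), physician-in-triage (an upfront stage for all arrivals with a
rework probability downstream), and a no-split baseline. Warmup (default
20% of the horizon) is excluded from summaries; ties are impossible by
construction (continuous clocks), and each replication is seeded
explicitly. Conservation (arrivals = departures + in-system) and Little's
law are enforced in the test suite.

## The evaluation stage

`summarize_table1()` produces the usual before/after cohort table: Welch
comparisons for continuous variables, Pearson chi-square for proportions
(the standard defaults for a before/after cohort table), plus the
LOS difference in minutes and as a percent of the pre mean.
`vpp_routing_table2()` stratifies vertical-pathway routing by ESI with
ESI 3 split into skin/urinary/eye versus other, and applies the
small-cell rule exactly: Fisher's exact test whenever any cell of the
2×2 table is below 10, Pearson chi-square otherwise.
`reconstruct_denominators()` inverts printed "count (percent)" pairs to
their exact denominators by search, for checking printed stratum sizes.

`fit_log_los_model()` regresses log LOS on the post indicator with three
optional control groups — patient (age, ESI categorical or continuous,
complaint), operational (disposition, procedures, optional physician
fixed or random effects via `lme4`), and saturation/timing (staffing on
duty, census, shift). Educational-period rows are excluded by default
(the contrast is pre vs post); calendar covariates are deliberately
absent, congestion and staffing controls standing in for them. The
implied percent change is `100(exp(β)−1)` and the minutes change is
evaluated at the pre-period mean. Return outcomes use the same design
with a logit link — the closest binary analogue of the log-linear LOS
model. Tests are two-sided with no multiplicity correction — the before/after
design reports each contrast on its own terms; `robustness_suite()` reports the spread of the
estimate across specifications instead.

One subtlety the replica makes visible: the census covariates are
measured at arrival and are partly *mediators* of a LOS intervention
(shorter stays thin the census), so the fully adjusted specification can
sit slightly off the unadjusted contrast, the same pattern that makes
adjusted and raw estimates differ in real before/after cohorts. The
parameter-recovery suite therefore checks nominal 95% CI coverage of the
planted effect across 100 simulated studies and ~5% false-positive rate
across 100 null studies, at the default (unconfounded) generator.

## Problem sizes and numerical choices

The package's own test and acceptance runs use: the full default cohort
(~14,300 encounters, ~5,500 per contrast arm) for distillation and
recovery; 100 simulated studies per recovery arm; 10⁵ customers × 3
replications × 12 grid points for the queue validation; a 0.001 τ grid
plus exact breakpoints for the optimizer; 36 ED states × 45 strata with a
one-third state holdout, averaged over 3 seeds, for protocol agreement.
Zero-variance vitals standardise to 0 rather than NaN; empty strata fall
back to ESI-level mean scores; infeasible states (no stable split) label
everything main-ED and are logged, never silently dropped.

## Limitations

The agreement and recovery results certify internal consistency of the
pipeline under the generator's assumptions — a planted logistic truth,
exponential service abstractions, congestion without feedback — not
clinical performance. Real triage data would add label noise, complaint
ambiguity, drift and confounding that the defaults deliberately exclude.
The M/M/1 abstractions collapse multi-server, time-varying reality into
single aggregated servers re-solved per state; the state grid, not the
queue model, carries the time variation.
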