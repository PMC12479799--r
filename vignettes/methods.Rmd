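---
title: "Model and methods behind mditrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind mditrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mditrate)
```

`mditrate` implements a decision support engine for adults with type 1
diabetes on multiple daily injections (MDI): a real-time bolus
calculator, a weekly Bayesian titration algorithm for the basal dose and
the prandial parameters (carbohydrate ratios or fixed doses), the
continuous glucose monitoring (CGM) outcome metrics and biostatistics of
a parallel two-arm trial, and a seeded virtual-patient cohort with an
in-silico trial runner that exercises the whole pipeline. This vignette
explains the models, the defaults and why they are what they are, what
the synthetic data does and does not emulate, and the numerical choices
a maintainer would want to know about.

## The bolus calculator

The calculator mirrors standard MDI practice. For a meal `m` with `c`
grams of carbohydrate the recommended dose is

    food       = c / CR_m            (carb counting)  or  F_m (fixed dose)
    correction = (G_adj - G_target) / ISF
    dose       = max(0, food + max(0, correction - IOB) [corr > 0]
                        or food + correction            [corr <= 0])

rounded to the bolus pen increment with exact ties rounding *down*
(hypoglycemia-conservative; the tie direction is a design choice, as is
everything about rounding — pens cannot deliver fractions of their
increment). `G_adj` is the entered sensor glucose shifted by the trend
arrow (+2.8, +1.4, 0, −1.4, −2.8 mmol/L for the five arrows; these
offsets follow common clinical guidance and are configurable — deployed
calculators do not publish theirs). Insulin on board (IOB) decays
linearly over the active insulin time (default 4 h); an exponential
curve is available behind an argument. Two asymmetries are deliberate:

* IOB offsets only the *positive* part of a meal-time correction, never
  the food component — otherwise a recent bolus could erase the cover
  for food that is about to be eaten. A standalone correction is offset
  in full.
* A negative correction (glucose below target) *does* reduce the meal
  dose, but the total is floored at zero.

Override reasons (exercise, illness, and so on) are stored as
annotations and never enter any computation; a regression test pins
this. Adherence alerts follow two hard rules: three consecutive days
without a basal log, or three or fewer diary entries in the trailing
36 hours. Entries can be deleted within 30 minutes of creation.

## The glucoregulatory model

Both the virtual patient and the titrator's internal fitting model are
the same continuous-time compartmental model: a Bergman-style minimal
model with a two-compartment subcutaneous rapid-insulin chain and a
two-compartment gut chain,

    S1' = u(t) - S1/tau_I            (sc rapid insulin, mU)
    S2' = (S1 - S2)/tau_I
    I'  = S2/(tau_I V_I) - k_e I     (plasma insulin, mU/L)
    X'  = -p2 X + p2 S_I (I + k_b B) (remote insulin action, 1/min)
    Q1' = -Q1/tau_m + meal impulses  (gut glucose, mmol)
    Q2' = (Q1 - Q2)/tau_m
    G'  = -(S_G + X) G + S_G G_b + Q2/(tau_m V_G)

Rapid boluses are impulses into `S1` (1 U = 1000 mU); a meal of `g`
grams of type `m` is an impulse of `f_m * g * 1000/180.16` mmol into
`Q1` — the per-meal bioavailability is applied at ingestion, which for a
single gut chain is algebraically the same as scaling the absorption
flux and stays well defined when meal types mix. The once-daily
long-acting basal `B` (units/day) enters as a constant plasma
contribution `k_b B`, a steady-state approximation appropriate for
degludec and glargine, which dominate this population. The model has a
closed-form fasting equilibrium,

    G_ss = S_G G_b / (S_G + S_I k_b B),
    B(target) = S_G (G_b - target) / (S_I k_b target),

which `steady_state_basal()` exposes; it doubles as the analytic oracle
for basal titration in the test suite.

Defaults (population medians): `S_I = 8e-4` min⁻¹ per mU/L, `S_G = 0.01`
min⁻¹, `G_b = 17` mmol/L, `p2 = 0.02` min⁻¹, `tau_I = 55` min,
`k_e = 0.14` min⁻¹, `V_I = 9` L, `k_b = 0.7` (mU/L)/(U/day),
`tau_m = 40` min, `f = 0.8`, `V_G = 12` L. These sit in the ranges used
throughout the minimal-model literature for adults (volumes ≈ 0.12–0.16
L/kg at 75 kg; `S_I k_b` chosen so a typical patient needs ≈ 25 U/day of
basal to hold 6.5 mmol/L). `G_b`, the insulin-free equilibrium, is a
model construct, not an observable; 17 mmol/L makes untreated glucose
drift toward the high teens.

Integration is a fixed-step fourth-order Runge–Kutta written in C++
(1-min default step; the titration loops use 10–15 min). A fixed-step
scheme was chosen over an adaptive library solver because the titration
objective evaluates the week-long simulation hundreds of times inside an
optimizer and the trial runner must stop at every dosing decision; the
dynamics are smooth between impulses, and a step-halving test plus an
independent `deSolve::lsoda` comparison pin the accuracy (sup-norm
< 0.05 mmol/L between 1-min and 0.25-min steps). Glucose is floored at
0.1 mmol/L inside the stepper; non-finite states abort with a
diagnostic.

The sensor model produces historic records on the 15-minute grid of
intermittently scanned CGM plus scan records at decision times, with
AR(1) noise (marginal sd 0.4 mmol/L, lag-1 correlation 0.7 on the
15-minute grid), an optional additive bias below 5 mmol/L (first
generation flash sensors over-report hypoglycemia), and clamping to the
2.2–27.8 mmol/L reporting range.

## The weekly titration algorithm

`titrate_week()` composes five stages, each exposed separately:

1. **Fit** (`fit_patient_model`). Maximum a-posteriori estimation of
   φ = (`S_I`, `G_b`, `k_b`, `f_breakfast`, `f_lunch`, `f_dinner`) from
   one week of historic sensor records and the app diary. Only these six
   are fitted; the kinetic constants stay at population values —
   sparse flash-monitoring data cannot identify time constants, and
   fixing them is what makes the weekly fit stable. The likelihood is
   Gaussian on historic-record residuals (`sigma_cgm = 0.5` mmol/L,
   absorbing sensor noise and model misfit) with independent log-normal
   priors; optimization is L-BFGS-B on log φ from the prior median, and
   per-parameter posterior standard deviations come from the numerical
   Hessian at the MAP (Laplace approximation). Fixed-dose users enter no
   carbohydrate amounts, so diary meals are imputed at 45/60/70 g
   (breakfast/lunch/dinner) and the fitted bioavailability absorbs the
   scale error — only the product matters downstream. Weeks with under
   two days of sensor data or no logged bolus take the degraded-data
   path: the therapy is returned unchanged with the reason recorded.
2. **Optimal therapy** (`optimal_therapy`). The basal comes from the
   closed-form fasting solution at the MAP; each prandial parameter is a
   bounded one-dimensional search (2.5× around the current value)
   minimizing the weekly band cost
   `mean(4 max(0, 3.9 − G)² + max(0, G − 10)²)` while replaying the
   week's bolused meals interactively (the calculator re-doses each meal
   from the simulated glucose under the candidate parameters). The 4×
   hypoglycemia weight and the 3.9–10 band encode the usual clinical
   asymmetry. A tiny quadratic anchor (`1e-4 · log²(v/v_prev)`) breaks
   ties toward the current value when a week is so well controlled that
   the cost is flat — without it a golden-section search would wander.
3. **Blend** (`blend_therapy`). Per parameter, the recommendation is a
   log-scale mixture `log θ = w log θ* + (1−w) log θ_prev` with
   `w = max(0, R²) · clip(1 − (posterior sd / prior sd)², 0, 1)`. A week
   the model cannot explain, or one that leaves the posterior as wide as
   the prior, moves nothing. Physiology-to-therapy mapping is
   conservative: each therapy parameter inherits the *weakest* shrinkage
   among the physiology parameters that determine it (basal from
   `S_I`, `G_b`, `k_b`; meal `m` from `S_I` and `f_m`).
4. **Safety** (`safety_attenuate`). One-sided: if any postprandial
   window (meal to +4 h) that week contains a reading below 3.9 mmol/L
   or a nadir below 4.5 mmol/L, that meal's insulin may not increase; if
   overnight (23:00–07:00) readings dip below 3.9, the basal may not
   increase. Decreases always pass. "Trending low" is operationalized by
   the 4.5 nadir; the deployed rule is unpublished.
5. **Finalize** (`finalize_recommendation`). Movement is capped at ±20 %
   per week on the delivered-insulin scale (carb ratios are compared via
   1/CR so "20 % more insulin" means the same thing for both meal
   strategies), then doses round to the pen increments and ratios to
   0.1 g/U — to the nearest grid point, stepping back toward the
   previous value if rounding crossed the cap, and keeping an off-grid
   predecessor rather than jumping the cap. Any parameter whose
   cumulative change from the *reference* (baseline, or the last
   clinically approved value) exceeds 30 % flags the recommendation for
   review; flagged recommendations are held unless auto-approval is on
   (the in-silico stand-in for the study team), and an approved flagged
   recommendation advances the reference.

The posterior of week *t*, with standard deviations inflated by a
forgetting factor of 1.25 (and never wider than the initial population
prior, with a floor of 0.02 on the log scale), becomes the prior of week
*t+1*: information accumulates, but no week can lock the algorithm into
overconfidence. ISF and the glucose target are never titrated.

## The virtual cohort and in-silico trial

`generate_cohort()` draws physiology from log-normal populations
(`S_I` sdlog 0.35, `G_b` 0.28, `k_b` 0.25, `f` 0.15), computes each
participant's *oracle* therapy (closed-form basal for a 6.5 mmol/L
fasting target; prandial parameters from the same band-cost search on a
one-day replay), then mis-specifies it: every titratable parameter is
multiplied on the insulin scale by `exp(severity + N(0, 0.25))`, where
the participant-level severity is an offset of −0.41 minus an
exponential excess (scale 1.00, truncated at 2.0). The one-sided
severity shape is deliberate: a treated clinical population contains
many mildly lagging prescriptions and a thinning tail of severe ones,
and none that grossly over-dose. The prescribed ISF is coupled to the
same severity (a badly lagging prescription also has a too-weak
correction factor), which is what lets chronically hyperglycemic
participants persist despite using a bolus calculator daily.

Realism features that matter for calibration: unannounced snacks
(per-participant log-normal rate around 1/day, ~20 g, never bolused or
logged), carbohydrate under-counting by carb-counting users
(per-participant log-scale bias around −0.2, per-entry sd 0.25),
day-to-day subcutaneous absorption variability (log-normal, sd 0.25, on
the effective but not the logged dose), partial adherence (per-person
meal-bolus probability Beta(27, 3), basal-log probability Beta(22, 2),
evening correction checks ~0.4), and occasional dose overrides (3 % of
calculated doses, annotated with a reason).

Each candidate participant runs a 14-day burn-in under the mis-specified
therapy; mean historic glucose converts to estimated HbA1c via the
glucose management indicator `GMI(%) = 3.31 + 0.02392 · mean mg/dL` —
an in-silico surrogate throughout, never a claim about laboratory assay
values — and candidates below the 7.5 % inclusion threshold are
rejected and redrawn. With the defaults the reference cohort (n = 84,
seed 20271) realizes mean 8.68 % and SD 0.99 %. The severity scale and
offset are the calibration dials for that distribution; the correction
feedback loop makes the truncated mean remarkably insensitive to
uniform under-dosing, which is why severity heterogeneity, not a larger
bias, carries the spread.

Sensor-use stratum is assigned as an exact composition (76 % regular
users, shuffled) mirroring the reported cohort rather than independent
coin flips, and `permuted_block_randomize()` uses within-stratum
permuted blocks of 10 (regular) and 4 (new), balancing the final partial
block to within one assignment — so a cohort of 84 randomizes exactly
1:1.

`run_trial()` simulates every participant week by week (meals, snacks,
decisions, sensor noise — all from a per-participant stream derived from
the trial seed). Both arms use the calculator; experimental participants
additionally get the weekly recommendation, applied the following week
upon acknowledgement, with an 8 % chance of being declined. Control
parameters stay fixed (the real control arm saw sparse standard-care
edits whose magnitudes are unreported; the default leaves them out, and
a config switch documents the simplification). Weekly CGM metrics,
therapy trajectories and the recommendation ledger are recorded;
`summarize_trial()` reduces them to per-participant endpoints, the
baseline-adjusted treatment effect (an ANCOVA of change on arm plus
baseline — with one post-baseline measurement the usual mixed model
reduces to exactly this), and arm-level usage medians.

What the generator does *not* emulate: exercise, stress, alcohol and
illness effects (the app stores them as notes only), intra-day insulin
sensitivity rhythms, sensor warm-up and dropout, dropouts and site
effects, and control-arm self-adjustments. Two known quantitative gaps:
simulated standalone correction boluses (~0.0–0.1/day) fall short of the
reported ~0.56/day because the single evening correction check usually
collides with dinner insulin-on-board; and the titrator flags more
recommendations for review (~28 %) than the deployed system did (~10 %),
because the virtual cohort starts further from its oracle therapy.
Passing tests on this cohort therefore demonstrate the *algorithmic*
properties — convergence, caps, safety dominance, flag bookkeeping,
directional efficacy — not behavioral fidelity of real MDI users.

## Outcome metrics and statistics

`cgm_metrics()` computes percent time in the consensus bands (closed
"in-range" intervals 3.9–10 and 3.9–7.8; strict "below" 3.9/3.0 and
"above" 7.8/10/13.9/16.7 mmol/L), mean and SD, over historic records
only — scans duplicate the same sensor signal and would double-count —
for overall, daytime (07:00–23:00) and overnight (23:00–07:00) periods.
The statistical operations delegate to the standard implementations
(`power.t.test`, `fisher.test`, `prop.test` without continuity
correction, `shapiro.test`-gated `t.test`/`wilcox.test`, `lm`), with
Wald intervals on proportion differences; the test suite verifies the
Fisher path against brute-force hypergeometric enumeration and the
chi-squared path against the pooled two-proportion z². One published
p value (0.048 for a 52 % vs 31 % comparison) is not reproducible from
the rounded counts by either test (0.046 chi-squared, 0.077 Fisher); the
package reports its own exactly defined tests and does not chase it.

## Problem sizes and seeds

Full-scale runs (84 participants × 12 weeks, 504 weekly fits) use a
15-minute fit integration step and 12 quasi-Newton iterations per fit —
about five minutes on one core; single-week analyses default to finer
settings (10 min, 30 iterations). The acceptance suite runs one
full-scale trial, a 50-replicate parameter-recovery study, six small
seeded trials for the directional-efficacy property, and a
2000-replicate null calibration of the treatment-effect test. The
reference cohort seed (20271) is part of the study configuration;
everything else derives from user-supplied seeds, and fixed seeds
reproduce runs bit for bit.
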