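---
title: "Vergence formulas, constant optimization and stacked learning for postoperative refraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vergence formulas, constant optimization and stacked learning for postoperative refraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After cataract surgery the eye's refraction is set by the implanted
intraocular lens (IOL): its labelled power and, critically, where its
optical plane ends up sitting inside the eye — the effective lens position
(ELP). Classical power formulas predict the postoperative spherical
equivalent from preoperative biometry (axial length, corneal curvature,
anterior chamber depth, ...) through a thin-lens vergence model plus a
formula-specific ELP regression, calibrated per lens model by one or more
"constants". iolstack implements four such formulas (SRK/T, Holladay 1,
Hoffer Q, Haigis), the data-driven personalization of their constants, and
a stacked machine-learning layer that consumes a formula's prediction as
one of its features. Because real surgical cohorts are rarely shareable,
the package also ships a synthetic cohort generator with a known optical
ground truth, so every stage is testable end to end.

## The vergence chain

All four formulas share one optical core. With corneal power $K$ (diopters),
ELP $d$ (mm), optical axial length $L$ (mm), IOL power $P$ (diopters),
aqueous index $n = 1.336$ and vertex distance $V = 12$ mm:

$$
z_{ret} = \frac{1000n}{L - d},\quad
z_{in} = z_{ret} - P,\quad
f_{IOL} = \frac{1000n}{z_{in}},\quad
f_c = f_{IOL} + d,
$$
$$
V_c = \frac{1000n}{f_c},\quad
z = V_c - K,\quad
\mathrm{SE} = \frac{z}{1 + (V/1000)\, z}.
$$

The chain, not any closed form, is the normative definition here; the test
suite checks that for SRK/T it agrees to better than $10^{-8}$ D with a
single rational expression derived independently from the same algebra.
Two sign facts follow from the chain and matter for everything downstream:
predicted refraction falls as $P$ rises, and **rises** as $d$ rises — a
more posterior lens is effectively weaker, so deepening the assumed ELP
shifts every prediction hyperopically.

The formulas differ only in conventions, frozen as follows (in our
experience the single largest interoperability pitfall between published
implementations):

| formula | corneal power | optical axial length | ELP model | constant |
|---|---|---|---|---|
| SRK/T | $337.5/r$ | $L + 0.65696 - 0.02029\,L$ | corneal height + A-constant offset | A |
| Holladay 1 | $(1000/3)/r$ | $L + 0.2$ | anatomic ACD + surgeon factor | SF |
| Hoffer Q | $337.5/r$ | $L$ | tangent model, +0.05 mm in chain | pACD |
| Haigis | $331.5/r$ | $L$ | $a_0 + a_1\,\mathrm{ACD} + a_2\,L$ | $a_0,a_1,a_2$ |

Numerical guards: the corneal-height square roots are clamped at zero
(steep corneas), Hoffer Q's axial length is clamped to [18.5, 31] mm with
the short-eye branch taken at exactly 23 mm, and the SRK/T long-eye branch
switches at 24.2 mm (the residual branch discontinuity is about 0.01 mm
for average corneas and is tested, not hidden). The chain raises explicit
errors for $d \ge L$ and for vergence singularities rather than returning
garbage.

The inverse solver (`solve_iol_power()`) is the exact algebraic inverse of
the chain; predict-after-solve round trips to $10^{-9}$ D, which the suite
asserts for all four formulas.

## Constant optimization

Scalar constants (A, SF, pACD) are personalized by zeroing the mean signed
prediction error (predicted minus observed) on a training cohort. Because
the mean error is strictly increasing in any ELP-type constant (see the
sign fact above), a bracketing root method applies; brackets default to
A in (113, 125), SF in (-2, 5), pACD in (2, 9) and auto-expand by up to
±10 units. Candidate constants are evaluated with the ELP clamped into
[0.5, $L$-2] mm so that bracket expansion can probe extreme values without
leaving the chain's domain; no clamping is active near any realistic
optimum. Whether one should zero the mean error or minimize the MAE is a
genuine free choice; zero mean error is the standard personalization
convention and the default, with `criterion = "mae"` available.

The Haigis triple is fitted the way it was designed to be: each training
eye's ELP is back-solved from its observed refraction (the chain reduces
to a quadratic in $d$; the root in $(0, L)$ is taken, anterior preferred,
matching the physiologic 2–8 mm range), then $d$ is regressed on
$(1, \mathrm{ACD}, L)$ by ordinary least squares. Eyes with no physical
root — e.g. zero-power lenses, whose refraction carries no ELP
information — are dropped with a reported count; a failure rate above 10%
escalates to an error under strict mode. Constants are optimized per lens
model, with a pooled fallback for lens models below a minimum eye count
(default 30).

## The synthetic cohort

The generator emulates a large single-center cataract population:
truncated multivariate normal biometry with marginals
AL 24.02 ± 1.57 mm, mean corneal radius 7.63 ± 0.27 mm,
ACD 3.10 ± 0.41 mm, lens thickness 4.57 ± 0.43 mm, WTW 11.74 ± 0.41 mm.
Joint structure is stipulated, not estimated (no joint information is
available to emulate): corr(AL, ACD) = 0.4, corr(ACD, LT) = −0.4,
corr(AL, WTW) = 0.3, others zero — physiologically plausible signs, fully
configurable. Age (N(72, 9), truncated [40, 95] years) is generated but
carries no outcome signal; it exists as a feature-selection decoy.

The outcome model: true ELP $d^* = a_0 + a_1\mathrm{ACD} + a_2 L$ with
$(a_0, a_1, a_2) = (-1.72, 0.277, 0.260)$ plus a per-lens-model shift
(three synthetic lens labels at 0/+0.15/−0.15 mm) and N(0, 0.1 mm) noise;
the implanted power targets a truncated-normal surgeon target
(N(−0.3, 0.3) D on [−3.5, 0.5]) under Haigis vergence conventions, rounded
to 0.5 D steps; the observed refraction is the chain refraction at the
rounded power plus N(0, 0.25 D) measurement noise. Under these settings
the mean implanted power comes out near 19.6 D, matching the biometry
marginals' provenance. The Haigis-style truth deliberately mis-specifies
SRK/T's corneal-height ELP, so a learner stacked on the SRK/T prediction
has genuine headroom over it — the configuration `truth_formula = "srkt"`
instead makes SRK/T exactly correct at a known A constant, which is how
A-recovery is tested. Defaults of 2159 patients with bilateral fraction
0.706 reproduce a ~2830-eye training set after 500 test patients are
split off.

Bilaterality: both eyes of a patient share a patient-level latent biometry
component (between-eye correlation 0.7). The train/test split is
patient-wise: one eye per test patient, the fellow eye discarded
entirely, so no patient leaks across the split.

What the generator does **not** emulate: keratoconus, post-refractive
corneas, macular pathology, measurement-device failure modes, non-Gaussian
biometry tails, or correlated measurement errors. Passing tests on this
population therefore demonstrate internal correctness of the optics,
optimization and learning machinery — not clinical accuracy on real eyes.
In particular, the absolute MAE levels reported on synthetic data depend
on the stipulated noise levels and are not comparable to clinical MAEs.

## The stacked predictor

Candidate explanatory variables: age, axial length, corneal radius, ACD,
lens thickness, WTW, the base formula's optimized constant (per lens
model), IOL power, and the base formula's predicted refraction. The
outcome is the observed postoperative spherical equivalent, unscaled;
features are standardized to training mean 0 and sd 1 using the
population-sd convention (divide by $n$; a configurable, documented
choice — at these sample sizes the distinction is cosmetic).

The base formula is chosen by fitting a gradient-boosted regressor
(xgboost, exact greedy, single-threaded) on the biometric candidates plus
all four formula predictions and taking the formula with the largest gain
importance; ties break deterministically to the earlier of (srkt,
holladay1, hofferq, haigis). The feature subset is then chosen by
exhaustive search over all $2^9 - 1 = 511$ candidate subsets under 5-fold
cross-validated MAE with a shared fold assignment — exhaustive rather than
greedy because it is cheap with a fast selector, deterministic, and free
of path dependence. Per-subset MAE standard errors are reported so a
one-standard-error reading is possible; the winner (minimum MAE, ties to
fewer features) is reused unchanged by all four model kinds.

Model kinds and default grids (tuned by 5-fold CV MAE, exhaustive grid):

* **svr** — radial-basis support vector regression (e1071);
  cost {0.1, 1, 10, 100} x epsilon {0.01, 0.1} x gamma {0.01, 0.1, 1}.
* **rfr** — random forest (ranger, fixed seed, single-threaded);
  trees {100, 300} x max depth {unbounded, 4, 8}.
* **gbr** — gradient boosting (xgboost); eta {0.01, 0.1} x rounds
  {100, 500} x depth {2, 3, 4}.
* **nn** — an ensemble of 30 single-hidden-layer networks (nnet: 8
  hidden units, linear output, squared-error loss, weight decay 0.01,
  BFGS capped at 200 iterations) differing only in their
  weight-initialization seed; the prediction is the members' arithmetic
  mean. Averaging over restarts removes initialization jitter — the
  across-seed spread of the 30-member mean is measured in the acceptance
  battery at roughly $1/\sqrt{30}$ of a single network's. A deeper
  architecture was considered and rejected: with at most nine tabular
  features a single modest hidden layer is adequate, no installed R stack
  provides multi-layer perceptrons, and nnet's BFGS optimizer is exactly
  reproducible. nnet has no epoch-level early stopping; weight decay plus
  the iteration cap serves as the regularizer.

All fitting is deterministic given (data, grid, seeds): single-threaded
tree learners, exact xgboost splits, seeded forests, seeded NN members
with per-base-seed disjoint seed blocks.

## Evaluation battery

Errors are predicted minus observed, in diopters (the sign convention used
consistently by the offset correction and all reports). Summaries: MAE,
median AE, sd of signed error, and counts within 0.25/0.5/1.0 D under a
strict inequality (an error of exactly 0.5 D is not "less than 0.5 D").

Paired comparisons across methods: Friedman test on the absolute errors
(the completely tied case is reported as statistic 0, p 1 — the limit of
the untied statistic, which R's tie correction otherwise renders 0/0);
each method versus a designated reference by Wilcoxon signed-rank when
Shapiro–Wilk rejects normality at 0.05 in either group's absolute errors
(a per-comparison gate; gating on the paired differences is available as
a flag, since the granularity of such gates is a genuine convention
choice), else the paired t test; Bonferroni adjustment multiplies by the
number of pairwise comparisons actually performed and caps at 1. Pairwise
results are always reported but flagged when the Friedman test is not
significant. Proportions within 0.5 D are compared by Pearson chi-squared
on the 2x2 table **without** continuity correction — the only convention
that reproduces all three worked comparisons in the test suite to four
decimal places. Axial-length subgroups use left-closed bins at 22 and
24 mm (short < 22 ≤ middle < 24 ≤ long).

Mean-offset correction (for externally supplied predictions whose internal
constant cannot be optimized, e.g. from a web calculator): subtract the
training-set mean error from the test predictions; the corrected training
predictions then have exactly zero mean error, which is asserted.

## Seeds and determinism

Every stochastic step takes an explicit integer seed, and identical seeds
give bit-identical results. One numerical subtlety is handled centrally:
R initializes the Mersenne–Twister state by iterating the map
$s \mapsto 69069\,s + 1$, so seed pairs related by that map (0 and 1 being
the everyday case) yield shifted copies of the same state, and `sample()`
then produces nearly identical permutations — enough to make a cohort
generated at seed 0 and a patient split at seed 1 overlap far beyond
chance. All internal `set.seed()` calls therefore pass through a few
Lehmer-LCG scrambling steps (exact in double precision), which places
related user seeds on unrelated generator states without affecting
reproducibility.

## Problem sizes used by the checks

The test suite exercises the optics and statistics at small sizes
(tens to hundreds of eyes) and the end-to-end claims at study scale:
constant recovery on cohorts of ~2000 and ~2830 eyes over three seeds, and
the stacked-learner comparison at ~2830 training eyes / 500 test eyes over
three seeds with reduced hyperparameter grids (the grids are a tuning
knob, not part of the claim; the full defaults are used by
`run_pipeline()`). The acceptance script runs the full default pipeline —
simulation, split, constant optimization, base-formula and subset
selection, all four learners, evaluation — once at the given seed.

## Known limitations

* Lens-constant chains other than the four implemented (e.g. proprietary
  formulas) can only enter through the external-prediction path with mean
  offset correction.
* The generator's correlation structure and noise levels are stipulated;
  parameter-recovery tolerances are calibrated to those settings.
* Toric lenses, post-refractive-surgery corneas and axial-length
  modification rules are out of scope.
* The Wilcoxon/t normality gate uses a deterministic subsample above
  Shapiro–Wilk's n = 5000 limit.
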