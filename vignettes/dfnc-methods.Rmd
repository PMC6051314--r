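---
title: "Dynamic connectivity states: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dfncstates` implements a complete dynamic functional network connectivity
(dFNC) analysis for component time courses extracted from resting-state
fMRI (e.g. by group ICA, which is outside the package's scope): band-pass
filtering, tapered sliding-window connectivity, k-means decomposition into
recurring connectivity states, per-state mass-univariate group statistics
with FDR control, and state-aware classification with a least-squares
linear SVM (LS-SVM) under nested leave-one-out cross-validation (LOOCV).
This vignette explains the underlying models, the tunable parameters, the
synthetic cohort used for validation, and the numerical and design
decisions a careful user should know about.

## The analysis model

**Inputs.** Per subject, a `T x R` matrix of component time courses
(default study geometry: `T = 145` timepoints at TR = 2 s, `R = 48`
components) and a phenotype table (group HC/mTBI, sex, age, education,
WTAR).

**Preprocessing.** Each column is band-pass filtered with a fifth-order
Butterworth design, passband 0.01-0.15 Hz. We apply the filter forward and
backward (zero phase), after demeaning each column and extending the series
odd-symmetrically by `pad_len` samples (default three filter lengths, 33
samples) at both ends. The published description of this step names only
the filter family, order and band; single-pass versus zero-phase, padding,
and demeaning are implementation choices, so all of them are explicit,
documented arguments of `filter_spec()`. We chose zero phase because
phase-shifting the time courses by a state-dependent amount would smear
state boundaries; demeaning is exact DC removal and avoids slow edge
transients that the filter's finite stopband attenuation would otherwise
leave on 145-sample series.

**Windowed connectivity.** The window taper is a rectangle of 15 TRs (30 s)
convolved with a Gaussian of sigma = 3 TRs truncated at 3 sigma, normalized
to unit mass. Note that the taper's full support is `15 + 2*ceiling(3*3) =
33` TRs: the nominal "window size 15" names the rectangle, while the number
of windows is `W = T - 33 + 1 = 113` at stride 1. This matters when
comparing window counts across implementations, so `taper_spec()` documents
it prominently. Within each window we compute weighted Pearson correlations
(weighted means and covariances with the taper weights) for all
`P = R(R-1)/2 = 1128` component pairs, vectorized in a fixed order (upper
triangle, row-major, i &lt; j). Columns with zero weighted variance produce
a correlation of 0 with a warning, keeping downstream matrices finite. No
Fisher z-transform and no regularized covariance are applied: plain
correlation is the estimator throughout, matching the analysis this package
reimplements; both are easy to add upstream of clustering if desired.

**States.** All subjects' windowed vectors (96 x 113 = 10,848 windows) are
clustered with k-means (squared Euclidean distance, k-means++
initialization, 10 restarts, empty clusters re-seeded from the farthest
point). The number of states is chosen by an elbow criterion on a cluster
validity index — the ratio of mean within-cluster point-to-centroid
distance to mean between-centroid distance — computed for k = 2..9. The
original analysis invokes "elbow criteria" without a formula, and its exact
validity index is not published; ours is a documented stand-in with the
same monotone behaviour (lower is better). The elbow is formalized as the
k with the largest discrete second difference of the curve (greatest
curvature), ties to the smallest k. Second differences are undefined at the
range ends, so one guard is added: if the curve never descends — its
minimum is already at the smallest k — that k is returned (this is what
"two well-separated clusters" produce over a 2..9 scan: the curve rises
after k = 2). A flat or monotone-linear curve returns the smallest k with a
warning. `k` can also be pinned in the run configuration to reproduce a
fixed-k analysis; the pipeline records `"k: pinned"` in its state summary.

Each subject's *representative state matrix* is the mean of their windowed
vectors assigned to that state; subjects with no window in a state are
absent from that state's roster, so per-state sample sizes vary.

**Group statistics.** Within each state, each of the 1128 pairs gets a
pooled-variance two-sample t-test (sign convention: patient minus control)
over the state's roster, and Benjamini-Hochberg FDR is applied within that
state's family of 1128 tests (not pooled across states). Pooled rather than
Welch variance was chosen because recomputing the published demographic
table from its printed summaries matches the pooled form at two decimals
for the verifiable rows. Demographic sex splits use Fisher's exact test
with the point-probability two-sided convention (the `stats::fisher.test`
convention; conventions differ across software, so this is documented).
FDR-significant pairs are additionally regressed (OLS, intercept included)
on sex, age, education and WTAR, with per-coefficient t-tests; whether the
original covariate regression included an intercept is unstated, and we
include one because a no-intercept regression of a correlation-scale
response is not meaningful.

**Classification.** The classifier is a least-squares linear SVM: squared
slack variables and equality constraints turn training into one linear
system in (bias, dual coefficients), with regularization `C = 0.1` (the
soft-margin constant of the published analysis; in the LS-SVM literature
this constant is usually called gamma). It is equivalent to ridge
regression on +/-1 labels with an unpenalized intercept and penalty `1/C`;
this equivalence is the test oracle. The per-point penalty convention means
duplicating every training point is equivalent to doubling `C`.

Two cross-validation designs are provided:

- `per_state_loocv_auc()`: LOOCV within each state's roster using all 1128
  features; AUC is computed on the pooled held-out decision values (with a
  single test point per fold, per-fold AUC does not exist). AUC is the
  rank-based Mann-Whitney form with ties counted one half.
- `nested_loocv()`: the outer loop leaves one subject out; candidates are
  all (state, t-threshold) combinations for states the left-out subject
  visited (4 states x 6 thresholds = 24 when all are visited; thresholds
  0, 0.25, 0.5, 0.75, 1, 2). Each candidate is scored by an inner LOOCV
  over the outer-training roster, where features are the pairs whose
  group-difference |t| on the *inner* training subset exceeds the
  threshold. The best candidate (ties: larger threshold — fewer features —
  then lower state index) is refit on the outer-training roster and scores
  the left-out subject. The published wording ("t-values previously
  obtained") is ambiguous about whether selection t-values are recomputed
  inside the inner loop; we default to the strict no-leakage reading and
  expose `t_mode = "outer"` for sensitivity analysis. A subject visiting no
  state cannot be classified and is excluded with a warning.

The static-FNC baseline applies the same nested machinery to full-series
correlations with a single "state" containing everyone, so selection is
over thresholds only. The two classifiers are compared by resampling each
report's pooled held-out (score, label) pairs 10,000 times (subjects drawn
with replacement, stratified by class), computing an AUC per resample, and
applying a pooled two-sample t-test between the two bootstrap AUC samples
(df = 2B - 2 = 19,998). What exactly the original bootstrap resampled is
unstated; stratified subject resampling of pooled LOOCV scores is our
documented choice, and the resulting t statistic should be read as a
descriptive effect-size-like quantity (bootstrap replicates are not
independent samples).

## The synthetic cohort

Real cohort data for this analysis are not publicly deposited, so the
package ships a generator that emulates the study conditions end to end
and makes every stage testable against ground truth.

Each subject's latent state sequence is a first-order Markov chain over
K = 4 states with per-state self-transition probability
`1 - 1/dwell_mean[state]` (defaults 40, 50, 75, 75 timepoints — every
dwell comfortably exceeds the 33-sample window support so windows are
mostly state-pure, and reported state dwelling in this method family is
long, with some subjects spending most of a scan in one state). Given the
state, rows are independent draws from a zero-mean multivariate normal
with that state's correlation matrix (white emission; an optional
moving-average smoothing of the innovations exists but is off by default,
because within-state temporal autocorrelation of ICA time courses is not
characterized in the source analysis and white noise is the assumption
under which the windowed estimator is unbiased).

State correlation matrices combine two levels of structure, mirroring how
empirical dFNC centroids look (a shared modular backbone plus broad
state-specific patterns):

- a *block backbone*: the 48 components are split into 8 "network" blocks
  of 6; every state elevates one distinct block pair (within-block 0.50,
  between 0.35, background within-block 0.10 elsewhere), and the effect
  state gets one extra mildly coupled cross-network site (level 0.10)
  where the group effect lives;
- a *dense state signature*: each state adds a rank-one component with a
  fixed per-state sign pattern (`state_factor_var`, renormalized to unit
  diagonal, identical in both groups), which spreads a
  state-specific +/-0.2-scale pattern over all pairs.

The signatures place the states roughly 10 apart in connectivity-vector
norm — beyond the radius of the windowed-estimation noise — so window
assignment and model selection are limited by the injected group effect,
not by state confusability. The dominant state's signature is
deliberately somewhat stronger (variance 0.375 versus 0.25): perfectly
regular state geometries leave coarse clusterings degenerate (at k = 2, a
2+2 and a 3+1 grouping of four equidistant states have identical
within-cluster cost but different between-centroid spreads), which makes
the low-k end of the validity curve unstable from cohort to cohort; a
mild anisotropy makes every coarse clustering unique and the curve's
single bend at the true K reproducible.

Non-uniform state *visit sparsity* (defaults 0, 0.03, 0.40, 0.35)
reproduces the reported roster pattern in which nearly all subjects visit
the two high-occupancy states while only about half enter each of the two
sparse states, and the longer dwells of the sparse states keep the
*population occupancy* of the four states roughly balanced (about
0.26/0.31/0.21/0.22) — k-means merge costs are occupancy-weighted, so
heavily skewed occupancies would distort the validity curve's descent.

The patient-group effect lives in state 2 only and has two parts, echoing
the reported finding of a few strong cerebellum-sensorimotor increases
embedded in a broad sub-threshold trend toward most cortical areas:

- a focal increment `effect_delta = 0.3` on 4 designated cross-block pairs
  (these are what the per-state FDR analysis should recover), and
- a diffuse rank-one "shared signal" with strength `trend_delta =
  effect_delta/4`, loading 1 on the trend block and 1/2 elsewhere, raising
  trend-block-to-elsewhere correlations by about 0.075 and the remaining
  pairs by half that. Individually these shifts sit below the FDR
  threshold at the study's sample size, but jointly they are what gives a
  multivariate classifier its advantage in the effect state — without the
  diffuse part, an all-features LS-SVM at T = 145 and n = 48 + 48 has an
  AUC ceiling near 0.67, because the estimation noise of 1124 null feature
  means swamps four informative features. A flat broad increment is not an
  option: adding a constant to a block-versus-rest set of entries is a
  rank-two perturbation with minimum eigenvalue `-delta * sqrt(|A||B|)`,
  which destroys positive definiteness long before delta reaches a useful
  size; the rank-one factor is positive semidefinite by construction.

All matrices are checked for symmetry, unit diagonal and positive
definiteness; a nearest-PD repair (eigenvalue floor) is applied only if
needed, and fails loudly if it moves any requested entry by more than 0.01.
Phenotypes are drawn independently of the time series, with a WTAR group
gap of about 5 points and matched age/education/sex distributions.

The generator intentionally omits: hemodynamics, scanner noise, motion,
spatial maps, ICA estimation, and temporal autocorrelation. Consequently,
passing recovery tests shows the *pipeline* is correct under its own
assumptions; it does not show that real fMRI satisfies those assumptions.

## Validation and problem sizes

The test suite validates each estimator against an independent oracle
(weighted correlation vs. textbook Pearson at equal weights; BH-FDR vs. a
literal step-up loop; AUC vs. Mann-Whitney and trapezoidal integration;
LS-SVM dual vs. closed-form primal ridge; Fisher vs. hypergeometric
enumeration; k-means vs. `stats::kmeans` on separated blobs) and runs the
full pipeline on a 96-subject, 48-component, 145-timepoint cohort — the
study geometry — checking elbow selection of K = 4, window-label recovery
above 0.9 after permutation matching, localization of FDR discoveries to
the effect state with all injected pairs recovered, a per-state AUC margin
of at least 0.15 in favour of the effect state, modal selection of the
effect state by nested LOOCV, and chance-level behaviour plus ~0 FDR
discoveries on a null cohort. Simulation-heavy unit tests use smaller
geometries (8-16 subjects, 10-12 components, 3-4 states) chosen so the
whole suite exercises every code path at a few minutes' cost; single-state
law-of-large-numbers checks use long series (10,000-50,000 timepoints)
instead of many subjects.

## Numerical notes and limitations

- Correlations are clipped to [-1, 1] only to absorb floating-point
  overshoot (tolerance 1e-10); a larger overshoot is an error, never
  silently clipped.
- k-means is deterministic given a seed; different BLAS builds can in
  principle change which of several near-tied restarts wins, but the
  restart winner is chosen by within-cluster sum of squares, which is
  stable for separated data.
- The elbow rule cannot select the largest k of the scanned range (no
  curvature is defined there); scan one k beyond the range of interest.
- Inner-loop feature selection recomputes t-values in O(P) per fold via
  sum downdates, and kernels for the six nested feature sets are built
  incrementally from the largest threshold down, so the nested LOOCV on
  the full cohort runs in about a minute.
- With LOOCV and strong regularization, a held-out subject's score
  contains a small class-imbalance bias (the training set has one fewer
  member of the subject's class); pooled-score AUC is still valid because
  the bias is the same for every fold of the same class, but per-state
  AUCs at chance level can drift slightly below 0.5.
- Bootstrap comparison t-statistics are descriptive: resamples are not
  independent, so the nominal df overstates the information content.
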