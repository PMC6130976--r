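---
title: "Predicting output-null neural activity under a BCI readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting output-null neural activity under a BCI readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcinull)
```

## The problem

A linear brain-computer-interface (BCI) readout maps a low-dimensional
summary of motor-cortical population activity to a 2-D cursor velocity.
Because the readout matrix `B` (2 x k) has a (k-2)-dimensional null space,
many population activity patterns are *behaviorally redundant*: they produce
identical cursor movements. This package asks, and answers on simulated
sessions with known ground truth, the question of **which redundant pattern
the subject actually produces** — the distribution of *output-null* activity
given the *output-potent* activity.

The analysis chain is:

1. **Intrinsic manifold.** A factor-analysis (FA) model
   $u_t \sim \mathcal N(Lz_t + d, \Psi)$, $\Psi$ diagonal, is fit by EM to
   spike counts in non-overlapping 45 ms bins. Factor activity is the
   posterior mean $z_t = L^\top(LL^\top+\Psi)^{-1}(u_t-d)$, orthonormalized
   through the SVD $L = USV^\top$ as $\tilde z_t = SV^\top z_t$ so that it
   carries spike-count units ($Lz_t = U\tilde z_t$). The package fixes the
   SVD sign freedom (first nonzero entry of each basis column positive);
   every reported quantity is invariant to this choice.
2. **Readout and decomposition.** The cursor follows
   $v_t = Av_{t-1} + B\tilde z_t + c$. The SVD of `B` yields orthonormal
   bases `R` (k x 2, row space) and `N` (k x (k-2), null space);
   $z^r_t = R^\top \tilde z_t$ drives the cursor, $z^n_t = N^\top \tilde z_t$
   is invisible to it. A second readout is created mid-session by permuting
   the factor indices of `B` (a *within-manifold* perturbation).
3. **Trial selection.** Only the stable, learned block of second-mapping
   trials is analyzed: acquisition times are boxcar-smoothed over correct
   trials (100-trial centered window), normalized so 1 is the worst smoothed
   value in the first 50 perturbed trials and 0 the best afterwards, and
   thresholded at 0.5 together with the similarly normalized running
   variance; passing runs separated by at most 10 trials are joined and the
   longest run of at least 100 trials is kept. Analyzed time steps come from
   successful trials, after the 300 ms cursor freeze, with the cursor 50 to
   125 mm from the origin (half-open band).
4. **Six predictors of output-null activity**, each constrained to be
   *physiologically plausible* — the implied unit activity
   $\hat u = U\tilde z + d$ must lie between 0 and each unit's maximum count
   observed under the first mapping (rejection sampling, at most 100
   attempts, then the step is skipped):
   * **Minimal Firing** — the count vector of smallest norm producing the
     observed velocity, via a box-constrained quadratic program, then
     Poisson spiking noise.
   * **Minimal Deviation** — factor activity closest to a baseline pattern
     $\eta$ (the direction-binned average of first-mapping output-null
     activity mapped back through `N`); the noiseless prediction is the
     constant $N^\top\eta$.
   * **Uncontrolled-uniform** — independent uniform draws within the
     per-dimension range of first-mapping activity.
   * **Uncontrolled-empirical** — resampling the first-mapping activity's
     null-space projections.
   * **Persistent Strategy** — resampling restricted to first-mapping steps
     whose cursor-target angle lies within 22.5 degrees of the current one.
   * **Fixed Distribution** — the null component of the first-mapping
     pattern whose potent component (under the *second* mapping) is nearest
     the currently observed potent activity (K = 1 nearest neighbour;
     K > 1 samples among the K nearest).
5. **Scoring.** Evaluation steps are grouped into eight 45-degree wedges of
   cursor-movement direction (half-open, so 22.5 degrees falls in the
   45-degree bin). Per (direction, dimension) cell the *histogram error* is
   half the total-variation distance between normalized histograms on shared
   zero-anchored edges, averaged over cells and scaled to percent; per
   direction the *mean error* is the Euclidean distance between mean vectors
   (also reported in spikes/s by dividing by the 0.045 s bin) and the
   *covariance error* is the affine-invariant Förstner metric
   $\sqrt{\sum_i \log^2 \lambda_i}$ over generalized eigenvalues. A
   split-half *error floor* (100 random halvings) estimates the smallest
   error finite sampling allows.
6. **Potency-switching variance.** For dimensions that were potent under
   mapping 1 but null under mapping 2 (orthonormal basis of
   $(NN^\top)R_1$), the log ratio of projected variances between the two
   mappings, per direction bin (both mappings binned through the second
   readout via $v = Bz + c$), distinguishes the accounts: minimal-firing
   predictions collapse that variance, uncontrolled predictions inflate it,
   and a fixed activity repertoire leaves it nearly unchanged.

## The simulator: what the ground truth means

Since the analyses require closed-loop two-mapping sessions,
`simulate_session()` generates them with a configurable ground truth:

* **Units and manifold.** 90 units driven by a 10-D latent manifold with a
  geometrically decaying strength spectrum (amplitude ratio ~4.6 from first
  to last factor — dominant co-modulation patterns, as in motor cortex).
  Baselines are drawn per unit and grow with the unit's modulation depth,
  keeping linear rates away from zero; rates are clipped at zero and counts
  are Poisson (the clipped fraction is reported and is below ~1% at the
  defaults).
* **Repertoire.** The subject owns a fixed library of 4000 cosine-tuned
  patterns parameterized by intended movement direction, with isotropic
  scatter. The decoder mapping 1 is calibrated by regressing intended
  calibration velocities on decoded factors, so "natural" activity moves the
  cursor where the subject intends.
* **Closed loop.** At each 45 ms step the subject aims at the target,
  compensates the posterior shrinkage of the decode chain (it has learned
  the whole loop, so intended velocities are achieved in expectation), and
  produces a factor pattern whose potent component meets the requirement
  *within the repertoire's potent support* — requirements are clamped to the
  97.5% Mahalanobis ellipse of the library's potent projections, so
  movements along poorly afforded readout directions are slower rather than
  extrapolated, just as a real subject cannot exceed its repertoire. The
  emitted Poisson counts are decoded to drive the cursor, so the recorded
  velocity is exactly the readout of the recorded factor trajectory
  (non-frozen bins; the task clamps $v=0$ during the 300 ms freeze, which
  the 45 ms bins realize as 7 whole bins).
* **Worlds.** The null component follows one of three rules, identical
  under both mappings:
  `coupled` — the null component of the library pattern nearest the required
  potent value, plus null-space noise (at zero noise this is a deterministic
  function of the potent requirement); `independent` — per-dimension
  Gaussians matched to the library's null marginals, ignoring the potent
  requirement; `minimal` — the counts solve the minimum-norm program for the
  required velocity and are emitted directly as Poisson rates.
* **Learning.** The second mapping is a permutation of the first, screened
  (as such experiments screen their perturbations) to be *learnable but
  substantial*: among 200 candidate permutations, those whose
  worst-direction achievable speed clears 40% of the intended speed are
  kept, and the one rotating the repertoire's decoded directions most is
  used. Learning itself is modeled as instantaneous re-aiming plus
  exploratory aiming noise decaying from 75 to 8 degrees across a 100-trial
  burn-in. This produces slow, wandering, mostly successful early trials —
  the monkey-like gradual acquisition-time decline the stable-block rules
  are built around. (A fully wrong believed readout instead yields
  mostly-failed early trials whose rare successes are lucky-fast, inverting
  the smoothed acquisition series.) The burn-in is a modeling stand-in, not
  a claim about biological learning.

**What passing tests on this generator do and do not show.** The generator
reproduces the *structure* of the experiments — two mappings, learning
curve, trial selection, physiological ranges, Poisson discreteness, and a
controllable coupling between null and potent activity — so recovering the
correct hypothesis ranking per world validates the full analysis chain. It
does not emulate spike-history effects, unit drift, imperfect internal
models (the simulated subject knows its mapping exactly after burn-in), or
FA model mismatch (emission uses the fitted manifold), so the tests say
nothing about robustness to those features of real recordings.

## Numerical choices

* FA EM runs on the sample covariance to a relative log-likelihood change
  below 1e-8 (at most 5000 iterations), PCA-initialized with a small seeded
  jitter; noise variances are floored at 1e-6.
* The Minimal Firing program (minimize $\|u\|_2^2$ subject to two velocity
  equality constraints and $0 \le u \le u_{max}$) is solved through its 2-D
  concave dual (BFGS) followed by an exact KKT polish on the free set;
  solutions match a stock active-set QP solver to ~1e-10 and a grid-search
  oracle on toy problems. Velocity feasibility tolerance is 1e-6; an
  infeasible step (required velocity unreachable inside the box) is
  skipped. An $\ell_1$ objective is available through a stock LP solver.
* The histogram bin width minimizes the unbiased leave-one-out
  cross-validation risk over a 30-point geometric grid spanning a factor of
  16 around the normal-reference width $3.49\,\sigma n^{-1/3}$; the grid is
  built from the sample scale, making the selection scale-equivariant. One
  width per session; edges anchored at zero.
* The covariance metric adds a relative ridge (1e-8 of the mean diagonal)
  only when the plain Cholesky/eigen decomposition fails, so affine
  invariance is exact on well-conditioned inputs. The square-root (metric)
  form is the default; the squared form is a monotone transform and cannot
  change hypothesis rankings, so either convention yields the same
  conclusions.
* Direction bins and the Persistent Strategy wedge use half-open intervals;
  zero-velocity steps are flagged and excluded from binning. Ties in the
  nearest-neighbour scan break toward the lowest candidate index.
* Candidate pools ("source" activity) are all time steps recorded under
  proficient control of the source mapping — every first-mapping step, and
  stable-block steps when the second mapping is the source (reverse
  direction); the evaluation side always carries the full analysis filters.
* Split-half floors are computed from half-sized samples and therefore
  slightly overestimate the floor of a full-sample predictor; comparisons
  against the floor are one-sided (error no more than floor + 2 sd).

## Problem sizes

The packaged checks run single sessions at the defaults (300 + 500 trials,
roughly 4,000-10,000 analyzed second-mapping steps and ~13,000 candidate
steps), 100 split-half repetitions for floors, and five seeds for the
variance-ratio comparison; factor-model recovery uses 10,000 samples of a
30-unit, 5-factor model. These sizes make every stochastic check stable
under its seed while keeping a full run in minutes on one CPU.

## Limitations

* The simulated subject's internal model equals the true mapping after
  burn-in; analyses of internal-model mismatch are out of scope.
* The repertoire is stationary within a session; slow drift, fatigue, and
  session-to-session changes are not modeled.
* The minimal world emits exactly the program optimum plus Poisson noise;
  graded effort costs or signal-dependent noise are not modeled.
* Reported spikes/s conversions assume the 45 ms bin exactly.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(world = "coupled", seed = 1)
res <- run_pipeline(cfg)
res$report$summary
res$report$floors
unique(res$variance[, c("group", "average")])
autoplot(res$report)
```
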