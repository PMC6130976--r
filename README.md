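# bcinull

Tools for studying **neural redundancy** under a linear brain-computer-
interface (BCI) readout: when many population activity patterns produce the
same cursor movement, which redundant pattern does the subject actually
produce?

The package is aimed at computational neuroscientists analyzing (or
simulating) closed-loop BCI experiments in which a subject controls a cursor
through a velocity readout of motor-cortical population activity and the
readout is abruptly perturbed mid-session.

## The model

Spike counts `u_t` (q units, 45 ms bins) are summarized by a factor-analysis
model of the intrinsic manifold,

    u_t ~ N(L z_t + d, Psi),    z_t = L'(LL' + Psi)^{-1}(u_t - d),

with factors orthonormalized through `L = U S V'` so that `z~_t = S V' z_t`
has spike-count units. A Kalman-style readout

    v_t = A v_{t-1} + B z~_t + c

drives the cursor. The SVD of `B` splits factor activity into an
**output-potent** component `z^r = R' z~` (drives the cursor) and an
**output-null** component `z^n = N' z~` (behaviorally invisible, the
redundant part). Six hypotheses predict the distribution of `z^n` at every
analyzed time step of a second, within-manifold-permuted mapping —
Minimal Firing, Minimal Deviation, Uncontrolled-uniform,
Uncontrolled-empirical, Persistent Strategy, and Fixed Distribution — each
constrained to physiologically plausible unit activity
(`0 <= U z~ + d <= u_max`). Predictions are scored per cursor-direction bin
by histogram error (half total-variation distance, in percent), mean error
(Euclidean distance, also reported as spikes/s), and the affine-invariant
covariance metric `sqrt(sum_i log^2 lambda_i)` over generalized eigenvalues,
against split-half error floors. A subspace variance-ratio analysis
(`log(Var_2/Var_1)` in the dimensions that switched from potent to null)
separates the competing accounts.

A closed-loop simulator (`sim_config()`, `make_ground_truth()`,
`simulate_session()`) generates complete two-mapping center-out sessions
with a configurable ground-truth rule coupling (or decoupling) output-null
to output-potent activity, so the entire chain can be validated against
known truth. See the vignette `vignettes/output-null-prediction.Rmd` for the
full methods account.

## Worked example

Simulate a session in the `coupled` world (output-null activity drawn from a
fixed repertoire tied to the output-potent activity) and run the full
analysis:

```r
library(bcinull)
cfg <- sim_config(world = "coupled", seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
Output-null prediction errors (direction: forward )
              hypothesis hist_pct mean_err mean_err_spikes_s cov_err
1         minimal_firing     58.6    2.570             57.11   4.956
2      minimal_deviation     24.6    1.091             24.25   0.733
3   uncontrolled_uniform     55.7    1.672             37.15   5.625
4 uncontrolled_empirical     27.8    1.584             35.21   1.563
5    persistent_strategy     36.1    2.008             44.63   0.900
6     fixed_distribution     18.4    0.155              3.45   0.546

Floors:
      metric floor_mean floor_sd
1  histogram     24.488   0.2948
2       mean      0.168   0.0172
3 covariance      0.721   0.0305

Variance ratios (session averages):
                   group  average
1                   data  0.02084
2         minimal_firing -1.07549
3      minimal_deviation -0.07226
4   uncontrolled_uniform  2.00733
5 uncontrolled_empirical  0.74926
6    persistent_strategy  0.37318
7     fixed_distribution  0.00501
```

Reading the output: the Fixed Distribution hypothesis — reuse of the
first-mapping activity pattern whose second-mapping potent projection best
matches the current one — predicts the observed output-null histograms at
the split-half floor (18.4% against a floor of 24.5 ± 0.3% estimated from
half-sized samples), while the Minimal Firing account is farthest off
(58.6%). The variance ratio near zero for the observed data (0.02) says the
population did **not** inflate its variability in dimensions that became
behaviorally irrelevant, matching the Fixed Distribution account (0.005) and
contradicting both the minimal-firing account (−1.08, variance collapse) and
the uncontrolled-uniform account (+2.01, variance inflation). Skip fractions
report the (rare) steps where no physiologically plausible prediction was
found within 100 attempts.

`autoplot(res$report)` draws the per-hypothesis error bars against the
floor; `tidy()`/`glance()` methods return the same numbers as tibbles.

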