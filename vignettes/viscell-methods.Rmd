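---
title: "Methods: dynamical modeling of single-cell viscoelasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamical modeling of single-cell viscoelasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscell)
```

## The model and its assumptions

`viscell` models a cell under AFM indentation as a linear time-invariant
system whose input is the piezo (PZT) z-position `u(t)` and whose output is
the tip--sample force `y(t)`. The mechanical structure is the generalized
Maxwell model: a lone spring `k0` in parallel with `n` Maxwell branches, each
a spring `k_i` in series with a damper `b_i`. The state `x_i` is the
displacement of the spring--damper junction of branch `i`:

$$\dot x_i = -\frac{k_i}{b_i}\,x_i + \frac{k_i}{b_i}\,u,\qquad
  y = -\sum_i k_i x_i + \Big(k_0 + \sum_i k_i\Big)\,u.$$

For a constant hold `u` starting from unrelaxed branches the output is

$$y(t) = k_0 u + u\sum_i k_i\,e^{-(k_i/b_i)\,t},$$

a constant plus `n` exponential decays with time constants
`tau_i = b_i/k_i`. Branches are always stored fast-first (ascending `tau`,
ties broken by ascending `k`), so fitted parameter vectors are comparable
across cells.

Assumptions worth stating plainly:

* **Linearity.** Superposition holds exactly in the model; real cells are
  nonlinear, and the linear model is a description of the relaxation phase
  only, at one hold depth.
* **Input convention.** The input is the PZT z-position, not the indentation
  depth (the two differ by the cantilever deflection). The package follows
  the z-position convention and exposes both channels to the caller, so users
  who prefer indentation as input can pass it explicitly.
* **Units.** Stiffnesses are N/m, damping N·s/m, displacements µm, so forces
  appear in µm·N/m. Published per-cell parameter magnitudes (k0 of order
  1 N/m) together with a 1 µm hold imply µN-scale model forces, while
  measured tip forces are nN-scale; the published account does not reconcile
  the two. The package therefore treats units as self-consistent model units
  and makes no claim that the parameter magnitudes are absolute SI values.
* **b = 0 branches.** Several published population SDs put substantial mass
  at zero damping. The closed form treats a `b = 0` branch as instantaneously
  decayed (its term contributes only at `t = 0`); the Runge--Kutta integrator
  rejects it rather than divide by zero.

Two independent response computations are maintained deliberately:
`relaxation_response()` (closed form) and `simulate_state_space()`
(fixed-step RK4 at `tau_min/50` or finer, linear in the state so non-stiff at
that step). Their agreement to 1e-6 over the 6 s window is a standing test of
both.

## Order identification

The relaxation record is the step response of the system; differencing
adjacent samples gives the impulse sequence `g(i) = y(i+1) - y(i)`, and the
`l × l` Hankel matrices `H(l, k)` built from `g` have rank equal to the
system order for noise-free data. The selection statistic is the
determinant ratio

$$D_l = \frac{\bigl|\tfrac{1}{L-2l+2}\sum_k \det H(l,k)\bigr|}
             {\bigl|\tfrac{1}{L-2l}\sum_k \det H(l+1,k)\bigr|},$$

which grows below the true order and peaks at it. Three implementation
choices required care, and each was settled empirically during development:

1. **Signed averaging.** For a decaying multi-exponential sequence the signal
   determinants are sign-coherent across `k`
   (`det H(2,k) = c_1 c_2 (\lambda_1\lambda_2)^k (\lambda_1-\lambda_2)^2`),
   while noise-dominated determinants have random signs and their mean
   shrinks like `1/sqrt(K)`. Averaging signed determinants (as the ratio
   above is written) therefore boosts the peak at the true order; averaging
   absolute values instead makes every ratio at or above the true order scale
   like `1/sigma` and destroys the peak. In simulation at the 1%-noise level
   the absolute-value variant selected the correct order in fewer than 20 of
   100 replicates under every decimation tried; the signed variant with the
   censoring below selects it in 99--100.
2. **Round-off rank crash.** On noise-free data, determinants above the true
   order are round-off junk; junk/junk ratios are large and random, so a raw
   argmax is meaningless. If the mean absolute determinant collapses by more
   than eight orders of magnitude between dimensions `l` and `l+1`, the
   dimension-`l+1` matrices are numerically singular and the order is `l`
   — this is the exact rank criterion applied at machine precision, and it
   fires before any statistics are needed.
3. **Noise-calibrated censoring.** On noisy data the raw noise level of the
   record is estimated from the high-frequency content of its flat tail
   (`mad(diff(tail))/sqrt(2)`), propagated through the decimation, and used
   in a Monte-Carlo perturbation (default 100 replicates) to attach a
   standard error to each mean determinant. Dimensions whose signed mean
   determinant is within `z = 3` standard errors of zero carry no detectable
   rank; the selected order is the largest surviving dimension, equivalently
   the argmax of the censored `D_l` profile. If nothing above `l = 1`
   survives, the order is 1 — this replaces any special-case rule for
   first-order systems, whose profile shape is otherwise indistinguishable
   from a second-order one (both decay monotonically beyond their peak).

**Decimation, not pre-filtering.** Order identification runs on the raw
(unfiltered) window, decimated by *block averaging* to a default of 16 points
over the first half of the record. Two reasons. A zero-phase Butterworth
applied first injects its own four poles into the impulse sequence — in
simulation the statistic then correctly identifies the cascaded
signal-plus-filter system, order ≈ 6, which is not the quantity of interest.
And coarse block averaging both suppresses white noise by `sqrt(m)` without
adding poles and concentrates the determinant signal-to-noise: at fine
sampling the slow mode moves so little between adjacent samples that every
2×2 minor is noise-dominated. The decimation target is a logged, configurable
choice (`npoints`); the noise-free result is decimation-invariant because the
rank-crash rule decides it.

Defaults: `lmax = 6` (2·lmax+2 samples must fit the window, and cell systems
observed are low order), analysis window = first half of the record (the
published curves are steady after 4 s of a 6 s hold; the tail contributes
noise-only determinants that dilute the k-average), `z = 3`, 100 Monte-Carlo
replicates, crash tolerance 1e-8.

## Parameter estimation

Given the order, the fit minimizes the squared error between the model
relaxation and the measured window. Exponential-sum fitting is notoriously
ill-conditioned, so the problem is solved separably: for any candidate time
constants the amplitudes `A_0, A_i >= 0` enter linearly and are solved by a
small non-negative least squares (active set); only `log tau_i` are iterated
(L-BFGS-B, bounds `[dt/2, 50 t_end]`, convergence on relative objective
change `1e-10`, cap 500 iterations). Positivity of all amplitudes is the
physical constraint that springs and dampers are passive. The mapping back is
`k_0 = A_0/u`, `k_i = A_i/u`, `b_i = k_i tau_i`, and branches are re-sorted
ascending in `tau`.

Starting values come from classical peeling: the baseline from a geometric
(Aitken) extrapolation of three tail block means — a plain tail mean
overestimates the baseline whenever the slowest mode has not fully decayed
inside the window — then log-linear regression of the slowest exponential on
the last third, subtraction, and a re-fit of each faster term on an early
window (`t <= tau_prev/8`) where the slower terms are flat. If a peel leaves
no positive residual the remaining time constants fall back to a geometric
grid spanning `[2 dt, t_end]`. A final guard keeps the optimizer from ever
returning a worse objective than its initializer.

Noise-free curves from all four published mean parameter rows are recovered
to well under 1% relative error in all five parameters; with 1% amplitude
noise the median error across seeded replicates stays under 10%. A time
constant shorter than a few sampling intervals is unrecoverable in principle
(the branch appears only in the first sample); population draws whose clamped
`b_1 = 0` produce such branches are recovered as what they observably are.

## Preprocessing

Force conversion is `F [nN] = 1000 · k_spring [N/m] · deflection [µm]`, with
the calibrated spring constant supplied by the user (no thermal-tune
handling). Smoothing is a 4th-order Butterworth low-pass, default 10 Hz
cutoff, applied forward--backward so the phase is zero and relaxation time
constants are not dragged; start-up transients are controlled by
odd-extension padding plus steady-state initial conditions, which is what
makes the DC gain exact to 1e-9. The filter coefficients were cross-checked
against an independent reference implementation to 12 digits during
development. Segmentation finds the longest contiguous window with
`|dz/dt|` below a threshold (default 0.1 µm/s against 4 µm/s ramps) and at
least 1 s long, and returns the re-zeroed time, the mean z as `u`, and the
force samples. Baseline offsets are assumed already removed; no contact-point
detection is attempted (out of scope).

## The synthetic world

The generator emulates the published population statistics of four cell
types: each of the five parameters is drawn independently from a Gaussian
with the type's mean and SD. Independence is forced, not chosen: only
marginal moments are published. Draws are truncated at floors
(`k >= 0.01·mean`, `b >= 0`) rather than resampled, because several rows put
large Gaussian mass below zero and resampling would shift the means.
Measurement noise is additive i.i.d. Gaussian with SD expressed as a fraction
of the relaxation amplitude `u·sum(k_i)` (default scenarios use 1%); real
cantilever noise is colored and drift-laden, and neither drift nor adhesion
is modeled.

Consequently a green synthetic test establishes that the *pipeline* is
correct and robust at the stated noise level — it does not establish
instrument-level accuracy, and it cannot reproduce cohort quantities that
depend on the unpublished parameter correlations. Two such quantities are
deliberately treated as structural, not numeric, targets: the published PCA
eigenvalue table (its eigenvalues sum to the number of variables, which
identifies correlation-matrix PCA even though the text says "covariance";
the package follows the arithmetic and standardizes) and the published 95%
classification success rate. For classification the package asserts instead:
perfect separation when class means are at least 6 pooled SDs apart in every
coordinate, and at least 85% mean accuracy over 20 seeds on the
marginals-only world with the published 30-train/10-test-per-class design
(measured ≈ 89% ± 4%, with the dominant confusion between MCF-7 and
Neuro-2a, matching the published account of which cells were confused).

## Classification

PCA standardizes columns and eigen-decomposes the correlation matrix,
reporting eigenvalues, differences, contribution rates and cumulative totals,
plus the count of eigenvalues above 1 (Kaiser), which is reported but drives
nothing. The classifier is a 5--20--40--4 feed-forward network with logistic
hidden units and a softmax output, trained full-batch by Adam (step 0.01, up
to 2000 epochs) on the cross-entropy, with features standardized by
training-set statistics only and early stopping on a stratified 20%
validation split (skipped for classes with fewer than 5 samples). The
architecture is fixed to the published one; activation, optimizer and epochs
are unstated there and are package defaults, all overridable.

## Known limitations

* Single hold depth per record; no multi-depth or frequency-domain fitting.
* No uncertainty quantification beyond residual norms.
* Order identification assumes an approximately uniform noise floor within
  the analysis window.
* The synthetic world omits parameter correlations, colored noise, drift and
  adhesion; see above for what that implies about green tests.
* Units are model-consistent, not reconciled absolute SI (see assumptions).
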