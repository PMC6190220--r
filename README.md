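# viscell

Quantifying single-cell viscoelasticity from AFM stress-relaxation force
curves with a generalized Maxwell model.

## The problem

When an atomic force microscope (AFM) tip indents a living cell and the
piezo actuator is then held at a constant depth, the measured force does not
stay constant: the cytoskeleton keeps rearranging and the force relaxes
toward a plateau. That stress-relaxation transient carries the cell's
mechanical fingerprint — its elasticity *and* its viscosity — which elastic
contact models (Hertz) cannot see. `viscell` treats the cell as a linear
dynamical system: the piezo z-position is the input `u(t)`, the tip force is
the output `y(t)`, and the system is a generalized Maxwell model — a lone
spring `k0` in parallel with `n` spring–damper branches `(k_i, b_i)`:

    dx_i/dt = -(k_i/b_i) x_i + (k_i/b_i) u(t),   i = 1..n
    y(t)    = -sum_i k_i x_i + (k0 + sum_i k_i) u(t)

Under a constant hold `u`, the relaxation response is a constant plus `n`
exponential decays with time constants `tau_i = b_i / k_i`:

    y(t) = k0 u + u * sum_i k_i exp(-(k_i/b_i) t)

The package answers three questions, in order:

1. **What order is the system?** The impulse sequence
   `g(i) = y(i+1) - y(i)` fills Hankel matrices `H(l, k)` whose rank equals
   the system order for noise-free data. The determinant-ratio statistic
   `D_l = |mean_k det H(l,k)| / |mean_k det H(l+1,k)|` peaks at the true
   order; `viscell` combines it with an exact numerical-rank test and a
   noise-calibrated significance floor so the selection works on both clean
   and noisy curves (see the methods vignette for why both are needed).
   Measured cells come out second order: five parameters, three elastic
   (`k0, k1, k2`) and two viscous (`b1, b2`).
2. **What are the parameters?** Separable (variable-projection) nonlinear
   least squares: amplitudes are solved in closed form under positivity for
   each candidate pair of time constants, and only the log time constants are
   iterated.
3. **Can the parameters identify the cell type?** The fitted five-parameter
   vectors are summarized by correlation-matrix PCA and classified with a
   two-hidden-layer (20, 40) backpropagation network.

A synthetic-data module generates parameter populations and noisy curves for
the four cell types the method was validated on (MCF-7, Neuro-2a, HEK-293,
L-929) from their published means and SDs, so the entire pipeline is testable
without any instrument data.

## Worked example

Simulate one noisy MCF-7-like cell, identify its order, and extract its
parameters:

```r
library(viscell)

p <- maxwell_params(k0 = 2.984, k = c(1.110, 1.385), b = c(0.118, 3.108))
curve <- generate_curve(p, u_const = 1, fs = 1000, duration = 6,
                        noise_sd = 0.01, seed = 42)

set.seed(42)
prof <- identify_order_curve(curve)
print(prof)
#> Hankel order identification (noise-censored): selected order 2
#>  l       dl
#>  1  39.6214
#>  2 111.8743
#>  3       NA
#>  ...

fit <- fit_relaxation(curve$t, lowpass(curve$force, fs = 1000),
                      u_const = 1, order = prof$selected_order)
print(fit)
#> Maxwell fit: order 2, residual norm 0.2744, R^2 0.999926 (converged)
#> Generalized Maxwell model, order 2 (5 parameters)
#>   k0 = 2.986 N/m
#>   path 1: k = 1.133 N/m, b = 0.1168 N s/m (tau = 0.1032 s)
#>   path 2: k = 1.386 N/m, b = 3.093 N s/m (tau = 2.232 s)
```

The `D_l` profile peaks at `l = 2` (dimensions above the detected rank are
censored to `NA`), so the cell is a second-order system; the five recovered
parameters sit within ~2% of the generating values despite 1% measurement
noise. `k0` is the long-time stiffness the cell relaxes to; the fast branch
(`tau ~ 0.1 s`) and slow branch (`tau ~ 2.2 s`) decouple the initial and
sustained viscous response.

Cohort-level analysis (order identification, fitting, PCA, classification on
a simulated four-type cohort) is one call:

```r
res <- demo_pipeline(n_per_type = 20, noise_sd = 0.01, config = run_config(seed = 1))
print(res)
```

A command-line interface with `simulate`, `identify-order`, `fit`, `pca`,
`classify` and `demo` subcommands lives at
`system.file("cli", "viscell.R", package = "viscell")`.

## Acceptance script

`scripts/acceptance.R` regenerates the headline numbers from scratch with the
installed package: it simulates noise-free relaxation curves from the
published MCF-7 and L-929 mean parameter rows, runs Hankel order
identification on the differenced MCF-7 curve, refits both curves at order 2,
and writes the identified order and the recovered `k0` / `b2` values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
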