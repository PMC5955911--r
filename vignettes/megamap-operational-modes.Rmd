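---
title: "Operational modes of the megamap: model, reduction, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational modes of the megamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megamapr)
```

## The model

`megamapr` implements a firing-rate network of `N` hippocampal place cells
with recurrent excitation, global feedback inhibition, and external input:

    tau * du/dt = -u + W f(u) - w_I * f_I(u) * 1 + b

with the threshold-linear activation `f(u) = f_pk * pmax(u, 0)` and a single
instantaneous inhibitory unit

    f_I(u) = pmax(sum(f(u)) - theta * f_net, 0).

`u` loosely represents depolarization (dimensionless), `b` is the external
(entorhinal) input, and all interneurons are lumped into one unit because
hippocampal interneurons carry little spatial signal. Treating inhibition as
instantaneous assumes its time constant is much shorter than `tau`; without
that simplification oscillatory regimes may appear, which this package does
not model.

The *megamap* is the variant of this network in which each cell has a
Poisson-distributed number of place fields scattered over a large
environment, so that cells are recombined flexibly across locations. For
each cell `i` with field centers `c_im`, the training input and the desired
(embedded) activity at location `x` are

    b_i(x) = b_pk * sum_m exp(-|x - c_im|^2 / (2 sigma^2))
    f_i(x) = sum_m f_pk * ((1 + u0) exp(-|x - c_im|^2 / (2 sigma^2)) - u0)_+

so each field contributes a Gaussian input bump and a thresholded activity
bump that vanishes at the radius `R = sigma * sqrt(2 log((1 + u0) / u0))`.

### Parameters, units, defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `tau` | membrane time constant (ms) | 10 | standard rate-model value |
| `f_pk` | peak rate of a bump (Hz) | 15 | CA3 place-field peak rates |
| `theta` | inhibition threshold (fraction of `f_net`) | 0.9 | inhibition engages only near full bump activity |
| `w_I` | inhibitory weight | calibrated | chosen so the *reduced* inhibitory weight `f_pk * N_bar * w_I` equals 5.3 |
| `sigma` | field width (m) | 0.10 | gives a bump radius `R ≈ 0.17` m, a typical field size |
| `u0` | activation shift | 0.3 | sets how sharply bumps are truncated |
| `b_pk` | training-input amplitude | calibrated | chosen so the reduced training strength is 0.33 (see below) |
| `f_net` | net embedded activity (Hz) | measured | grid average of `sum_i f_i(x)` |

`sigma`, `u0` and `b_pk` are not fixed by the theory; the defaults above are
this package's choices, picked so that scaled-down maps reproduce the same
reduced-parameter regime (`w0 ≈ 1.2`, `w_I_hat = 5.3`, `b_pk_hat = 0.33`,
`theta = 0.9`) that the reference phase diagrams use. All are overridable
through `megamap_params()`.

### Net-activity normalization

The embedded patterns are constructed so that `f_net = sum_i f_i(x)` is
independent of `x`. A raw sum of Poisson-placed bumps fluctuates around its
mean — mildly for maps with hundreds of active cells per bump, strongly (CV
above 10%) for the desk-scale maps this package tests with, where boundary
truncation adds further bias. Because inhibition balances the network at
`theta * f_net`, even an 8% local deviation shifts the effective
self-excitation of a bump by several tenths. `megamapr` therefore rescales
each embedded pattern to the common target exactly
(`normalize_net = TRUE`, the default once `f_net` is set); the raw
sum-of-bumps form remains available by passing scalar parameters or setting
`normalize_net = FALSE`.

## Weight construction

**Optimal (delta-rule) weights.** Every training-grid location contributes a
constraint: under its training input, the embedded pattern must be a fixed
point. For cells active in the pattern this pins `u_i = f_i(x) / f_pk`; for
silent cells only the inequality "net drive ≤ 0" is required, enforced with
perceptron-style corrections on violation (fixed points constrain only the
rectified part of `u`, so sub-threshold values are free). The update is the
delta rule with a per-pattern normalized step,
`dW[i, S] = (eta / ||f||^2) * err_i * f[S]`, cycling over shuffled grid
locations; at the default `eta = 1` each visit removes a pattern's residual
exactly (a Kaczmarz projection), which converges in tens of epochs where a
small raw step needs thousands.

Two numerical choices matter here:

* *No autapses.* Updates are projected onto `W_ii = 0`. Without this, every
  pattern a cell participates in deposits self-weight (the cell's own column
  carries ~`1/|S|` of each correction). In small networks (`|S| ≈ 50`) this
  inflates within-bump excitation enough to destabilize previously learned
  bumps during incremental learning; with the constraint the incremental
  phenomenology (flat `w0`, growing `q`, falling dominant eigenvalue) is
  recovered.
* *Convergence.* Training stops when the worst fixed-point residual drops
  below `embed_tol` (default `1e-3` on the `u` scale); the per-epoch history
  is kept in the returned report.

**Hebbian weights.** `W[j, k] = sum_{m,n} w_tune(|c_jm - c_kn|)` over all
field pairs, where the tuning curve `w_tune` is measured by training a
synthetic single-field-per-cell network and radially averaging the learned
weights (`compute_tuning_curve()`). The curve is tabulated at 1 cm
resolution, linearly interpolated, truncated where it falls below `1e-4` of
its peak, and clamped at zero for the Hebbian sum — keeping the construction
additive and the matrix exactly symmetric, diagonal (cross-field self terms)
included. On a single-field map the two constructions share the same radial
kernel; the exact delta-rule solution additionally carries non-radial
structure, so the agreement is between radial profiles, not entry by entry.

**Incremental learning.** `incremental_learning()` trains region by region
over a concentric growth sequence, never revisiting earlier regions
(optimal: the delta rule continues from the previous matrix on the new
region's locations only; Hebbian: the new field pairs' terms are added).
Non-reinforcement is essential: it is what lets cross-excitation between
distant units accumulate instead of being balanced away. Training the whole
environment in one pass yields `q ≈ 0`.

## The operational-mode test

At a fixed point, stability depends only on *which* cells are active. With
`S` the active excitatory set and the inhibitory unit active, the fixed
point is stable iff `r < 1`, where `r` is the largest real part over
eigenvalues of `f_pk * (W - w_I * 11') * D(S)` (`stability_index()`;
computed on the active submatrix, since zeroed columns add only zero
eigenvalues). Neither the input nor the state magnitudes enter.

`classify_mode()` applies this a priori: take two well-separated probe
locations (at least 0.5 m apart, inside the boundary margin), form the union
of their embedded active sets, and evaluate `r` with inhibition active. If
`r < 1` a two-bump state can persist — the *combinatorial* mode; otherwise
any stable state carries a single bump — the *winner-take-all (WTA)* mode.
The test decides stability, not existence, of the two-bump fixed point, and
values within `1e-3` of 1 are reported `"marginal"` rather than classified,
since borderline verdicts depend on the probe locations chosen.

## Reduction to two units

Summing the dynamics over each embedded set and scaling by `f_pk / f_net`
gives an exact-in-form two-unit model:

    tau * du1/dt = -u1 + w0 [u1]_+ + q [u2]_+ - w_I_hat [[u1]_+ + [u2]_+ - theta]_+ + b1

(and symmetrically for unit 2), with

    w0 = (f_pk / f_net) * sum_{i,j in S1} W_ij f_j(x1)
    q  = (f_pk / N_bar) * sum_{i in S1, j in S2} W_ij
    w_I_hat = f_pk * N_bar * w_I

where `N_bar` is the mean active-set size. Four approximations underlie the
mapping: disjoint units, equal unit sizes, symmetric cross-coupling, and a
bump of fixed radius (the reduction tracks bump height only).
`reduce_megamap()` reports diagnostics for the first three — overlap
fraction (must stay under 5%), directed cross-sums and their asymmetry
(under 10% of the coupling scale, floored at 10% of `w0` so vanishing
coupling is not flagged) — and computes `w0` at both locations, returning
the mean. Cells in both sets are assigned to the nearer location so partial
sums stay disjoint.

Training the reduced model's two patterns forces the identity
`1 = w0 - w_I_hat (1 - theta) + b_pk_hat`; with the reference values
`w0 = 1.2`, `w_I_hat = 5.3`, `theta = 0.9` this fixes the reduced training
strength at `b_pk_hat = 0.33`. `check_constraints()` evaluates this identity
and the four admissibility constraints (`0 < theta < 1`, `0 < b_pk << 1`,
`w0 > 1`, `q < w_I_hat (1 - theta)`).

## Fixed points, Types I–IV, bifurcations

`enumerate_fixed_points()` solves the linear system of each of the eight
on/off configurations (unit 1, unit 2, inhibition) and keeps
sign-consistent solutions; stability again comes from the active-submatrix
eigenvalue index. The resulting analysis:

* a unit-`k`-only fixed point, when it exists, is always stable;
* a both-active fixed point is stable iff `w0 - q < 1` (Jacobian eigenvalues
  `(w0 - q - 1)/tau` and `(w0 + q - 2 w_I_hat - 1)/tau`), and under that
  condition it is unique, amplifying the input difference as
  `u1 - u2 = (b1 - b2) / (q - (w0 - 1))`;
* no stable all-silent state exists when `w0 > 1` (an all-silent candidate
  sits on an activation boundary; a supra-threshold perturbation grows, so
  it is reported unstable);
* inhibition-off configurations are enumerated but expected sign-
  inconsistent under the constraints; any survivor would appear in the
  output rather than being dropped.

With the net input held constant (`b1 + b2 = b_pk_hat`), all boundaries are
expressed through `g(x) = 2x (w_I_hat - (w0-1)) / (w_I_hat (1+theta) -
(w0-1) + x)`, strictly increasing with `g(0) = 0`: hysteresis (Type III)
iff `q < (w0-1) + g(-|db|)`, two co-stable bumps (Type IV) iff
`q > (w0-1) + g(|db|)`, otherwise the stronger input wins outright (Type
I/II). `bifurcation_diagram()` classifies a grid analytically and verifies
it by simulation with the protocol: start from the desired pattern of the
weaker-input unit, classify by which units are active at equilibrium;
points within `1e-6` of a boundary are excluded as marginal. The
`m_unit_rhs()` generalization extends the same form to `M` conflicting
inputs and collapses to the two-unit model at `M = 2`.

## Time integration

Both models integrate with fixed-step explicit Euler, `dt = tau / 20`
(0.5 ms) by default and a hard cap at `tau / 10`. The right-hand side is
piecewise linear — smooth inside each activation region — so the method's
first-order error is benign; halving the step moves equilibria by less than
`1e-4` on fixture networks (asserted in the tests). Equilibrium is declared
at `max |du/dt| < 1e-6` per ms with a 2000 ms default horizon;
non-convergence is reported in a flag, never raised. A state norm above
`1e6` raises a divergence error (possible when the admissibility
constraints are violated, e.g. unbounded Hebbian growth). The inhibitory
unit is recomputed from `u` at every evaluation and carries no state.

## What the synthetic maps emulate — and what they do not

The generator reproduces the study conditions at desk scale: Poisson field
counts calibrated so 80% of cells are silent per 1 m² (`lambda =
-log(0.8) ≈ 0.223` per m² per cell), uniform field centers, training
locations on a uniform grid at least 15 cm from every wall, and probe pairs
at least 0.5 m apart. Scaled-down instances use 320–900 cells in 2.6–6.8 m²
with 40–90 active cells per bump, against roughly 10,000 cells and 222-cell
bumps in the reference simulations. Three consequences, all handled
explicitly rather than averaged away by size:

* quenched Poisson variability makes some locations unable to pin a bump;
  fixtures select probe locations with single-bump `r < 1`
  (bumps drift from unfavorable locations even at full scale);
* the transition into the combinatorial regime cannot be reached by simply
  growing the map to 25 m²; the `comb_small` fixture instead plants shared
  remote fields for pairs of cells from the two units
  (`add_shared_fields()`) in outer regions learned later — the same
  mechanism (shared fields elsewhere → cross-excitation) compressed into
  less area;
* raw net activity fluctuates strongly, hence the exact normalization
  described above.

Passing tests therefore demonstrate the mechanisms — embedding, the
eigenvalue test, the reduction, the mode transition and its bifurcation
structure — under faithfully scaled conditions; they do not certify
quantitative behavior of a full-size megamap, nor biological realism of
place-field statistics beyond the Poisson model. Bump drift without input
is observed but not quantified. Oscillatory regimes, spiking dynamics,
plasticity during retrieval, and weight normalization for the unstable
Hebbian growth are out of scope.

## Problem sizes used by the tests

The test-suite fixtures are: `wta_small` (900 cells, 2.56 m², one-pass
training), `comb_small` (900 cells, 6.76 m², three concentric regions, 130
shared-field pairs per outer ring, incremental training), `single_field`
(320 single-field cells), all on 0.12 m training grids; the stability-test
oracle runs on 50+ random networks of up to 30 cells; phase-diagram
verification uses a 25 × 25 grid. These sizes keep a full run of the suite
in the low minutes on one core while leaving every mechanism exercised end
to end.
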