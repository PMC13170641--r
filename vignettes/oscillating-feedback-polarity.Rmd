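---
title: "Cell-cycle-entrained feedback oscillations in PAR polarity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle-entrained feedback oscillations in PAR polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Cell polarity networks face a trade-off. Strong mutual-antagonism feedback
makes membrane polarity domains stable — a bistable, switch-like system holds
its pattern against noise — but the same feedback makes the system refractory
to orientation cues: a cell "trapped" in the wrong attractor cannot be
re-polarized. Weak feedback is the mirror image: the system follows cues
faithfully but cannot hold a pattern once the cue is gone.

In the *C. elegans* germline (P) lineage, the pPAR effectors PAR-1 and CHIN-1
associate with the membrane in phase with CDK-1 activity: membrane levels are
low after cell birth, rise after chromosome condensation, peak near nuclear
envelope breakdown (NEBD), and fall at anaphase onset. Because these effectors
carry the P-to-A arm of the mutual antagonism, the network's feedback strength
itself oscillates with the cell cycle. This package implements the models and
quantification used to study the consequence: a *time-varying polarization
landscape* in which a transient low-feedback window lets cues re-orient
polarity from any starting state, after which rising feedback locks the new
pattern in.

# The two-compartment PAR model

The core model collapses the membrane into anterior and posterior compartments
with concentrations $A_a, A_p$ (aPAR) and $P_a, P_p$ (pPAR):

$$
\frac{dA_a}{dt} = \tilde D (A_p - A_a) + k_\mathrm{on} A_\mathrm{cyto}
 - k_\mathrm{off} A_a - k_{AP} P_a^{\alpha} A_a ,
$$

with three analogous equations for $A_p$, $P_a$, $P_p$ (the pPAR equations use
$k_{PA} A^{\beta} P$), and mass conservation through
$A_\mathrm{cyto} = \rho_A - \psi (A_a + A_p)/2$ and its pPAR analog. The
cytoplasm is slaved to the membrane state, so total protein per species is
conserved exactly, by construction, in every simulation.

Time-dependence enters in two ways:

* a **feedback schedule** (`feedback_schedule()`), a piecewise-linear
  multiplier on $k_{AP}$ (optionally also on $k_{PA}$ for the co-oscillation
  variant) that stands in for CDK-1-gated membrane loading of the pPAR
  effectors; and
* a **cue** (`polarity_cue()`), a first-order redistribution of membrane aPAR
  from posterior to anterior ($+r A_p$ into $A_a$, $-r A_p$ out of $A_p$),
  the simplest continuous reading of cues that act by local depletion or
  inhibition of aPARs. The cue conserves total aPAR exactly.

## Default parameter sets and how they were chosen

Numeric rate tables for the original models were not available, so the shipped
defaults are *calibrated to the qualitative regime structure* the study
states, and then frozen:

| parameter | value | role |
|---|---|---|
| $\tilde D$ | 0.1 /time | weak inter-compartment exchange |
| $k_\mathrm{on}$, $k_\mathrm{off}$ | 1, 0.3 /time | attachment/detachment |
| $k_{AP} = k_{PA}$ | 50 | strong symmetric antagonism |
| $\alpha = \beta$ | 2 | antagonism exponents (standard in this model lineage) |
| $\rho_A = \rho_P$, $\psi$ | 1, 1 | pools, surface-to-volume |

With these values the high-feedback model has exactly four stable steady
states — uniform-A, uniform-P, and the two polarized states, one per quadrant
of the concentration-difference plane — plus a central unstable point, and
lowering $k_{AP}$ by the factor `low_feedback_multiplier()` (0.01) collapses
the structure to a single uniform-A attractor. These two properties, not any
numeric table, are the calibration target; `find_steady_states()` verifies
them directly.

The oscillating schedule (`oscillating_schedule()`) holds the multiplier at
0.01 from cell birth to $t = 60$, then rises linearly to 1 by $t = 70$,
mimicking the CDK-1 rise at mitotic entry. The default cue (rate 0.5, window
$[10, 75]$) deliberately **overlaps the feedback rise**: if the cue switches
off while feedback is still low, the cue-induced asymmetry relaxes back to the
uniform state before feedback can capture it. The overlap is therefore a
mechanistic requirement of the model, not a tuning convenience; with it, the
cue converts all four initial attractors to the cue-aligned polarized state
under the oscillating schedule, while under constant high feedback only the
uniform-A initial converts (`run_switching_matrix()`).

## Numerical choices

Trajectories use `deSolve::lsoda` (stiff-capable) at `rtol = 1e-8`,
`atol = 1e-10`, with the integration segmented at schedule breakpoints and cue
on/off times so the solver never steps across a non-smooth point. Steady
states come from damped Newton iteration with the analytic Jacobian,
multi-started from a deterministic 5^4 grid over the admissible region;
duplicate roots are merged below an inter-root distance of 1e-6 (far below
attractor separation in all shipped regimes) and every accepted root must
satisfy $\max_i |f_i| < 10^{-9}$. Stability is read off the real parts of the
Jacobian eigenvalues with a degeneracy warning below 1e-8. Quadrant labels
use a dead zone of 1% of the no-feedback uniform balance, preventing sign
flicker at near-symmetric states.

# Stochastic landscapes and quasipotentials

`euler_maruyama_ensemble()` integrates
$X_{t+\Delta t} = X_t + f(X_t)\,\Delta t + \sigma \sqrt{\Delta t}\,\xi$ with
reflection at zero (preserving admissibility); the default
$\sigma = 0.1$ was chosen once so that in the high-feedback regime the four
wells are individually resolved and well-hopping is rare on the sampling
horizon — larger noise washes the wells out, smaller noise leaves bins
unpopulated. `build_landscape()` histograms the projection onto the
difference coordinates $(A_a - P_a, A_p - P_p)$ and reports
$U = -\log(\text{density})$ shifted to $\min U = 0$; unoccupied bins are `NA`
rather than an invented large value, so downstream code must handle them
explicitly.

The 2D projection of a four-variable flow is degenerate, so the quiver field
(`velocity_field()`) needs a lift rule: each grid point is placed on the
symmetric section where both compartment sums equal a reference value (by
default taken from the central fixed point), and the velocity is the projected
right-hand side there. This is an approximation by construction and is
documented as such.

For the one-species model the quasipotential can instead be computed exactly
as the stationary solution of the Fokker-Planck equation.
`fokker_planck_stationary()` uses a Scharfetter-Gummel (exponentially fitted)
finite-volume discretization with zero-flux boundaries and solves the sparse
null-space problem directly; on a 1D gradient drift it reproduces the
Boltzmann density $\propto e^{-2V/\sigma^2}$ to a few parts in $10^4$ at
$n = 200$ cells. The Euler-Maruyama histogram and the Fokker-Planck solution
are compared by total-variation distance on a shared 20x20 grid at
$\sigma = 0.25$, where the mirror wells mix on the sampling horizon; the
package's tests require TV < 0.1 and typically observe ~0.02.

# The one-species wave-pinning model

The mathematically tractable confirmation model follows the wave-pinning
lineage: one species $X$ in two compartments with Hill-saturated positive
feedback,

$$
\frac{dX_a}{dt} = \tilde D (X_p - X_a) + k_\mathrm{on} X_\mathrm{cyto}
 - k_\mathrm{off} X_a
 + \gamma X_\mathrm{cyto} \frac{X_a^{n}}{K^{n} + X_a^{n}} .
$$

The source prints the detachment term with a positive sign; it is implemented
as detachment ($-k_\mathrm{off} X$), since a positive sign gives unbounded
growth and contradicts the cited wave-pinning construction. Defaults
($\tilde D = 0.05$, $k_\mathrm{on} = 0.067$, $k_\mathrm{off} = 1$,
$\gamma = 1.5$, $K = 1$, $n = 2$, $\rho_X = 2$, $\psi = 1$) sit in the classic
bistable regime: a mirror pair of polarized attractors separated by an
unstable symmetric state. The feedback schedule multiplies $\gamma$ and the
cue redistributes $X_p \to X_a$, mirroring the two-compartment conventions.

# The 1D reaction-diffusion model and the P1/P2 scenarios

`pde_params()` describes the full spatial model on a membrane arc $[0, L]$
(default $L = 60$, $N = 128$, no-flux boundaries — a membrane parameterized
pole-to-pole; periodic available), integrated by forward Euler with central
finite differences at $\partial t = 0.01$, well inside the stability bound
$\Delta t < \Delta x^2 / 2D$. Asymmetric A/P rates are allowed; the defaults
reuse the compartment-model rates with $D_A = D_P = 1$, giving fronts a few
grid cells wide.

Scenario coordinates are **cue-anchored**: $x = 0$ is the pole where aPAR
consolidates in the cue-aligned outcome, and the coarse polarity class is read
from the two halves of the domain.

* **P1** (polarization from a uniform pPAR-high membrane): pPAR starts at its
  uniform-dominant steady level; aPAR is cytoplasmic except a furrow-derived
  Gaussian bump at the contact ($x = 0$); an attract-mode cue (weighted
  membrane redistribution toward the contact zone, conserving aPAR) stands in
  for the later actin-flow bias. Under the oscillating schedule aPAR loads
  during the low-feedback window, the bump breaks symmetry, and the domain
  boundary locks as feedback rises; under constant high feedback the uniform
  pPAR membrane suppresses all aPAR loading and polarization fails.
* **P2** (cue-induced polarity reversal): the initial profile is polarized
  the "wrong" way, with the aPAR domain at the contact end ($x = L$). The
  contact cue is an **inhibit-mode** cue: a localized first-order boost of
  aPAR detachment in the contact zone, with the protein returning to the
  cytoplasmic pool. A pure redistribution cue cannot create the experimental
  failure mode here: cytoplasmic replenishment refills the contact membrane
  as fast as redistribution drains it, so no new pPAR domain ever nucleates.
  Local inhibition is also the mechanism the experimental literature
  attributes to the contact signal. Under constant high feedback the old pPAR
  domain is locked while a new one nucleates at the contact — the transient
  two-pPAR-domain signature — and reversal fails; under the oscillating
  schedule the old domain dissolves during the low phase and a single
  reversed domain forms.

Domain counting (`count_domains()`) uses a threshold of half the profile
maximum and a minimum width of 5% of $L$, both configurable; these defaults
are scale-free and robust to amplitude drift. `kap_schedule_from_trace()`
turns any membrane-level time series (e.g. a synthetic cell-cycle trace) into
a feedback schedule by mapping the trace maximum to multiplier 1 and the
minimum to a configurable floor.

# Image quantification

The pipeline mirrors standard cortical-fluorescence quantification:

1. `straighten_membrane()` resamples the closed ROI contour at 1-pixel arc
   spacing, estimates smoothed tangents (window 5) to avoid polyline jaggies,
   and samples 100 positions along each local normal (50 outside, 50 inside)
   with bilinear interpolation.
2. `rolling_average()` applies a circular 20-pixel box filter along the
   contour (the contour is closed, so the filter wraps).
3. `fit_cross_profile()` fits each cross-membrane profile as a Gaussian
   (membrane) over an error-function step rising toward the cytoplasm plus a
   constant background, by Levenberg-Marquardt (`minpack.lm`) with bounded
   parameters. By default the step shares the Gaussian width — one fewer
   free parameter; a free-width variant is available. Initialization:
   center of the strip, width 3 px, amplitude from the data range, plateaus
   from the strip edges. The membrane concentration at a position is the
   fitted Gaussian amplitude; failed fits report `NA`, never zero.
4. `asi()` is the asymmetry index $(A - P) / [2(A + P)]$ over summed
   anterior/posterior signal, bounded by $\pm 0.5$.
5. `align_profiles_within()` / `align_profiles_between()` iteratively align
   circular profiles to their mean by integer circular shifts minimizing the
   MSE of mean-subtracted profiles (decoupling shift estimation from
   intensity differences); the between-embryo variant also tries the reversed
   traversal orientation and keeps whichever is better, ties broken toward
   non-inverted, zero shift. The MSE sequence is non-increasing by
   construction. Shifts are integer-only; the underlying method statement is
   silent on sub-pixel alignment.
6. `dog_subtract()` and `detect_clusters()` implement
   difference-of-Gaussians background subtraction (defaults 1 and 5 px) and
   scale-normalized Laplacian-of-Gaussian blob detection (scales 1-4 px) with
   local maxima over space and scale, greedy non-maximum suppression, and a
   default threshold of `max(8 * mad(finest response), 2% of peak response)`
   — the robust term handles noisy images, the relative floor keeps
   near-noise-free images from admitting interpolation ripples. Cluster
   intensity integrates the background-subtracted image over the detected
   footprint; density is total intensity over visible cell area. All
   filtering uses replicate padding: FFT-style circular wrapping creates
   spurious responses at image borders.

# Synthetic data: what it does and does not emulate

All test inputs are generated, seeded, and returned together with their
ground truth. The embryo generator builds the image from the *exact signed
distance* to an elliptical mid-membrane (vectorized Newton nearest-point
iteration), so the cross-membrane profile along any true normal is exactly
the model the fit assumes: background + erf step + Gaussian ridge with a
known, possibly angle-dependent, amplitude. The default geometry is a
50x30 micrometre ellipse at 0.155 micrometre/pixel; the tests use a smaller
8x5 micrometre embryo for speed, which exercises identical code paths.
Noise is additive Gaussian, and SNR is defined as membrane amplitude over
noise standard deviation.

This emulation validates the *quantification* pipeline, not image formation:
there is no point-spread function, no shot noise, no autofluorescence and no
segmentation error (the ROI is the true ridge center). Passing recovery tests
therefore demonstrates correctness of straightening, fitting, alignment and
detection, and says nothing about robustness to segmentation error or
non-Gaussian noise in real micrographs. Cell-cycle traces are piecewise
linear with a slight post-NEBD decline (keeping the argmax uniquely at NEBD)
and a sharp post-anaphase fall.

# Problem sizes

The shipped tests and the acceptance script use: steady-state enumeration
from a 5^4 start grid; 12 switching simulations to $t = 300$; PDE scenarios
at $N = 128$, $\partial t = 0.01$, to $t = 200$-$300$; Euler-Maruyama
ensembles of 200 trajectories sampled over 500 time units (and 100
trajectories for the one-species cross-check); Fokker-Planck grids of 200
(1D) and 20x20 (2D); synthetic embryos of roughly 185x224 pixels with ~67
fitted positions; and 25-blob cluster benchmarks. These sizes resolve every
qualitative claim the package tests while keeping a full run in a few
minutes.

# Known limitations

* The compartment and PDE rate constants are behavior-calibrated, not fitted
  to measured embryo kinetics; quantitative timescales are in model units.
* The quiver lift rule is one section through a degenerate projection;
  occupancy quasipotentials for the four-variable model depend on the noise
  amplitude and initial ensemble and are not large-deviation quasipotentials.
* The PDE model has no advective cortical-flow term; flows enter only through
  initial conditions and the attract-mode cue.
* Explicit Euler is first-order; halving $\partial t$ roughly halves the
  error, and the shipped step is two orders below the stability bound for
  the default diffusivities.
* Alignment is integer-shift only, and the cluster detector assumes roughly
  isotropic blobs within the configured scale range.

```{r example}
library(parosc)

# the headline computation: the switching matrix
run_switching_matrix(regimes = c("constant_high", "oscillating"))[, 1:3]

# a P2 reversal under both schedules
p_hi <- pde_params()
p_osc <- pde_params(kAP_schedule = oscillating_schedule())
max(run_scenario(scenario_spec("P2", p_hi), p_hi, 300)$diagnostics$n_domains_P)
max(run_scenario(scenario_spec("P2", p_osc), p_osc, 300)$diagnostics$n_domains_P)
```
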