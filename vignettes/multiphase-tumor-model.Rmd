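---
title: "A viscous multiphase model of tumor-macrophage dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A viscous multiphase model of tumor-macrophage dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorphase)
```

## The model

`tumorphase` simulates the growth of a solid tumor inside vascularized
healthy tissue as a mixture of seven interpenetrating viscous phases:
healthy cells ($\theta_h$), cancer cells ($\theta_c$), vasculature
($\theta_v$), interstitial fluid ($\theta_{int}$), pro-inflammatory
(M1) macrophages ($\theta_{M_1}$), pro-tumor (M2) macrophages
($\theta_{M_2}$), and — under immunotherapy — M1 macrophages whose
TGF-$\beta$ receptors are irreversibly bound by a small-molecule
inhibitor ($\theta_{M_{1p}}$).  Each phase obeys a mass balance

$$\partial_t \theta_i + \nabla\cdot(\vec u_i \theta_i)
  + \chi_J \nabla\cdot(\theta_i \nabla J) = q_i,$$

where at most one chemokine $J$ attracts each cellular phase (cancer
cells follow EGF, vessels VEGF, M1 and drug-bound M1 follow CSF-1, M2
follow CXCL12), and a creeping-flow momentum balance

$$\nabla\cdot(\theta_i \boldsymbol\sigma_i) + p_i\nabla\theta_i
  + \sum_{j\ne i} d_{ij}\,\theta_i\theta_j(\vec u_j - \vec u_i) = 0$$

with the full deviatoric viscous stress
$\boldsymbol\sigma_i = -p_i I + \mu_i(\nabla\vec u_i + \nabla\vec u_i^T)
- \tfrac23\mu_i(\nabla\cdot\vec u_i) I$.  Phase pressures are related by
an equation of state: the vascular pressure is the zero reference, the
interstitial pressure $p_{int}$ is the Lagrange multiplier of the
mixture continuity equation, and every cellular phase carries
$p_i = p_{int} + \Sigma(\theta)$, where the closure
$\Sigma = \Lambda(\theta-\theta^*)/\sum_i(\theta_i-\theta)^2$ switches
on when the total cell density $\theta$ exceeds the natural tissue
density $\theta^* = 0.6$ (the unusual squared-deviation denominator is
implemented literally as published).  When the drug-bound compartment is
populated it contributes to the cell density $\theta$ and to the cell
pressure, while the deviation sum retains its published six-phase form.

The reaction terms encode: oxygen- and fluid-limited proliferation with
oxygen-dependent death for both cell types; an M2-driven boost to cancer
proliferation and M1-driven cancer killing, both saturating in macrophage
density; VEGF-driven angiogenesis opposed by pressure-triggered vascular
occlusion through a smoothed Heaviside switch $\tfrac12(1+\tanh(y/h))$;
CSF-1-saturated M1 extravasation from the vasculature (the mixture's
only external mass source); TGF-$\beta$-driven alternative activation of
M1 into M2; and first-order death everywhere.  The interstitial fluid
absorbs or releases whatever the other phases exchange, so the sum of
all production terms equals the extravasation source exactly — an
algebraic identity the test suite asserts pointwise on randomized
states.  Under therapy, drug binding converts M1 to the protected
compartment at rate $k_{assoc,M_1}\theta_{M_1} d/(d_p+d)$; this
conversion cancels between the two compartments, and death of bound
macrophages feeds the interstitium like every other death term, so the
mass identity survives the extension.  With the drug field identically
zero all therapy terms vanish exactly, making the base model a
bit-for-bit special case of the extended one; the simulator relies on
this to compare treated and untreated runs.

Six diffusible species (oxygen $c$, VEGF $g$, CSF-1 $a$, CXCL12 $b$,
EGF $l$, TGF-$\beta$ $f$) plus the drug $d$ equilibrate much faster than
cells move, so each solves a quasi-steady reaction-diffusion problem
$D_J\nabla^2 J + s_J = 0$ with zero-flux boundaries at every instant.
VEGF and CSF-1 production carries the biphasic hypoxia response
$c/(c_a+c)^2$, maximal at $c = c_a$.  The vascular drug concentration
follows a pulsed oral schedule: each of $N$ doses raises it to $d_{max}$
and decays exponentially at rate $k_{el,d}$, with doses superposing.

All quantities are dimensionless: the time unit is the healthy-cell
doubling time (about one day) and the length unit 400 µm.  Parameter
defaults are the published dimensionless rates; `model_parameters()`
documents each one.  Two defaults are derived couplings
($k_{cm,c} = k_{cm,h} k_{m,c}$, $\chi_b = 5\chi_a$) and are recomputed
if their parents are overridden.

## Homeostasis and the angiogenesis constant

Initial conditions come from the cancer-free equilibrium: healthy cells
at $\theta^*$, no macrophages, and uniform $\theta_v, \theta_{int}, c,
g$ solving the algebraic system of healthy-cell balance, vessel
balance, volume closure ($\theta_v + \theta_{int} = 0.4$), oxygen
balance, and VEGF balance:

```{r}
homeo <- solve_homeostasis(model_parameters())
homeo
```

The vessel balance is closed by treating the angiogenesis constant as
its unknown.  Solved literally at the converged VEGF level
($g^0 \approx 0.600$) it yields $k_{ang} \approx 8.1\times10^{-3}$,
whereas the published constant $4.87\times10^{-3}$ is what the same
equation gives with the VEGF concentration replaced by 1.  The package
does not guess which the original computation used: the configured
default stays the published $4.87\times10^{-3}$, and
`solve_homeostasis()` reports `k_ang_implied` alongside.  One visible
consequence: with the published default the homeostatic tissue is not
an exact steady state (the interstitial fraction drifts by about
$4\times10^{-3}$ over ten time units), while re-running with
`k_ang = k_ang_implied` is stationary to machine precision.  The
stationarity test does exactly that, with the override stated
explicitly in the scenario.

## Discretization

Space is discretized by conservative finite volumes, by default on a 1D
radially symmetric disk (annular cells, exact annulus volumes, symmetry
at the origin): every single-centered-seed scenario of the model is
radially symmetric, and the 1D mode resolves it at a small fraction of
the 2D cost.  A 2D Cartesian mode with an embedded disk mask supports
off-center and multi-seed configurations; boundary cells carry their
exact clipped overlap with the disk.  By default only cells with at
least half their area inside the disk are kept — tiny sliver cells
would otherwise throttle the volume-aware CFL step — at the price of
about a percent of boundary area at coarse resolution; a fully
inclusive mask (`min_overlap = 0`) recovers the disk area $\pi R^2$
essentially exactly and is what the geometry tests assert.

Each step performs, in order: (1) the quasi-steady chemical solves —
oxygen first by damped Picard iteration on its Michaelis consumption
term (warm-started from the previous step, residual tolerance
$10^{-10}$), then VEGF and CSF-1 (which see oxygen), then the species
independent of oxygen, each one sparse linear solve (tridiagonal Thomas
solves in 1D); (2) the pressure closure and the flow solve — all phase
velocities and the interstitial pressure as one sparse saddle-point
system, momentum rows on faces and continuity rows on cells, solved by
direct sparse LU; (3) reaction-rate evaluation; (4) an explicit
conservative transport update with first-order upwinding of the
combined advective and chemotactic face velocity.  Upwinding under the
CFL bound `dt = cfl * min(h / |w|)` preserves positivity; values driven
into $(-10^{-10}, 0)$ by round-off are floored, anything lower aborts.
Dose times are always inserted into the event list — also for untreated
runs — so treated and untreated trajectories share identical step
sequences and can be compared bit for bit.

The continuity right-hand side needs $\partial_t\sum\theta_i$; because
the interstitial production balances all reactions, that time derivative
equals the extravasation source identically and the continuity equation
reduces to the chemotactic flux divergences.  This also resolves a
formal mismatch in the published continuity equation, whose
extravasation term omits the CSF-1 saturation present in the M1 mass
balance: the saturated form is used so that continuity is exactly the
sum of the phase balances.

Numerical guards: phase concentrations are floored at $10^{-8}$ inside
viscous, drag, and pressure-gradient coefficients so momentum rows of
locally absent phases stay nonsingular (their velocities are
diagnostically meaningless there and carry no mass — continuity uses
unfloored concentrations); the closure denominator carries a floor of
$10^{-8}$ against the all-deviations-zero degeneracy, with tested
insensitivity to a tenfold change; the outer-boundary stress condition
uses a second-order one-sided velocity gradient and linearly
extrapolated pressure, which matters for recovering boundary pressure
levels at design order.  In the 2D mode the stress-free condition is
imposed face-wise on the staircase mask boundary and the shear stress
is dropped at partial corners — a first-order boundary treatment
adequate for the coarse qualitative runs that mode is meant for; the 2D
solver also drops phases with no mass anywhere from the velocity system
(they re-enter as soon as any mass appears), which roughly quadruples
throughput on typical states.

Verification rests on manufactured solutions with closed-form oracles
(`manufactured_case()`): a reaction-diffusion cosine solution (second
order), radial advection of a bump against the method-of-characteristics
solution (first order), a viscosity-free two-phase drag balance with
linear-in-radius velocities, and a polynomial viscous flow whose
momentum and continuity forcing are derived symbolically.  Uniform
states supply a second oracle family: every chemical solve must match a
scalar root of its source function, and uniform unforced flow must be
exactly quiescent.  A radially symmetric 2D state cross-validates the
2D solver against the 1D one within discretization error.

## Scenarios and study conditions

`scenario()` bundles macrophage mode, seeds, domain, stepping, therapy,
and output cadence.  The three macrophage modes are parameter
restrictions: `m1_only` sets $k_{aa}=0$ (no alternative activation),
`inert` sets $k_{c,M_1}=k_{c,M_2}=0$ (macrophages occupy space,
extravasate and polarize, but neither kill nor boost — the minimal
operational reading of an "inert" phenotype), and `none` sets
$k_{ext,M_1}=0$.  Tumor seeds are cosine-squared lesions of amplitude
0.05 and radius 1; the multi-seed protocol divides the reference cancer
mass equally among $n$ seeds by shrinking each radius to $1/\sqrt n$ at
fixed amplitude (the planar integral of the profile scales with the
squared radius, so division is exact), placed on a regular polygon with
configurable spacing (default 3 length units between centers; seeds
must start disjoint).

The published reference computation resolves a disk of radius 30 with
roughly $2.5\times10^5$ finite-element unknowns and runs for hundreds
of dimensionless time units; a single such run reportedly takes on the
order of a hundred CPU-hours.  This package's test suite and examples
instead use scaled-down study conditions chosen once: a 1D disk of
radius 15 with 60 cells (quarter-unit resolution) run to $t = 60$ for
scenario comparisons, therapy runs to $t = 170$ with the published
dosing schedule (ten doses, half-unit period) shifted nothing — therapy
still starts at $t = 100$ — and coarse 2D multi-seed runs on a disk of
radius 6 at 0.6-unit resolution with seed spacing 2 run to $t = 28$, so
lesions merge within the simulated window (a smaller disk of radius 5
brings the stress-free boundary close enough to reverse the comparison,
so the domain size is part of the stated conditions).  At these sizes the
qualitative phenomena of interest — the macrophage-mode ordering of
tumor growth, monotone parameter responses, the therapy-induced drop
and rebound of tumor burden and M2/M1 ratio, and the multi-seed
elevation of the M2/M1 ratio around lesion merging — are reproduced,
while quantitative magnitudes (absolute tumor burdens, the published
25%/50% multi-seed ratio-spike sizes, the 95% ratio reduction under
therapy) belong to the full-resolution setting and are not reproduced
at desk scale.  What passing tests show is therefore directional and
structural fidelity, not figure-level quantitative agreement.

The synthetic-state generator (`random_valid_state()`) produces smooth
positive fields with total concentration near one from a few low-order
cosine modes — adequate for exercising algebraic identities, solver
residuals, and positivity, but intentionally unlike real tumor
morphology: it has no sharp interfaces, no necrotic cores, and no
correlation between vasculature and oxygenation.  Properties verified
on such states (mass bookkeeping, maximum principles, determinism)
transfer to real runs because they are state-independent identities;
accuracy statements rest on the manufactured-solution cases instead.

## Known limitations

Chemicals do not advect (the published quasi-steady assumption), time
integration is first-order explicit, the 2D boundary treatment is
first-order on a staircase mask, and no adaptive refinement exists.
The drug's quasi-steady solve uses the instantaneous vascular
concentration at the current step time (the alternative, a
dose-interval average, is not what the schedule formula suggests).
T-cells, vascular heterogeneity, and classical activation are outside
the model's scope.
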