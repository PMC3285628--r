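---
title: "A bistable reaction-diffusion model of cell membrane polarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable reaction-diffusion model of cell membrane polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarisim)
```

## The model

Many polarity pathways share one architecture: a membrane-bound signaling
molecule with two interconvertible states (`X0` unactivated, `X*`
activated, pointwise total `X_tot`), switched by two counteracting
enzymes, `A` (activating) and `B` (deactivating), that shuttle between the
membrane and a well-mixed cytosolic reservoir.  `A` is recruited by
activated receptors and, through a reinforcing feedback loop, by `X*`
itself; `B` is recruited by `X0`.  Enzymatic conversion follows
Michaelis-Menten kinetics,

$$F = k_{catA}\,(a_R + a_X)\,\frac{x_0}{K_A + x_0}
    - k_{catB}\,b\,\frac{x^*}{K_B + x^*},$$

so that when both arms operate near saturation the cycle is
Goldbeter-Koshland ultrasensitive.  The lipid fields also diffuse
laterally (`D`), while the bound enzymes do not.  Cytosolic diffusion is
much faster than lateral membrane transport, so the cytosol enters only
as two scalar reservoirs coupled to the surface integrals of binding and
unbinding.

Because shuttling (rates `k_on`, `k_off`) is faster than conversion, the
bound-enzyme fields are slaved to the slow lipid fields: at the
quasi-steady state each bound density is proportional to its recruiter
times the free cytosolic concentration, and the free amounts follow in
closed form from enzyme conservation (`enzyme_equilibria()`).
Substituting these equilibria and the conservation law
`x* + x0 = X_tot` leaves a single relevant degree of freedom, the
activated fraction `phi = x*/X_tot`, obeying `dphi/dt = f(phi)` with

$$f(\phi) = \gamma\,(1 - \phi)\left[
  \rho\,\frac{\sigma + \phi}{\kappa_A + 1 - \phi}
  - \frac{\phi}{\kappa_B + \phi}\right],
  \qquad \kappa_{A,B} = K_{A,B}/X_{tot}.$$

Two reduced coordinates control everything: the **enzyme ratio**
$\rho = k_{catA}\tilde k_X c_A / (k_{catB}\tilde k_B c_B)$
(activating over deactivating strength, with
$\tilde k = k_{on}/k_{off}$ and $c$ the free cytosolic concentrations)
and the **renormalized signal**
$\sigma = \tilde k_R\, \rho_R / (\tilde k_X X_{tot})$, receptor-driven
recruitment measured in units of feedback-driven recruitment.  A
structural feature of this topology is that full activation
(`phi = 1`) is always an equilibrium - with no `X0` left, the
deactivating enzyme has no recruiter - so the activated-rich phase sits
exactly at `phi_plus = 1` and the interior equilibria solve a quadratic.
The package nevertheless locates equilibria by bracketed bisection on a
dense grid (`find_equilibria()`); the quadratic serves as an independent
cross-check in the test suite.

The effective potential $V(\phi) = -\int_0^\phi f$
(`effective_potential()`) is a bookkeeping device - it orders the
dynamics without measuring any consumed energy.  Bistability (two stable
phases separated by a barrier `phi_u`) exists for `rho` inside a
signal-dependent interval (`bistability_boundaries()`); the two phases
exchange stability across the **coexistence line** `rho_star(sigma)`
where the wells are equally deep (`coexistence_line()`, a Maxwell-type
equal-depth construction).  On a closed membrane the reservoirs supply a
global negative feedback: growth of the activated phase depletes free
`A` and releases `B`, driving `rho` toward `rho_star` ("self-tuning").
The equilibrium area fraction of the activated cap follows from the
sharp-interface partition of the conservation laws pinned to the
coexistence line (`patch_area_ratio()`).

```{r phase, fig.width = 6, fig.height = 4}
p <- polarity_params()
pp <- phase_portrait(2, 0.05, p)
plot(pp)
```

## Spatial solvers

`build_sphere_mesh()` subdivides an icosahedron, projects nodes onto the
sphere and assembles a cotangent-weight finite-element Laplace-Beltrami
stiffness matrix with a lumped (diagonal) mass matrix.  At subdivision
level 4 the smallest nonzero eigenvalue matches the spherical-harmonic
value $2/R^2$ to a relative error below $10^{-5}$.

`simulate_meanfield()` integrates the five membrane fields plus the two
reservoirs by Strang splitting:

* the enzyme-shuttling/reservoir subsystem is *linear* at frozen lipid
  fields, so it is advanced exactly (2-by-2 matrix exponential for the
  two bound-`A` totals, exponential forcing integrals per node) - no
  stiffness limit from the on/off rates;
* the conversion term uses an explicit midpoint rule;
* lateral diffusion is Crank-Nicolson with cached sparse Cholesky
  factorizations on a quantized step ladder.

Step size adapts by step doubling on the activated fraction (default
local tolerance `1e-6`; the scenario presets use `1e-5`).  Conservation
is exact by construction: the stiffness rows sum to zero, `x0` is stored
as the pointwise complement, and the reservoirs close the enzyme
budgets after every substep.  Poisson perturbation events are applied at
the first step boundary past their exact arrival times (the arrival
process itself is exact), which keeps the factor cache effective; both
event actions of the study protocols are supported - setting one node's
activated fraction (with the node's bound enzymes slaved to the new
lipid state, since a fluctuation into the activated phase carries its
enzyme complement) and multiplicative Gaussian perturbation.

`gillespie_run()` simulates the exact lattice master equation with the
mesh nodes as sites: Michaelis-Menten conversion propensities evaluated
on counts (Michaelis constants scaled by site area - an acknowledged
approximation at low copy numbers), binding propensities linear in the
integer reservoir counts, and per-molecule diffusion leave rate
`D * N / S` split evenly among neighbours.  The direct method is
implemented in C++ with Fenwick-tree bookkeeping; the reservoir-coupled
binding channels are factored (`total = W + A_cyt*CA + B_cyt*CB`) so a
reservoir change costs O(1).  The same seed reproduces the identical
event sequence.

## Scenario presets and their study conditions

The paper-scale parameter tables are not machine-readable here, so every
preset value was chosen once, as a realistic setting that demonstrably
realizes the intended regime (checked at load time), and is recorded
with a provenance note in `inst/extdata/presets/*.yaml`.  Internal units
are molecules, micrometres, seconds; the `chi` factor converts surface
densities into volume concentrations (`chi = S/V`), and 1 nM = 0.602
molecules/um^3 at the I/O layer.

**Defaults** (`polarity_params()`): R = 5 um, `X_tot` = 600 /um^2,
`K = 60` /um^2 (`kappa = 0.1`, firmly ultrasensitive), `k_on = 0.012`
um^3/s against `k_off = 1`/s, `A_tot` = 60k, `B_tot` = 120k,
`D = 0.1` um^2/s.  The recruitment strength was fixed by requiring the
equilibrium patch-area fraction to be almost independent of the signal
over at least two decades at each end of the range - the two plateaux of
the patch-area curve - which lands at `k_on X_tot S/V` of order 4 and an
activated cap near one quarter of the membrane.

**Chemotaxis** (mean-field, mesh level 4, R = 7 um, `k_cat = 2`/s,
`A_tot` = 70k, `B_tot` = 60k): stimulation switches on at `t = 5` s with
`sigma_on = 0.20` and adapts with `tau = 8` s to a 15% plateau
(`sigma_p = 0.03`).  The protocol realizes the two-stage signature: at
onset the low phase disappears (monostable activated regime) and the
uniform field rises; passage through the saddle-node ghost is slow, so
the rise stalls below the reborn barrier when adaptation pulls `sigma`
back, and the field falls back to the low phase.  At the plateau the
reservoir state sits deep in the bistable region
(`|delta_V|` two orders above the barrier), so the node-flip Poisson
noise (rate 0.02/s over the sphere, value `phi = 1`) seeds supercritical
germs; patches grow, the reservoirs tighten `rho` onto the coexistence
line (`|delta_V|` falls well below 1% of its post-nucleation value) and
coarsening leaves a single cap.  The run report detects stage 1 as the
mean's rise while the spatial variance stays below `1e-3` and stage 2 as
the first variance excursion above `0.02` after the uniform peak with
the mean below that peak.  With the event rate at 0.02/s roughly one
seed in ten nucleates so early that the detection overlaps the uniform
crest; the acceptance criterion therefore asks for 4 of 5 seeds.

**Epithelial** (mean-field, mesh level 3, `k_cat = 0.45`/s,
`D = 0.12` um^2/s, equal totals, constant `sigma = 0.05`): uniform
activated-rich start with an unactivated-rich germ placed by an active
process.  The sweep over germ radii classifies dissolved versus
polarized outcomes and brackets the critical radius (about 0.6 um).  The
final cap area is measured by the reservoir-consistent moment estimator
`S (mean(phi) - phi_minus)/(phi_plus - phi_minus)`: because the
converged equilibrium and the algebraic prediction are pinned to the
same coexistence condition and the interface is quasi-equatorial (no
curvature shift), this measure agrees with `patch_area_ratio()` to well
under one mesh cell, whereas raw above-threshold node counting is
limited by the boundary band (about perimeter times node spacing).  The
prediction is evaluated with the mesh's own total area, since the
inscribed triangulation is the membrane the solver conserves.
Catalysis and diffusivity were set together so the interface width
neither pins on the lattice nor carries a significant interface-mass
excess.

**Yeast** (stochastic, 162 sites, R = 2.5 um, `X_tot` = 200 /um^2): the
low-copy ladder (`A_tot` = 40/394/1970, i.e. 1/10/50 nM of GEF)
emulates the flickering limit - slow-cycling feedback arm
(`k_on_X = 2e-4` um^3/s), a large catalytic burst per binding event
(`k_cat = 100`/s), weak GAP pool - with the feedback dissociation rate
pre-solved at run time so 10% of the GEF is bound at the reference
state (`calibrate_bound_fraction()`).  A small constant basal
recruitment (`sigma = 0.01`, through the receptor channel) stands in
for spontaneous GEF membrane association; without it the zero-activity
state is absorbing and no sustained flicker is possible.  At 1 nM the
patch count returns to zero dozens of times per run; the persistent
regime (preset parameters: fast-cycling strong feedback, GAP pool 370)
holds exactly one multi-site cap through the final half of the run from
a heterogeneous germ at the incipient bud site.  Nanocluster flickers
are counted at single-site scale while persistence is judged at
cap scale (at least two connected sites); the two scales are genuinely
different objects in this regime.

**Ras** (stochastic, R = 2 um): two paired runs differing only in the
GEF total: inside the bistable region (with a germ) a stable signaling
domain persists to the end; outside it no activated patch survives the
persistence horizon.

## Numerical choices

* Root bracketing on 2048 grid intervals, bisection to `1e-12`;
  saddle-node loci by bisection on the stable-root count to `1e-8`
  relative; coexistence by log-bisection of `delta_V` to `1e-10`
  relative, with probes stepped 1% into the logarithmic width of the
  bistable interval (at the locus itself the merging roots are
  numerically indistinguishable).
* Potential by adaptive quadrature (`abs.tol = 1e-10`); `V(0) = 0`.
* Front speeds on a periodic ring from the growth rate of the total
  activated mass (exactly zero for the diffusion step, so the estimate
  is unbiased), with a two-front block initial condition.
* Coarse meshes underestimate the sphere area (24% for the raw
  icosahedron, under 0.5% from level 3); all reservoir couplings use
  the mesh's own node areas, and analyses that compare against
  idealized-sphere formulas state so explicitly.
* The stochastic engine uses R's RNG through the C++ core, one stream
  per run, seed recorded in the trajectory.

## What the synthetic protocols do and do not show

The generator-driven scenarios emulate the study conditions - idealized
spherical membranes, prescribed stimulation schedules, well-mixed
reservoirs, Poisson node-flip fluctuations.  They do not model receptor
adaptation mechanistically (it is imposed), actin-mediated transport,
membrane deformation, autocrine loops, or measured kinetic constants:
every preset value is an assumption, so passing tests certify the
mechanism (bistability, nucleation, coarsening, self-tuning) and the
numerics, not quantitative agreement with any particular cell type.
Known limitations: `phi_plus = 1` exactly (no basal deactivation
pathway), Michaelis-Menten propensities are a site-level approximation
at low copy numbers, and node-flip noise cannot seed germs below the
node scale, so nucleation thresholds on coarse meshes are
discretization limited.
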