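---
title: "Phase-field modelling of dynamin-driven tubule constriction and fission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field modelling of dynamin-driven tubule constriction and fission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the model implemented by **tubefission**, its
assumptions, the parameters that matter, the numerical choices behind the
solver, and what the package's synthetic test conditions do and do not
establish about real membranes.

## The physical problem

Dynamin is a GTP-hydrolyzing protein that polymerizes into a helix around
membrane tubules and necks (radii of roughly 10–30 nm) and constricts them
until the membrane severs.  The package models the in-vitro setting of a
long tubule pulled from a giant unilamellar vesicle: the vesicle acts as a
lipid reservoir and imposes a fixed surface tension $\gamma$, and one or
more dynamin coats of polymerization length $H$ wrap the tubule and load
it with an inward pressure generated by ratchet-like power strokes between
dimers of adjacent helix rungs.

The membrane is described at the mesoscale by Canham–Helfrich elasticity:
the energy of the midplane surface $\Gamma$ is

$$\mathcal H[\Gamma] = \frac{k_b}{2}\int_\Gamma (2M)^2\,dS
  + k_G\int_\Gamma G\,dS + \gamma\int_\Gamma dS,$$

with $M$ and $G$ the mean and Gaussian curvatures, bending rigidity
$k_b$, Gaussian modulus $k_G$ and tension $\gamma$.  A cylinder of radius
$R_{in}=\sqrt{k_b/(2\gamma)}$ minimizes this energy; the default
parameters ($k_b = 20\,k_BT$, $\gamma = 1.5\times10^{-4}$ N/m) give
$R_{in} = 16.6$ nm.  Because the Gaussian term is topological
(Gauss–Bonnet), a sharp-interface description cannot follow the membrane
through fission; the package therefore uses a diffuse-interface
(Ginzburg–Landau) representation in which a phase field $\phi(r,z)$
distinguishes the tubule interior ($\phi=+1$) from the exterior
($\phi=-1$) and the membrane is the smooth transition layer around the
$\phi=0$ level set.  The diffuse elastic energy

$$F_e = \underbrace{\frac{k_b}{2}\,\frac{3}{2\sqrt2\,\epsilon^3}
  \int_\Omega \psi_b^2\, dV}_{F_b}
  + \underbrace{k_G\,\frac{35}{16\sqrt2}\,\epsilon^3 \int_\Omega
  \psi_G\, dV}_{F_G}
  + \underbrace{\gamma\,\frac{3}{2\sqrt2\,\epsilon}\int_\Omega\!\Big[
  \tfrac14(\phi^2-1)^2+\tfrac{\epsilon^2}{2}|\nabla\phi|^2\Big] dV}_{F_\gamma},$$

with $\psi_b = \phi(\phi^2-1) - \epsilon^2\nabla^2\phi$ and $\psi_G$ a
combination of $|\nabla\phi|^2$ and its derivatives, converges to the
sharp functional as $\epsilon\to 0$ while remaining regular across
topological transitions.  The interface width is tied to the physical
bilayer: $6\epsilon = l_{me} = 5$ nm.

Constriction enters through an interaction energy
$I[\phi] = \int h(\phi)\,p\,dV$ with the mediating cubic
$h(\phi)=\frac34(\phi-\phi^3/3)$, which spreads the coat pressure
$p(r,z)$ across the interface width ($\frac34(1-\phi^2)|\nabla\phi|$
tends weakly to the surface delta function).  The system relaxes by
Allen–Cahn (maximum-dissipation-rate) dynamics

$$\frac{\partial\phi}{\partial t} = -M_{pf}\Big(
  \frac{\delta F_e}{\delta\phi} + \tfrac34(1-\phi^2)\,p\Big),$$

an overdamped gradient descent whose clock is set by the mobility
$M_{pf} = 4.04\ \mathrm{nm^3/(s\,k_BT)}$ (sharp-interface counterpart
$M_{sharp} = 3\epsilon M_{pf}/\sqrt8 = 3.57\ \mathrm{nm^4/(s\,k_BT)}$).

## The dynamin pressure model

A coat is reduced to its mesoscale geometry: length $H$, pitch $h=10$ nm,
$N_d=13$ dimers per turn, and the tangential power-stroke force
$F_\tau\approx 2.5$ pN.  The chain tension built up by the power strokes
loads the membrane with

$$p(r,z) = \frac{N_d F_\tau}{h\,r}\; A(z)\; C(r),$$

exactly $N_dF_\tau/(hr)$ on the coat interior.  Two shape functions are
not fixed by the mesoscale argument and are the package's own surrogates:

* **Axial taper $A(z)$** — the tension builds up in the two extremal
  rungs and is constant in the inner ones, so $A$ is a smooth half-sine
  ramp of width one pitch centered on each coat edge.  With this choice
  $\int A\,dz = H$ exactly for $H \ge$ one pitch.  Coats shorter than a
  full turn get a reduced peak (and a warning): the chain argument needs
  at least one closed turn.
* **Radial cutoff $C(r)$** — the helix cannot follow the tubule below a
  maximum admitted curvature, around $R_{cut}=3$ nm of tubule radius, so
  the pressure fades to zero there.  $C$ is a tanh ramp of width
  $w = 0.28$ nm centered at $R_{cut}-3w$, times a Gaussian axis factor
  that makes $p\to0$ monotonically at the axis.  The center placement
  matters: the tubule's unforced neck-collapse radius (measured in this
  model by relaxing pre-constricted necks) is 2.0–2.9 nm, and the
  long-coat constriction equilibrium is $R_c=\sqrt{k_b/(2\bar\gamma)}
  \approx 3.5$ nm, so a cutoff that throttles the pressure already at
  3–3.5 nm leaves the neck stranded in a mechanical equilibrium just
  above the collapse radius and fission never occurs.  Keeping $C\approx 1$
  down to $\approx 2.7$ nm lets the coat push the neck into the collapse
  region, reproducing the observed phenomenology (fission for all
  sufficiently long coats).  Results are otherwise insensitive to the
  exact ramp shape.

On fission the dynamin polymers disassemble: coats overlapping the
fission site are deactivated and their pressure is removed, with no
depolymerization energy deposited on the membrane.

## Numerical implementation

* **Grid and boundary conditions.** All fields live on a homogeneous
  cell-centered $(r,z)$ lattice; the axis $r=0$ is never sampled.  z is
  periodic (Fourier); r uses an even mirror extension across the axis
  onto a $2N_r$ periodic domain (odd extension for radial vector
  components), which realizes a zero-normal-derivative outer wall.
  Derivatives are evaluated by FFTW real-to-complex transforms; the
  Laplacian of a tanh tubule profile matches the analytic derivative to
  better than $10^{-6}$ relative at the production spacing.  The
  boundary conditions are a package choice (the natural
  FFT-compatible pair); runs warn when the field fails to reach bulk at
  the outer wall or a coat sits within five elastic decay lengths
  ($\sqrt2 R_{in}$) of the z boundary.
* **Time stepping.** Semi-implicit Euler: the constant-coefficient
  stiffest part of the elastic force,
  $c_b(m_4\epsilon^4\nabla^4 - a_2\epsilon^2\nabla^2) -
  c_\gamma \epsilon^2\nabla^2$ with $c_b = 3k_b/(2\sqrt2\epsilon^3)$,
  is treated implicitly in Fourier space (defaults $m_4=3$, $a_2=2$);
  all nonlinear and forcing terms are explicit.  The quartic implicit
  coefficient additionally gets a state-adaptive boost proportional to
  $\max|\nabla\phi|^2$, covering the Gaussian-force stiffness that grows
  as the two lumen walls merge at pinch-off.  The implicit symbol
  vanishes as $k\to0$, so slow shape modes are integrated without bias;
  the step is then capped by the explicit bulk reaction rate at
  $dt \lesssim 2/(4 M_{pf} c_b)$ ($\approx 3\times10^{-3}$ s at default
  parameters), and the default takes 85% of that cap.  An adaptive
  controller halves the step when the per-step field change exceeds a
  target (the fast pinch-off stage).
* **Time accuracy.** The scheme is first-order in time, and the
  stabilizer damps the update of interface-profile modes by
  $1/(1 + dt\,M_{pf}\hat A(k))$, which at the throughput step slows the
  interface motion appreciably (the uniform-pressure wall velocity
  reaches its exact value $v = M_{sharp}\,p$ only as $dt \to 0$).
  Quasistatic path quantities — activation energies, critical radii,
  neck counts — are insensitive (the H = 20 nm activation energy moves
  by 2% under step halving), but *fission times* inflate by tens of
  percent at the default step.  Time measurements therefore use
  $dt \lesssim 7\times10^{-4}$ s, and the convergence test halves the
  step from $3.5\times10^{-4}$ s on a short tubule.
* **De-aliasing.** The Gaussian-curvature force contains products of up
  to fifth order in $\phi$ and its derivatives; without treatment their
  aliasing drives a spurious grid-scale interface instability (it grows
  at small $dt$ and is seeded by any forcing).  The 2/3-rule spectral
  truncation removes it and is therefore on by default, exposed as a
  stepper option.
* **Gaussian variational force.** $\delta F_G/\delta\phi$ is assembled
  from the analytic variation of the $\psi_G$ density as
  $-2\nabla\!\cdot\!(B\nabla\phi) - \nabla\!\cdot\!(q\nabla L - L\nabla q)
  + \nabla^2(2qL - \nabla q\cdot\nabla\phi)
  - \nabla^2(\nabla\!\cdot\!(q\nabla\phi))$
  with $q=|\nabla\phi|^2$, $L=\nabla^2\phi$,
  $B = 2L^2 + 2\nabla\phi\cdot\nabla L - 2\nabla^2 q$.  The algebra is
  internal; the contract is the directional-derivative test (agreement
  with a centered finite difference of the functional to $10^{-5}$
  relative), which the test suite enforces.
* **Degenerate inputs.** Columns with no $\phi=0$ crossing are "closed"
  (post-fission); multiple radial crossings take the outermost one (the
  membrane midplane).  Neck detection requires 0.5 nm of prominence, so
  grid-scale ripples are never counted as necks.

## Observables

The neck is the site of maximum constriction ($R_n$ = minimum midplane
radius); the critical state of a fission run is the maximum-$F_e$ state
preceding fission (no fission, no critical state), and its energy above
the unperturbed tubule is the activation energy.  Fission is flagged when
the $\phi>0$ phase disconnects along the axis — a single-field model
cannot distinguish hemifission from full fission, so this is the
model's fission event.  The normalized lumenal conductance uses a
series-resistor model with a Debye-corrected conducting radius
$r_{lum} = \max(0, r_{mid} - l_{me}/2 - \lambda_D)$, $\lambda_D = 1$ nm
by default; since only the ratio $G_n(t)=G(t)/G(0)$ is reported, the
leading dependence on the exact correction cancels, but $G_n$ reaches
zero slightly before the fission event (when the corrected lumen closes).

## Problem sizes and what the tests show

Production geometry is the 30 × 1400 nm domain with 108 × 5040 cells
(spacing $\epsilon/3$), available as `production_config()`.  The test
suite and the acceptance script use a reduced desk-scale geometry,
`reduced_config()`: 24 × 300 nm by default at 0.4 nm spacing
($\approx\epsilon/2$, still inside the resolution bound
$dx \le \epsilon/2$), which keeps a single coat at least five decay
lengths from the boundaries for $H \lesssim 45$ nm and cuts the cost
about twenty-fold; the reproduction runs trim the axial extent further
(256–280 nm, still beyond coat + 10 decay lengths).  Energy-level
checks (sharp-limit cylinder and sphere energies, Gauss–Bonnet
constancy) are run on small dedicated boxes at spacing $\epsilon/3$.

Two deliberate substitutions keep expensive checks at desk scale and are
worth knowing about:

* The weak-forcing comparison against linearized elasticity is made at a
  matched finite time using the mode-wise linear relaxation
  $\hat u_k(t) = \hat u_k^{eq}\,(1 - e^{-\lambda_k t})$,
  $\lambda_k = M_{sharp} k_b (k^4 + R_{in}^{-4})$, rather than at full
  equilibrium: the equilibration time of the weakly forced long-wave
  problem ($\sim(M_{sharp}k_b/R_{in}^4)^{-1}$, tens of minutes of
  simulated time) is far beyond desk scale, and the finite-time
  comparison is the stricter check (it also validates the
  diffuse-to-sharp mobility mapping).
* The neck-splitting threshold $H^\*$ is bracketed by the single-neck
  critical state at $H = 20$ nm and the two-neck one at $H = 45$ nm
  rather than bisected to exhaustion (a 5-nm bisection costs about six
  full constriction runs); the bisection machinery itself is exercised
  against the linearized model, whose closed-form threshold
  $H^\*_{l.e.} = 2\sqrt2\pi R_{in}$ provides exact ground truth.
* Repeated reproduction runs use *continuation starts*
  (`reduced_config(constrict_start = ...)`): the initial contour is
  pre-constricted under the coat (to 10–12 nm), shaped like the linear tubule response
  so the run joins the quasistatic energy valley after a short
  transient.  The critical (activation) state is a saddle of the energy
  landscape and does not depend on where along the valley the descent
  started, as long as the start lies above the critical radius; the
  critical-state tracker resets at each new pre-fission minimum of
  $F_e$, so the transient cannot corrupt the maximum.  This was
  validated against a full run from the undisturbed tubule at
  `H = 20` nm (same critical neck structure; activation energy within a
  few $k_BT$).  Fission *times* are only ever measured on full runs from
  the undisturbed configuration.

The synthetic conditions emulate clean, axisymmetric, tension-controlled
tubules with a preassembled, rigid, non-dynamic coat and no thermal
fluctuations, no hydrodynamics and no lipid-number conservation
(the reservoir assumption).  Passing tests therefore establish the
internal consistency of the elastic model and its numerics, and
agreement with the printed mesoscale theory — not the behavior of any
specific lipid mixture, of crowded membranes, or of dynamin mutants.

## Known limitations

* The exact axial and radial pressure profile shapes are surrogates
  (documented above); only their robustness class is supported.
* Hemifission and leakage pathways are outside a single-field model.
* The fission-time formula $t_f = \alpha(F_\tau)\,
  \frac{R_{in}^2}{2M_{sharp}}\,\frac{\gamma+\bar\gamma}{\bar\gamma^2}$
  is a long-coat result; for short coats the package reports measured
  times only.
* Absolute conductances (in siemens) are not modelled, only the
  normalized trace.

## A worked mini-example

```{r example}
library(tubefission)

pars <- elastic_params()            # k_b = 20 k_BT, gamma = 1.5e-4 N/m
pars$R_in                           # 16.56 nm

coat <- dynamin_coat(H = 20, z0 = 128)
sharp_prediction(pars, coat)        # R_c ~ 3.5 nm, H*_le ~ 147 nm, ...

cfg <- reduced_config(H = 20, L_z = 256,
                      stepper = time_stepper(dt = 3.1e-3))
traj <- run_simulation(cfg)         # ~10 min on one CPU
critical_state(traj)                # activation energy, neck structure
```
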