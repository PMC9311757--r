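---
title: "Predicting porin permeation from free-energy profiles"
author: "porinflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting porin permeation from free-energy profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porinflux)
```

## The problem

Small molecules — antibiotics and beta-lactamase inhibitors among them —
cross the outer membrane of Gram-negative bacteria mostly through porins
such as OmpF: hourglass-shaped beta-barrel channels whose constriction
region carries a strong transversal electric field.  Two geometric and
electrostatic properties of the permeant govern how easily it passes: how
small a cross-section it can present (its *minimal projection area*, MPA)
and how well its electric dipole can align with the transversal field (its
*transversal dipole moment*).  Molecular simulation gives access to both,
and to the free-energy landscape of the crossing itself; this package
implements the post-simulation analysis that turns those raw outputs into
measurable predictions: translocation currents, saturation concentrations
and dwell times.

The pipeline has three stages, each usable on its own:

1. **Descriptors** (`computeDescriptors()`): per-conformer MPA, minimum
   radius $R_\mathrm{min} = \sqrt{\mathrm{MPA}/\pi}$, dipole vector, and
   the transversal dipole component, summarized over a solution ensemble.
2. **Free-energy reduction** (`marginalizeFES()`): a 2D metadynamics
   surface $F(\mathrm{CV1}, z)$ over an orientation variable and the
   channel axis is Boltzmann-averaged to a 1D potential of mean force
   $F(z)$ referenced to the bulk.
3. **Transport** (`permeability()`, `ratesFromFES()`, `currentCurve()`):
   a Kramers-type integral gives the linear-regime permeability; a
   single-occupancy two-state Markov model extends it to saturating
   concentrations and dwell times.

## Descriptors

The projection area along a direction $\hat n$ is the area of the union
of the van der Waals disks obtained by projecting every atom onto the
plane normal to $\hat n$.  Published MPA pipelines often delegate this to an
external program; here the convention is fixed explicitly: **union of
projected vdW disks**, computed by slicing the plane and merging the
chords each disk cuts on a slice.  The slicing is exact in one dimension
and a midpoint quadrature in the other; at the default resolutions the
relative area error is well below 0.2% (the tests compare against a
Monte-Carlo point-in-union oracle).

The MPA minimizes this area over directions.  The search uses a Fibonacci
hemisphere grid (default 512 directions, antipodes identified) followed by
Nelder-Mead refinement in spherical angles from the six best grid
directions.  Multi-start refinement matters: for branched clusters the
area landscape over directions is multimodal, and a single local descent
can miss the global minimum by several percent.  Ties are broken by the
first direction found.

The dipole is $\vec\mu = \sum_i q_i (\vec r_i - \vec r_0)$ in Debye
(1 e·Å = 4.8032 D).  For neutral molecules $\vec\mu$ is origin
independent; for net-charged species (vaborbactam-like anions) it is not,
and the package defaults to the **centre of mass** and records the
convention in the output metadata.  Published dipole means for charged
species are therefore not exactly recomputable unless the source states
its origin convention — a genuine ambiguity, not a defect of either side.
The transversal dipole is $|\vec\mu - (\vec\mu\cdot\hat n)\hat n|$ with
$\hat n$ the MPA axis.

Distribution summaries use fixed-width histograms (0.1 Å for
$R_\mathrm{min}$, 1 D for dipoles, matching the precision such tables are
reported at).  Modes are bin centres of local density maxima whose
topographic prominence exceeds 1% of the peak density, so genuinely
bimodal ensembles (extended vs compact conformer populations) report both
modes while bin noise is ignored.

The pore-size profile mirrors the molecule-side convention: per z-slice,
the area accessible to a probe of radius 1.4 Å inside a circular outer
boundary, converted to an equivalent radius.  The definition is
purely metric (no connectivity test); choosing the outer boundary at the
atoms' radial extent keeps the outside of an enclosing ring from being
counted, which the ring test verifies against a Monte-Carlo rasterization.

## Free-energy reduction

The 1D profile is
$$F_{1}(z) = -k_BT \,\ln \int e^{-F(\mathrm{CV1},z)/k_BT}\,
  d\mathrm{CV1},$$
evaluated with trapezoidal weights and log-sum-exp stabilization, then
shifted so the declared bulk windows average exactly zero.  Choices made
where the source material is silent:

* **Bulk windows** default to the outer 20% of the z range at each end;
  both are averaged jointly, and an asymmetry larger than 0.5 kT between
  the two plateaus raises a warning rather than an error (real surfaces
  are rarely perfectly converged on both sides).
* **Channel interval** $[z_\mathrm{cis}, z_\mathrm{trans}]$: the
  outermost z where $|F|$ first exceeds 0.5 kT moving inward from each
  bulk window; overridable in the transport configuration.
* **Masked cells** (non-finite grid values) are excluded with measure
  renormalization; a column more than half masked is flagged, a fully
  masked column is an error.
* Energy is kcal/mol throughout with $k_B = 0.0019872$ kcal/mol/K, so
  $k_BT = 0.59616$ kcal/mol at 300 K.

Marginalization is gauge invariant (an additive constant on the 2D
surface cancels in the referencing) and reduces exactly in the separable
case — both are tested, the latter against the generator's analytic
ground truth.

## Transport

With the profile referenced to bulk, the linear-regime permeability is
$$P = \frac{D\,\sigma_\mathrm{ref}\,\gamma}
  {\int_{z_\mathrm{cis}}^{z_\mathrm{trans}} e^{F(z)/k_BT}\,dz},$$
where $\gamma = 6.0221\times10^{-4}$ molecules/Å$^3$ per mol/L converts
molarity to number density and $\sigma_\mathrm{ref}$ converts a 3D
concentration into a 1D boundary density.  $\sigma_\mathrm{ref}$ defaults
to the area of the 17 Å cylinder within which the simulated molecules
were restrained ($\pi\cdot17^2$ Å$^2$): the conversion is not stated in
the source material, so it is an explicit, logged parameter rather than a
hidden constant.  The default diffusion constant is the literature's
single effective value, $D = 1$ nm$^2$/ns; position-dependent $D$ is out
of scope.  The integral is evaluated in log space, so high barriers never
overflow.

The finite-difference Smoluchowski solver is the internal brute-force
check on that integral.  One subtlety: the Dirichlet data are imposed on
$u = \rho\,e^{F/k_BT}$ (continuity with the bulk reservoir, where $F = 0$
makes $u$ the bulk density) rather than on $\rho$ itself.  Because the
channel ends are *defined* at $|F| = 0.5\,k_BT$, a plain density clamp
there would disagree with the permeability integral by
$e^{\pm 0.5} \approx 65\%$; the reservoir-continuity condition is the
physically consistent choice and reduces to the density clamp whenever
the ends sit at $F = 0$.

The two-state (empty/occupied) single-occupancy channel model provides
the saturating regime.  Its ingredients:

* **Occupied state**: the deepest well inside the channel; wells within
  0.5 kT of the deepest are disambiguated by width (widest wins, with a
  warning); a profile with no well uses its deepest interior point and is
  flagged.
* **Escape**: the mean first-passage time from the well to the two
  channel ends, by the standard double quadrature of the adjoint
  equation; the splitting probabilities
  $\varphi_\mathrm{trans} = \int_{z_\mathrm{cis}}^{z_w} e^{\beta F}\big/
  \int_{z_\mathrm{cis}}^{z_\mathrm{trans}} e^{\beta F}$ divide it into
  $k_\mathrm{off}^\mathrm{side} = \varphi_\mathrm{side}/\tau$.
* **Entry**: fixed by linear-regime consistency,
  $k_\mathrm{on}^\mathrm{cis} = P\,(k_\mathrm{off}^\mathrm{cis} +
  k_\mathrm{off}^\mathrm{trans})/k_\mathrm{off}^\mathrm{trans}$ (and the
  mirrored expression), so the low-concentration slope of the Markov
  current equals $P$ by construction.  Whether published curves use this
  construction or an independently computed on-rate is not recoverable;
  the convention is flagged in the rate-set metadata.
* **Current**:
  $$I = \frac{k_\mathrm{on}^\mathrm{cis} c_\mathrm{cis}
    k_\mathrm{off}^\mathrm{trans} - k_\mathrm{on}^\mathrm{trans}
    c_\mathrm{trans} k_\mathrm{off}^\mathrm{cis}}
    {k_\mathrm{on}^\mathrm{cis} c_\mathrm{cis} +
     k_\mathrm{on}^\mathrm{trans} c_\mathrm{trans} +
     k_\mathrm{off}^\mathrm{cis} + k_\mathrm{off}^\mathrm{trans}},$$
  saturating at $I_\mathrm{max} = k_\mathrm{off}^\mathrm{trans}$ with
  half-saturation $K_{1/2} = (k_\mathrm{off}^\mathrm{cis} +
  k_\mathrm{off}^\mathrm{trans})/k_\mathrm{on}^\mathrm{cis}$.
* **Dwell time**: $\tau_b = 1/(k_\mathrm{off}^\mathrm{trans} +
  k_\mathrm{off}^\mathrm{cis})$, which is exactly the mean escape time.

The second brute-force oracle is a continuous-time Markov chain on the
discretized profile, with detailed-balance rates
$k_{i\to i\pm1} = (D/h^2)\,e^{-(F_{i\pm1}-F_i)/2k_BT}$ and absorption
beyond both ends, simulated in compiled code under R's RNG.  The oracle
check uses a moderate profile (2 kcal/mol shoulders around a 2.5 kcal/mol
central well) and a lattice of ~100 points: at that resolution the
chain-discretization bias is well below the 2% comparison band while
$10^5$ trajectories stay cheap.  Steep profiles would need a finer
lattice, which is why the oracle is a validation tool, not the production
path.

Units are Å/ns/kcal·mol$^{-1}$ internally and s$^{-1}$, M in every
reported rate; all conversion constants are single-sourced in
`permConstants()` and covered by a dedicated test.

## What the synthetic generator emulates — and what it does not

`simulateConformers()` produces rod, flexible-chain and compact-cluster
ensembles with controllable elongation, per-atom charges and angular
flexibility; `simulateFES()` produces 2D surfaces with flat bulk plateaus
(exactly zero over a stated width at both z ends), a Gaussian central
barrier at the constriction ($z = 0$, increasing cis → trans), optional
affinity wells and seeded band-limited roughness.  Separable surfaces
carry their analytic marginal as ground truth; the CV1 confinement term
is Boltzmann-centred so it never shifts the marginal.

These fixtures establish that the machinery is correct, not that real
molecules behave like rods: no force field is sampled, conformer frames
are equally weighted (plain MD convention), roughness is a stand-in for
metadynamics convergence error with no claim about its statistics, and
surfaces are taken as given with no bias correction.  Passing tests
therefore validate the *analysis*, while conclusions about a real
permeant still inherit the quality of its simulated ensemble and surface.

A further known limitation: the restraint cylinder implies an entropic
relation between the restrained free energy and bulk concentration; since
published profiles rarely state whether it is included,
$\sigma_\mathrm{ref}$ is exposed instead of guessed, and absolute
currents scale linearly with it.

## Problem sizes and the demo

The shipped defaults are sized for a desk run: 1D profiles on ~500-point
grids, 2D surfaces around $41\times121$, the finite-difference oracle at
2000 points, the CTMC oracle at $10^5$ trajectories, and the MPA
direction search at 512 directions — the full test suite and the
three-molecule demo each complete in about a minute on one CPU.
`runPipeline()` ties the stages together for three synthetic molecules
with decreasing central barriers (5, 4, 3 kcal/mol) where only the third
carries a 2 kcal/mol affinity well: the predicted low-concentration
currents order C > B > A (Arrhenius in the barrier) while C saturates at
the lowest concentration (its well depresses
$k_\mathrm{off}^\mathrm{trans}$, hence $K_{1/2} =
k_\mathrm{off}^\mathrm{trans}/P$ falls) — the qualitative pattern
reported for taniborbactam, QPX7728 and vaborbactam.

```{r demo, eval = FALSE}
out <- tempfile("demo")
rep <- runPipeline(list(outputDir = out, seed = 1))
rep$currents$ordering   # "C" "B" "A"
```
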