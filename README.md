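# porinflux

Post-simulation analysis of small-molecule permeation through bacterial
porins (OmpF-like channels), for computational chemists and channel
biophysicists who have molecular-dynamics / metadynamics output in hand
and want permeation observables out: translocation currents versus
concentration, saturation constants, and channel dwell times, plus the
conformational descriptors (minimal projection area, transversal dipole)
that rationalize them.

## What it computes

**Descriptors.** For each conformer of a solution ensemble: the minimal
projection area MPA (smallest area of the union of projected van der
Waals disks, minimized over projection directions), the minimum radius
R<sub>min</sub> = √(MPA/π), the electric dipole μ = Σ qᵢ(rᵢ − r₀) in
Debye, and the transversal dipole |μ − (μ·n̂)n̂| with n̂ the MPA axis.
Ensemble summaries report means, fixed-width histograms and (possibly
multiple) modes. A probe-accessible pore-size profile gives the channel
side of the same comparison.

**Free-energy reduction.** A 2D surface F(CV1, z) over an orientation
collective variable and the channel axis is reduced by Boltzmann
averaging,

&nbsp;&nbsp;F₁(z) = −k_BT ln ∫ e^(−F(CV1,z)/k_BT) dCV1,

log-sum-exp stabilized, then referenced so the bulk plateaus average
zero; wells, the channel barrier and 2D saddle points are extracted.

**Transport.** The linear-regime permeability is a Kramers-type integral
over the channel interval,

&nbsp;&nbsp;P = D σ_ref γ / ∫ e^(F(z)/k_BT) dz,

and a single-occupancy two-state Markov channel extends it to
saturation: exit rates from the mean first-passage time out of the
deepest channel well split by the splitting probabilities, entry rates
fixed by linear-regime consistency, current
I(c) saturating at I_max = k_off^trans, half-saturation
K₁/₂ = (k_off^cis + k_off^trans)/k_on^cis, dwell time
τ_b = 1/(k_off^trans + k_off^cis). Two brute-force oracles — a
finite-difference Smoluchowski solver and a compiled continuous-time
Markov-chain simulator — validate the integral and the rates in the test
suite.

A synthetic-data module (`simulateConformers()`, `simulateFES()`,
`syntheticProfile()`) generates ensembles and surfaces with analytic
ground truth, so the whole pipeline is testable without external data.

## Worked example

A 3 kcal/mol central barrier with a 2 kcal/mol affinity well on the cis
side (the high-affinity, low-barrier pattern):

```r
library(porinflux)

p <- syntheticProfile(barrierHeight = 3,
                      wells = data.frame(depth = 2, z = -5))
p
#> FES1D: 501 z points in [-25, 25] A, T = 300 K
#>   channel [-10.30, 8.50] A; max F in channel 2.637 kcal/mol
#>   features: well(-6.6 A, -0.97), barrier(1.0 A, 2.64)

cc <- currentCurve(p, transportConfig())   # D = 1 nm^2/ns, sigma = pi*17^2
cc
#> CurrentCurve: 60 concentrations in [1e-07, 0.1] M
#>   P = 1.569e+08 /s/M, Imax = 1.574e+07 /s, K_half = 0.1004 M

markovCurrent(cc@rates, 1e-6)
#> [1] 156.8491
```

Reading: the permeability P ≈ 1.6×10⁸ s⁻¹M⁻¹ means ~157 molecules/s
cross at a 1 µM gradient; the current stays linear until concentrations
approach K₁/₂ ≈ 0.1 M, where single-file occupancy caps it at
I_max = k_off^trans ≈ 1.6×10⁷ s⁻¹; the dwell time
`dwellTime(cc)` ≈ 2.3×10⁻¹⁰ s is far below the resolution of standard
single-channel electrophysiology — the regime where simulation-based
prediction is the practical tool.

Descriptors on a synthetic flexible chain with terminal ±0.5 e charges:

```r
ens <- simulateConformers("flexible_chain", nAtoms = 12,
                          flexibility = 0.2, nFrames = 20, seed = 1,
                          charges = c(0.5, rep(0, 10), -0.5))
rec <- computeDescriptors(ens, nDirs = 128)
summarizeDescriptor(rec$rmin, binWidth = 0.1)
#> DescriptorSummary: mean 2.21, mode(s) 2.15, 2.45 (bin width 0.1)
```

The longitudinal dipole of this rod-like chain barely projects into the
MPA plane (`mean(rec$dipoleXY)` ≈ 0.3 D against a ~38 D total) — the
geometric signature of a dipole that cannot align with a transversal
channel field.

`runPipeline(list(outputDir = "out", seed = 1))` runs the full
three-molecule demo (descriptors → marginalization → currents) and
writes per-stage files plus a provenance-stamped JSON report.

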