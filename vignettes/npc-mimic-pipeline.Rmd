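---
title: "Methods: modelling transport through biomimetic nuclear pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling transport through biomimetic nuclear pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcmimic)
```

`npcmimic` models an optical single-molecule transport assay: nanopores
(35–160 nm) in a ~90 nm freestanding palladium membrane are coated with the
FG-nucleoporin Nsp1, and translocations of labeled proteins (the transport
receptor Kap95, the inert probe BSA) are detected one molecule at a time as
fluorescence bursts at the pore exit. Because the metal membrane acts as a
zero-mode waveguide (ZMW), excitation is confined to an evanescent region
near the aperture and the emitters' photophysics is modified by the metal.
This vignette documents the models, the parameters that matter, and the
choices made where the design was genuinely open.

## Burst detection

Photon arrival times on each channel are treated as a piecewise-homogeneous
Poisson process. `detect_change_points()` performs recursive binary
segmentation: in a segment of $N$ photons spanning time $T$, the candidate
split after photon $k$ maximizes the generalized log-likelihood ratio
$$\Lambda(k) = k\ln(k/T_1) + (N-k)\ln\!\big((N-k)/T_2\big) - N\ln(N/T),$$
and the split is accepted when $2\Lambda$ exceeds the $\chi^2_1$ critical
value at level $\alpha/(N-1)$ (Bonferroni over the candidate positions;
default $\alpha = 0.01$). Segment boundaries always coincide with photon
arrival times. The background rate is the duration-weighted median of
segment rates — robust because bursts occupy a small fraction of the
measurement time — and a segment is retained as a burst when its mean rate
is at least `bg_rate_factor` (default 3) times the background and it
carries at least `min_event_photons` photons (default 5; we use 10–20 for
very bright bursts to suppress double-counted edge fragments). Adjacent
bursts are deliberately never merged, so re-entries of the same molecule
count as separate events.

Two properties of this detector matter for its use:

* **Calibration.** The per-test significance is controlled; on
  constant-rate streams the fraction of runs with any reported change point
  stays at or below $\alpha$.
* **Sensitivity is local.** A single-split statistic compares average rates
  of the two halves, so a short, rare spike diluted in a very long
  homogeneous segment produces only a small $\Lambda$ even when the spike
  itself is intense. The detector is therefore calibrated for records in
  which bursts are locally prominent — low background between events, or
  event rates high enough that segments between bursts stay short. This is
  the regime of the actual assay (hundreds of photons per molecule over
  millisecond transits on a sub-kHz background); the rate-calibration test
  uses exactly such a condition (20 s records, 50 Hz background per
  channel, 1 Hz events of $2\times10^5$ photons/s and 5 ms mean duration),
  mirroring measurements in which the labeled fraction is diluted to keep
  events well separated.

Event rates assume translocations follow Poisson statistics:
$k = n/T$, $\mathrm{sd} = \sqrt{n}/T$. Molecular-brightness QC compares the
mean photons per event to a reference and flags datasets deviating by more
than 30% (tolerance configurable), since drifting brightness biases
detection. Fluorescence lifetimes come from a maximum-likelihood
mono-exponential tail fit that ignores the first 1.160 ns of the decay (to
avoid the instrument response) and corrects for truncation at the end of
the TCSPC window: the MLE solves
$\bar{s} = \tau - W e^{-W/\tau}/(1 - e^{-W/\tau})$ for shifted times $s$
and truncated support $W$.

## Transport analysis

Measured event rates are normalized by species concentration, degree of
labeling (1.0 for BSA, 0.7 for Kap95 by default), and labeled fraction
(0.2 when labeled protein is mixed 1:4 with unlabeled protein, as done for
large pores); an optional factor $1/0.95$ undoes the ~5% rate reduction
caused by the applied detection-side flow. Per-pore means carry the
standard error of the mean over conditions, and the selectivity ratio
$k_\mathrm{Kap95}/k_\mathrm{BSA}$ propagates relative errors in quadrature.

Free diffusion through a cylindrical pore gives
$\kappa = \pi r^2 D \Delta c / L$; as a function of pore radius the
normalized rate is fitted as $k = \alpha (r - r_\mathrm{prot})^2$, where
subtracting the protein radius accounts for the excluded rim of the pore.
Default probe radii are 3.4 nm (BSA) and 4.5 nm (Kap95) — hydrodynamic
estimates, configurable. For coated pores an onset shift $b$ is added,
$k = \alpha (r - r_\mathrm{prot} - b)^2$ with $b \ge 0$; $b$ measures how
much of the radius the coating renders inaccessible. The fit is weighted
least squares (weights $1/\mathrm{sem}^2$, zero-sem points get the median
weight) via Levenberg–Marquardt with a bound at $b = 0$; the boundary
solution is always compared explicitly so the nested model reduces exactly
to the plain quadratic fit, and parameter SDs come from the linearized
covariance at the optimum.

Kap95-concentration dependence is summarized by the ratios
$k_{\mathrm{BSA},100}/k_{\mathrm{BSA},0}$ and
$k_{\mathrm{BSA},1000}/k_{\mathrm{BSA},0}$ per pore and per diameter class
(small < 50 nm, intermediate 50–60 nm, large ≥ 60 nm — reported
separately because the behavior changes qualitatively around the mesh
transition).

For large coated pores we use a selective-area model: each grafted chain
renders a volume near the wall selective, giving an annular selective area
fraction $f = \min(2\sigma_V/r, 1)$ with a single parameter $\sigma_V$, the
effective selective-layer thickness. The apparent selectivity of a pore
that splits into a selective area (selectivity $s_\mathrm{sel}$, taken from
small coated pores) and an open-like area ($s_\mathrm{open}$) is computed
by default with the harmonic rule
$$s_\mathrm{app} = \frac{1}{f/s_\mathrm{sel} + (1-f)/s_\mathrm{open}},$$
which follows from assuming BSA fluxes add per area while the Kap95 flux is
uniform over the cross-section (Kap95 transport is empirically unaffected
by the coating). This mixture rule is a modelling choice; an arithmetic
alternative ($s_\mathrm{app} = f s_\mathrm{sel} + (1-f) s_\mathrm{open}$)
is available behind the `mixing` switch. $\sigma_V$ fits weight points by
their propagated selectivity errors when available.

## Void analysis

The permeability of the fluctuating mesh is estimated without simulating
translocations. Space is divided into cubic voxels (side 0.6 nm); for each
configuration a voxel is *available* to a spherical probe when no bead
center lies strictly within (probe radius + bead radius) of the voxel
center, and, inside the membrane span, when the probe fits inside the
lumen ($r_{xy} \le R - r_\mathrm{probe}$). The scaffold wall and metal slab
are treated as continuum geometry, evaluated slice-wise; the per-bead
neighbor search touches only a bounded sub-block of the grid and is
exactly equivalent to an all-pairs distance check (verified against a
brute-force oracle in the tests).

Per z-slice, the reported occupancy is the available fraction of the
analysis mask: the pore cross-section inside the membrane (the metal
volume is excluded), the full box cross-section in the bulk. For an open
pore this reproduces the annulus formula
$\big((R - r_\mathrm{probe})/R\big)^2$. The Boltzmann inversion, however,
acts on the *absolute accessible area* per slice relative to the bulk
reference: $E(z) = -\ln\!\big(a(z)/a_\mathrm{ref}\big)$ in units of
$k_BT$, with $a_\mathrm{ref}$ the mean accessible area over bulk slices at
least 10 nm from the membrane. With a uniform denominator this is exactly
$-\ln(O/O_\mathrm{ref})$; across the pore it additionally carries the
entropic cost of confinement from the bulk into the lumen. That term is
what makes the predicted open-pore rate scale with the accessible pore
area, $k \propto (R - r_\mathrm{probe})^2$ — the same quadratic law the
measured open-pore rates follow — so a single proportionality constant
$k_0$ per species, calibrated on open pores by least squares
($k_0 = \sum w k x / \sum w x^2$ with $x = e^{-\Delta E}$), transfers to
coated pores. Slices with zero accessible area get infinite energy; if any
falls inside the averaging range the barrier is infinite and the predicted
rate is 0, with a warning rather than a NaN.

The barrier $\Delta E$ is the mean PMF over the central 30 nm of the
channel by default (configurable); trajectory averaging precedes the
inversion. Axi-radial maps average circumferentially around the pore axis:
mass densities use an average residue mass of 100 Da
(1 Da/nm³ = 1.66054 mg/mL), and void maps report per-voxel availability
frequencies binned in $(r, z)$.

The Debye screening constant,
$\kappa = \sqrt{2 N_A e^2 I / (\varepsilon_0 \varepsilon_r k_B T)}$,
is provided as a configuration-level quantity (1.27 nm$^{-1}$ at 150 mM
1:1 salt, 294 K, $\varepsilon_r = 80$).

## ZMW photophysics

The intrinsic quantum yield of a labeled protein follows from its measured
lifetime and the free dye's reference values,
$\Phi_0 = (\tau_0/\tau_\mathrm{lit})\,\Phi_\mathrm{lit}$ (0.46 for
BSA–Alexa488 from $\tau_0 = 2.30$ ns, $\tau_\mathrm{lit} = 4.0$ ns,
$\Phi_\mathrm{lit} = 0.80$). Inputs inconsistent enough to imply
$\Phi_0 > 1$ raise an error instead of being clipped. Near the metal the
radiative rate scales with the far-field power and an absorption loss
channel appears: $\gamma_r/\gamma_{r0} = P_\mathrm{ff}/P_{r0}$,
$\gamma_\mathrm{loss}/\gamma_{r0} = (P_r - P_\mathrm{ff})/P_{r0}$. Quantum
yield, lifetime and detection efficiency follow as
$$\Phi = \frac{\gamma_r'}{\gamma_r' + \gamma_\mathrm{loss}' +
(1-\Phi_0)/\Phi_0}, \qquad
\tau = \frac{1/\gamma_{r0}}{\gamma_r' + \gamma_\mathrm{loss}' +
(1-\Phi_0)/\Phi_0}, \qquad
\eta = \frac{P_\mathrm{ff}^\mathrm{det}}{P_\mathrm{ff}},$$
with $\gamma_{r0} = \Phi_\mathrm{lit}/\tau_\mathrm{lit}$, so that in free
space ($P_r' = P_\mathrm{ff}' = 1$, symmetric emission) the model returns
$\Phi_0$, $\tau_0$ and $\eta = 1/2$ identically, and
$\Phi/\tau = \gamma_{r0}\gamma_r'$ holds pointwise. The detected signal is
$S(z) \propto I_\mathrm{ex}(z)\,\eta(z)\,\Phi(z)$, normalized to its peak
(an integral normalization is available), and the signal-averaged lifetime
uses the trapezoidal rule. Orientation averages weight horizontal and
vertical dipoles 2:1 (two degenerate horizontal axes for an isotropic
emitter); the weights are configurable. Power profiles given on a
different z-grid are linearly interpolated; extrapolation is an error.

## Synthetic data: what it emulates, and what it does not

* **Photon streams** have Poisson background per channel plus bursts with
  constant brightness over exponentially distributed durations. Real
  bursts have diffusion-shaped intensity profiles and re-entry clusters;
  constant-brightness bursts are sufficient to exercise the detection
  statistics but not to test shape-sensitive analyses. Macrotimes are
  integer clock ticks (10 ns default) made strictly increasing, so all
  ordering logic is exact.
* **Brushes** are non-self-avoiding random walks of fixed bond length
  (defaults: 600 beads/chain, 0.38 nm bonds, 0.3 nm bead radius, one chain
  per 300 nm² of wall) anchored on a near-triangular lattice; rows share
  the target count so the number of chains equals
  `round(wall area × density)` exactly. There is no inter-chain excluded
  volume, no cohesion and no sequence: the generator provides steric
  statistics for the void analysis, not polymer physics. In particular,
  how faithfully it reproduces the channel-opening transition of the real
  Nsp1 mesh near 60 nm pores is unknown — the stand-in is qualitative, and
  the cohesiveness-driven density redistribution seen in residue-scale
  force-field simulations is outside its scope. Frames are either i.i.d.
  redraws (`independent`, giving known sampling error to trajectory
  averages) or chain-suffix regrowths (`perturbed`).
* **Power profiles** decay exponentially inside the aperture with a
  configurable 1/e length (10–20 nm is realistic for visible light); loss
  and detection-side fractions are user profiles. Standing-wave structure
  above the membrane and pore-size-dependent mode shapes are not modelled.
* **Rate tables** draw multiplicative Gaussian noise of fixed CV around
  the quadratic law, with SEM columns set consistently, so fit-recovery
  tests have exact ground truth.

All generators consume one integer seed and restore the caller's RNG
state; identical seeds give identical outputs.

## Numerical choices and problem sizes

* Voxel centers sit at $(i + \tfrac12) \times$ voxel size from the box
  corner; a bead blocks a voxel on *strict* inequality, so oracle
  comparisons are exact.
* The change-point recursion only considers splits leaving both children
  at least `min_photons_per_segment` (default 5) photons.
* `optimize()` results for one-parameter fits are polished by guarded
  Newton steps and always compared against the $b = 0$ / $\sigma_V = 0$
  boundary, so noiseless round trips recover parameters to $10^{-6}$
  relative or better.
* Tick collisions after rounding are resolved by minimal right-shifts
  (`cummax`), preserving order without floating-point comparisons.
* The test suite runs at desk scale: void grids up to $250^3$ voxels
  (pores to 120 nm in a common 150 nm box), brushes of 40–50 beads per
  chain for constraint checks, 100–200 seeds for recovery and calibration
  statistics, and $10^4$-sample Monte Carlo oracles for error
  propagation. The full-size defaults (600-bead chains, multi-frame
  trajectories) run in minutes and are exercised through the same code
  paths.

## Known limitations

* Counting by change-point segmentation without merging can double-count a
  burst (edge fragments) or miss faint events diluted in long homogeneous
  stretches; the calibration condition documents the regime in which the
  estimator is unbiased, and the minimum-photon cut is the lever that
  trades the two failure modes.
* The void analysis is purely steric: no interactions, no diffusivity
  differences between species (hence per-species $k_0$), no
  confinement-dependent diffusivity reduction.
* The selective-area mixture rule is a deliberate simplification of a
  pore that separates into selective and open regions; both mixing rules
  bound the truth but neither is derived from transport theory.
* Photon-HDF5 support covers the subset of the standard the pipeline
  needs (timestamps, detectors, nanotimes and their units); vendor TTTR
  formats are out of scope.
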