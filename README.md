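# npcmimic

Analysis pipeline for single-molecule transport measurements through
biomimetic nuclear pore complexes (NPCs): solid-state nanopores in a
freestanding metal membrane, coated with the intrinsically disordered
FG-nucleoporin Nsp1 and read out optically as zero-mode waveguides (ZMWs).
The package is aimed at groups running (or modelling) optical nanopore
translocation assays: it covers burst detection in single-photon data,
event-rate and selectivity statistics, diffusion-based size-dependence
models, a void-analysis predictor of translocation rates through polymer
meshes, and the photophysics of emitters inside a metal nanoaperture.

## What it computes

**Burst detection.** Photon arrival times are segmented by recursive
change-point analysis of a piecewise-homogeneous Poisson process. For a
segment of N photons observed over time T, a split after photon k is scored
by the generalized log-likelihood ratio

    Lambda(k) = k ln(k/T1) + (N-k) ln((N-k)/T2) - N ln(N/T)

and accepted when 2*Lambda exceeds the chi-squared(1) critical value at the
Bonferroni-corrected level alpha/(N-1). Segments above the background rate
(duration-weighted median of segment rates) with enough photons are retained
as bursts; event rates carry Poisson errors, sd = sqrt(n)/T.

**Transport analysis.** Event rates are normalized by concentration, degree
of labeling and labeled fraction, averaged per pore, and combined into the
selectivity ratio k_Kap95 / k_BSA. Size dependence follows Fick's law,
kappa = pi r^2 D dc / L, fitted as k = alpha (r - r_prot)^2 for open pores
and k = alpha (r - r_prot - b)^2 for coated pores, where the onset shift b
estimates the thickness of the selective coating. For large pores a
selective-area model, f = min(2 sigma_V / r, 1) with
s_app = 1 / (f/s_sel + (1-f)/s_open), yields the effective layer thickness
sigma_V.

**Void analysis.** Bead configurations of the polymer mesh are voxelized
(0.6 nm voxels); a voxel is available to a spherical probe when no bead or
scaffold lies within the combined radii. Per-slice availability is averaged
over the trajectory and Boltzmann-inverted into a potential of mean force,
E(z) = -ln(a(z)/a_ref) in kBT; the barrier dE (PMF averaged over the pore
center) gives translocation rates via the Arrhenius relation
k = k0 exp(-dE), with k0 calibrated on open pores.

**ZMW photophysics.** From dipole power ratios, the modified quantum yield
Phi = g_r / (g_r + g_loss + (1-Phi0)/Phi0), lifetime
tau = (1/gamma_r0) / (g_r + g_loss + (1-Phi0)/Phi0), detection efficiency
eta = P_ff,det / P_ff, and the detected signal S(z) ~ Iex(z) eta(z) Phi(z)
with its signal-averaged lifetime.

**Synthetic data.** Generators with known ground truth for photon streams
(Poisson background plus constant-brightness bursts), TCSPC decays,
grafted random-walk brushes in cylindrical pores, dipole power profiles,
and rate-versus-diameter tables.

## Worked example

```r
library(npcmimic)

cfg <- photon_sim_config(duration = 20, background_rate_per_channel = 50,
                         event_rate = 1, burst_brightness = 2e5,
                         burst_duration_mean = 5e-3, seed = 42)
stream <- gen_photon_stream(cfg)
bursts <- extract_bursts(stream, change_point_params(min_event_photons = 10))
event_rate(bursts, stream$duration)
#> <event_rate_estimate> 1 +/- 0.22 Hz (20 events / 20 s)

cond <- measurement_condition(conc_kap = 100, dol_kap = 0.7)
normalize_event_rate(event_rate(bursts, 20), cond, species = "Kap95")$k
#> [1] 0.01428571   # Hz/nM

truth <- rate_model_truth(2.8e-4, 3.4, 11.5, noise_cv = 0.1,
                          diameters = seq(35, 160, length.out = 24))
fit_offset_quadratic(gen_rate_dataset(truth, seed = 1), r_prot = 3.4)
#> <npc_fit>
#>   alpha   = 0.000287194 +/- 7e-06 Hz/nM/nm^2
#>   b       = 11.5891 +/- 0.13 nm

g <- pore_geometry(60, membrane_thickness = 90)
pore <- gen_brush(g, brush_config(grafting_density = 0, seed = 1))
pmf <- pmf_from_occupancy(occupancy_profile(pore, probe_radius = 3.4))
barrier_energy(pmf)
#> [1] 1.066932   # kBT; predicted rate = k0 * exp(-1.067)
```

The simulated stream contains 20 true events in 20 s; the pipeline detects
them all (1.0 +/- 0.22 Hz) and normalization by 100 nM at a 0.7 degree of
labeling gives 0.0143 Hz/nM. The offset fit recovers the 11.5 nm onset
shift of the generating model, and the open 60 nm pore has a purely
entropic (confinement) barrier of ~1.1 kBT relative to the bulk reference.

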