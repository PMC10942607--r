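Package: npcmimic
Title: Single-Molecule Transport Analysis for Biomimetic Nuclear Pore
    Complexes in Zero-Mode Waveguides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optical single-molecule translocation
    measurements through FG-nucleoporin-coated metal nanopores that act as
    zero-mode waveguides. Detects fluorescence bursts in single-photon
    arrival-time records by change-point analysis, computes
    concentration-normalized event rates with Poisson errors and
    selectivity ratios, and fits diffusion-based size-dependence models of
    pore selectivity. Predicts translocation rates of inert probes through
    disordered-protein meshes by voxel-based void analysis, Boltzmann
    inversion to a potential of mean force, and Arrhenius rate calibration.
    Models the modulation of fluorescence quantum yield, lifetime, and
    detection efficiency near a zero-mode waveguide from dipole power
    profiles. Includes synthetic-data generators (photon streams, decay
    microtimes, grafted polymer-brush bead configurations, dipole power
    profiles, and rate-versus-diameter tables) with known ground truth, and
    readers/writers for Photon-HDF5, extended XYZ, and delimited text
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: HDF5 (libhdf5 headers and library)
Config/testthat/edition: 3
NeedsCompilation: yes
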