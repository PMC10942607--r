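#' Voxel grid over a nanopore simulation box
#'
#' Voxels of side `voxel_size` tile the box; voxel centers sit at
#' `origin + (i + 1/2) * voxel_size` on each axis. The analysis mask excludes
#' the metal-slab volume (membrane span outside the pore lumen).
#'
#' @param geometry a [pore_geometry()].
#' @param voxel_size voxel side length in nm (default 0.6 nm).
#' @return an object of class `voxel_grid` with dims, axis center
#'   coordinates, and precomputed slice masks.
#' @export
voxel_grid <- function(geometry, voxel_size = 0.6) {
  stopifnot(inherits(geometry, "pore_geometry"))
  stopifnot_scalar(voxel_size, "voxel_size", min = 0, strict_min = TRUE)
  dims <- c(ceiling(geometry$box_x / voxel_size),
            ceiling(geometry$box_y / voxel_size),
            ceiling(geometry$box_z / voxel_size))
  origin <- -c(dims[1], dims[2], dims[3]) * voxel_size / 2
  xc <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_size
  yc <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_size
  zc <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_size
  rxy <- sqrt(outer(xc^2, yc^2, "+"))  # nx x ny matrix of radial distances
  in_membrane <- zc >= geometry$membrane_z_lo & zc <= geometry$membrane_z_hi
  structure(list(voxel_size = voxel_size, dims = dims, origin = origin,
                 x = xc, y = yc, z = zc, rxy = rxy,
                 in_membrane = in_membrane, geometry = geometry),
            class = "voxel_grid")
}

#' Instantaneous void map for a spherical probe
#'
#' A voxel is available when a spherical probe of radius `probe_radius`
#' placed at its center overlaps neither a bead (center distance strictly
#' below `probe_radius + bead_radius`) nor the pore scaffold/metal slab
#' (within the membrane span the probe center must lie at radial distance
#' `<= R - probe_radius` from the axis). The per-bead neighbor search is
#' restricted to a bounded sub-block of the grid and is exactly equivalent
#' to an all-pairs distance check.
#'
#' @param frame data frame of bead coordinates with columns `x, y, z` and
#'   `radius` (or pass `bead_radius`).
#' @param probe_radius probe radius in nm (> 0).
#' @param grid a [voxel_grid()].
#' @param bead_radius fallback bead radius when `frame` has no `radius`
#'   column.
#' @return logical array (`dims` of the grid) of voxel availability, class
#'   `void_map`, with the probe radius attached as an attribute.
#' @export
void_map <- function(frame, probe_radius, grid, bead_radius = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  stopifnot_scalar(probe_radius, "probe_radius", min = 0, strict_min = TRUE)
  g <- grid$geometry
  R <- g$pore_diameter / 2
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  avail <- array(TRUE, dim = grid$dims)
  # scaffold/metal: inside the membrane span the probe must fit in the lumen
  wall_blocked <- grid$rxy > R - probe_radius
  for (k in which(grid$in_membrane)) avail[, , k] <- !wall_blocked
  rad <- if (!is.null(frame$radius)) frame$radius
         else rep(if (is.null(bead_radius)) 0 else bead_radius, NROW(frame))
  if (NROW(frame) > 0L) {
    out <- .Call("C_void_stamp", as.logical(avail), as.integer(grid$dims),
                 as.double(grid$origin), as.double(grid$voxel_size),
                 as.double(frame$x), as.double(frame$y), as.double(frame$z),
                 as.double(probe_radius + rad))
    avail <- array(out, dim = grid$dims)
  }
  structure(avail, class = c("void_map", "array"),
            probe_radius = probe_radius)
}

# per-slice numerator/denominator under the analysis mask:
# inside the membrane the denominator is the pore cross-section, in the bulk
# the full box cross-section; avail_area is the absolute accessible area.
slice_occupancy <- function(vm, grid) {
  g <- grid$geometry
  R <- g$pore_diameter / 2
  pore_mask <- grid$rxy <= R
  n_pore <- sum(pore_mask)
  nz <- grid$dims[3]
  occ <- numeric(nz)
  denom <- numeric(nz)
  for (k in seq_len(nz)) {
    if (grid$in_membrane[k]) {
      occ[k] <- sum(vm[, , k][pore_mask]) / n_pore
      denom[k] <- n_pore
    } else {
      occ[k] <- mean(vm[, , k])
      denom[k] <- grid$dims[1] * grid$dims[2]
    }
  }
  list(occupancy = occ, denom_area = denom * grid$voxel_size^2)
}

#' Trajectory-averaged potential occupancy along the pore axis
#'
#' For every frame a void map is computed and reduced to the fraction of
#' available voxels per z-slice. Inside the membrane span the denominator is
#' the pore cross-section (the metal slab is excluded from the analysis
#' mask); in the bulk it is the full box cross-section. The absolute
#' accessible area per slice (`avail_area`, nm^2) is carried alongside the
#' fractions, since the Boltzmann inversion acts on it.
#'
#' @param trajectory a `bead_trajectory` (see [gen_brush()]).
#' @param probe_radius probe radius in nm.
#' @param grid optional [voxel_grid()]; built from the trajectory geometry at
#'   `voxel_size` if omitted.
#' @param voxel_size used when `grid` is `NULL`.
#' @param every analyze every `every`-th frame.
#' @return an `occupancy_profile` data frame with columns `z`, `occupancy`,
#'   `sem`, `avail_area`; geometry and probe radius travel as attributes.
#' @export
occupancy_profile <- function(trajectory, probe_radius, grid = NULL,
                              voxel_size = 0.6, every = 1L) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  if (length(trajectory$frames) < 1L) stop("empty trajectory")
  if (is.null(grid)) grid <- voxel_grid(trajectory$geometry, voxel_size)
  idx <- seq(1L, length(trajectory$frames), by = every)
  occ_mat <- matrix(NA_real_, nrow = grid$dims[3], ncol = length(idx))
  denom_area <- NULL
  for (j in seq_along(idx)) {
    vm <- void_map(trajectory$frames[[idx[j]]], probe_radius, grid,
                   bead_radius = trajectory$bead_radius)
    so <- slice_occupancy(vm, grid)
    occ_mat[, j] <- so$occupancy
    denom_area <- so$denom_area
  }
  m <- rowMeans(occ_mat)
  sem <- if (length(idx) > 1L)
    apply(occ_mat, 1L, sd) / sqrt(length(idx)) else rep(0, nrow(occ_mat))
  out <- data.frame(z = grid$z, occupancy = m, sem = sem,
                    avail_area = m * denom_area)
  class(out) <- c("occupancy_profile", "data.frame")
  attr(out, "geometry") <- grid$geometry
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_frames") <- length(idx)
  attr(out, "voxel_size") <- grid$voxel_size
  out
}

#' Build an occupancy profile from plain vectors
#'
#' Convenience constructor for externally computed (or analytic) occupancy
#' curves; with a uniform denominator area the Boltzmann inversion reduces to
#' `-log(O / O_ref)` exactly.
#'
#' @param z slice centers in nm.
#' @param occupancy available fraction per slice, in `[0, 1]`.
#' @param area denominator area per slice (scalar or vector), nm^2.
#' @param membrane_span optional `c(z_lo, z_hi)` of the membrane.
#' @return an `occupancy_profile` data frame.
#' @export
as_occupancy_profile <- function(z, occupancy, area = 1,
                                 membrane_span = NULL) {
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must be in [0, 1]")
  out <- data.frame(z = z, occupancy = occupancy, sem = 0,
                    avail_area = occupancy * rep_len(area, length(z)))
  class(out) <- c("occupancy_profile", "data.frame")
  if (!is.null(membrane_span)) {
    geom <- list(membrane_z_lo = membrane_span[1],
                 membrane_z_hi = membrane_span[2])
    attr(out, "geometry") <- geom
  }
  out
}

#' Potential of mean force by Boltzmann inversion
#'
#' Converts the trajectory-averaged accessible area per slice into an
#' effective free-energy profile, `E(z) = -ln(a(z) / a_ref)` in kBT. The
#' reference is the mean accessible area over bulk slices at least
#' `bulk_margin` nm away from the membrane (or an explicit value). With a
#' uniform slice denominator this is exactly `-ln(O / O_ref)`; across the
#' pore it additionally carries the entropic cost of confinement from the
#' bulk into the lumen, which is what makes predicted open-pore rates scale
#' with the accessible pore area.
#'
#' Slices with zero accessible area get `+Inf` energy and are flagged; they
#' are excluded from averaging with a warning downstream.
#'
#' @param profile an `occupancy_profile`.
#' @param reference `"bulk_mean"` or `"explicit"`.
#' @param ref_area reference accessible area (nm^2) when
#'   `reference = "explicit"`.
#' @param bulk_margin distance from the membrane (nm) beyond which slices
#'   count as bulk.
#' @return a `pmf_profile` data frame with columns `z`, `energy` (kBT),
#'   `occupancy`; reference and membrane span travel as attributes.
#' @export
pmf_from_occupancy <- function(profile, reference = c("bulk_mean",
                                                      "explicit"),
                               ref_area = NULL, bulk_margin = 10) {
  reference <- match.arg(reference)
  stopifnot(inherits(profile, "occupancy_profile"))
  geom <- attr(profile, "geometry")
  if (reference == "explicit") {
    if (is.null(ref_area) || ref_area <= 0)
      stop("'ref_area' must be a positive reference accessible area")
    a_ref <- ref_area
  } else {
    if (!is.null(geom)) {
      bulk <- profile$z < geom$membrane_z_lo - bulk_margin |
              profile$z > geom$membrane_z_hi + bulk_margin
      if (!any(bulk)) bulk <- rep(TRUE, nrow(profile))
    } else bulk <- rep(TRUE, nrow(profile))
    a_ref <- mean(profile$avail_area[bulk])
    if (!is.finite(a_ref) || a_ref <= 0)
      stop("bulk reference accessible area is zero")
  }
  energy <- -log(profile$avail_area / a_ref)
  out <- data.frame(z = profile$z, energy = energy,
                    occupancy = profile$occupancy)
  class(out) <- c("pmf_profile", "data.frame")
  attr(out, "ref_area") <- a_ref
  attr(out, "geometry") <- geom
  out
}

#' Energy barrier from a PMF profile
#'
#' Mean PMF over the slices whose centers fall in `z_range`; by default the
#' central `width` nm of the membrane span. Slices flagged with infinite
#' energy (zero accessible area) make the barrier infinite, with a warning.
#'
#' @param pmf a `pmf_profile` (see [pmf_from_occupancy()]).
#' @param z_range numeric `c(lo, hi)` in nm; default centered on the
#'   membrane.
#' @param width default averaging width in nm when `z_range` is omitted.
#' @return barrier height in kBT.
#' @export
barrier_energy <- function(pmf, z_range = NULL, width = 30) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(z_range)) {
    geom <- attr(pmf, "geometry")
    if (is.null(geom))
      stop("no membrane span stored; supply 'z_range'")
    mid <- (geom$membrane_z_lo + geom$membrane_z_hi) / 2
    z_range <- mid + c(-width / 2, width / 2)
  }
  sel <- pmf$z >= z_range[1] & pmf$z <= z_range[2]
  if (!any(sel)) stop("no PMF slices inside the requested z range")
  e <- pmf$energy[sel]
  if (any(!is.finite(e))) {
    warning("zero-occupancy slices inside the barrier range; ",
            "barrier is infinite (predicted rate 0)")
    return(Inf)
  }
  mean(e)
}

#' Arrhenius translocation rate
#'
#' `k = k0 * exp(-dE)` with the barrier in units of kBT. An infinite barrier
#' (zero accessible area somewhere in the averaging range) gives rate 0.
#'
#' @param dE energy barrier in kBT.
#' @param k0 proportionality constant in Hz/nM (see [calibrate_k0()]).
#' @return predicted normalized rate in Hz/nM.
#' @export
arrhenius_rate <- function(dE, k0) {
  if (any(k0 <= 0)) stop("'k0' must be > 0")
  k0 * exp(-dE)
}

#' Calibrate the Arrhenius proportionality constant on open pores
#'
#' Least-squares scale factor relating computed Boltzmann factors
#' `exp(-dE)` to measured normalized event rates of open pores:
#' `k0 = sum(w k x) / sum(w x^2)`. A single constant per species is then
#' used for open and coated pores alike.
#'
#' @param predictor computed `exp(-dE)` per open pore.
#' @param measured measured normalized rates (Hz/nM).
#' @param weights optional weights (default 1).
#' @return a `rate_calibration` list with `k0` and residual diagnostics.
#' @export
calibrate_k0 <- function(predictor, measured, weights = NULL) {
  if (length(predictor) < 1L) stop("no open pores provided")
  if (length(predictor) != length(measured))
    stop("'predictor' and 'measured' lengths differ")
  w <- if (is.null(weights)) rep(1, length(predictor)) else weights
  k0 <- sum(w * measured * predictor) / sum(w * predictor^2)
  res <- measured - k0 * predictor
  structure(list(k0 = k0, residual_norm = sqrt(sum(w * res^2)),
                 n_pores = length(predictor)),
            class = "rate_calibration")
}

#' Axi-radial mass-density map of a bead trajectory
#'
#' Beads are binned in annular (r, z) bins around the pore axis,
#' circumferentially averaged, and converted to mass density using the
#' average residue mass (about 100 Da for this FG-Nup at residue scale);
#' 1 Da/nm^3 = 1.66054 mg/mL.
#'
#' @param trajectory a `bead_trajectory`.
#' @param residue_mass bead mass in Da.
#' @param r_bin,z_bin bin widths in nm.
#' @return an `axiradial_map`: list with `r` and `z` bin centers and a
#'   `value` matrix (rows r, columns z) in mg/mL.
#' @export
axiradial_density <- function(trajectory, residue_mass = 100,
                              r_bin = 1, z_bin = 1) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  stopifnot_scalar(r_bin, "r_bin", min = 0, strict_min = TRUE)
  stopifnot_scalar(z_bin, "z_bin", min = 0, strict_min = TRUE)
  g <- trajectory$geometry
  n_frames <- length(trajectory$frames)
  all_r <- unlist(lapply(trajectory$frames, function(f)
    sqrt(f$x^2 + f$y^2)))
  all_z <- unlist(lapply(trajectory$frames, function(f) f$z))
  r_max <- max(g$box_x, g$box_y) / 2 * sqrt(2)
  if (length(all_r)) r_max <- max(r_max, max(all_r))
  r_breaks <- seq(0, r_bin * ceiling(r_max / r_bin + 1e-9), by = r_bin)
  z_lo <- -g$box_z / 2
  z_breaks <- seq(z_lo, z_lo + z_bin * ceiling(g$box_z / z_bin), by = z_bin)
  nr <- length(r_breaks) - 1L
  nz <- length(z_breaks) - 1L
  counts <- matrix(0, nrow = nr, ncol = nz)
  if (length(all_r)) {
    ri <- findInterval(all_r, r_breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    zi <- findInterval(pmin(pmax(all_z, z_breaks[1]), max(z_breaks)),
                       z_breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tab <- table(factor(ri, levels = seq_len(nr)),
                 factor(zi, levels = seq_len(nz)))
    counts <- matrix(as.numeric(tab), nrow = nr)
  }
  vol <- outer(pi * (r_breaks[-1]^2 - r_breaks[-length(r_breaks)]^2),
               rep(z_bin, nz))  # nm^3 per annular bin
  density <- counts * residue_mass * 1.66053906660 / (vol * n_frames)
  structure(list(r = (r_breaks[-1] + r_breaks[-length(r_breaks)]) / 2,
                 z = (z_breaks[-1] + z_breaks[-length(z_breaks)]) / 2,
                 value = density, units = "mg/mL",
                 r_breaks = r_breaks, z_breaks = z_breaks,
                 n_frames = n_frames, residue_mass = residue_mass),
            class = "axiradial_map")
}

#' Axi-radial void (availability probability) map
#'
#' Per-voxel availability frequency over the trajectory, circumferentially
#' binned around the pore axis. Values are probabilities in `[0, 1]`.
#'
#' @param trajectory a `bead_trajectory`.
#' @param probe_radius probe radius in nm.
#' @param grid optional [voxel_grid()].
#' @param r_bin radial bin width in nm (default: the voxel size).
#' @param voxel_size used when `grid` is `NULL`.
#' @param every analyze every `every`-th frame.
#' @return an `axiradial_map` with availability probabilities.
#' @export
axiradial_void <- function(trajectory, probe_radius, grid = NULL,
                           r_bin = NULL, voxel_size = 0.6, every = 1L) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  if (length(trajectory$frames) < 1L) stop("empty trajectory")
  if (is.null(grid)) grid <- voxel_grid(trajectory$geometry, voxel_size)
  if (is.null(r_bin)) r_bin <- grid$voxel_size
  idx <- seq(1L, length(trajectory$frames), by = every)
  freq <- array(0, dim = grid$dims)
  for (j in idx) {
    vm <- void_map(trajectory$frames[[j]], probe_radius, grid,
                   bead_radius = trajectory$bead_radius)
    freq <- freq + vm
  }
  freq <- freq / length(idx)
  r_vox <- as.vector(grid$rxy)  # recycled along z below
  r_breaks <- seq(0, r_bin * ceiling(max(r_vox) / r_bin + 1e-9), by = r_bin)
  nr <- length(r_breaks) - 1L
  ri <- findInterval(r_vox, r_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  nz <- grid$dims[3]
  value <- matrix(NA_real_, nrow = nr, ncol = nz)
  rgrp <- factor(ri, levels = seq_len(nr))
  cnt <- tabulate(ri, nbins = nr)
  for (k in seq_len(nz)) {
    sums <- as.vector(tapply(as.vector(freq[, , k]), rgrp, sum))
    value[, k] <- ifelse(cnt > 0, sums / cnt, NA_real_)
  }
  structure(list(r = (r_breaks[-1] + r_breaks[-length(r_breaks)]) / 2,
                 z = grid$z, value = value, units = "probability",
                 n_frames = length(idx), probe_radius = probe_radius),
            class = "axiradial_map")
}

#' Debye screening constant of an electrolyte
#'
#' `kappa = sqrt(2 N_A e^2 I / (eps0 epsr kB T))`, returned in 1/nm. At
#' 150 mM 1:1 salt, 294 K and relative permittivity 80 this gives
#' 1.27 nm^-1.
#'
#' @param ionic_strength ionic strength in mol/L.
#' @param temperature temperature in K.
#' @param rel_permittivity relative permittivity of the solvent.
#' @return screening constant in nm^-1.
#' @export
debye_kappa <- function(ionic_strength, temperature = 294,
                        rel_permittivity = 80) {
  stopifnot_scalar(ionic_strength, "ionic_strength", min = 0)
  stopifnot_scalar(temperature, "temperature", min = 0, strict_min = TRUE)
  stopifnot_scalar(rel_permittivity, "rel_permittivity", min = 0,
                   strict_min = TRUE)
  I_m3 <- ionic_strength * 1e3 * .const$N_A  # ions per m^3 per unit charge
  kappa_m <- sqrt(2 * .const$e^2 * I_m3 /
                  (.const$eps0 * rel_permittivity * .const$kB * temperature))
  kappa_m * 1e-9
}
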