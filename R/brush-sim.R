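#' Cylindrical nanopore geometry in a metal membrane
#'
#' Coordinates are centered: the pore axis is the z-axis, x and y span
#' `[-box_x/2, box_x/2]` etc., and the metal slab occupies the membrane span
#' `[membrane_z_lo, membrane_z_hi]` outside the pore lumen of radius
#' `pore_diameter/2`.
#'
#' @param pore_diameter lumen diameter in nm.
#' @param membrane_thickness metal membrane thickness in nm (90 nm for the
#'   freestanding Pd membranes this mimics).
#' @param bulk_margin bulk solution depth above and below the membrane, nm.
#' @param lateral_margin box margin around the pore in x and y, nm.
#' @param scaffold_bead_radius radius of the scaffold beads lining the wall,
#'   nm; their centers sit on the cylinder of radius
#'   `pore_diameter/2 + scaffold_bead_radius` so that the lumen surface is at
#'   `pore_diameter/2`.
#' @return an object of class `pore_geometry`.
#' @export
pore_geometry <- function(pore_diameter, membrane_thickness = 90,
                          bulk_margin = 30, lateral_margin = 10,
                          scaffold_bead_radius = 1.5) {
  stopifnot_scalar(pore_diameter, "pore_diameter", min = 0, strict_min = TRUE)
  stopifnot_scalar(membrane_thickness, "membrane_thickness",
                   min = 0, strict_min = TRUE)
  stopifnot_scalar(bulk_margin, "bulk_margin", min = 0)
  stopifnot_scalar(lateral_margin, "lateral_margin", min = 0)
  box_xy <- pore_diameter + 2 * lateral_margin
  box_z <- membrane_thickness + 2 * bulk_margin
  structure(list(pore_diameter = pore_diameter,
                 membrane_thickness = membrane_thickness,
                 box_x = box_xy, box_y = box_xy, box_z = box_z,
                 membrane_z_lo = -membrane_thickness / 2,
                 membrane_z_hi = membrane_thickness / 2,
                 scaffold_bead_radius = scaffold_bead_radius),
            class = "pore_geometry")
}

#' Configuration for a grafted polymer brush
#'
#' @param grafting_density chains per nm^2 of pore wall (the matched
#'   experimental value is 1 chain per 300 nm^2).
#' @param chain_length beads (residues) per chain.
#' @param bond_length fixed bond length in nm (0.38 nm, the Calpha-Calpha
#'   distance at residue scale).
#' @param bead_radius bead radius in nm.
#' @param n_frames number of configurations in the trajectory.
#' @param resample_mode `"independent"` draws every frame from scratch
#'   (frames are i.i.d., so trajectory averages have known sampling error);
#'   `"perturbed"` regrows a random suffix of each chain between frames.
#' @param seed integer seed.
#' @return an object of class `brush_config`.
#' @export
brush_config <- function(grafting_density = 1 / 300, chain_length = 600,
                         bond_length = 0.38, bead_radius = 0.3,
                         n_frames = 1, resample_mode = c("independent",
                                                         "perturbed"),
                         seed = 1L) {
  stopifnot_scalar(grafting_density, "grafting_density", min = 0)
  stopifnot_scalar(chain_length, "chain_length", min = 1)
  stopifnot_scalar(bond_length, "bond_length", min = 0, strict_min = TRUE)
  stopifnot_scalar(bead_radius, "bead_radius", min = 0, strict_min = TRUE)
  stopifnot_scalar(n_frames, "n_frames", min = 1)
  structure(list(grafting_density = grafting_density,
                 chain_length = as.integer(chain_length),
                 bond_length = bond_length, bead_radius = bead_radius,
                 n_frames = as.integer(n_frames),
                 resample_mode = match.arg(resample_mode),
                 seed = seed),
            class = "brush_config")
}

new_bead_trajectory <- function(frames, geometry, bead_radius = NA_real_) {
  structure(list(frames = frames, geometry = geometry,
                 bead_radius = bead_radius),
            class = "bead_trajectory")
}

#' @export
print.bead_trajectory <- function(x, ...) {
  nb <- if (length(x$frames)) nrow(x$frames[[1]]) else 0L
  cat("<bead_trajectory> ", length(x$frames), " frame(s), ", nb,
      " beads/frame, pore diameter ", x$geometry$pore_diameter, " nm\n",
      sep = "")
  invisible(x)
}

# anchor sites: near-triangular lattice on the inner pore wall that carries
# exactly round(wall_area * density) chains
brush_anchor_sites <- function(geometry, cfg) {
  R <- geometry$pore_diameter / 2
  h <- geometry$membrane_thickness
  n_target <- round(pi * geometry$pore_diameter * h * cfg$grafting_density)
  if (n_target == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  a <- sqrt(2 / (sqrt(3) * cfg$grafting_density))  # triangular lattice pitch
  n_rows <- max(1L, round(h / (a * sqrt(3) / 2)))
  per_row <- rep(n_target %/% n_rows, n_rows)
  extra <- n_target %% n_rows
  if (extra > 0L) per_row[seq_len(extra)] <- per_row[seq_len(extra)] + 1L
  r_anchor <- R - cfg$bead_radius
  xs <- ys <- zs <- numeric(0)
  dz <- h / n_rows
  for (i in seq_len(n_rows)) {
    m <- per_row[i]
    if (m == 0L) next
    phi <- 2 * pi * (seq_len(m) - 1) / m + (i %% 2) * pi / m
    xs <- c(xs, r_anchor * cos(phi))
    ys <- c(ys, r_anchor * sin(phi))
    zs <- c(zs, rep(geometry$membrane_z_lo + (i - 0.5) * dz, m))
  }
  sites <- data.frame(x = xs, y = ys, z = zs)
  # closest pair of anchors must leave room for two bead radii
  if (nrow(sites) > 1L) {
    arc <- min(2 * pi * r_anchor / per_row[per_row > 0])
    if (min(arc, dz) < 2 * cfg$bead_radius)
      stop("grafting density too high: anchor spacing ",
           format(min(arc, dz), digits = 3), " nm < 2 * bead_radius")
  }
  sites
}

# is a bead center admissible (not clashing with wall, metal or box)?
bead_ok <- function(x, y, z, geometry, bead_radius) {
  if (abs(x) > geometry$box_x / 2 - bead_radius) return(FALSE)
  if (abs(y) > geometry$box_y / 2 - bead_radius) return(FALSE)
  if (z < -geometry$box_z / 2 + bead_radius ||
      z > geometry$box_z / 2 - bead_radius) return(FALSE)
  if (z >= geometry$membrane_z_lo && z <= geometry$membrane_z_hi) {
    R <- geometry$pore_diameter / 2
    if (sqrt(x^2 + y^2) > R - bead_radius) return(FALSE)
  }
  TRUE
}

# grow a fixed-bond random walk from `start` (excluded from output);
# directions clashing with the scaffold are redrawn (hard reflection)
grow_chain <- function(start, n_beads, geometry, cfg) {
  out <- matrix(NA_real_, nrow = n_beads, ncol = 3)
  cur <- start
  b <- cfg$bond_length
  for (i in seq_len(n_beads)) {
    for (try in 1:200) {
      u <- runif(1, -1, 1)
      phi <- runif(1, 0, 2 * pi)
      s <- sqrt(1 - u^2)
      cand <- cur + b * c(s * cos(phi), s * sin(phi), u)
      if (bead_ok(cand[1], cand[2], cand[3], geometry, cfg$bead_radius)) break
      cand <- NULL
    }
    if (is.null(cand))
      stop("chain growth failed: no admissible direction after 200 draws")
    out[i, ] <- cand
    cur <- cand
  }
  out
}

#' Generate a polymer-brush trajectory inside a nanopore
#'
#' Chains are anchored at their C-terminus to the inner pore wall on a
#' near-triangular lattice at the requested grafting density and grown as
#' non-self-avoiding random walks of fixed bond length, with hard reflection
#' off the pore scaffold, the metal slab, and the box walls. There is no
#' inter-chain excluded volume: the mesh generator is a steric stand-in whose
#' statistics feed the void analysis, not a force-field model.
#'
#' @param geometry a [pore_geometry()].
#' @param cfg a [brush_config()].
#' @return a `bead_trajectory`: list of per-frame data frames with columns
#'   `x, y, z, radius` (nm) plus the geometry. The anchor sites are attached
#'   as attribute `"anchors"`.
#' @export
gen_brush <- function(geometry, cfg) {
  stopifnot(inherits(geometry, "pore_geometry"), inherits(cfg, "brush_config"))
  with_seed(cfg$seed, {
    anchors <- brush_anchor_sites(geometry, cfg)
    n_chains <- nrow(anchors)
    grow_frame <- function() {
      if (n_chains == 0L)
        return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          radius = numeric(0)))
      coords <- vector("list", n_chains)
      for (ci in seq_len(n_chains)) {
        start <- as.numeric(anchors[ci, ])
        xyz <- grow_chain(start, cfg$chain_length, geometry, cfg)
        coords[[ci]] <- xyz
      }
      m <- do.call(rbind, coords)
      data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
                 radius = cfg$bead_radius)
    }
    frames <- vector("list", cfg$n_frames)
    frames[[1]] <- grow_frame()
    if (cfg$n_frames > 1L) {
      for (f in 2:cfg$n_frames) {
        if (cfg$resample_mode == "independent") {
          frames[[f]] <- grow_frame()
        } else {
          prev <- frames[[f - 1]]
          cur <- prev
          if (n_chains > 0L) {
            for (ci in seq_len(n_chains)) {
              idx <- (ci - 1) * cfg$chain_length
              pivot <- sample.int(cfg$chain_length, 1L)
              start <- if (pivot == 1L) as.numeric(anchors[ci, ])
                       else as.numeric(cur[idx + pivot - 1L, 1:3])
              n_regrow <- cfg$chain_length - pivot + 1L
              xyz <- grow_chain(start, n_regrow, geometry, cfg)
              cur[idx + pivot:cfg$chain_length, 1:3] <- xyz
            }
          }
          frames[[f]] <- cur
        }
      }
    }
    out <- new_bead_trajectory(frames, geometry, cfg$bead_radius)
    attr(out, "anchors") <- anchors
    out
  })
}
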