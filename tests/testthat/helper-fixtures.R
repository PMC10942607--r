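# Shared fixtures and independent oracles for the test suite.

# photon stream built directly from arrival times (seconds), single channel
make_stream <- function(times, duration, channel = "red",
                        ticks_per_second = 1e8) {
  ticks <- npcmimic:::strictify_ticks(round(sort(times) * ticks_per_second))
  npcmimic:::new_photon_stream(ticks, numeric(0),
                               rep(channel, length(times)), duration,
                               ticks_per_second)
}

# background stream plus rectangular bursts at given start times; pass
# burst_photons for a fixed per-burst photon count (e.g. "each >= 50")
make_burst_stream <- function(bg_rate, duration, burst_starts, burst_len,
                              burst_rate, channel = "red",
                              burst_photons = NULL) {
  nb <- stats::rpois(1, bg_rate * duration)
  t <- stats::runif(nb, 0, duration)
  for (t0 in burst_starts) {
    k <- if (is.null(burst_photons)) stats::rpois(1, burst_rate * burst_len)
         else burst_photons
    t <- c(t, stats::runif(k, t0, t0 + burst_len))
  }
  make_stream(sort(t), duration, channel)
}

# brute-force all-pairs void-map oracle: voxel available iff no bead center
# is strictly within (probe + bead radius) of its center, and the in-membrane
# wall rule holds; must match void_map() voxel by voxel
brute_force_void <- function(frame, probe_radius, grid) {
  g <- grid$geometry
  R <- g$pore_diameter / 2
  dims <- grid$dims
  avail <- array(TRUE, dim = dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      cx <- grid$x[i]; cy <- grid$y[j]; cz <- grid$z[k]
      if (grid$in_membrane[k] && sqrt(cx^2 + cy^2) > R - probe_radius) {
        avail[i, j, k] <- FALSE
        next
      }
      if (nrow(frame) > 0L) {
        d2 <- (frame$x - cx)^2 + (frame$y - cy)^2 + (frame$z - cz)^2
        if (any(d2 < (probe_radius + frame$radius)^2))
          avail[i, j, k] <- FALSE
      }
    }
  avail
}

# tiny pore geometry whose grid stays below 33^3 voxels
tiny_geometry <- function() {
  pore_geometry(pore_diameter = 10, membrane_thickness = 8,
                bulk_margin = 4, lateral_margin = 4, scaffold_bead_radius = 1.5)
}

# free-space photophysics inputs: all power ratios 1, symmetric emission
freespace_inputs <- function(z = seq(-50, 50, by = 2)) {
  data.frame(z = z, iex = 1,
             pr_h = 1, pff_h = 1, pffdet_h = 0.5,
             pr_v = 1, pff_v = 1, pffdet_v = 0.5)
}

alexa488_ref <- function() fluorophore_ref(2.30, dye = "alexa488")
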