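#' Synthetic dipole power and excitation profiles near a zero-mode waveguide
#'
#' Emulates the z-profiles an electromagnetic solver would export for a
#' nanoaperture: the excitation intensity decays exponentially inside the
#' aperture (evanescent confinement) with 1/e length `decay_length`, a
#' fraction `loss_fraction_profile` of the radiated dipole power is absorbed
#' by the metal, and a fraction `asymmetry_profile` of the far-field power
#' leaves toward the detection side. The membrane entrance is at z = 0 and
#' the aperture interior has z < 0.
#'
#' @param z_grid sorted z positions in nm.
#' @param decay_length evanescent 1/e decay length in nm (10-20 nm is typical
#'   for visible light in sub-100 nm apertures).
#' @param loss_fraction_profile scalar or per-z fraction of radiated power
#'   absorbed by the metal, in `[0, 1]`.
#' @param asymmetry_profile scalar or per-z fraction of far-field power
#'   emitted toward the detection side, in `[0, 1]`.
#' @param total_power_profile scalar or per-z total radiated power relative
#'   to free space (`P_r / P_r0`).
#' @param entrance_z z position of the aperture entrance, nm.
#' @return a data frame of class `photophysics_inputs` with columns `z`,
#'   `iex`, and per orientation `o` in `h`, `v`: `pr_o`, `pff_o`, `pffdet_o`
#'   (all powers relative to the free-space radiated power).
#' @export
gen_power_profiles <- function(z_grid, decay_length,
                               loss_fraction_profile = 0,
                               asymmetry_profile = 0.5,
                               total_power_profile = 1,
                               entrance_z = 0) {
  if (is.unsorted(z_grid, strictly = TRUE))
    stop("'z_grid' must be strictly increasing")
  stopifnot_scalar(decay_length, "decay_length", min = 0, strict_min = TRUE)
  n <- length(z_grid)
  expand <- function(p, name, lo = 0, hi = Inf) {
    p <- rep_len(p, n)
    if (any(!is.finite(p)) || any(p < lo) || any(p > hi))
      stop("'", name, "' must lie in [", lo, ", ", hi, "]")
    p
  }
  loss <- expand(loss_fraction_profile, "loss_fraction_profile", 0, 1)
  asym <- expand(asymmetry_profile, "asymmetry_profile", 0, 1)
  pr <- expand(total_power_profile, "total_power_profile", 0)
  iex <- exp(pmin(z_grid - entrance_z, 0) / decay_length)
  pff <- pr * (1 - loss)
  pffdet <- pff * asym
  out <- data.frame(z = z_grid, iex = iex,
                    pr_h = pr, pff_h = pff, pffdet_h = pffdet,
                    pr_v = pr, pff_v = pff, pffdet_v = pffdet)
  class(out) <- c("photophysics_inputs", "data.frame")
  out
}

#' Ground truth for a rate-versus-diameter model
#'
#' Parameters of the quadratic size-dependence model
#' `k = alpha * (r - r_prot - b)^2` used to simulate concentration-normalized
#' event-rate tables with known truth.
#'
#' @param alpha scaling factor in Hz nM^-1 nm^-2.
#' @param r_prot protein radius in nm.
#' @param offset_b onset shift in nm (thickness of the selective coating;
#'   0 for open pores).
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   noise applied to the rates.
#' @param diameters pore diameters in nm.
#' @return an object of class `rate_model_truth`.
#' @export
rate_model_truth <- function(alpha, r_prot, offset_b = 0, noise_cv = 0,
                             diameters) {
  stopifnot_scalar(alpha, "alpha", min = 0)
  stopifnot_scalar(r_prot, "r_prot", min = 0)
  stopifnot_scalar(offset_b, "offset_b", min = 0)
  stopifnot_scalar(noise_cv, "noise_cv", min = 0)
  if (length(diameters) < 1L) stop("'diameters' must not be empty")
  if (any(diameters <= 2 * (r_prot + offset_b)))
    stop("all diameters must exceed 2 * (r_prot + offset_b)")
  structure(list(alpha = alpha, r_prot = r_prot, offset_b = offset_b,
                 noise_cv = noise_cv, diameters = diameters),
            class = "rate_model_truth")
}

#' Simulate a concentration-normalized rate table
#'
#' Rates follow `alpha * (r - r_prot - b)^2` perturbed by multiplicative
#' Gaussian noise with coefficient of variation `noise_cv`; the per-point SEM
#' column is set to `noise_cv * true_rate`, consistent with the noise model.
#'
#' @param truth a [rate_model_truth()].
#' @param seed integer seed, or `NULL`.
#' @return a `rate_table` data frame with columns `pore_id`, `diameter`,
#'   `radius`, `normalized_rate` (Hz/nM), `sem` (Hz/nM).
#' @export
gen_rate_dataset <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "rate_model_truth"))
  with_seed(seed, {
    r <- truth$diameters / 2
    k_true <- truth$alpha * (r - truth$r_prot - truth$offset_b)^2
    fac <- if (truth$noise_cv > 0)
      pmax(1 + truth$noise_cv * rnorm(length(r)), 0) else rep(1, length(r))
    out <- data.frame(pore_id = sprintf("pore%02d", seq_along(r)),
                      diameter = truth$diameters, radius = r,
                      normalized_rate = k_true * fac,
                      sem = truth$noise_cv * k_true,
                      stringsAsFactors = FALSE)
    class(out) <- c("rate_table", "data.frame")
    out
  })
}
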