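#' Built-in dye reference table
#'
#' Free-dye literature lifetimes and quantum yields used to derive the
#' intrinsic radiative rate of a labeled protein.
#'
#' @return data frame with columns `dye`, `tau_lit` (ns), `phi_lit`.
#' @export
dye_table <- function() {
  data.frame(dye = c("alexa488", "alexa647"),
             tau_lit = c(4.0, 1.37),
             phi_lit = c(0.80, 0.33),
             stringsAsFactors = FALSE)
}

#' Intrinsic quantum yield from a measured lifetime
#'
#' For a conjugate whose non-radiative rate differs from the free dye,
#' `phi0 = (tau0 / tau_lit) * phi_lit`. Values above 1 indicate inconsistent
#' inputs and raise an error rather than being clipped.
#'
#' @param tau0 measured fluorescence lifetime of the conjugate, ns.
#' @param tau_lit free-dye literature lifetime, ns.
#' @param phi_lit free-dye literature quantum yield.
#' @return intrinsic quantum yield in (0, 1].
#' @export
intrinsic_qy <- function(tau0, tau_lit, phi_lit) {
  stopifnot_scalar(tau0, "tau0", min = 0, strict_min = TRUE)
  stopifnot_scalar(tau_lit, "tau_lit", min = 0, strict_min = TRUE)
  stopifnot_scalar(phi_lit, "phi_lit", min = 0, strict_min = TRUE, max = 1)
  phi0 <- tau0 / tau_lit * phi_lit
  if (phi0 > 1)
    stop("implied intrinsic quantum yield ", format(phi0, digits = 3),
         " exceeds 1; check tau0/tau_lit/phi_lit")
  phi0
}

#' Fluorophore reference for photophysics calculations
#'
#' @param tau0_measured measured conjugate lifetime, ns.
#' @param dye name in [dye_table()], or `NULL` when `tau_lit`/`phi_lit` are
#'   given directly.
#' @param tau_lit,phi_lit free-dye reference values (override the table).
#' @return a `fluorophore_ref` list with `tau_lit`, `phi_lit`,
#'   `tau0_measured`, derived `phi0` and `gamma_r0 = phi_lit / tau_lit`
#'   (1/ns).
#' @export
fluorophore_ref <- function(tau0_measured, dye = NULL, tau_lit = NULL,
                            phi_lit = NULL) {
  if (!is.null(dye)) {
    tb <- dye_table()
    row <- tb[tb$dye == tolower(dye), ]
    if (nrow(row) != 1L)
      stop("unknown dye '", dye, "'; known: ",
           paste(tb$dye, collapse = ", "))
    if (is.null(tau_lit)) tau_lit <- row$tau_lit
    if (is.null(phi_lit)) phi_lit <- row$phi_lit
  }
  if (is.null(tau_lit) || is.null(phi_lit))
    stop("supply 'dye' or both 'tau_lit' and 'phi_lit'")
  phi0 <- intrinsic_qy(tau0_measured, tau_lit, phi_lit)
  structure(list(tau_lit = tau_lit, phi_lit = phi_lit,
                 tau0_measured = tau0_measured, phi0 = phi0,
                 gamma_r0 = phi_lit / tau_lit),
            class = "fluorophore_ref")
}

#' Relative radiative and loss rates from dipole powers
#'
#' The radiative rate scales with the far-field power and the loss rate with
#' the power absorbed by the metal:
#' `gamma_r / gamma_r0 = Pff / Pr0` and
#' `gamma_loss / gamma_r0 = (Pr - Pff) / Pr0`.
#'
#' @param p_r_rel total radiated power relative to free space.
#' @param p_ff_rel far-field power relative to the free-space radiated power.
#' @return list with `gamma_r_rel`, `gamma_loss_rel`.
#' @export
relative_rates <- function(p_r_rel, p_ff_rel) {
  if (any(p_ff_rel < 0) || any(p_r_rel < p_ff_rel))
    stop("power ordering violated: need p_r_rel >= p_ff_rel >= 0")
  list(gamma_r_rel = p_ff_rel, gamma_loss_rel = p_r_rel - p_ff_rel)
}

#' Quantum yield in the presence of the nanostructure
#'
#' `phi = gamma_r_rel / (gamma_r_rel + gamma_loss_rel + (1 - phi0) / phi0)`,
#' where the last term is the unchanged internal non-radiative rate in units
#' of the free-space radiative rate.
#'
#' @param gamma_r_rel,gamma_loss_rel relative rates (see
#'   [relative_rates()]).
#' @param phi0 intrinsic quantum yield.
#' @return modified quantum yield in `[0, 1]`.
#' @export
modified_qy <- function(gamma_r_rel, gamma_loss_rel, phi0) {
  if (any(gamma_r_rel < 0) || any(gamma_loss_rel < 0))
    stop("rates must be >= 0")
  stopifnot_scalar(phi0, "phi0", min = 0, strict_min = TRUE, max = 1)
  gamma_r_rel / (gamma_r_rel + gamma_loss_rel + (1 - phi0) / phi0)
}

#' Fluorescence lifetime in the presence of the nanostructure
#'
#' The inverse of the sum of all de-excitation rates:
#' `tau = (1 / gamma_r0) / (gamma_r_rel + gamma_loss_rel + (1-phi0)/phi0)`
#' with `gamma_r0 = phi_lit / tau_lit`. In free space (rates 1, 0) this
#' reduces to the measured lifetime `tau0`.
#'
#' @inheritParams modified_qy
#' @param fluor a [fluorophore_ref()].
#' @return lifetime in ns.
#' @export
modified_lifetime <- function(gamma_r_rel, gamma_loss_rel, fluor) {
  stopifnot(inherits(fluor, "fluorophore_ref"))
  if (any(gamma_r_rel < 0) || any(gamma_loss_rel < 0))
    stop("rates must be >= 0")
  (1 / fluor$gamma_r0) /
    (gamma_r_rel + gamma_loss_rel + (1 - fluor$phi0) / fluor$phi0)
}

#' Detection efficiency from far-field powers
#'
#' Fraction of the far-field power radiated toward the detection side:
#' `eta = Pff_det / Pff`.
#'
#' @param p_ff_det_rel far-field power toward the detection side.
#' @param p_ff_rel total far-field power.
#' @return efficiency in `[0, 1]`.
#' @export
detection_efficiency <- function(p_ff_det_rel, p_ff_rel) {
  if (any(p_ff_rel <= 0)) stop("far-field power must be > 0")
  if (any(p_ff_det_rel < 0) || any(p_ff_det_rel > p_ff_rel))
    stop("need 0 <= p_ff_det_rel <= p_ff_rel")
  p_ff_det_rel / p_ff_rel
}

#' Z-profile of detected signal, quantum yield, lifetime and efficiency
#'
#' Per dipole orientation the quantum yield, lifetime and detection
#' efficiency are computed from the power ratios; the detected signal is
#' `S(z) = Iex(z) * eta(z) * phi(z)`. Orientation averages use
#' `orientation_weights` (default 2:1 horizontal:vertical — two degenerate
#' horizontal dipole axes for an isotropic emitter). The signal is
#' normalized to its peak by default.
#'
#' @param inputs a `photophysics_inputs` data frame (see
#'   [gen_power_profiles()]) with columns `z`, `iex`, `pr_h`, `pff_h`,
#'   `pffdet_h`, `pr_v`, `pff_v`, `pffdet_v`. Power columns given on a
#'   different z grid can be passed via `power_inputs`; they are linearly
#'   interpolated onto the `z` grid of `inputs` and must cover it
#'   (extrapolation is an error).
#' @param fluor a [fluorophore_ref()].
#' @param orientation_weights weights `c(horizontal, vertical)`.
#' @param normalize `"peak"` (max S = 1) or `"integral"`.
#' @param power_inputs optional data frame with `z` and the power columns.
#' @return a `photophysics_profile` data frame with per-orientation and
#'   orientation-averaged `phi`, `tau` (ns), `eta`, and normalized `signal`.
#' @export
signal_profile <- function(inputs, fluor,
                           orientation_weights = c(horizontal = 2,
                                                   vertical = 1),
                           normalize = c("peak", "integral"),
                           power_inputs = NULL) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(fluor, "fluorophore_ref"))
  z <- inputs$z
  pw <- if (is.null(power_inputs)) inputs else power_inputs
  cols <- c("pr_h", "pff_h", "pffdet_h", "pr_v", "pff_v", "pffdet_v")
  if (!all(cols %in% names(pw)))
    stop("missing power columns: ",
         paste(setdiff(cols, names(pw)), collapse = ", "))
  if (!is.null(power_inputs)) {
    if (min(z) < min(pw$z) || max(z) > max(pw$z))
      stop("power profiles do not cover the excitation z grid; ",
           "extrapolation is not allowed")
    pw <- data.frame(z = z, lapply(pw[cols], function(v)
      approx(power_inputs$z, v, xout = z)$y))
    names(pw) <- c("z", cols)
  }
  wts <- orientation_weights / sum(orientation_weights)
  per_orient <- lapply(c(h = "h", v = "v"), function(o) {
    rr <- relative_rates(pw[[paste0("pr_", o)]], pw[[paste0("pff_", o)]])
    phi <- modified_qy(rr$gamma_r_rel, rr$gamma_loss_rel, fluor$phi0)
    tau <- modified_lifetime(rr$gamma_r_rel, rr$gamma_loss_rel, fluor)
    eta <- detection_efficiency(pw[[paste0("pffdet_", o)]],
                                pw[[paste0("pff_", o)]])
    list(phi = phi, tau = tau, eta = eta,
         s = inputs$iex * eta * phi)
  })
  avg <- function(field) wts[1] * per_orient$h[[field]] +
    wts[2] * per_orient$v[[field]]
  s_raw <- avg("s")
  if (all(s_raw == 0)) stop("detected signal is identically zero")
  s_norm <- switch(normalize,
                   peak = s_raw / max(s_raw),
                   integral = s_raw / trapz(z, s_raw))
  out <- data.frame(z = z,
                    phi_h = per_orient$h$phi, tau_h = per_orient$h$tau,
                    eta_h = per_orient$h$eta,
                    phi_v = per_orient$v$phi, tau_v = per_orient$v$tau,
                    eta_v = per_orient$v$eta,
                    phi = avg("phi"), tau = avg("tau"), eta = avg("eta"),
                    signal = s_norm)
  class(out) <- c("photophysics_profile", "data.frame")
  attr(out, "fluor") <- fluor
  attr(out, "orientation_weights") <- wts
  out
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Signal-averaged fluorescence lifetime
#'
#' `<tau>_S = int S(z) tau(z) dz / int S(z) dz` by the trapezoidal rule on
#' the stored grid; this is the lifetime a detector integrating over the
#' whole exit profile would report.
#'
#' @param profile a `photophysics_profile` (see [signal_profile()]).
#' @return lifetime in ns.
#' @export
signal_averaged_lifetime <- function(profile) {
  stopifnot(inherits(profile, "photophysics_profile"))
  denom <- trapz(profile$z, profile$signal)
  if (denom <= 0) stop("total signal is zero")
  trapz(profile$z, profile$signal * profile$tau) / denom
}
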