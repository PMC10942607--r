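#' Measurement condition for a translocation experiment
#'
#' One entry of the nine-condition concentration scheme (BSA at 0/250/500 nM
#' crossed with Kap95 at 0/100/1000 nM).
#'
#' @param conc_bsa,conc_kap analyte concentrations in nM.
#' @param dol_bsa,dol_kap degree of labeling (1 for BSA-Alexa488, 0.7 for
#'   Kap95-Alexa647).
#' @param labeled_fraction fraction of labeled molecules (0.2 when labeled
#'   protein is mixed 1:4 with unlabeled protein for large pores).
#' @param duration measurement duration in seconds.
#' @return an object of class `measurement_condition`.
#' @export
measurement_condition <- function(conc_bsa = 0, conc_kap = 0, dol_bsa = 1,
                                  dol_kap = 0.7, labeled_fraction = 1,
                                  duration = NA_real_) {
  stopifnot_scalar(conc_bsa, "conc_bsa", min = 0)
  stopifnot_scalar(conc_kap, "conc_kap", min = 0)
  if (conc_bsa > 0) stopifnot_scalar(dol_bsa, "dol_bsa", min = 0,
                                     strict_min = TRUE, max = 1)
  if (conc_kap > 0) stopifnot_scalar(dol_kap, "dol_kap", min = 0,
                                     strict_min = TRUE, max = 1)
  stopifnot_scalar(labeled_fraction, "labeled_fraction", min = 0,
                   strict_min = TRUE, max = 1)
  structure(list(conc_bsa = conc_bsa, conc_kap = conc_kap,
                 dol_bsa = dol_bsa, dol_kap = dol_kap,
                 labeled_fraction = labeled_fraction, duration = duration),
            class = "measurement_condition")
}

#' Pore record from TEM sizing
#'
#' @param pore_id identifier.
#' @param diameter_min,diameter_max minimum and maximum TEM diameters in nm;
#'   the pore diameter is their arithmetic mean.
#' @param coating `"open"` (passivated) or `"nsp1"`.
#' @return an object of class `pore_record`.
#' @export
pore_record <- function(pore_id, diameter_min, diameter_max,
                        coating = c("open", "nsp1")) {
  if (diameter_max < diameter_min)
    stop("'diameter_max' must be >= 'diameter_min'")
  structure(list(pore_id = pore_id, diameter_min = diameter_min,
                 diameter_max = diameter_max,
                 diameter = (diameter_min + diameter_max) / 2,
                 coating = match.arg(coating)),
            class = "pore_record")
}

#' Concentration-normalize an event rate
#'
#' Divides the measured event rate by the concentration of the species, its
#' degree of labeling and the labeled fraction, optionally applying a
#' hydrodynamic flow correction (the applied detection-side pressure reduces
#' measured event rates by about 5%, i.e. `flow_correction = 1/0.95`).
#'
#' @param rate an `event_rate_estimate` (see [event_rate()]).
#' @param condition a [measurement_condition()].
#' @param species `"Kap95"` or `"BSA"`.
#' @param flow_correction multiplicative correction factor (default 1).
#' @return list with `k` (Hz/nM) and `sd` (Hz/nM).
#' @export
normalize_event_rate <- function(rate, condition, species = c("Kap95", "BSA"),
                                 flow_correction = 1.0) {
  species <- match.arg(species)
  conc <- if (species == "Kap95") condition$conc_kap else condition$conc_bsa
  dol <- if (species == "Kap95") condition$dol_kap else condition$dol_bsa
  if (conc <= 0)
    stop("concentration of ", species, " is zero in this condition")
  scale <- flow_correction / (conc * dol * condition$labeled_fraction)
  list(k = rate$rate * scale, sd = rate$sd * scale)
}

#' Average normalized rates of one pore across conditions
#'
#' @param k normalized rates (Hz/nM) measured at the different conditions.
#' @return list with `mean` and `sem` (sample SD over sqrt(n); 0 when n = 1).
#' @export
aggregate_pore <- function(k) {
  if (length(k) < 1L) stop("no rates to aggregate")
  list(mean = mean(k),
       sem = if (length(k) > 1L) sd(k) / sqrt(length(k)) else 0)
}

#' Selectivity ratio of a pore
#'
#' Ratio of the average normalized Kap95 and BSA event rates, with relative
#' errors added in quadrature.
#'
#' @param k_kap,k_bsa mean normalized rates (Hz/nM).
#' @param err_kap,err_bsa their standard errors.
#' @return list with `ratio` and `err`.
#' @export
selectivity_ratio <- function(k_kap, k_bsa, err_kap = 0, err_bsa = 0) {
  if (k_bsa <= 0) stop("BSA rate must be > 0")
  s <- k_kap / k_bsa
  rel <- sqrt((if (k_kap > 0) (err_kap / k_kap)^2 else 0) +
              (err_bsa / k_bsa)^2)
  list(ratio = s, err = s * rel)
}

#' Diffusion-limited translocation rate through a cylindrical pore
#'
#' Fick's law for free diffusion through a pore of radius `r` and length `L`:
#' `kappa = pi r^2 D delta_c / L` events per second.
#'
#' @param D diffusion coefficient in m^2/s.
#' @param r pore radius in m.
#' @param L pore length in m.
#' @param delta_c concentration difference in molecules/m^3 (see
#'   [nM_to_per_m3()]).
#' @return absolute rate in events/s.
#' @export
fick_rate <- function(D, r, L, delta_c) {
  stopifnot_scalar(D, "D", min = 0, strict_min = TRUE)
  stopifnot_scalar(r, "r", min = 0)
  stopifnot_scalar(L, "L", min = 0, strict_min = TRUE)
  pi * r^2 * D * delta_c / L
}

#' Predicted open-pore selectivity from Fick's law
#'
#' For an open pore the normalized rates of the two species follow
#' `D (r - r_prot)^2`, so the predicted selectivity is
#' `D_kap (r - r_kap)^2 / (D_bsa (r - r_bsa)^2)`, approaching `D_kap/D_bsa`
#' for large pores. With Stokes-Einstein diffusivities `D` proportional to
#' `1/r_prot`, the default asymptote is `r_bsa / r_kap` (about 0.76).
#'
#' @param r pore radius in nm.
#' @param r_kap,r_bsa protein radii in nm.
#' @param D_ratio `D_kap / D_bsa`; default from Stokes-Einstein,
#'   `r_bsa / r_kap`.
#' @return predicted selectivity ratio.
#' @export
fick_selectivity <- function(r, r_kap = 4.5, r_bsa = 3.4,
                             D_ratio = r_bsa / r_kap) {
  D_ratio * (r - r_kap)^2 / (r - r_bsa)^2
}

rate_table_weights <- function(sem) {
  w <- 1 / sem^2
  if (any(!is.finite(w))) {
    finite <- w[is.finite(w)]
    w[!is.finite(w)] <- if (length(finite)) median(finite) else 1
  }
  w
}

#' Fit the quadratic size-dependence model
#'
#' Weighted least squares of `k = alpha * (r - r_prot)^2` with the protein
#' radius fixed; `alpha` has the closed form `sum(w k x) / sum(w x^2)` with
#' `x = (r - r_prot)^2` and weights `1/sem^2` (points with zero SEM receive
#' the median finite weight).
#'
#' @param table a `rate_table` with columns `radius` (or `diameter`),
#'   `normalized_rate`, `sem`.
#' @param r_prot protein radius in nm.
#' @return an `npc_fit` list with `alpha`, `alpha_sd`, `residual_norm`.
#' @export
fit_quadratic <- function(table, r_prot) {
  tb <- as_rate_table(table)
  if (all(tb$radius <= r_prot)) stop("all radii are <= r_prot")
  x <- (tb$radius - r_prot)^2
  w <- rate_table_weights(tb$sem)
  alpha <- sum(w * tb$normalized_rate * x) / sum(w * x^2)
  res <- tb$normalized_rate - alpha * x
  n <- length(x)
  s2 <- if (n > 1L) sum(w * res^2) / (n - 1L) else 0
  structure(list(alpha = alpha, alpha_sd = sqrt(s2 / sum(w * x^2)),
                 r_prot = r_prot, offset_b = 0,
                 residual_norm = sqrt(sum(w * res^2))),
            class = "npc_fit")
}

as_rate_table <- function(table) {
  tb <- as.data.frame(table)
  if (!"radius" %in% names(tb)) {
    if (!"diameter" %in% names(tb))
      stop("rate table needs a 'radius' or 'diameter' column")
    tb$radius <- tb$diameter / 2
  }
  if (!"sem" %in% names(tb)) tb$sem <- 0
  stopifnot(all(c("normalized_rate") %in% names(tb)))
  tb
}

#' Fit the offset quadratic size-dependence model
#'
#' Weighted nonlinear least squares of `k = alpha * (r - r_prot - b)^2` with
#' `b >= 0`. The onset shift `b` reduces the pore radius effectively
#' accessible to the probe and estimates the thickness of the selective
#' coating on the wall. Fitting uses Levenberg-Marquardt
#' ([minpack.lm::nlsLM]) with a bounded `b`; the boundary solution `b = 0`
#' (which reduces the model exactly to [fit_quadratic()]) is always compared
#' against the interior optimum. Parameter SDs come from the covariance of
#' the linearized problem at the optimum.
#'
#' @inheritParams fit_quadratic
#' @return an `npc_fit` list with `alpha`, `offset_b`, their SDs, and
#'   `residual_norm`.
#' @export
fit_offset_quadratic <- function(table, r_prot) {
  tb <- as_rate_table(table)
  if (length(unique(tb$radius)) < 3L)
    stop("need at least 3 points with distinct radii")
  w <- rate_table_weights(tb$sem)
  k <- tb$normalized_rate
  r <- tb$radius
  sse_b <- function(b) {
    x <- (r - r_prot - b)^2
    a <- sum(w * k * x) / sum(w * x^2)
    sum(w * (k - a * x)^2)
  }
  b_hi <- max(r) - r_prot - 1e-6
  if (b_hi <= 0) stop("all radii are <= r_prot")
  b0 <- optimize(sse_b, c(0, b_hi), tol = 1e-8)$minimum
  x0 <- (r - r_prot - b0)^2
  a0 <- sum(w * k * x0) / sum(w * x0^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(k ~ alpha * (r - r_prot - b)^2,
                      start = list(alpha = max(a0, 1e-12), b = max(b0, 0)),
                      lower = c(0, 0), weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    sse_lm <- sse_b(cf[["b"]])
    if (sse_lm <= sse_b(b0) + 1e-12) {
      a0 <- cf[["alpha"]]
      b0 <- cf[["b"]]
    }
  }
  if (sse_b(0) <= sse_b(b0)) {  # boundary: nested quadratic model
    b0 <- 0
    x0 <- (r - r_prot)^2
    a0 <- sum(w * k * x0) / sum(w * x0^2)
  }
  # covariance of the linearized problem at the optimum
  x0 <- (r - r_prot - b0)^2
  J <- cbind(alpha = x0, b = -2 * a0 * (r - r_prot - b0))
  res <- k - a0 * x0
  n <- length(k)
  s2 <- if (n > 2L) sum(w * res^2) / (n - 2L) else 0
  JtWJ <- crossprod(J * sqrt(w))
  cov <- tryCatch(s2 * solve(JtWJ), error = function(e)
    matrix(NA_real_, 2, 2))
  structure(list(alpha = a0, alpha_sd = sqrt(cov[1, 1]),
                 offset_b = b0, offset_b_sd = sqrt(cov[2, 2]),
                 r_prot = r_prot,
                 residual_norm = sqrt(sum(w * res^2)),
                 converged = TRUE),
            class = "npc_fit")
}

#' @export
print.npc_fit <- function(x, ...) {
  cat("<npc_fit>\n")
  if (!is.null(x$alpha))
    cat(sprintf("  alpha   = %.6g +/- %.2g Hz/nM/nm^2\n",
                x$alpha, x$alpha_sd))
  if (!is.null(x$offset_b) && x$offset_b != 0 || !is.null(x$offset_b_sd))
    cat(sprintf("  b       = %.6g +/- %.2g nm\n", x$offset_b,
                if (is.null(x$offset_b_sd)) 0 else x$offset_b_sd))
  if (!is.null(x$sigma_v))
    cat(sprintf("  sigma_V = %.6g +/- %.2g nm\n", x$sigma_v, x$sigma_v_sd))
  invisible(x)
}

#' Kap95-concentration dependence of BSA permeation
#'
#' Ratios of the normalized BSA event rate at 100 and 1000 nM Kap95 to the
#' rate without Kap95, per pore and averaged within diameter classes
#' (small < 50 nm, intermediate 50-60 nm, large >= 60 nm). Errors propagate
#' in quadrature from the per-condition SEMs.
#'
#' @param table data frame with columns `pore_id`, `diameter`, `k_bsa_0`,
#'   `k_bsa_100`, `k_bsa_1000` and optional `sem_0`, `sem_100`, `sem_1000`.
#' @return list with `per_pore` (ratios and errors per pore) and `by_class`
#'   (class averages with SEM).
#' @export
kap_dependence <- function(table) {
  tb <- as.data.frame(table)
  need <- c("pore_id", "diameter", "k_bsa_0", "k_bsa_100", "k_bsa_1000")
  if (!all(need %in% names(tb)))
    stop("missing columns: ", paste(setdiff(need, names(tb)), collapse = ", "))
  if (any(tb$k_bsa_0 <= 0)) stop("baseline rate k_bsa_0 must be > 0")
  for (s in c("sem_0", "sem_100", "sem_1000"))
    if (!s %in% names(tb)) tb[[s]] <- 0
  ratio_err <- function(num, den, e_num, e_den)
    (num / den) * sqrt((e_num / num)^2 + (e_den / den)^2)
  per_pore <- data.frame(
    pore_id = tb$pore_id, diameter = tb$diameter,
    ratio_100 = tb$k_bsa_100 / tb$k_bsa_0,
    ratio_100_err = ratio_err(tb$k_bsa_100, tb$k_bsa_0, tb$sem_100, tb$sem_0),
    ratio_1000 = tb$k_bsa_1000 / tb$k_bsa_0,
    ratio_1000_err = ratio_err(tb$k_bsa_1000, tb$k_bsa_0, tb$sem_1000,
                               tb$sem_0),
    stringsAsFactors = FALSE)
  cls <- cut(tb$diameter, c(-Inf, 50, 60, Inf),
             labels = c("small", "intermediate", "large"), right = FALSE)
  agg <- function(v) {
    m <- tapply(v, cls, mean)
    s <- tapply(v, cls, function(x)
      if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0)
    list(mean = m, sem = s)
  }
  a100 <- agg(per_pore$ratio_100)
  a1000 <- agg(per_pore$ratio_1000)
  by_class <- data.frame(class = levels(cls),
                         n = as.integer(table(cls)),
                         ratio_100 = as.numeric(a100$mean),
                         ratio_100_sem = as.numeric(a100$sem),
                         ratio_1000 = as.numeric(a1000$mean),
                         ratio_1000_sem = as.numeric(a1000$sem),
                         stringsAsFactors = FALSE)
  list(per_pore = per_pore, by_class = by_class)
}

#' Selective area fraction of a large coated pore
#'
#' Under the selective-area model each grafted chain renders a volume near
#' the wall selective; at wall grafting the selective cross-section is an
#' annulus of thickness `sigma_v`, giving an area fraction `2 sigma_v / r`
#' (capped at 1).
#'
#' @param r pore radius in nm.
#' @param sigma_v effective selective-layer thickness in nm.
#' @return fraction in `[0, 1]`.
#' @export
selective_area_fraction <- function(r, sigma_v) {
  if (any(r <= 0)) stop("'r' must be > 0")
  if (any(sigma_v < 0)) stop("'sigma_v' must be >= 0")
  pmin(2 * sigma_v / r, 1)
}

#' Apparent selectivity of a pore split into selective and open areas
#'
#' With a fraction `f` of the cross-section selective (selectivity `s_sel`)
#' and the rest behaving like an open pore (`s_open`), the default
#' `"harmonic"` mixing assumes the Kap95 flux is uniform over the area while
#' BSA fluxes add per area: `s_app = 1 / (f/s_sel + (1-f)/s_open)`. The
#' `"arithmetic"` alternative mixes the selectivities linearly.
#'
#' @param f selective area fraction in `[0, 1]`.
#' @param s_sel selectivity of the selective area (small coated pores).
#' @param s_open selectivity of an open pore.
#' @param mixing `"harmonic"` (default) or `"arithmetic"`.
#' @return apparent selectivity.
#' @export
apparent_selectivity <- function(f, s_sel, s_open,
                                 mixing = c("harmonic", "arithmetic")) {
  mixing <- match.arg(mixing)
  if (any(f < 0 | f > 1)) stop("'f' must lie in [0, 1]")
  if (any(c(s_sel, s_open) <= 0)) stop("selectivities must be > 0")
  switch(mixing,
         harmonic = 1 / (f / s_sel + (1 - f) / s_open),
         arithmetic = f * s_sel + (1 - f) * s_open)
}

#' Fit the effective selective-layer thickness
#'
#' Least squares of
#' `apparent_selectivity(selective_area_fraction(r, sigma_v))` against the
#' observed selectivities of large pores, weighted by `1/err^2` when errors
#' are supplied. The SD of `sigma_v` comes from the linearized problem at
#' the optimum.
#'
#' @param diameter pore diameters in nm (pores >= `min_diameter` are used).
#' @param selectivity observed selectivity ratios.
#' @param err optional selectivity errors.
#' @param s_sel,s_open selectivities of the selective and open areas.
#' @param min_diameter smallest diameter included (default 60 nm).
#' @param mixing passed to [apparent_selectivity()].
#' @return an `npc_fit` list with `sigma_v`, `sigma_v_sd`, `n_pores`.
#' @export
fit_sigmaV <- function(diameter, selectivity, err = NULL, s_sel, s_open,
                       min_diameter = 60, mixing = "harmonic") {
  keep <- diameter >= min_diameter
  if (sum(keep) < 2L) stop("need at least 2 pores with diameter >= ",
                           min_diameter, " nm")
  r <- diameter[keep] / 2
  s <- selectivity[keep]
  w <- if (is.null(err)) rep(1, length(r)) else rate_table_weights(err[keep])
  if (all(s <= s_open))
    warning("all selectivities are at or below the open-pore value; ",
            "sigma_v is degenerate at 0")
  pred <- function(sv) apparent_selectivity(
    selective_area_fraction(r, max(sv, 0)), s_sel, s_open, mixing)
  sse <- function(sv) sum(w * (s - pred(sv))^2)
  hi <- max(r)  # f saturates at 1 for sigma_v >= r/2
  opt <- optimize(sse, c(0, hi), tol = 1e-9)$minimum
  if (sse(0) <= sse(opt)) opt <- 0
  # refine by local quadratic steps (optimize tolerance is ~sqrt(eps))
  for (i in 1:4) {
    hstep <- max(1e-7, 1e-7 * opt)
    if (opt < hstep) break
    g <- (sse(opt + hstep) - sse(opt - hstep)) / (2 * hstep)
    hess <- (sse(opt + hstep) - 2 * sse(opt) + sse(opt - hstep)) / hstep^2
    if (is.finite(g) && is.finite(hess) && hess > 0) {
      cand <- max(0, opt - g / hess)
      if (sse(cand) <= sse(opt)) opt <- cand
    }
  }
  hstep <- max(1e-6, 1e-6 * opt)
  J <- if (opt >= hstep)
    (pred(opt + hstep) - pred(opt - hstep)) / (2 * hstep)
  else (pred(opt + hstep) - pred(opt)) / hstep
  res <- s - pred(opt)
  n <- length(s)
  s2 <- if (n > 1L) sum(w * res^2) / (n - 1L) else 0
  sv_sd <- sqrt(s2 / sum(w * J^2))
  structure(list(sigma_v = opt, sigma_v_sd = sv_sd, n_pores = n,
                 s_sel = s_sel, s_open = s_open,
                 residual_norm = sqrt(sum(w * res^2))),
            class = "npc_fit")
}
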