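#' Parameters for change-point burst detection
#'
#' @param alpha_cp per-test false-positive probability of the likelihood-ratio
#'   test for a rate change. The critical value uses the chi-squared (1 df)
#'   approximation with a Bonferroni correction over the candidate split
#'   positions of the segment.
#' @param min_photons_per_segment smallest segment (in photons) the recursion
#'   may produce.
#' @param bg_rate_factor a segment is kept as a burst when its mean rate is at
#'   least this multiple of the background rate (duration-weighted median of
#'   segment rates).
#' @param min_event_photons minimum photons for a retained burst.
#' @return an object of class `change_point_params`.
#' @export
change_point_params <- function(alpha_cp = 0.01, min_photons_per_segment = 5,
                                bg_rate_factor = 3, min_event_photons = 5) {
  stopifnot_scalar(alpha_cp, "alpha_cp", min = 0, strict_min = TRUE, max = 1)
  if (alpha_cp >= 1) stop("'alpha_cp' must be < 1")
  stopifnot_scalar(min_photons_per_segment, "min_photons_per_segment", min = 1)
  stopifnot_scalar(bg_rate_factor, "bg_rate_factor", min = 0)
  stopifnot_scalar(min_event_photons, "min_event_photons", min = 1)
  structure(list(alpha_cp = alpha_cp,
                 min_photons_per_segment = as.integer(min_photons_per_segment),
                 bg_rate_factor = bg_rate_factor,
                 min_event_photons = as.integer(min_event_photons)),
            class = "change_point_params")
}

# generalized log-likelihood ratio for one rate change after photon k of a
# segment of N photons observed over [t1, tN]:
#   Lambda(k) = k log(k/T1) + (N-k) log((N-k)/T2) - N log(N/T)
cp_loglik <- function(times) {
  n <- length(times)
  t1 <- times[1]
  tn <- times[n]
  total <- tn - t1
  k <- seq_len(n - 1L)
  T1 <- times[k] - t1
  T2 <- tn - times[k]
  lam <- rep(-Inf, n - 1L)
  ok <- T1 > 0 & T2 > 0
  lam[ok] <- k[ok] * log(k[ok] / T1[ok]) +
    (n - k[ok]) * log((n - k[ok]) / T2[ok]) - n * log(n / total)
  lam
}

#' Detect rate change points in a photon arrival-time record
#'
#' Recursive binary segmentation of a (presumed piecewise-homogeneous)
#' Poisson process. At each level the candidate split maximizes the
#' generalized log-likelihood ratio for a single rate change; the split is
#' accepted when twice the ratio exceeds the chi-squared (1 df) critical
#' value at the Bonferroni-corrected level `alpha_cp / (N - 1)`. Recursion
#' stops when no split is accepted or a child would fall below
#' `min_photons_per_segment` photons.
#'
#' @param times sorted photon arrival times in seconds.
#' @param params a [change_point_params()].
#' @return sorted integer vector of change-point indices: a value `k` means
#'   the rate changes between photons `k` and `k + 1`.
#' @export
detect_change_points <- function(times, params = change_point_params()) {
  if (is.unsorted(times)) stop("'times' must be sorted")
  if (length(times) < 2L) return(integer(0))
  mps <- params$min_photons_per_segment
  alpha <- params$alpha_cp
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * mps) return(integer(0))
    lam <- cp_loglik(times[lo:hi])
    k <- seq_len(n - 1L)
    admissible <- k >= mps & (n - k) >= mps
    if (!any(admissible)) return(integer(0))
    lam[!admissible] <- -Inf
    kbest <- which.max(lam)
    crit <- qchisq(1 - alpha / (n - 1L), df = 1)
    if (!is.finite(lam[kbest]) || 2 * lam[kbest] <= crit) return(integer(0))
    split <- lo + kbest - 1L
    c(recurse(lo, split), split, recurse(split + 1L, hi))
  }
  sort(recurse(1L, length(times)))
}

# segments implied by change points: rows of (first, last) photon indices
cp_segments <- function(n, cps) {
  bounds <- c(0L, cps, n)
  data.frame(first = head(bounds, -1L) + 1L, last = tail(bounds, -1L))
}

weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Extract fluorescence bursts from a photon stream
#'
#' Each channel is segmented independently by [detect_change_points()]. Every
#' segment becomes a candidate burst with boundaries on photon arrival times;
#' the background rate is the duration-weighted median of segment rates, and
#' a segment is retained as a burst when its mean rate is at least
#' `bg_rate_factor` times the background and it holds at least
#' `min_event_photons` photons. Segments failing the criterion are flagged
#' `is_background`; adjacent bursts are never merged.
#'
#' @param stream a `photon_stream` (see [gen_photon_stream()]).
#' @param params a [change_point_params()].
#' @param channels channels to process (default both).
#' @return a `burst_table` data frame with columns `t_start`, `t_stop` (s),
#'   `n_photons`, `mean_rate` (Hz), `channel`, `is_background`. The estimated
#'   background rate per channel is attached as attribute
#'   `"background_rate"`.
#' @export
extract_bursts <- function(stream, params = change_point_params(),
                           channels = levels(stream$channels)) {
  stopifnot(inherits(stream, "photon_stream"))
  rows <- list()
  bg_rates <- setNames(numeric(length(channels)), channels)
  for (ch in channels) {
    t <- stream$macrotimes[stream$channels == ch]
    if (length(t) < 2L) next
    cps <- detect_change_points(t, params)
    seg <- cp_segments(length(t), cps)
    t_start <- t[seg$first]
    t_stop <- t[seg$last]
    n_ph <- seg$last - seg$first + 1L
    dur <- t_stop - t_start
    rate <- ifelse(dur > 0, n_ph / dur, Inf)
    bg <- weighted_median(rate[dur > 0], dur[dur > 0])
    bg_rates[ch] <- bg
    keep <- is.finite(rate) & rate >= params$bg_rate_factor * bg &
      n_ph >= params$min_event_photons
    rows[[ch]] <- data.frame(t_start = t_start, t_stop = t_stop,
                             n_photons = n_ph, mean_rate = rate,
                             channel = ch, is_background = !keep,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_start = numeric(0), t_stop = numeric(0),
               n_photons = integer(0), mean_rate = numeric(0),
               channel = character(0), is_background = logical(0))
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("burst_table", "data.frame")
  attr(out, "background_rate") <- bg_rates
  out
}

#' Event rate with Poisson uncertainty
#'
#' Translocation events are assumed to follow Poisson statistics, so the
#' purely statistical uncertainty of the rate `n / T` is `sqrt(n) / T`.
#'
#' @param bursts a `burst_table` (background-flagged rows are not counted),
#'   or a number of events.
#' @param duration measurement duration in seconds.
#' @return an `event_rate_estimate`: list with `rate` (Hz), `sd` (Hz),
#'   `n_events`, `duration`.
#' @export
event_rate <- function(bursts, duration) {
  stopifnot_scalar(duration, "duration", min = 0, strict_min = TRUE)
  n <- if (is.data.frame(bursts)) sum(!bursts$is_background)
       else as.integer(bursts)
  structure(list(rate = n / duration, sd = sqrt(n) / duration,
                 n_events = n, duration = duration),
            class = "event_rate_estimate")
}

#' @export
print.event_rate_estimate <- function(x, ...) {
  cat(sprintf("<event_rate_estimate> %.4g +/- %.2g Hz (%d events / %.4g s)\n",
              x$rate, x$sd, x$n_events, x$duration))
  invisible(x)
}

#' Molecular-brightness quality control
#'
#' Datasets whose mean photons per event deviate from the reference
#' brightness by more than `tolerance` (relative) are flagged; drifting
#' brightness (misalignment, air bubbles) biases event detection and such
#' datasets should be excluded from rate comparisons.
#'
#' @param bursts a `burst_table`; only retained (non-background) bursts are
#'   considered.
#' @param reference_brightness expected photons per event.
#' @param tolerance allowed relative deviation (default 30%).
#' @return list with `mean_brightness`, `reference`, `relative_deviation`,
#'   `pass`.
#' @export
brightness_qc <- function(bursts, reference_brightness, tolerance = 0.3) {
  stopifnot_scalar(reference_brightness, "reference_brightness",
                   min = 0, strict_min = TRUE)
  keep <- if (is.data.frame(bursts) && "is_background" %in% names(bursts))
    bursts[!bursts$is_background, , drop = FALSE] else bursts
  if (NROW(keep) < 1L) stop("no retained bursts to assess")
  mb <- mean(keep$n_photons)
  dev <- abs(mb - reference_brightness) / reference_brightness
  list(mean_brightness = mb, reference = reference_brightness,
       relative_deviation = dev, pass = dev <= tolerance)
}

#' Fluorescence lifetime by single-exponential tail fit
#'
#' Maximum-likelihood fit of a mono-exponential decay to microtimes beyond
#' `t_start` (default 1.160 ns, skipping the instrument response). For an
#' exponential truncated at the end of the TCSPC window the MLE solves
#' `mean(s) = tau - W exp(-W/tau) / (1 - exp(-W/tau))` with `s = t - t_start`
#' and `W = window - t_start`; without truncation it reduces to the sample
#' mean of the shifted times.
#'
#' @param microtimes photon microtimes in ns.
#' @param t_start tail-fit start in ns.
#' @param window TCSPC window length in ns; `NULL` disables the truncation
#'   correction.
#' @return fitted lifetime in ns.
#' @export
tail_fit_lifetime <- function(microtimes, t_start = 1.160, window = NULL) {
  s <- microtimes[microtimes >= t_start] - t_start
  if (length(s) < 100L)
    stop("need at least 100 photons beyond t_start (have ", length(s), ")")
  m <- mean(s)
  if (is.null(window)) return(m)
  W <- window - t_start
  if (W <= 0) stop("'window' must exceed 't_start'")
  f <- function(tau) tau - W * exp(-W / tau) / (1 - exp(-W / tau)) - m
  # f is increasing in tau; bracket the root
  hi <- max(2 * m, 1e-3)
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  uniroot(f, c(1e-9, hi), tol = 1e-12)$root
}
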