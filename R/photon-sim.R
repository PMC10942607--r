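#' Configuration for simulated two-channel photon streams
#'
#' Describes a confocal single-photon experiment on a nanopore: a constant
#' Poisson background on each detection channel plus translocation bursts
#' that arrive as a Poisson process and emit photons at constant brightness
#' for an exponentially distributed duration. Every photon carries a TCSPC
#' microtime drawn from a mono-exponential decay.
#'
#' @param duration measurement duration in seconds.
#' @param background_rate_per_channel background rate in Hz on each channel.
#' @param event_rate true translocation-burst arrival rate in Hz (summed over
#'   both channels; bursts are assigned to a channel at random).
#' @param burst_duration_mean mean burst duration in seconds.
#' @param burst_brightness photon emission rate in photons/s during a burst.
#' @param lifetime_true mono-exponential fluorescence lifetime in ns used for
#'   the microtimes.
#' @param irf_offset offset of the decay start within the TCSPC window, ns.
#' @param tcspc_window TCSPC window length in ns (25 ns corresponds to a
#'   40 MHz pulsed laser).
#' @param seed integer seed; the same seed reproduces the same stream.
#' @return an object of class `photon_sim_config`.
#' @seealso [gen_photon_stream()]
#' @export
photon_sim_config <- function(duration = 60,
                              background_rate_per_channel = 1000,
                              event_rate = 2,
                              burst_duration_mean = 5e-3,
                              burst_brightness = 2e4,
                              lifetime_true = 2.3,
                              irf_offset = 1.0,
                              tcspc_window = 25,
                              seed = 1L) {
  stopifnot_scalar(duration, "duration", min = 0, strict_min = TRUE)
  stopifnot_scalar(background_rate_per_channel, "background_rate_per_channel",
                   min = 0)
  stopifnot_scalar(event_rate, "event_rate", min = 0)
  stopifnot_scalar(burst_duration_mean, "burst_duration_mean",
                   min = 0, strict_min = TRUE)
  stopifnot_scalar(burst_brightness, "burst_brightness", min = 0)
  stopifnot_scalar(lifetime_true, "lifetime_true", min = 0, strict_min = TRUE)
  stopifnot_scalar(irf_offset, "irf_offset", min = 0)
  stopifnot_scalar(tcspc_window, "tcspc_window", min = 0, strict_min = TRUE)
  if (irf_offset >= tcspc_window)
    stop("'irf_offset' must be smaller than 'tcspc_window'")
  structure(list(duration = duration,
                 background_rate_per_channel = background_rate_per_channel,
                 event_rate = event_rate,
                 burst_duration_mean = burst_duration_mean,
                 burst_brightness = burst_brightness,
                 lifetime_true = lifetime_true,
                 irf_offset = irf_offset,
                 tcspc_window = tcspc_window,
                 seed = seed),
            class = "photon_sim_config")
}

.photon_channels <- c("red", "blue")

new_photon_stream <- function(ticks, microtimes, channels, duration,
                              ticks_per_second, condition = NULL) {
  structure(list(ticks = ticks,
                 macrotimes = ticks / ticks_per_second,
                 microtimes = microtimes,
                 channels = factor(channels, levels = .photon_channels),
                 duration = duration,
                 ticks_per_second = ticks_per_second,
                 condition = condition),
            class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  cat("<photon_stream> ", length(x$ticks), " photons over ",
      format(x$duration), " s (", round(length(x$ticks) / x$duration),
      " Hz); channels: ",
      paste(sprintf("%s=%d", levels(x$channels), tabulate(x$channels, 2L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# enforce a strictly increasing integer tick sequence (minimal right-shifts)
strictify_ticks <- function(ticks) {
  n <- length(ticks)
  if (n < 2L) return(ticks)
  cummax(ticks - seq_len(n)) + seq_len(n)
}

#' Simulate a two-channel photon stream with translocation bursts
#'
#' Background photons arrive as homogeneous Poisson processes on the red and
#' blue channels. Translocation bursts arrive as a Poisson process with rate
#' `event_rate`; each burst is assigned to a random channel and emits photons
#' at constant rate `burst_brightness` over an exponentially distributed
#' duration (no diffusion-shaped intensity profile). Microtimes are
#' mono-exponential with lifetime `lifetime_true`, shifted by `irf_offset`
#' and wrapped into the TCSPC window. Macrotimes are stored as integer ticks
#' and strictly ordered.
#'
#' @param cfg a [photon_sim_config()].
#' @param ticks_per_second macrotime clock rate (ticks per second).
#' @return a `photon_stream` with elements `ticks`, `macrotimes` (s),
#'   `microtimes` (ns), `channels`, `duration`, `ticks_per_second`. The
#'   ground-truth burst table (t_start, t_stop, channel, n_photons) is
#'   attached as attribute `"truth"`.
#' @export
gen_photon_stream <- function(cfg, ticks_per_second = 1e8) {
  stopifnot(inherits(cfg, "photon_sim_config"))
  with_seed(cfg$seed, {
    t_all <- numeric(0)
    ch_all <- character(0)
    for (ch in .photon_channels) {
      nb <- rpois(1L, cfg$background_rate_per_channel * cfg$duration)
      t_all <- c(t_all, runif(nb, 0, cfg$duration))
      ch_all <- c(ch_all, rep(ch, nb))
    }
    n_ev <- rpois(1L, cfg$event_rate * cfg$duration)
    truth <- data.frame(t_start = numeric(0), t_stop = numeric(0),
                        channel = character(0), n_photons = integer(0),
                        stringsAsFactors = FALSE)
    if (n_ev > 0L) {
      starts <- runif(n_ev, 0, cfg$duration)
      durs <- rexp(n_ev, 1 / cfg$burst_duration_mean)
      chans <- sample(.photon_channels, n_ev, replace = TRUE)
      nph <- integer(n_ev)
      for (i in seq_len(n_ev)) {
        k <- rpois(1L, cfg$burst_brightness * durs[i])
        tp <- starts[i] + runif(k, 0, durs[i])
        tp <- tp[tp <= cfg$duration]
        nph[i] <- length(tp)
        t_all <- c(t_all, tp)
        ch_all <- c(ch_all, rep(chans[i], length(tp)))
      }
      truth <- data.frame(t_start = starts,
                          t_stop = pmin(starts + durs, cfg$duration),
                          channel = chans, n_photons = nph,
                          stringsAsFactors = FALSE)
      truth <- truth[order(truth$t_start), , drop = FALSE]
      rownames(truth) <- NULL
    }
    ord <- order(t_all)
    t_all <- t_all[ord]
    ch_all <- ch_all[ord]
    micro <- (cfg$irf_offset + rexp(length(t_all), 1 / cfg$lifetime_true)) %%
      cfg$tcspc_window
    ticks <- strictify_ticks(round(t_all * ticks_per_second))
    out <- new_photon_stream(ticks, micro, ch_all, cfg$duration,
                             ticks_per_second)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate TCSPC microtimes from a mono-exponential decay
#'
#' Draws `irf_offset + Exp(lifetime)` and wraps the result into the TCSPC
#' window (photons emitted after the next laser pulse show up early in the
#' following window, as in a real TCSPC histogram).
#'
#' @param n number of photons (>= 1).
#' @param lifetime decay constant in ns (> 0).
#' @param irf_offset decay start within the window, ns.
#' @param window TCSPC window length in ns.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return numeric vector of `n` microtimes in `[0, window)` ns.
#' @export
gen_decay_microtimes <- function(n, lifetime, irf_offset = 0, window = 25,
                                 seed = NULL) {
  stopifnot_scalar(n, "n", min = 1)
  stopifnot_scalar(lifetime, "lifetime", min = 0, strict_min = TRUE)
  stopifnot_scalar(irf_offset, "irf_offset", min = 0)
  stopifnot_scalar(window, "window", min = 0, strict_min = TRUE)
  if (irf_offset >= window) stop("'irf_offset' must be smaller than 'window'")
  with_seed(seed, (irf_offset + rexp(n, 1 / lifetime)) %% window)
}
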