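#' One-sided power spectrum with dominant-frequency extraction
#'
#' Subtracts the window mean (removing the DC component), applies a
#' discrete Fourier transform with a rectangular window (no taper) and
#' returns the one-sided power spectrum, normalized so that the summed
#' power equals the windowed signal variance (Parseval). The dominant
#' frequency is the raw argmax bin above 0 Hz, with no interpolation; the
#' frequency resolution is 1 / (window length in seconds).
#'
#' @param lfp numeric LFP trace in mV.
#' @param dt sampling step in seconds.
#' @param window `c(t_start, t_end)` in seconds relative to the start of
#'   the trace; defaults to the whole trace. Must span at least 1 s so the
#'   resolution suffices for beta-band statements.
#'
#' @return An object of class `"nmm_spectrum"`: list with `freqs` (Hz,
#'   ascending from 0), `power` (mV^2 per bin), `dominant_freq` (Hz; `NA`
#'   with a `flat` flag when the windowed signal is constant) and
#'   `dominant_power`.
#' @examples
#' tgrid <- seq(0, 3, by = 1e-4)[-1]
#' sp <- power_spectrum(sin(2 * pi * 22 * tgrid), dt = 1e-4)
#' sp$dominant_freq  # 22 Hz (bin resolution 1/3 Hz)
#' @export
power_spectrum <- function(lfp, dt, window = NULL) {
  n_total <- length(lfp)
  if (is.null(window)) window <- c(0, n_total * dt)
  stopifnot(length(window) == 2, window[1] >= 0, window[2] > window[1])
  if (window[2] - window[1] < 1 - 1e-9) {
    stop("spectrum window must span at least 1 s (resolution too coarse ",
         "below that)", call. = FALSE)
  }
  i0 <- as.integer(round(window[1] / dt)) + 1L
  i1 <- as.integer(round(window[2] / dt))
  if (i1 > n_total) stop("spectrum window extends past the trace",
                         call. = FALSE)
  x <- lfp[i0:i1]
  n <- length(x)
  x <- x - mean(x)

  X <- fft(x)
  # two-sided |X|^2 / n^2 sums to var(x); fold onto one side
  p2 <- Mod(X)^2 / n^2
  half <- seq_len(floor(n / 2) + 1L)
  power <- p2[half]
  if (n %% 2L == 0L) {
    power[2:(length(half) - 1L)] <- 2 * power[2:(length(half) - 1L)]
  } else if (length(half) > 1L) {
    power[2:length(half)] <- 2 * power[2:length(half)]
  }
  freqs <- (half - 1L) / (n * dt)

  flat <- max(power[-1L]) <= .Machine$double.eps * max(1, sum(power))
  if (flat) {
    dom_f <- NA_real_
    dom_p <- 0
  } else {
    k <- which.max(power[-1L]) + 1L
    dom_f <- freqs[k]
    dom_p <- power[k]
  }
  structure(list(freqs = freqs, power = power,
                 dominant_freq = dom_f, dominant_power = dom_p,
                 flat = flat, resolution = 1 / (n * dt)),
            class = "nmm_spectrum")
}

#' @export
print.nmm_spectrum <- function(x, ...) {
  if (x$flat) {
    cat("<nmm_spectrum> flat signal (no dominant frequency)\n")
  } else {
    cat(sprintf("<nmm_spectrum> dominant %.3g Hz (power %.3g mV^2), resolution %.3g Hz\n",
                x$dominant_freq, x$dominant_power, x$resolution))
  }
  invisible(x)
}

last_second_index <- function(n, dt, from_s) {
  i0 <- as.integer(round(from_s / dt)) + 1L
  if (i0 > n) stop("trace too short: needs at least ", from_s + dt,
                   " s at dt = ", dt, call. = FALSE)
  i0:n
}

#' Oscillation index (OI)
#'
#' Quantifies the oscillatory level of an LFP over the final simulated
#' second (excluding the transient and the stimulation-settling period):
#' the sum of squared deviations from the window mean over samples
#' `2/dt + 1 ... N`, divided by `1/dt` - i.e. the mean squared deviation
#' of the last second. Implemented exactly as this printed index (no
#' square root); `sqrt = TRUE` returns its square root, which is the
#' root-mean-square deviation.
#'
#' @param lfp numeric LFP trace in mV, covering at least 3 s.
#' @param dt sampling step in seconds.
#' @param sqrt return the square root of the index (default `FALSE`).
#' @return OI in mV^2 (or mV when `sqrt = TRUE`); always >= 0.
#' @examples
#' tg <- seq(0, 3, by = 1e-4)[-1]
#' oscillation_index(2 * sin(2 * pi * 5 * tg), 1e-4)  # ~ A^2/2 = 2
#' @export
oscillation_index <- function(lfp, dt, sqrt = FALSE) {
  n <- length(lfp)
  if (n < round(3 / dt)) {
    stop("oscillation_index needs a trace covering at least 3 s",
         call. = FALSE)
  }
  idx <- last_second_index(n, dt, 2)
  x <- lfp[idx]
  oi <- sum((x - mean(x))^2) / (1 / dt)
  if (sqrt) base::sqrt(oi) else oi
}

#' Energy index (EI)
#'
#' Average stimulation power over the post-onset window: the sum of
#' squared stimulation-signal samples over `1/dt + 1 ... N` (i.e.
#' t in (1 s, 3 s]) divided by `2/dt`. Proxy for the energy the
#' stimulator expends; 0 for unstimulated runs. Scales quadratically with
#' the signal amplitude.
#'
#' @param w_trace stimulation-signal trace in mV, covering 3 s.
#' @param dt sampling step in seconds.
#' @return EI in mV^2; always >= 0.
#' @export
energy_index <- function(w_trace, dt) {
  n <- length(w_trace)
  if (n < round(3 / dt)) {
    stop("energy_index needs a trace covering at least 3 s", call. = FALSE)
  }
  idx <- last_second_index(n, dt, 1)
  sum(w_trace[idx]^2) / (2 / dt)
}

#' Last-second extrema of an LFP trace
#'
#' Maximum and minimum of the trace over its final second
#' (t in (2 s, 3 s]), as used for bifurcation diagrams versus the
#' stimulation intensity.
#'
#' @param lfp numeric LFP trace in mV, covering at least 3 s.
#' @param dt sampling step in seconds.
#' @return Named numeric vector `c(max = ..., min = ...)`; `max == min`
#'   iff the signal is constant on the window.
#' @export
trace_extrema <- function(lfp, dt) {
  n <- length(lfp)
  if (n < round(3 / dt)) {
    stop("trace_extrema needs a trace covering at least 3 s", call. = FALSE)
  }
  x <- lfp[last_second_index(n, dt, 2)]
  c(max = max(x), min = min(x))
}

#' Full metrics report for one simulation
#'
#' Computes per-nucleus oscillation indices, the energy index, and
#' per-nucleus power spectra. Unstimulated runs are analyzed over the full
#' trace; stimulated runs over the final 2 s (post-onset), mirroring the
#' transient-exclusion convention of the oscillation index.
#'
#' @param sim an `"nmm_sim"` object from [simulate_network()].
#' @param spectra also compute per-nucleus spectra (default `TRUE`).
#' @return An object of class `"nmm_metrics"`: list with `oi_stn`,
#'   `oi_gpe`, `oi_ppn`, `ei`, `dominant_freq` (named vector per nucleus,
#'   when `spectra`) and `spectra` (list per nucleus, when `spectra`).
#' @export
metrics_report <- function(sim, spectra = TRUE) {
  stopifnot(inherits(sim, "nmm_sim"))
  dt <- sim$config$dt
  out <- list(
    oi_stn = oscillation_index(sim$v_stn, dt),
    oi_gpe = oscillation_index(sim$v_gpe, dt),
    oi_ppn = oscillation_index(sim$v_ppn, dt),
    ei = energy_index(sim$w, dt)
  )
  if (spectra) {
    win <- if (is.null(sim$config$scheme)) NULL else
      c(sim$config$scheme$onset, sim$config$T)
    sp <- lapply(list(stn = sim$v_stn, gpe = sim$v_gpe, ppn = sim$v_ppn),
                 power_spectrum, dt = dt, window = win)
    out$spectra <- sp
    out$dominant_freq <- vapply(sp, function(s) s$dominant_freq, numeric(1))
  }
  structure(out, class = "nmm_metrics")
}

#' @export
print.nmm_metrics <- function(x, ...) {
  cat(sprintf("<nmm_metrics> OI (mV^2): STN %.4g, GPe %.4g, PPN %.4g; EI %.4g mV^2\n",
              x$oi_stn, x$oi_gpe, x$oi_ppn, x$ei))
  if (!is.null(x$dominant_freq)) {
    cat(sprintf("  dominant freq (Hz): STN %.3g, GPe %.3g, PPN %.3g\n",
                x$dominant_freq[["stn"]], x$dominant_freq[["gpe"]],
                x$dominant_freq[["ppn"]]))
  }
  invisible(x)
}
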