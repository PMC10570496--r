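#' Delayed-feedback stimulation scheme
#'
#' A scheme is defined by the nucleus receiving the stimulation (`target`),
#' the nucleus whose LFP drives it (`source`), the dimensionless intensity
#' `K` and the delay `tau`. The stimulation signal is the delayed
#' difference `w(t) = K * (v_source(t - tau) - v_source(t))`, switched on
#' at `onset` and injected as the sigmoid offset of the target nucleus.
#'
#' Four named presets are provided:
#' * `"A"` - stimulate STN with its own LFP, `K = 0.4`, `tau = 25` ms
#'   (the traditional self-feedback strategy);
#' * `"B"` - stimulate GPe with its own LFP, `K = -2`, `tau = 2` ms;
#' * `"C"` - stimulate GPe with the PPN LFP, `K = -2`, `tau = 4` ms;
#' * `"D"` - stimulate STN with the PPN LFP, `K = 3`, `tau = 8` ms.
#'
#' The excitatory targets (STN) take positive intensities and the
#' inhibitory target (GPe) negative ones; see the package vignette for the
#' reading of strategy C adopted here.
#'
#' @param target nucleus receiving the signal: `"stn"`, `"gpe"` or `"ppn"`.
#' @param source nucleus whose LFP drives the signal.
#' @param K stimulation intensity (dimensionless; sign matters).
#' @param tau_ms time delay in milliseconds; must be >= 0.
#' @param onset stimulation start time in seconds (default 1).
#' @param name optional label carried through sweep tables.
#'
#' @return An object of class `"stim_scheme"`: a list with fields `target`,
#'   `source`, `K`, `tau` (seconds), `tau_ms`, `onset`, `name`.
#' @seealso [scheme_preset()], [feedback_signal()], [route_stimulation()]
#' @examples
#' stim_scheme("stn", "stn", K = 0.4, tau_ms = 25)
#' scheme_preset("D")
#' @export
stim_scheme <- function(target, source, K, tau_ms, onset = 1, name = NULL) {
  target <- match_nucleus(target)
  source <- match_nucleus(source)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K)) {
    stop("stimulation intensity K must be a single finite number",
         call. = FALSE)
  }
  if (!is.numeric(tau_ms) || length(tau_ms) != 1L || !is.finite(tau_ms) ||
      tau_ms < 0) {
    stop("delay tau_ms must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(onset) || length(onset) != 1L || onset < 0) {
    stop("onset must be a single number >= 0 (seconds)", call. = FALSE)
  }
  structure(
    list(target = target, source = source, K = K,
         tau = tau_ms / 1000, tau_ms = tau_ms, onset = onset,
         name = if (is.null(name)) "custom" else name),
    class = "stim_scheme"
  )
}

#' Named stimulation strategy presets
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"` (see [stim_scheme()]).
#' @param onset stimulation start time in seconds (default 1).
#' @return A [stim_scheme()] object.
#' @export
scheme_preset <- function(name = c("A", "B", "C", "D"), onset = 1) {
  name <- match.arg(name)
  switch(name,
    A = stim_scheme("stn", "stn", K = 0.4, tau_ms = 25, onset = onset, name = "A"),
    B = stim_scheme("gpe", "gpe", K = -2,  tau_ms = 2,  onset = onset, name = "B"),
    C = stim_scheme("gpe", "ppn", K = -2,  tau_ms = 4,  onset = onset, name = "C"),
    D = stim_scheme("stn", "ppn", K = 3,   tau_ms = 8,  onset = onset, name = "D")
  )
}

match_nucleus <- function(x) {
  if (!is.character(x) || length(x) != 1L) {
    stop("nucleus identifier must be one of 'stn', 'gpe', 'ppn'",
         call. = FALSE)
  }
  x <- tolower(x)
  if (!x %in% c("stn", "gpe", "ppn")) {
    stop("unknown nucleus identifier '", x,
         "' (expected 'stn', 'gpe' or 'ppn')", call. = FALSE)
  }
  x
}

nucleus_index <- function(x) match(x, c("stn", "gpe", "ppn"))

#' @export
print.stim_scheme <- function(x, ...) {
  cat(sprintf(
    "<stim_scheme %s> target %s <- source %s LFP, K=%g, tau=%g ms, onset=%g s\n",
    x$name, toupper(x$target), toupper(x$source), x$K, x$tau_ms, x$onset))
  invisible(x)
}

#' Ring buffer over recent source-LFP samples
#'
#' Holds enough history to evaluate `v(t - tau)` on a fixed time grid. The
#' delay is discretized to `round(tau / dt)` steps; with the default step
#' of 0.1 ms all preset delays (25, 2, 4, 8 ms) are exact multiples, so
#' no rounding error is introduced for them.
#'
#' @param tau delay in seconds.
#' @param dt time step in seconds.
#' @return An object of class `"delay_buffer"` (environment) with methods
#'   used via [buffer_push()] and [buffer_lookup()].
#' @export
delay_buffer <- function(tau, dt) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  lag <- as.integer(round(tau / dt))
  buf <- new.env(parent = emptyenv())
  buf$lag <- lag
  buf$dt <- dt
  buf$samples <- numeric(lag + 1L)
  buf$n_pushed <- 0L
  buf$cursor <- 0L
  class(buf) <- "delay_buffer"
  buf
}

#' Record one source-LFP sample
#'
#' @param buf a [delay_buffer()].
#' @param v the sample (mV) at the current step.
#' @return The buffer, invisibly.
#' @export
buffer_push <- function(buf, v) {
  buf$cursor <- (buf$cursor %% length(buf$samples)) + 1L
  buf$samples[buf$cursor] <- v
  buf$n_pushed <- buf$n_pushed + 1L
  invisible(buf)
}

#' Look up the sample recorded `round(tau/dt)` steps ago
#'
#' @param buf a [delay_buffer()].
#' @return The delayed sample in mV; errors if the buffer does not yet
#'   span the requested delay.
#' @export
buffer_lookup <- function(buf) {
  if (buf$n_pushed <= buf$lag) {
    stop("delay buffer holds ", buf$n_pushed,
         " samples but the delay requires ", buf$lag + 1L, call. = FALSE)
  }
  len <- length(buf$samples)
  idx <- ((buf$cursor - 1L - buf$lag) %% len) + 1L
  buf$samples[idx]
}

#' Delayed-feedback stimulation signal
#'
#' Evaluates `w(t) = K * (v_source(t - tau) - v_source(t))` for `t` at or
#' after the scheme's onset, and 0 before it. The current sample must
#' already have been pushed into the buffer. The signal vanishes whenever
#' the source LFP has been constant over the delay interval, and for
#' `tau = 0` it is identically zero.
#'
#' @param buf a [delay_buffer()] fed with the source-LFP samples up to and
#'   including the current step.
#' @param current_v the source LFP at the current step (mV).
#' @param scheme a [stim_scheme()].
#' @param t current time in seconds.
#' @return The stimulation signal in mV.
#' @examples
#' sch <- stim_scheme("stn", "stn", K = 2, tau_ms = 10, onset = 0)
#' buf <- delay_buffer(sch$tau, dt = 1e-3)
#' for (i in 0:10) buffer_push(buf, i * 1e-3)   # unit ramp v(t) = t
#' feedback_signal(buf, 10e-3, sch, t = 10e-3)  # 2 * (-tau) = -0.02
#' @export
feedback_signal <- function(buf, current_v, scheme, t) {
  if (t < scheme$onset) return(0)
  scheme$K * (buffer_lookup(buf) - current_v)
}

#' Route a stimulation signal to its target nucleus
#'
#' @param scheme a [stim_scheme()].
#' @param w the stimulation signal (mV).
#' @return Named numeric vector `c(w_stn, w_gpe, w_ppn)` with `w` in the
#'   target slot and 0 elsewhere.
#' @export
route_stimulation <- function(scheme, w) {
  out <- c(w_stn = 0, w_gpe = 0, w_ppn = 0)
  out[nucleus_index(scheme$target)] <- w
  out
}
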