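#' Analytic test signals
#'
#' Deterministic traces with known metric values, used as oracles when
#' testing the spectral and index functions: a single sinusoid, a
#' constant, a unit-slope ramp, and a two-tone mixture. Signals are
#' sampled on the grid `t_i = (i - 1) * dt`, `i = 1..round(T/dt)`,
#' matching the simulator's convention.
#'
#' @param kind `"sin"`, `"const"`, `"ramp"` or `"two_tone"`.
#' @param dt sampling step in seconds.
#' @param T duration in seconds.
#' @param f,A frequency (Hz) and amplitude for `"sin"` (defaults 22, 1).
#' @param c level for `"const"` (default 3).
#' @param slope slope in mV/s for `"ramp"` (default 1).
#' @param f1,A1,f2,A2 the two tones for `"two_tone"`
#'   (defaults 10 Hz x 1, 30 Hz x 2).
#' @return Numeric trace of length `round(T/dt)`.
#' @examples
#' x <- make_fixture("sin", dt = 1e-4, T = 3, f = 22)
#' power_spectrum(x, 1e-4)$dominant_freq  # 22
#' @export
make_fixture <- function(kind, dt = 1e-4, T = 3,
                         f = 22, A = 1, c = 3, slope = 1,
                         f1 = 10, A1 = 1, f2 = 30, A2 = 2) {
  stopifnot(dt > 0, T > 0)
  tg <- (seq_len(round(T / dt)) - 1) * dt
  switch(kind,
    sin = A * sin(2 * pi * f * tg),
    const = rep(c, length(tg)),
    ramp = slope * tg,
    two_tone = A1 * sin(2 * pi * f1 * tg) + A2 * sin(2 * pi * f2 * tg),
    stop("unknown fixture kind '", kind, "'", call. = FALSE)
  )
}
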