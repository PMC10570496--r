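# Shared constants and small independent oracles for the metric tests.

DT <- 1e-4

summed_oi <- function(sim, dt = DT) {
  oscillation_index(sim$v_stn, dt) +
    oscillation_index(sim$v_gpe, dt) +
    oscillation_index(sim$v_ppn, dt)
}

# Brute-force oscillation index straight from the printed index bounds:
# sum over samples 2/dt + 1 .. N of squared deviation from the window
# mean, divided by 1/dt. Loop-based on purpose, as an independent oracle.
oi_bruteforce <- function(v, dt) {
  N <- length(v)
  idx <- (round(2 / dt) + 1):N
  m <- sum(v[idx]) / length(idx)
  acc <- 0
  for (i in idx) acc <- acc + (v[i] - m)^2
  acc / (1 / dt)
}

# Direct DFT power at one frequency (Goertzel-style), for spectrum checks.
dft_power_at <- function(x, dt, f) {
  n <- length(x)
  x <- x - mean(x)
  k <- round(f * n * dt)
  X <- sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n))
  2 * Mod(X)^2 / n^2
}
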