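test_that("power spectrum recovers single tones at bin resolution", {
  x <- make_fixture("sin", dt = DT, T = 3, f = 22, A = 1)
  sp <- power_spectrum(x, DT)
  expect_equal(sp$dominant_freq, 22, tolerance = 1e-9)
  expect_equal(sp$resolution, 1 / 3)
  expect_true(all(diff(sp$freqs) > 0) && sp$freqs[1] == 0)
})

test_that("constant traces are flagged flat after DC removal", {
  x <- make_fixture("const", dt = DT, T = 3, c = 5)
  sp <- power_spectrum(x, DT)
  expect_true(sp$flat)
  expect_true(is.na(sp$dominant_freq))
  expect_lt(sum(sp$power), 1e-20)
})

test_that("the larger of two tones wins and matches a direct DFT", {
  x <- make_fixture("two_tone", dt = DT, T = 3,
                    f1 = 10, A1 = 1, f2 = 30, A2 = 2)
  sp <- power_spectrum(x, DT)
  expect_equal(sp$dominant_freq, 30, tolerance = 1e-9)
  k30 <- which.min(abs(sp$freqs - 30))
  expect_equal(sp$power[k30], dft_power_at(x, DT, 30), tolerance = 1e-9)
  k10 <- which.min(abs(sp$freqs - 10))
  expect_equal(sp$power[k10], dft_power_at(x, DT, 10), tolerance = 1e-9)
})

test_that("summed spectral power equals the windowed variance (Parseval)", {
  set.seed(9)
  x <- cumsum(rnorm(round(2 / DT))) * 1e-2
  sp <- power_spectrum(x, DT)
  v <- mean((x - mean(x))^2)
  expect_equal(sum(sp$power), v, tolerance = 1e-10)
})

test_that("spectrum windows are validated", {
  x <- make_fixture("sin", dt = DT, T = 3)
  expect_error(power_spectrum(x, DT, window = c(0, 0.5)), "1 s")
  expect_error(power_spectrum(x, DT, window = c(2.5, 4)), "past the trace")
  sp <- power_spectrum(x, DT, window = c(1, 3))
  expect_equal(sp$resolution, 0.5)
})

test_that("oscillation index matches its analytic and brute-force oracles", {
  expect_equal(oscillation_index(make_fixture("const", c = 3), DT), 0)

  x <- make_fixture("sin", f = 5, A = 2)
  expect_equal(oscillation_index(x, DT), 2, tolerance = 1e-3)
  expect_equal(oscillation_index(x, DT), oi_bruteforce(x, DT))
  expect_equal(oscillation_index(x, DT, sqrt = TRUE),
               sqrt(oscillation_index(x, DT)))

  # invariance to constant shifts
  expect_equal(oscillation_index(x + 17.3, DT), oscillation_index(x, DT))

  set.seed(2)
  y <- make_fixture("sin", f = 13, A = 0.7) + rnorm(round(3 / DT), sd = 0.1)
  expect_equal(oscillation_index(y, DT), oi_bruteforce(y, DT))

  expect_error(oscillation_index(y[1:100], DT), "3 s")
})

test_that("energy index matches its oracles and scales quadratically", {
  expect_equal(energy_index(make_fixture("const", c = 0), DT), 0)
  expect_equal(energy_index(make_fixture("const", c = 1.5), DT), 1.5^2)
  w <- make_fixture("sin", f = 5, A = 1)
  expect_equal(energy_index(w, DT), 0.5, tolerance = 1e-6)
  for (a in c(0.1, 2, -3)) {
    expect_equal(energy_index(a * w, DT), a^2 * energy_index(w, DT))
  }
  expect_error(energy_index(w[1:10], DT), "3 s")
})

test_that("last-second extrema match analytic values", {
  expect_equal(trace_extrema(make_fixture("const", c = 3), DT),
               c(max = 3, min = 3))
  x <- 1.5 + make_fixture("sin", f = 8, A = 2)
  ex <- trace_extrema(x, DT)
  expect_equal(ex[["max"]], 3.5, tolerance = 1e-4)
  expect_equal(ex[["min"]], -0.5, tolerance = 1e-4)
  set.seed(1)
  z <- rnorm(round(3 / DT))
  ez <- trace_extrema(z, DT)
  expect_gte(ez[["max"]], ez[["min"]])
})

test_that("dominant frequency is invariant to constant LFP offsets", {
  sim <- simulate_network(seed = 8)
  f0 <- power_spectrum(sim$v_stn, DT)$dominant_freq
  f1 <- power_spectrum(sim$v_stn + 250, DT)$dominant_freq
  expect_identical(f0, f1)
})

test_that("metrics_report summarizes a run consistently", {
  sim <- simulate_network(seed = 4, scheme = scheme_preset("A"))
  mr <- metrics_report(sim)
  expect_equal(mr$oi_stn, oscillation_index(sim$v_stn, DT))
  expect_equal(mr$ei, energy_index(sim$w, DT))
  # stimulated spectra use the post-onset window (2 s -> 0.5 Hz bins)
  expect_equal(mr$spectra$stn$resolution, 0.5)
  expect_true(all(c("stn", "gpe", "ppn") %in% names(mr$dominant_freq)))
})
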