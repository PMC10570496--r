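test_that("external inputs reproduce their stated statistics", {
  cfg0 <- coupling_config("pathological", cor_sd = 0, str_sd = 0, gpi_sd = 0)
  set.seed(1)
  expect_equal(draw_external_inputs(cfg0),
               c(u_cor = 27, u_str = 2, u_gpi = 20))

  cfg <- coupling_config("pathological")
  set.seed(42); a <- replicate(5, draw_external_inputs(cfg))
  set.seed(42); b <- replicate(5, draw_external_inputs(cfg))
  expect_identical(a, b)

  n <- 30000
  set.seed(7)
  draws <- replicate(n, draw_external_inputs(cfg)["u_cor"])
  expect_lt(abs(mean(draws) - 27), 3 * 0.1 / sqrt(n))
})

test_that("one Euler step from rest matches the hand update", {
  pops <- default_populations()
  coupling <- coupling_config("pathological", cor_sd = 0, str_sd = 0,
                              gpi_sd = 0)
  dt <- 1e-4
  st <- step_model(model_state(), c(u_cor = 27, u_str = 2, u_gpi = 20),
                   populations = pops, coupling = coupling, dt = dt)
  # potentials unchanged after one step from rest; z picks up dt*gain/x*u
  expect_true(all(vapply(st, function(ch) ch$v, 0) == 0))
  u0 <- c(gpe = 200, cor = 27, ppn = 100, stn = 150, gpe = 200, str = 2,
          gpi = 20, stn = 150)  # sigmoid midpoints r/2 and the externals
  gains <- c(5 * 20, 20, 1 * 20, 20 * 20, 2 * 20, 20, 20, 13 * 20)
  x8 <- c(rep(0.006, 3), rep(0.014, 3), rep(0.005, 2))
  expect_equal(vapply(st, function(ch) ch$z, 0),
               dt * gains / x8 * u0, ignore_attr = TRUE)
})

test_that("two consecutive steps equal the composed update", {
  coupling <- coupling_config("pathological")
  set.seed(3); inp1 <- draw_external_inputs(coupling)
  set.seed(4); inp2 <- draw_external_inputs(coupling)
  s1 <- step_model(model_state(), inp1, coupling = coupling)
  s2 <- step_model(s1, inp2, coupling = coupling)
  s1b <- step_model(model_state(), inp1, coupling = coupling)
  s2b <- step_model(s1b, inp2, coupling = coupling)
  expect_identical(s2, s2b)
})

test_that("compiled and reference engines agree to the last bit", {
  sch <- stim_scheme("gpe", "ppn", K = -2, tau_ms = 4, onset = 0.05)
  a <- simulate_network(T = 0.2, seed = 11, scheme = sch,
                        engine = "compiled")
  b <- simulate_network(T = 0.2, seed = 11, scheme = sch, engine = "r")
  expect_identical(a$v_stn, b$v_stn)
  expect_identical(a$v_gpe, b$v_gpe)
  expect_identical(a$v_ppn, b$v_ppn)
  expect_identical(a$w, b$w)
})

test_that("identical seed and config reproduce traces bit-for-bit", {
  a <- simulate_network(seed = 123, scheme = scheme_preset("B"))
  b <- simulate_network(seed = 123, scheme = scheme_preset("B"))
  expect_identical(a$v_stn, b$v_stn)
  expect_identical(a$w, b$w)
})

test_that("unstimulated runs carry an all-zero stimulation trace", {
  sim <- simulate_network(T = 0.5, seed = 2)
  expect_true(all(sim$w == 0))
  stim <- simulate_network(T = 1.5, seed = 2,
                           scheme = scheme_preset("A", onset = 1))
  expect_true(all(stim$w[stim$t < 1] == 0))
  expect_true(any(stim$w[stim$t >= 1] != 0))
})

test_that("pathological coupling oscillates far above normal", {
  p <- simulate_network(coupling_config("pathological"), seed = 5)
  n <- simulate_network(coupling_config("normal"), seed = 5)
  dt <- DT
  for (nm in c("v_stn", "v_gpe", "v_ppn")) {
    expect_lt(oscillation_index(n[[nm]], dt),
              0.2 * oscillation_index(p[[nm]], dt))
  }
  expect_equal(power_spectrum(p$v_stn, dt)$dominant_freq, 22,
               tolerance = 0.1)
})

test_that("the simulator reports divergence with the step index", {
  expect_error(simulate_network(T = 200, dt = 1, seed = 1),
               "diverged.*step", )
  expect_error(simulate_network(T = 200, dt = 1, seed = 1, engine = "r"),
               "diverged.*step")
})

test_that("scheme validation guards onset and history", {
  expect_error(simulate_network(T = 0.5, scheme = scheme_preset("A")),
               "onset")
  expect_error(
    simulate_network(T = 3, scheme = stim_scheme("stn", "stn", 1,
                                                 tau_ms = 1500, onset = 1)),
    "history")
})

test_that("refining dt converges: stable frequency, shrinking OI error", {
  N <- round(3 / DT)
  set.seed(31)
  coarse <- matrix(rnorm(3 * N), ncol = 3, byrow = TRUE)
  # common random numbers: each coarse draw held over the finer substeps
  half <- coarse[rep(seq_len(N), each = 2), ]
  quarter <- coarse[rep(seq_len(N), each = 4), ]

  a <- simulate_network(noise = coarse, dt = DT)
  b <- simulate_network(noise = half, dt = DT / 2)
  c3 <- simulate_network(noise = quarter, dt = DT / 4)
  fa <- power_spectrum(a$v_stn, DT)$dominant_freq
  fb <- power_spectrum(b$v_stn, DT / 2)$dominant_freq
  expect_lt(abs(fa - fb), 1)

  oia <- oscillation_index(a$v_stn, DT)
  oib <- oscillation_index(b$v_stn, DT / 2)
  oic <- oscillation_index(c3$v_stn, DT / 4)
  # first-order consistency: successive refinements tighten the index
  expect_lt(abs(oib - oic), abs(oia - oib))
})
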