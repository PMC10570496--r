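test_that("sigmoid rate hits its midpoint, ceiling and exact values", {
  stn <- population_params(H = 20, x = 0.006, r = 300, y = 0.1)
  gpe_like <- population_params(H = 20, x = 0.014, r = 400, y = 0.1)

  expect_equal(sigmoid_rate(0, 0, stn), 150)                 # r/2 at midpoint
  expect_equal(sigmoid_rate(1e6, 0, gpe_like), 400)          # saturation
  expect_equal(sigmoid_rate(10, 0, stn), 300 / (1 + exp(-1)))
  expect_equal(sigmoid_rate(10, 0, stn), 219.4, tolerance = 1e-3)
  # the offset shifts the argument exactly like the potential does
  expect_equal(sigmoid_rate(3, 7, stn), sigmoid_rate(10, 0, stn))
})

test_that("sigmoid output stays inside (0, r) and is monotone", {
  pop <- population_params(H = 20, x = 0.005, r = 200, y = 0.1)
  # stay where double precision resolves the sigmoid tails
  v <- seq(-300, 300, length.out = 2001)
  u <- sigmoid_rate(v, 0, pop)
  expect_true(all(u > 0 & u < pop$r))
  expect_true(all(diff(u) > 0))
  expect_true(all(diff(sigmoid_rate(0, v, pop)) > 0))  # monotone in offset
})

test_that("sigmoid is antisymmetric about its midpoint", {
  pop <- population_params(H = 20, x = 0.006, r = 300, y = 0.1)
  v <- c(-40, -3, 0.5, 12, 90)
  expect_equal(sigmoid_rate(v, 0, pop) + sigmoid_rate(-v, 0, pop),
               rep(pop$r, length(v)))
})

test_that("sigmoid rejects non-finite input", {
  pop <- population_params(20, 0.006, 300, 0.1)
  expect_error(sigmoid_rate(NaN, 0, pop), "finite")
  expect_error(sigmoid_rate(0, Inf, pop), "finite")
})

test_that("population parameters are validated", {
  expect_error(population_params(-1, 0.006, 300, 0.1), "H")
  expect_error(population_params(20, 0, 300, 0.1), "x")
  expect_error(population_params(20, 0.006, -300, 0.1), "r")
  expect_error(population_params(20, 0.006, 300, 0), "y")
})

test_that("channel derivative matches the second-order kinetics", {
  # origin with zero input is a fixed point
  expect_equal(channel_derivative(list(v = 0, z = 0), 0, 17, 0.01),
               c(dv = 0, dz = 0))
  # hand evaluation of the linear form
  expect_equal(channel_derivative(list(v = 0.1, z = 0), 0, 20, 0.01),
               c(dv = 0, dz = -1000))
  # the DC equilibrium v* = gain * x * u zeroes both derivatives
  gain <- 20; x <- 0.006; u <- 1
  d <- channel_derivative(list(v = gain * x * u, z = 0), u, gain, x)
  expect_equal(d, c(dv = 0, dz = 0))
  expect_equal(gain * x * u, 0.12)
  expect_error(channel_derivative(list(v = 0, z = 0), 0, 20, -0.01), "> 0")
})

test_that("channel derivative is linear in the input (superposition)", {
  st <- list(v = 0.3, z = -2)
  for (case in list(c(1, 2), c(-4, 0.5), c(10, -10))) {
    d12 <- channel_derivative(st, case[1] + case[2], 15, 0.014)
    d1 <- channel_derivative(st, case[1], 15, 0.014)
    d2 <- channel_derivative(st, case[2], 15, 0.014)
    d0 <- channel_derivative(st, 0, 15, 0.014)
    expect_equal(d12, d1 + d2 - d0)
  }
})

test_that("simulated channel equilibrium matches the analytic DC gain", {
  # integrate one channel with constant input at the model's own step and
  # compare against gain * x * u (the transfer function at s = 0)
  gain <- 20; x <- 0.006; u <- 1; dt <- 1e-4
  st <- list(v = 0, z = 0)
  for (i in seq_len(round(1 / dt))) {
    d <- channel_derivative(st, u, gain, x)
    st$v <- st$v + dt * d[["dv"]]
    st$z <- st$z + dt * d[["dz"]]
  }
  expect_equal(st$v, gain * x * u, tolerance = 1e-3)
})

test_that("LFP composition uses the signed channel sums", {
  st <- model_state()
  st$stn1$v <- 1; st$stn2$v <- 2; st$stn3$v <- 3
  st$gpe1$v <- 5; st$gpe2$v <- 1; st$gpe3$v <- 2
  st$ppn1$v <- 1; st$ppn2$v <- 3
  lfp <- compose_lfp(st)
  expect_equal(unname(lfp), c(4, 2, 2))
  expect_named(lfp, c("v_stn", "v_gpe", "v_ppn"))
})

test_that("a zero-gain network stays identically at rest", {
  pops <- lapply(default_populations(), function(p)
    population_params(0, p$x, p$r, p$y))
  sim <- simulate_network(populations = pops, T = 0.1, seed = 1)
  expect_true(all(sim$v_stn == 0))
  expect_true(all(sim$v_gpe == 0))
  expect_true(all(sim$v_ppn == 0))
})
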