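#' Sigmoid pulse-density (firing rate) function
#'
#' Converts a population's summed membrane potential into an average pulse
#' density via the saturating sigmoid
#' `r / (1 + exp(-y * (v + w_stim)))`. The offset `w_stim` is the
#' delayed-feedback stimulation signal delivered to this population; it is
#' zero in unstimulated runs.
#'
#' @param v membrane potential in mV (vectorized).
#' @param w_stim stimulation offset in mV (default 0; recycled against `v`).
#' @param pop a [population_params()] object supplying `r` and `y`.
#'
#' @return Pulse density in 1/s, strictly inside `(0, r)` and monotone
#'   increasing in both `v` and `w_stim`.
#' @examples
#' stn <- population_params(20, 0.006, 300, 0.1)
#' sigmoid_rate(0, 0, stn)  # midpoint r/2 = 150
#' @export
sigmoid_rate <- function(v, w_stim = 0, pop) {
  if (!inherits(pop, "population_params")) {
    stop("'pop' must be a population_params object", call. = FALSE)
  }
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stop("membrane potential 'v' must be finite", call. = FALSE)
  }
  if (!is.numeric(w_stim) || anyNA(w_stim) || any(!is.finite(w_stim))) {
    stop("stimulation offset 'w_stim' must be finite", call. = FALSE)
  }
  pop$r / (1 + exp(-pop$y * (v + w_stim)))
}

#' One synaptic channel as a pair of first-order ODEs
#'
#' Each synaptic channel turns a presynaptic pulse density `u_in` into a
#' postsynaptic potential contribution `v` via the second-order kinetics
#' `v'' = (gain/x) u - (2/x) v' - (1/x^2) v`, written here as the pair
#' `dv/dt = z`, `dz/dt = (gain/x) u - (2/x) z - (1/x^2) v`. The DC gain of
#' the channel is `gain * x`: a constant input `u` settles at
#' `v = gain * x * u`.
#'
#' @param state named list or vector with elements `v` (mV) and `z` (mV/s).
#' @param u_in driving pulse density in 1/s.
#' @param gain effective synaptic gain in mV (a coupling strength times the
#'   population gain `H`, or `H` alone for external inputs).
#' @param x synaptic time constant in seconds; must be > 0.
#'
#' @return Named numeric vector `c(dv = ..., dz = ...)`.
#' @examples
#' channel_derivative(list(v = 0, z = 0), u_in = 1, gain = 20, x = 0.006)
#' @export
channel_derivative <- function(state, u_in, gain, x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("time constant 'x' must be a single number > 0", call. = FALSE)
  }
  v <- state[["v"]]
  z <- state[["z"]]
  c(dv = z, dz = (gain / x) * u_in - (2 / x) * z - v / x^2)
}

#' All-zero model state
#'
#' The full model state holds eight synaptic channels (16 scalar
#' variables): three afferent channels for STN (GPe inhibition, cortical
#' drive, PPN excitation), three for GPe (STN excitation, self-inhibition,
#' striatal drive) and two for PPN (GPi drive, STN excitation).
#'
#' @return A named list of eight channels, each `list(v = 0, z = 0)`, in
#'   order `stn1, stn2, stn3, gpe1, gpe2, gpe3, ppn1, ppn2`.
#' @export
model_state <- function() {
  chans <- c("stn1", "stn2", "stn3", "gpe1", "gpe2", "gpe3", "ppn1", "ppn2")
  stats::setNames(lapply(chans, function(ch) list(v = 0, z = 0)), chans)
}

#' Compose local field potentials from channel potentials
#'
#' The LFP of each nucleus is the signed sum of its afferent channel
#' potentials, with inhibitory channels entering negatively:
#' `v_STN = stn3 + stn2 - stn1` (PPN and cortex excite, GPe inhibits),
#' `v_GPe = gpe1 - gpe2 - gpe3` (STN excites, self-inhibition and striatum
#' inhibit), `v_PPN = ppn2 - ppn1` (STN excites, GPi inhibits).
#'
#' @param state a model state as returned by [model_state()] (or any list
#'   of the same shape).
#'
#' @return Named numeric vector `c(v_stn, v_gpe, v_ppn)` in mV.
#' @examples
#' st <- model_state(); st$stn2$v <- 2; st$stn3$v <- 3; st$stn1$v <- 1
#' compose_lfp(st)["v_stn"]  # 4
#' @export
compose_lfp <- function(state) {
  c(
    v_stn = state$stn3$v + state$stn2$v - state$stn1$v,
    v_gpe = state$gpe1$v - state$gpe2$v - state$gpe3$v,
    v_ppn = state$ppn2$v - state$ppn1$v
  )
}

# Effective gains and time constants for the 8 channels, in the fixed
# channel order used throughout (stn1..3, gpe1..3, ppn1..2).
channel_gains <- function(populations, coupling) {
  Hs <- populations$stn$H; Hg <- populations$gpe$H; Hp <- populations$ppn$H
  c(coupling$lambda1 * Hs, Hs, coupling$lambda5 * Hs,
    coupling$lambda2 * Hg, coupling$lambda3 * Hg, Hg,
    Hp, coupling$lambda4 * Hp)
}

channel_taus <- function(populations) {
  c(rep(populations$stn$x, 3), rep(populations$gpe$x, 3),
    rep(populations$ppn$x, 2))
}
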