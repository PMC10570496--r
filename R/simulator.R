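#' Draw one step of external inputs
#'
#' Draws the three noisy external pulse densities (cortical drive to STN,
#' striatal drive to GPe, GPi drive to PPN) for a single integration step,
#' as `mean + sd * N(0, 1)` with independent draws in the fixed order
#' Cor, Str, GPi. Uses R's current RNG stream, so results are reproducible
#' after `set.seed()`.
#'
#' @param coupling a [coupling_config()] supplying the input statistics.
#' @return Named numeric vector `c(u_cor, u_str, u_gpi)` in 1/s.
#' @examples
#' set.seed(1)
#' draw_external_inputs(coupling_config("pathological", cor_sd = 0))
#' @export
draw_external_inputs <- function(coupling) {
  z <- rnorm(3)
  c(u_cor = coupling$cor_mean + coupling$cor_sd * z[1],
    u_str = coupling$str_mean + coupling$str_sd * z[2],
    u_gpi = coupling$gpi_mean + coupling$gpi_sd * z[3])
}

#' Advance the model by one forward-Euler step
#'
#' Computes the pulse densities of the three populations from the current
#' LFPs via [sigmoid_rate()] (including any per-nucleus stimulation
#' offsets), evaluates all eight channel derivatives with the pathway
#' gains, and advances every `(v, z)` pair by one explicit Euler step.
#' This is the reference (pure R) update; [simulate_network()] uses an
#' identical compiled loop by default.
#'
#' @param state model state (see [model_state()]).
#' @param inputs external inputs as from [draw_external_inputs()].
#' @param offsets per-nucleus stimulation offsets
#'   `c(w_stn, w_gpe, w_ppn)` in mV (see [route_stimulation()]).
#' @param populations list of [population_params()] as from
#'   [default_populations()].
#' @param coupling a [coupling_config()].
#' @param dt time step in seconds.
#' @return The updated model state.
#' @export
step_model <- function(state, inputs, offsets = c(0, 0, 0),
                       populations = default_populations(),
                       coupling = coupling_config("pathological"),
                       dt = 1e-4) {
  lfp <- compose_lfp(state)
  u_stn <- sigmoid_rate(lfp[["v_stn"]], offsets[[1]], populations$stn)
  u_gpe <- sigmoid_rate(lfp[["v_gpe"]], offsets[[2]], populations$gpe)
  u_ppn <- sigmoid_rate(lfp[["v_ppn"]], offsets[[3]], populations$ppn)

  gains <- channel_gains(populations, coupling)
  taus <- channel_taus(populations)
  drives <- c(u_gpe, inputs[["u_cor"]], u_ppn,
              u_stn, u_gpe, inputs[["u_str"]],
              inputs[["u_gpi"]], u_stn)

  for (k in seq_along(state)) {
    d <- channel_derivative(state[[k]], drives[k], gains[k], taus[k])
    state[[k]]$v <- state[[k]]$v + dt * d[["dv"]]
    state[[k]]$z <- state[[k]]$z + dt * d[["dz"]]
  }
  if (!all(is.finite(unlist(state, use.names = FALSE)))) {
    stop("simulation diverged (non-finite state)", call. = FALSE)
  }
  state
}

#' Simulate the closed-loop network
#'
#' Integrates the three-population neural mass model with forward Euler,
#' redrawing the Gaussian external inputs independently at every step, and
#' (optionally) applying a delayed-feedback stimulation scheme from its
#' onset onward. LFPs are recorded on the grid `t_i = (i - 1) * dt`,
#' `i = 1..N` with `N = round(T / dt)`; the feedback signal at each step
#' is computed from the recorded LFP history (the pre-onset history is the
#' actually simulated trajectory) and injected as the sigmoid offset of
#' the target nucleus at that same step.
#'
#' All 16 state variables start at zero; the initial transient is excluded
#' from all metrics, which analyze the final portion of the run.
#'
#' @param coupling a [coupling_config()] (default: pathological preset).
#' @param populations population parameters as from [default_populations()].
#' @param scheme a [stim_scheme()], or `NULL` for an unstimulated run.
#' @param T total duration in seconds (default 3).
#' @param dt time step in seconds (default 1e-4).
#' @param seed integer seed; if non-`NULL`, `set.seed(seed)` is called
#'   before drawing the noise so runs are bit-for-bit reproducible.
#' @param noise optional `N x 3` matrix of standard-normal draws (columns
#'   Cor, Str, GPi) overriding internal noise generation; used e.g. for
#'   common-random-number step-size studies.
#' @param engine `"compiled"` (default) or `"r"`; both implement the same
#'   update rule, the R engine serving as a slow reference.
#'
#' @return An object of class `"nmm_sim"`: a list with the time grid `t`,
#'   LFP traces `v_stn`, `v_gpe`, `v_ppn`, the applied stimulation trace
#'   `w` (identically 0 before onset and when `scheme` is `NULL`), and a
#'   `config` echo (coupling, populations, scheme, `T`, `dt`, `seed`,
#'   generator family).
#' @examples
#' sim <- simulate_network(coupling_config("pathological"), seed = 1,
#'                         T = 3)
#' power_spectrum(sim$v_stn, sim$config$dt)$dominant_freq  # ~22 Hz
#' @export
simulate_network <- function(coupling = coupling_config("pathological"),
                             populations = default_populations(),
                             scheme = NULL, T = 3, dt = 1e-4,
                             seed = NULL, noise = NULL,
                             engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  stopifnot(is.numeric(T), T > 0, is.numeric(dt), dt > 0, dt < T)
  validate_coupling(coupling)
  N <- as.integer(round(T / dt))

  if (!is.null(scheme)) {
    if (!inherits(scheme, "stim_scheme")) {
      stop("'scheme' must be a stim_scheme object or NULL", call. = FALSE)
    }
    if (scheme$onset >= T) {
      stop("stimulation onset (", scheme$onset,
           " s) must fall within the run (T = ", T, " s)", call. = FALSE)
    }
    if (scheme$tau > scheme$onset) {
      stop("delay tau (", scheme$tau, " s) exceeds the history available ",
           "at onset (", scheme$onset, " s)", call. = FALSE)
    }
  }

  if (is.null(noise)) {
    if (!is.null(seed)) set.seed(seed)
    # byrow so that each step consumes three consecutive draws in the
    # fixed order Cor, Str, GPi
    noise <- matrix(rnorm(3L * N), ncol = 3L, byrow = TRUE)
  } else {
    noise <- as.matrix(noise)
    if (nrow(noise) != N || ncol(noise) != 3L) {
      stop("'noise' must be an N x 3 matrix with N = round(T/dt) = ", N,
           call. = FALSE)
    }
  }

  target <- if (is.null(scheme)) 0L else nucleus_index(scheme$target)
  source <- if (is.null(scheme)) 1L else nucleus_index(scheme$source)
  K <- if (is.null(scheme)) 0 else scheme$K
  delay_steps <- if (is.null(scheme)) 0L else as.integer(round(scheme$tau / dt))
  onset_step <- if (is.null(scheme)) N + 1L else
    as.integer(round(scheme$onset / dt)) + 1L

  pops <- unlist(lapply(populations[c("stn", "gpe", "ppn")],
                        function(p) c(p$H, p$x, p$r, p$y)),
                 use.names = FALSE)
  lam <- lambda_vector(coupling)
  means <- c(coupling$cor_mean, coupling$str_mean, coupling$gpi_mean)
  sds <- c(coupling$cor_sd, coupling$str_sd, coupling$gpi_sd)

  traces <- if (engine == "compiled") {
    sim_core(noise, pops, lam, means, sds, dt, target, source, K,
             delay_steps, onset_step)
  } else {
    sim_core_r(noise, pops, lam, means, sds, dt, target, source, K,
               delay_steps, onset_step)
  }

  structure(
    list(
      t = (seq_len(N) - 1) * dt,
      v_stn = traces$v_stn, v_gpe = traces$v_gpe, v_ppn = traces$v_ppn,
      w = traces$w,
      config = list(coupling = coupling, populations = populations,
                    scheme = scheme, T = T, dt = dt, seed = seed,
                    engine = engine,
                    generator = RNGkind()[1])
    ),
    class = "nmm_sim"
  )
}

# Pure-R reference implementation of the integration loop; mirrors
# sim_core() exactly and is compared against it in the test suite.
sim_core_r <- function(noise, pops, lam, means, sds, dt, target, source, K,
                       delay_steps, onset_step) {
  N <- nrow(noise)
  Hs <- pops[1]; xs <- pops[2]; rs <- pops[3]; ys <- pops[4]
  Hg <- pops[5]; xg <- pops[6]; rg <- pops[7]; yg <- pops[8]
  Hp <- pops[9]; xp <- pops[10]; rp <- pops[11]; yp <- pops[12]
  gain <- c(lam[1] * Hs, Hs, lam[5] * Hs, lam[2] * Hg, lam[3] * Hg, Hg,
            Hp, lam[4] * Hp)
  tc <- c(xs, xs, xs, xg, xg, xg, xp, xp)
  v <- numeric(8); z <- numeric(8)
  vs <- numeric(N); vg <- numeric(N); vp <- numeric(N); w <- numeric(N)

  for (i in seq_len(N)) {
    vstn <- v[3] + v[2] - v[1]
    vgpe <- v[4] - v[5] - v[6]
    vppn <- v[8] - v[7]
    vs[i] <- vstn; vg[i] <- vgpe; vp[i] <- vppn

    wi <- 0
    if (target > 0L && i >= onset_step) {
      j <- i - delay_steps
      if (j < 1L) stop("delay exceeds available history at step ", i,
                       call. = FALSE)
      cur <- switch(source, vstn, vgpe, vppn)
      past <- switch(source, vs[j], vg[j], vp[j])
      wi <- K * (past - cur)
    }
    w[i] <- wi

    uS <- rs / (1 + exp(-ys * (vstn + if (target == 1L) wi else 0)))
    uG <- rg / (1 + exp(-yg * (vgpe + if (target == 2L) wi else 0)))
    uP <- rp / (1 + exp(-yp * (vppn + if (target == 3L) wi else 0)))
    u <- c(uG, means[1] + sds[1] * noise[i, 1], uP,
           uS, uG, means[2] + sds[2] * noise[i, 2],
           means[3] + sds[3] * noise[i, 3], uS)

    dz <- gain / tc * u - 2 / tc * z - v / tc^2
    v <- v + dt * z
    z <- z + dt * dz
    if (!all(is.finite(v)) || !all(is.finite(z))) {
      stop("simulation diverged (non-finite state) at step ", i,
           call. = FALSE)
    }
  }
  list(v_stn = vs, v_gpe = vg, v_ppn = vp, w = w)
}

#' @export
print.nmm_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<nmm_sim> %d steps, T=%g s, dt=%g s, preset=%s, scheme=%s\n",
              length(x$t), cfg$T, cfg$dt,
              attr(cfg$coupling, "preset") %||% "custom",
              if (is.null(cfg$scheme)) "none" else cfg$scheme$name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
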