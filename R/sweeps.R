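#' Specification of a (K, tau) parameter sweep
#'
#' Defines the grid of stimulation intensities and delays to explore for a
#' scheme template, the number of noise replicates per cell and the base
#' seed. Replicate seeds are hashed from the base seed and the cell's
#' `(K, tau)` values (not grid indices), so refining a grid does not
#' change the values of existing cells.
#'
#' @param target,source nucleus identifiers for the scheme template.
#' @param k_grid numeric vector of stimulation intensities.
#' @param tau_ms_grid numeric vector of delays in ms (singleton for 1-D
#'   sweeps in K).
#' @param replicates noise replicates per cell (default 20).
#' @param base_seed integer base seed (default 1).
#' @param onset stimulation onset in seconds (default 1).
#' @param name scheme label carried into the result table.
#' @return An object of class `"sweep_spec"`.
#' @examples
#' sweep_spec("stn", "stn", k_grid = 0.4, tau_ms_grid = 1:50,
#'            replicates = 5, name = "A")
#' @export
sweep_spec <- function(target, source, k_grid, tau_ms_grid,
                       replicates = 20, base_seed = 1, onset = 1,
                       name = "custom") {
  target <- match_nucleus(target)
  source <- match_nucleus(source)
  stopifnot(length(k_grid) >= 1, all(is.finite(k_grid)),
            length(tau_ms_grid) >= 1, all(is.finite(tau_ms_grid)),
            all(tau_ms_grid >= 0), replicates >= 1)
  structure(
    list(target = target, source = source,
         k_grid = as.numeric(k_grid),
         tau_ms_grid = as.numeric(tau_ms_grid),
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         onset = onset, name = name),
    class = "sweep_spec"
  )
}

#' Sweep specification from a preset scheme
#'
#' Convenience wrapper building a [sweep_spec()] around one of the named
#' strategies, sweeping K at the preset delay, tau at the preset
#' intensity, or both.
#'
#' @param scheme a [stim_scheme()] (e.g. from [scheme_preset()]).
#' @param k_grid intensities to sweep; default: the scheme's own K.
#' @param tau_ms_grid delays (ms) to sweep; default: the scheme's own tau.
#' @param ... passed to [sweep_spec()] (`replicates`, `base_seed`).
#' @return A [sweep_spec()].
#' @export
sweep_spec_for <- function(scheme, k_grid = scheme$K,
                           tau_ms_grid = scheme$tau_ms, ...) {
  stopifnot(inherits(scheme, "stim_scheme"))
  sweep_spec(scheme$target, scheme$source, k_grid, tau_ms_grid,
             onset = scheme$onset, name = scheme$name, ...)
}

# Deterministic per-replicate seed hashed from the cell's parameter values,
# kept well below 2^31. Hashing on values (to 0.001 in K, 0.1 ms in tau)
# rather than grid indices keeps cell results stable under grid refinement.
cell_seed <- function(base_seed, K, tau_ms, replicate) {
  hk <- as.integer(round(K * 1000)) %% 100003L
  ht <- as.integer(round(tau_ms * 10)) %% 100003L
  h <- (hk * 10007L + ht * 257L + (replicate - 1L)) %% 1000003L
  (abs(as.integer(base_seed)) + h) %% 2147483647L
}

#' Run a replicate-averaged parameter sweep
#'
#' For every `(K, tau)` cell, runs `replicates` seeded simulations of the
#' full closed-loop model and averages the per-nucleus oscillation indices
#' and the energy index over the replicates that completed. Cells are
#' evaluated independently (their seeds depend only on the cell's
#' parameter values and the base seed), so results are order-invariant
#' and deterministic given the base seed. A diverged replicate is dropped
#' from the cell average and counted out of `n_ok`; a cell with no
#' completed replicate carries `NA` values.
#'
#' @param spec a [sweep_spec()].
#' @param coupling a [coupling_config()] (default: pathological preset,
#'   the regime the stimulation is meant to control).
#' @param populations population parameters as from [default_populations()].
#' @param T,dt integration settings passed to [simulate_network()].
#' @param progress print a line per grid cell (default `FALSE`).
#'
#' @return A data frame of class `"nmm_sweep"` in long format with columns
#'   `scheme`, `K`, `tau_ms`, `oi_stn`, `oi_gpe`, `oi_ppn`, `oi_sum`,
#'   `ei`, `max_stn`, `min_stn`, `max_gpe`, `min_gpe`, `max_ppn`,
#'   `min_ppn`, `n_ok` (one row per cell).
#' @examples
#' \donttest{
#' sp <- sweep_spec_for(scheme_preset("A"), tau_ms_grid = c(20, 25, 30),
#'                      replicates = 2)
#' run_sweep(sp)
#' }
#' @export
run_sweep <- function(spec, coupling = coupling_config("pathological"),
                      populations = default_populations(),
                      T = 3, dt = 1e-4, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(K = spec$k_grid, tau_ms = spec$tau_ms_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))

  for (g in seq_len(nrow(grid))) {
    K <- grid$K[g]
    tau_ms <- grid$tau_ms[g]
    scheme <- stim_scheme(spec$target, spec$source, K = K, tau_ms = tau_ms,
                          onset = spec$onset, name = spec$name)
    acc <- matrix(NA_real_, nrow = spec$replicates, ncol = 10L)
    for (r in seq_len(spec$replicates)) {
      sd_r <- cell_seed(spec$base_seed, K, tau_ms, r)
      sim <- tryCatch(
        simulate_network(coupling, populations, scheme = scheme,
                         T = T, dt = dt, seed = sd_r),
        error = function(e) NULL
      )
      if (is.null(sim)) next
      ext_s <- trace_extrema(sim$v_stn, dt)
      ext_g <- trace_extrema(sim$v_gpe, dt)
      ext_p <- trace_extrema(sim$v_ppn, dt)
      acc[r, ] <- c(oscillation_index(sim$v_stn, dt),
                    oscillation_index(sim$v_gpe, dt),
                    oscillation_index(sim$v_ppn, dt),
                    energy_index(sim$w, dt),
                    ext_s, ext_g, ext_p)
    }
    ok <- !is.na(acc[, 1L])
    m <- if (any(ok)) colMeans(acc[ok, , drop = FALSE]) else rep(NA_real_, 10L)
    rows[[g]] <- data.frame(
      scheme = spec$name, K = K, tau_ms = tau_ms,
      oi_stn = m[1], oi_gpe = m[2], oi_ppn = m[3],
      oi_sum = m[1] + m[2] + m[3], ei = m[4],
      max_stn = m[5], min_stn = m[6], max_gpe = m[7], min_gpe = m[8],
      max_ppn = m[9], min_ppn = m[10],
      n_ok = sum(ok), stringsAsFactors = FALSE
    )
    if (progress) {
      message(sprintf("[%s] K=%g tau=%g ms: OI sum %.4g, EI %.4g (%d/%d ok)",
                      spec$name, K, tau_ms, rows[[g]]$oi_sum, rows[[g]]$ei,
                      rows[[g]]$n_ok, spec$replicates))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "spec") <- spec
  class(out) <- c("nmm_sweep", class(out))
  out
}

#' Replicate-averaged unstimulated baseline oscillation indices
#'
#' @param coupling a [coupling_config()] (default pathological).
#' @param replicates number of seeded runs to average (default 20).
#' @param base_seed integer base seed.
#' @param populations,T,dt as in [simulate_network()].
#' @return Named numeric vector `c(oi_stn, oi_gpe, oi_ppn, oi_sum)` in
#'   mV^2.
#' @export
baseline_oi <- function(coupling = coupling_config("pathological"),
                        replicates = 20, base_seed = 1,
                        populations = default_populations(),
                        T = 3, dt = 1e-4) {
  acc <- vapply(seq_len(replicates), function(r) {
    sim <- simulate_network(coupling, populations, scheme = NULL,
                            T = T, dt = dt, seed = base_seed + r - 1L)
    c(oscillation_index(sim$v_stn, dt),
      oscillation_index(sim$v_gpe, dt),
      oscillation_index(sim$v_ppn, dt))
  }, numeric(3))
  m <- rowMeans(acc)
  c(oi_stn = m[1], oi_gpe = m[2], oi_ppn = m[3], oi_sum = sum(m))
}

#' Locate the primary oscillation-suppression island
#'
#' Classifies grid cells as suppressed when their summed oscillation index
#' (three nuclei) falls below `fraction` of the summed unstimulated
#' baseline, finds the largest 4-connected suppressed component on the
#' `(tau, K)` lattice, and returns its center: the cell minimizing the
#' summed OI (ties broken by smallest EI, then smallest tau, then
#' smallest |K|).
#'
#' @param grid an `"nmm_sweep"` data frame from [run_sweep()].
#' @param baseline summed baseline OI in mV^2 (e.g.
#'   `baseline_oi()[["oi_sum"]]`), or the full named vector from
#'   [baseline_oi()].
#' @param fraction suppression threshold as a fraction of baseline
#'   (default 0.1).
#' @return A list with `found` (logical), and when found: `tau_ms`, `K`,
#'   `oi_sum`, `ei` of the center cell, `island` (data frame of the
#'   component's cells) and `n_suppressed` (total suppressed cells in the
#'   grid). When no cell is suppressed, `found = FALSE` and the rest is
#'   `NULL` (no error is thrown).
#' @export
island_center <- function(grid, baseline, fraction = 0.1) {
  stopifnot(is.data.frame(grid),
            all(c("K", "tau_ms", "oi_sum", "ei") %in% names(grid)))
  if (!is.null(names(baseline)) && "oi_sum" %in% names(baseline)) {
    baseline <- baseline[["oi_sum"]]
  }
  stopifnot(is.numeric(baseline), length(baseline) == 1, baseline > 0)

  ks <- sort(unique(grid$K))
  taus <- sort(unique(grid$tau_ms))
  ki <- match(grid$K, ks)
  ti <- match(grid$tau_ms, taus)
  suppressed <- !is.na(grid$oi_sum) & grid$oi_sum < fraction * baseline
  if (!any(suppressed)) {
    return(list(found = FALSE, tau_ms = NULL, K = NULL, oi_sum = NULL,
                ei = NULL, island = NULL, n_suppressed = 0L))
  }

  # label 4-connected components of suppressed cells on the (tau, K) lattice
  cellmap <- matrix(NA_integer_, nrow = length(taus), ncol = length(ks))
  cellmap[cbind(ti[suppressed], ki[suppressed])] <-
    which(suppressed)
  comp <- rep(NA_integer_, nrow(grid))
  ncomp <- 0L
  for (s in which(suppressed)) {
    if (!is.na(comp[s])) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      tr <- ti[cur]; kc <- ki[cur]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        nr <- tr + d[1L]; nc <- kc + d[2L]
        if (nr < 1L || nr > nrow(cellmap) || nc < 1L || nc > ncol(cellmap))
          next
        nb <- cellmap[nr, nc]
        if (!is.na(nb) && is.na(comp[nb])) {
          comp[nb] <- ncomp
          queue <- c(queue, nb)
        }
      }
    }
  }

  sizes <- tabulate(comp[!is.na(comp)], nbins = ncomp)
  min_oi <- vapply(seq_len(ncomp), function(cc)
    min(grid$oi_sum[!is.na(comp) & comp == cc]), numeric(1))
  # largest component; equal sizes resolved by the deeper minimum
  primary <- order(-sizes, min_oi)[1L]
  members <- which(!is.na(comp) & comp == primary)
  isl <- grid[members, , drop = FALSE]
  ord <- order(isl$oi_sum, isl$ei, isl$tau_ms, abs(isl$K))
  center <- isl[ord[1L], ]

  list(found = TRUE,
       tau_ms = center$tau_ms, K = center$K,
       oi_sum = center$oi_sum, ei = center$ei,
       island = isl[order(isl$tau_ms, isl$K), , drop = FALSE],
       n_suppressed = sum(suppressed))
}
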