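#' Per-population synaptic and sigmoid parameters
#'
#' Bundles the four constants that define one lumped neural population:
#' the synaptic gain `H` (mV), the lumped synaptic time constant `x` (s),
#' the maximum pulse density `r` (1/s) and the sigmoid slope `y` (1/mV).
#' The linear (synaptic) block of each population is the second-order
#' transfer function `H*x / (x*s + 1)^2`; the nonlinear block is the
#' sigmoid `r / (1 + exp(-y * v))`.
#'
#' @param H synaptic gain in mV; must be >= 0.
#' @param x synaptic time constant in seconds; must be > 0.
#' @param r maximum pulse density in 1/s; must be > 0.
#' @param y sigmoid slope in 1/mV; must be > 0.
#'
#' @return An object of class `"population_params"`: a named list with
#'   elements `H`, `x`, `r`, `y`.
#' @examples
#' stn <- population_params(H = 20, x = 0.006, r = 300, y = 0.1)
#' @export
population_params <- function(H, x, r, y) {
  for (nm in c("H", "x", "r", "y")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("population parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (H < 0) stop("synaptic gain H must be >= 0", call. = FALSE)
  if (x <= 0) stop("time constant x must be > 0", call. = FALSE)
  if (r <= 0) stop("maximum pulse density r must be > 0", call. = FALSE)
  if (y <= 0) stop("sigmoid slope y must be > 0", call. = FALSE)
  structure(list(H = H, x = x, r = r, y = y), class = "population_params")
}

#' Default population parameters for STN, GPe and PPN
#'
#' Returns the default constants for the three modeled nuclei. The STN and
#' GPe populations use the STN-GPe neural mass parameterization; the PPN
#' population has a fast time constant (5 ms) and a lower pulse-density
#' ceiling, reflecting its mixed cholinergic/glutamatergic make-up.
#'
#' @return A named list with elements `stn`, `gpe`, `ppn`, each a
#'   [population_params()] object.
#' @examples
#' default_populations()$stn$x  # 0.006 s
#' @export
default_populations <- function() {
  list(
    stn = population_params(H = 20, x = 0.006, r = 300, y = 0.1),
    gpe = population_params(H = 20, x = 0.014, r = 400, y = 0.1),
    ppn = population_params(H = 20, x = 0.005, r = 200, y = 0.1)
  )
}

#' Pathway coupling strengths and external input statistics
#'
#' The five coupling strengths scale the pulse-density inputs along the
#' modeled pathways:
#' * `lambda1` - GPe -> STN inhibition,
#' * `lambda2` - STN -> GPe excitation,
#' * `lambda3` - GPe -> GPe self-inhibition,
#' * `lambda4` - STN -> PPN excitation,
#' * `lambda5` - PPN -> STN excitation.
#'
#' Switching between the `"normal"` set (1.12, 19, 6.6, 10, 3) and the
#' `"pathological"` set (5, 20, 2, 13, 1) switches the network between a
#' quiet, noise-dominated regime and a strongly beta-oscillatory regime,
#' emulating the loss of dopaminergic modulation. The remaining fields give
#' the mean and standard deviation (1/s) of the three noisy external pulse
#' densities: cortical drive to STN, striatal drive to GPe and GPi drive
#' to PPN.
#'
#' @param preset `"normal"` or `"pathological"`; selects the lambda set.
#' @param ... individual overrides of any field (e.g. `lambda2 = 19.5`,
#'   `cor_sd = 0`).
#'
#' @return An object of class `"coupling_config"`: a named list with the
#'   five lambdas, `cor_mean`, `cor_sd`, `str_mean`, `str_sd`, `gpi_mean`,
#'   `gpi_sd`, and a `preset` attribute recording the starting point.
#' @examples
#' coupling_config("pathological")$lambda1  # 5
#' coupling_config("normal", cor_sd = 0)    # noise-free cortical drive
#' @export
coupling_config <- function(preset = c("pathological", "normal"), ...) {
  preset <- match.arg(preset)
  lam <- switch(preset,
    normal       = c(1.12, 19, 6.6, 10, 3),
    pathological = c(5, 20, 2, 13, 1)
  )
  cfg <- list(
    lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
    lambda4 = lam[4], lambda5 = lam[5],
    cor_mean = 27, cor_sd = 0.1,
    str_mean = 2,  str_sd = 0.1,
    gpi_mean = 20, gpi_sd = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown coupling field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- modifyList(cfg, dots)
  }
  validate_coupling(cfg)
  structure(cfg, preset = preset, class = "coupling_config")
}

validate_coupling <- function(cfg) {
  for (nm in paste0("lambda", 1:5)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("coupling strength '", nm, "' must be a single finite number >= 0",
           call. = FALSE)
    }
  }
  for (nm in c("cor_sd", "str_sd", "gpi_sd")) {
    if (cfg[[nm]] < 0) stop("input '", nm, "' must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

lambda_vector <- function(coupling) {
  c(coupling$lambda1, coupling$lambda2, coupling$lambda3,
    coupling$lambda4, coupling$lambda5)
}

#' @export
print.coupling_config <- function(x, ...) {
  cat("<coupling_config> preset:", attr(x, "preset"), "\n")
  cat(sprintf("  lambda1..5: %s\n",
              paste(unlist(x[paste0("lambda", 1:5)]), collapse = ", ")))
  cat(sprintf("  inputs (mean +/- sd, 1/s): Cor %g +/- %g, Str %g +/- %g, GPi %g +/- %g\n",
              x$cor_mean, x$cor_sd, x$str_mean, x$str_sd,
              x$gpi_mean, x$gpi_sd))
  invisible(x)
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("<population_params> H=%g mV, x=%g s, r=%g 1/s, y=%g 1/mV\n",
              x$H, x$x, x$r, x$y))
  invisible(x)
}
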