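#' Load a full model configuration from YAML or a named preset
#'
#' Configuration documents have sections `stn`, `gpe`, `ppn` (each with
#' keys `H`, `x`, `r`, `y`), `coupling` (`lambda1` .. `lambda5`), `inputs`
#' (`cor_mean`, `cor_sd`, `str_mean`, `str_sd`, `gpi_mean`, `gpi_sd`),
#' optional `simulation` (`T`, `dt`, `onset`) and optional `scheme`
#' (`preset` or `target`/`source`/`K`/`tau_ms`/`onset`). The shipped
#' presets `"normal"` and `"pathological"` reproduce the default parameter
#' table exactly. Unknown keys are rejected rather than silently ignored.
#'
#' @param path_or_preset `"normal"`, `"pathological"`, or the path to a
#'   YAML file.
#' @param overrides named list merged over the loaded document (nested,
#'   e.g. `list(inputs = list(cor_sd = 0))`).
#' @return A list with elements `populations` (list of
#'   [population_params()]), `coupling` ([coupling_config()]),
#'   `simulation` (list `T`, `dt`, `onset`) and `scheme`
#'   ([stim_scheme()] or `NULL`).
#' @examples
#' cfg <- load_config("pathological")
#' cfg$coupling$lambda1  # 5
#' @export
load_config <- function(path_or_preset, overrides = NULL) {
  if (path_or_preset %in% c("normal", "pathological")) {
    path <- system.file("extdata", paste0(path_or_preset, ".yaml"),
                        package = "nmmstim", mustWork = TRUE)
  } else {
    path <- path_or_preset
    if (!file.exists(path)) {
      stop("configuration file not found: ", path, call. = FALSE)
    }
  }
  doc <- yaml::read_yaml(path)
  if (!is.null(overrides)) doc <- merge_nested(doc, overrides)

  known_sections <- c("stn", "gpe", "ppn", "coupling", "inputs",
                      "simulation", "scheme")
  unknown <- setdiff(names(doc), known_sections)
  if (length(unknown)) {
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sec in c("stn", "gpe", "ppn", "coupling", "inputs")) {
    if (is.null(doc[[sec]])) {
      stop("configuration is missing required section '", sec, "'",
           call. = FALSE)
    }
  }

  pops <- lapply(c(stn = "stn", gpe = "gpe", ppn = "ppn"), function(sec) {
    s <- doc[[sec]]
    # YAML 1.1 parses a bare key `y` as boolean TRUE; accept and restore it
    names(s)[names(s) == "TRUE"] <- "y"
    bad <- setdiff(names(s), c("H", "x", "r", "y"))
    if (length(bad)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (key in c("H", "x", "r", "y")) {
      if (is.null(s[[key]])) {
        stop("section '", sec, "' is missing key '", key, "'",
             call. = FALSE)
      }
    }
    population_params(s$H, s$x, s$r, s$y)
  })

  cp <- doc$coupling
  bad <- setdiff(names(cp), paste0("lambda", 1:5))
  if (length(bad)) {
    stop("unknown key(s) in section 'coupling': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  inp <- doc$inputs
  bad <- setdiff(names(inp), c("cor_mean", "cor_sd", "str_mean", "str_sd",
                               "gpi_mean", "gpi_sd"))
  if (length(bad)) {
    stop("unknown key(s) in section 'inputs': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coupling <- do.call(coupling_config,
                      c(list(preset = "pathological"), cp, inp))
  attr(coupling, "preset") <-
    if (path_or_preset %in% c("normal", "pathological")) path_or_preset
    else "file"

  simdef <- list(T = 3, dt = 1e-4, onset = 1)
  if (!is.null(doc$simulation)) {
    bad <- setdiff(names(doc$simulation), names(simdef))
    if (length(bad)) {
      stop("unknown key(s) in section 'simulation': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    simdef <- modifyList(simdef, doc$simulation)
  }

  scheme <- NULL
  if (!is.null(doc$scheme)) {
    s <- doc$scheme
    if (!is.null(s$preset)) {
      scheme <- scheme_preset(s$preset, onset = s$onset %||% simdef$onset)
    } else {
      bad <- setdiff(names(s), c("target", "source", "K", "tau_ms", "onset"))
      if (length(bad)) {
        stop("unknown key(s) in section 'scheme': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      for (key in c("target", "source", "K", "tau_ms")) {
        if (is.null(s[[key]])) {
          stop("section 'scheme' is missing key '", key, "'", call. = FALSE)
        }
      }
      scheme <- stim_scheme(s$target, s$source, s$K, s$tau_ms,
                            onset = s$onset %||% simdef$onset)
    }
  }

  list(populations = pops, coupling = coupling, simulation = simdef,
       scheme = scheme)
}

merge_nested <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_nested(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Write a simulation result to CSV with a JSON manifest
#'
#' The trace CSV has columns `t`, `v_stn`, `v_gpe`, `v_ppn`, `w`. A JSON
#' sidecar `<path>.manifest.json` records everything needed to regenerate
#' the traces bit-for-bit: the full parameter set, the seed, the RNG
#' generator family, the package version and per-run summary metrics.
#'
#' @param sim an `"nmm_sim"` from [simulate_network()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_result()]
#' @export
write_result <- function(sim, path) {
  stopifnot(inherits(sim, "nmm_sim"))
  df <- data.frame(t = sim$t, v_stn = sim$v_stn, v_gpe = sim$v_gpe,
                   v_ppn = sim$v_ppn, w = sim$w)
  tryCatch(write.csv(df, path, row.names = FALSE),
           error = function(e) stop("failed to write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  cfg <- sim$config
  mr <- metrics_report(sim, spectra = TRUE)
  manifest <- list(
    package = "nmmstim",
    version = as.character(utils::packageVersion("nmmstim")),
    generator = cfg$generator,
    seed = cfg$seed,
    T = cfg$T, dt = cfg$dt, engine = cfg$engine,
    coupling = c(unclass(cfg$coupling), list(preset = attr(cfg$coupling, "preset"))),
    populations = lapply(cfg$populations, unclass),
    scheme = if (is.null(cfg$scheme)) NULL else unclass(cfg$scheme),
    metrics = list(oi_stn = mr$oi_stn, oi_gpe = mr$oi_gpe,
                   oi_ppn = mr$oi_ppn, ei = mr$ei,
                   dominant_freq = as.list(mr$dominant_freq)),
    output = basename(path)
  )
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

manifest_path <- function(path) paste0(path, ".manifest.json")

#' Read back a simulation result written by [write_result()]
#'
#' @param path the CSV path given to [write_result()].
#' @return A list with `t`, `v_stn`, `v_gpe`, `v_ppn`, `w` and (when the
#'   sidecar exists) `manifest`.
#' @export
read_result <- function(path) {
  if (!file.exists(path)) stop("result file not found: ", path,
                               call. = FALSE)
  df <- read.csv(path)
  out <- as.list(df)
  mp <- manifest_path(path)
  if (file.exists(mp)) out$manifest <- jsonlite::read_json(mp)
  out
}

#' Write a sweep grid to long-format CSV
#'
#' Columns are as in [run_sweep()]; a JSON manifest records the sweep
#' specification. An empty grid yields a header-only CSV with a warning.
#'
#' @param grid an `"nmm_sweep"` from [run_sweep()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(grid, path) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0L) {
    warning("writing an empty sweep grid (header only)")
  }
  write.csv(as.data.frame(grid), path, row.names = FALSE)
  spec <- attr(grid, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(
      list(package = "nmmstim",
           version = as.character(utils::packageVersion("nmmstim")),
           spec = unclass(spec), output = basename(path)),
      manifest_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a sweep grid written by [write_sweep()]
#'
#' @param path the CSV path given to [write_sweep()].
#' @return A data frame; the manifest (if present) is attached as the
#'   `"manifest"` attribute.
#' @export
read_sweep <- function(path) {
  if (!file.exists(path)) stop("sweep file not found: ", path,
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  mp <- manifest_path(path)
  if (file.exists(mp)) attr(df, "manifest") <- jsonlite::read_json(mp)
  df
}
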