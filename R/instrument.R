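#' Instrument configuration for an elastic backscattering scan
#'
#' Describes one spectrometer configuration: the usable momentum-transfer
#' window, the detector Q grid, the (metadata-only) energy resolution, and the
#' temperature protocol. Two presets mirror the thermal- and cold-neutron
#' backscattering setups commonly used for elastic scans of hydrated protein
#' and lipoprotein powders: a stepped-temperature thermal instrument
#' ("IN13-like", Q window 0.52--2.06 1/Angstrom, ~8 ueV resolution) and a
#' continuous-ramp cold instrument ("IN16-like", 0.54--1.85 1/Angstrom,
#' ~0.9 ueV, 0.3 K/min ramp binned downstream to 5 K).
#'
#' @param name Label for the configuration.
#' @param q_window Numeric length-2, `c(Qmin, Qmax)` in 1/Angstrom.
#' @param q_grid Strictly increasing Q values in 1/Angstrom. Points outside
#'   `q_window` are permitted here; [select_q_window()] trims them.
#' @param energy_resolution Energy resolution (FWHM) in ueV; metadata only.
#' @param temperatures Stepped protocol: vector of sample temperatures in K.
#'   Exactly one of `temperatures` and `ramp` must be given.
#' @param ramp Continuous protocol: list with elements `rate` (K/min),
#'   `bin_width` (K), `t_min`, `t_max` (K).
#' @return An object of class `instrument_config`.
#' @seealso [in13_config()], [in16_config()]
#' @export
instrument_config <- function(name, q_window, q_grid,
                              energy_resolution = NA_real_,
                              temperatures = NULL, ramp = NULL) {
  stopifnot(length(q_window) == 2L, is.numeric(q_window))
  if (q_window[1] >= q_window[2]) {
    stop("q_window must satisfy Qmin < Qmax")
  }
  stopifnot(is.numeric(q_grid), length(q_grid) >= 1L)
  if (any(diff(q_grid) <= 0)) stop("q_grid must be strictly increasing")
  if (is.null(temperatures) == is.null(ramp)) {
    stop("give exactly one of `temperatures` (stepped) or `ramp` (continuous)")
  }
  if (!is.null(temperatures)) {
    stopifnot(is.numeric(temperatures), length(temperatures) >= 1L)
    if (any(diff(temperatures) <= 0)) {
      stop("stepped temperatures must be strictly increasing")
    }
    protocol <- list(kind = "stepped", temperatures = as.numeric(temperatures))
  } else {
    stopifnot(is.list(ramp),
              all(c("rate", "bin_width", "t_min", "t_max") %in% names(ramp)))
    if (ramp$rate <= 0 || ramp$bin_width <= 0 || ramp$t_min >= ramp$t_max) {
      stop("ramp needs rate > 0, bin_width > 0 and t_min < t_max")
    }
    protocol <- c(list(kind = "ramp"), ramp)
  }
  structure(
    list(name = name,
         q_window = as.numeric(q_window),
         q_grid = as.numeric(q_grid),
         energy_resolution = energy_resolution,
         protocol = protocol),
    class = "instrument_config"
  )
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf("Instrument configuration '%s'\n", x$name))
  cat(sprintf("  Q window: %.2f - %.2f 1/A (%d grid points)\n",
              x$q_window[1], x$q_window[2], length(x$q_grid)))
  if (!is.na(x$energy_resolution)) {
    cat(sprintf("  Energy resolution: %.2g ueV\n", x$energy_resolution))
  }
  if (x$protocol$kind == "stepped") {
    tt <- x$protocol$temperatures
    cat(sprintf("  Stepped protocol: %d temperatures, %.0f - %.0f K\n",
                length(tt), min(tt), max(tt)))
  } else {
    cat(sprintf("  Ramp protocol: %.2g K/min over %.0f - %.0f K, bin %.0f K\n",
                x$protocol$rate, x$protocol$t_min, x$protocol$t_max,
                x$protocol$bin_width))
  }
  invisible(x)
}

#' Thermal backscattering preset (stepped temperature protocol)
#'
#' Q window 0.52--2.06 1/Angstrom, ~8 ueV resolution. The stepped protocol
#' runs 20--160 K in 20 K steps, 170--280 K in 10 K steps and 285--305 K in
#' 5 K steps.
#'
#' @param q_points Number of equally spaced grid points across the Q window.
#' @return An `instrument_config`.
#' @export
in13_config <- function(q_points = 16L) {
  instrument_config(
    name = "IN13-like",
    q_window = c(0.52, 2.06),
    q_grid = seq(0.52, 2.06, length.out = q_points),
    energy_resolution = 8,
    temperatures = c(seq(20, 160, by = 20), seq(170, 280, by = 10),
                     seq(285, 305, by = 5))
  )
}

#' Cold-neutron backscattering preset (continuous ramp protocol)
#'
#' Q window 0.54--1.85 1/Angstrom, ~0.9 ueV resolution. Temperature is ramped
#' continuously at 0.3 K/min; the emulation samples one scan per minute
#' (every 0.3 K) and the analysis bins to 5 K intervals.
#'
#' @param q_points Number of equally spaced grid points across the Q window.
#' @param t_min,t_max Ramp limits in K.
#' @return An `instrument_config`.
#' @export
in16_config <- function(q_points = 16L, t_min = 20, t_max = 310) {
  instrument_config(
    name = "IN16-like",
    q_window = c(0.54, 1.85),
    q_grid = seq(0.54, 1.85, length.out = q_points),
    energy_resolution = 0.9,
    ramp = list(rate = 0.3, bin_width = 5, t_min = t_min, t_max = t_max)
  )
}

#' Temperatures at which an instrument protocol records scans
#'
#' For a stepped protocol these are the programmed set points; for a ramp,
#' one sample per minute of ramping (i.e. every `rate` K).
#'
#' @param cfg An `instrument_config`.
#' @return Numeric vector of temperatures in K.
#' @export
protocol_temperatures <- function(cfg) {
  stopifnot(inherits(cfg, "instrument_config"))
  if (cfg$protocol$kind == "stepped") {
    cfg$protocol$temperatures
  } else {
    seq(cfg$protocol$t_min, cfg$protocol$t_max, by = cfg$protocol$rate)
  }
}
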