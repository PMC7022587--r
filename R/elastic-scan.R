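#' Elastic scan container
#'
#' One per-temperature table of elastic intensities I_el(Q, omega = 0 +/- dE)
#' with uncertainties.
#'
#' @param temperature Sample temperature in K.
#' @param q Momentum transfer values in 1/Angstrom; must be > 0.
#' @param intensity Elastic intensities (counts-normalised).
#' @param sigma One-standard-deviation uncertainties; `>= 0`.
#' @return A data frame of class `elastic_scan` with columns `q`, `intensity`,
#'   `sigma` and a `temperature` attribute, sorted by `q`.
#' @export
elastic_scan <- function(temperature, q, intensity, sigma = 0) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  n <- length(q)
  sigma <- rep_len(sigma, n)
  if (length(intensity) != n) stop("q and intensity lengths differ")
  if (any(q <= 0)) stop("Q values must be > 0")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  ord <- order(q)
  structure(
    data.frame(q = as.numeric(q)[ord],
               intensity = as.numeric(intensity)[ord],
               sigma = as.numeric(sigma)[ord]),
    temperature = as.numeric(temperature),
    class = c("elastic_scan", "data.frame")
  )
}

#' Temperature of an elastic scan
#' @param scan An `elastic_scan`.
#' @return Temperature in K.
#' @export
scan_temperature <- function(scan) attr(scan, "temperature")

#' @export
print.elastic_scan <- function(x, ...) {
  cat(sprintf("Elastic scan at %.2f K (%d Q points, %.3g - %.3g 1/A)\n",
              scan_temperature(x), nrow(x), min(x$q), max(x$q)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Generate synthetic elastic scans under the Gaussian approximation
#'
#' Produces one scan per protocol temperature with intensities
#' `I(Q, T) = i0 * exp(-<u2>(T) * Q^2 / 6)` where `<u2>(T)` comes from a
#' piecewise-linear MSD model, plus optional Gaussian counting-like noise of
#' relative scale `noise_fraction` (per-point standard deviation
#' `noise_fraction * sqrt(I / max I) * i0`... see Details).
#'
#' @details The noise model is Gaussian with per-point standard deviation
#'   `noise_fraction * sqrt(intensity / max(intensity)) * max(intensity)`,
#'   i.e. proportional to the square root of the relative intensity, which
#'   mimics counting statistics while staying scale-free in `noise_fraction`.
#'   The same value populates the `sigma` column. With `noise_fraction = 0`
#'   intensities are exact and `sigma` is 0.
#'
#' @param cfg An [instrument_config()]; scans are generated on its full Q grid
#'   at the protocol temperatures (one per minute of ramping for ramp
#'   protocols).
#' @param model An [msd_model()] giving the ground-truth MSD(T).
#' @param i0 Intensity scale at Q = 0; must be > 0.
#' @param noise_fraction Relative noise scale; `>= 0`.
#' @param seed Integer seed for the noise draws.
#' @return A list of class `elastic_dataset`: `scans` (list of
#'   [elastic_scan()]), `truth` (data frame `temperature`, `msd`), `cfg`,
#'   `model`.
#' @export
make_elastic_dataset <- function(cfg, model, i0 = 1, noise_fraction = 0,
                                 seed = 1L) {
  stopifnot(inherits(cfg, "instrument_config"), inherits(model, "msd_model"))
  if (i0 <= 0) stop("i0 must be positive")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  temps <- protocol_temperatures(cfg)
  if (length(temps) == 0L) stop("temperature protocol is empty")
  msd_true <- msd_at(model, temps)
  q <- cfg$q_grid

  rng <- local({
    set.seed(as.integer(seed))
    function(n, sd) stats::rnorm(n, sd = sd)
  })
  scans <- vector("list", length(temps))
  for (i in seq_along(temps)) {
    inten <- i0 * exp(-msd_true[i] * q^2 / 6)
    if (noise_fraction > 0) {
      sd_pt <- noise_fraction * sqrt(inten / max(inten)) * max(inten)
      inten <- inten + rng(length(q), sd = 1) * sd_pt
      inten[inten <= 0] <- .Machine$double.eps  # keep log-domain fits defined
    } else {
      sd_pt <- rep(0, length(q))
    }
    scans[[i]] <- elastic_scan(temps[i], q, inten, sd_pt)
  }
  structure(
    list(scans = scans,
         truth = data.frame(temperature = temps, msd = msd_true),
         cfg = cfg, model = model, i0 = i0,
         noise_fraction = noise_fraction, seed = as.integer(seed)),
    class = "elastic_dataset"
  )
}

#' @export
print.elastic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic elastic dataset: %d scans on '%s', i0 = %g, noise = %g\n",
              length(x$scans), x$cfg$name, x$i0, x$noise_fraction))
  invisible(x)
}
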