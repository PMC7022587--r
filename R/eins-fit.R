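#' Restrict an elastic scan to an instrument's Q window
#'
#' The Gaussian approximation for the elastic intensity holds only while
#' `<u2> * Q^2` stays moderate, so each instrument defines a fixed
#' momentum-transfer window (e.g. 0.52--2.06 1/Angstrom for the thermal
#' preset) inside which ln I is approximately linear in Q^2.
#'
#' @param scan An [elastic_scan()].
#' @param cfg An [instrument_config()] (or a numeric length-2 window).
#' @return The windowed `elastic_scan`, order preserved.
#' @export
select_q_window <- function(scan, cfg) {
  stopifnot(inherits(scan, "elastic_scan"))
  win <- if (inherits(cfg, "instrument_config")) cfg$q_window else cfg
  stopifnot(is.numeric(win), length(win) == 2L)
  keep <- scan$q >= win[1] & scan$q <= win[2]
  if (sum(keep) < 3L) {
    stop(sprintf("window too narrow: only %d point(s) survive in [%g, %g]",
                 sum(keep), win[1], win[2]))
  }
  out <- scan[keep, , drop = FALSE]
  elastic_scan(scan_temperature(scan), out$q, out$intensity, out$sigma)
}

#' Fit the mean square displacement of one elastic scan
#'
#' Weighted least-squares fit of `ln I` versus `Q^2`; the Gaussian
#' approximation `I = I0 exp(-<u2> Q^2 / 6)` gives `<u2> = -6 * slope`. The
#' uncertainty on ln I is `sigma / intensity` (first-order propagation) and
#' weights are its inverse square; when every sigma is zero (noise-free
#' synthetic data) the fit is unweighted.
#'
#' @param scan A windowed [elastic_scan()] with at least 3 points and all
#'   intensities > 0.
#' @param weighted Use `1/sigma^2` weights when sigmas are available
#'   (default `TRUE`); `FALSE` forces an unweighted fit.
#' @return List of class `msd_fit`: `msd` (square Angstrom), `msd_sigma`,
#'   `i0` (fitted intercept back-transformed), `temperature`, `n_points`.
#' @export
fit_msd <- function(scan, weighted = TRUE) {
  stopifnot(inherits(scan, "elastic_scan"))
  if (nrow(scan) < 3L) stop("need >= 3 points to fit MSD")
  if (any(scan$intensity <= 0)) stop("non-positive intensity in scan")
  if (length(unique(scan$q)) < 2L) stop("singular design: all Q equal")
  q2 <- scan$q^2
  y <- log(scan$intensity)
  use_w <- weighted && any(scan$sigma > 0)
  if (use_w) {
    s_ln <- scan$sigma / scan$intensity
    s_ln[s_ln <= 0] <- min(s_ln[s_ln > 0])  # guard exact-zero sigmas
    fit <- stats::lm(y ~ q2, weights = 1 / s_ln^2)
  } else {
    fit <- stats::lm(y ~ q2)
  }
  co <- suppressWarnings(summary(fit))$coefficients  # noise-free data fits exactly
  structure(
    list(msd = unname(-6 * co["q2", "Estimate"]),
         msd_sigma = unname(6 * co["q2", "Std. Error"]),
         i0 = exp(unname(co["(Intercept)", "Estimate"])),
         temperature = scan_temperature(scan),
         n_points = nrow(scan),
         weighted = use_w),
    class = "msd_fit"
  )
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD fit at %.2f K: <u2> = %.4g +/- %.2g A^2 (%d points, %s)\n",
              x$temperature, x$msd, x$msd_sigma, x$n_points,
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Gaussian-approximation validity mask for a fitted MSD
#'
#' The approximation is considered valid at a Q point while
#' `<u2> * Q^2 <= 2`. The default policy is warn-only: the fixed instrument
#' window is retained and out-of-range points are merely flagged.
#'
#' @param msd Fitted MSD in square Angstrom, `>= 0`.
#' @param scan The [elastic_scan()] the MSD was fitted on.
#' @param limit Validity threshold on `<u2> * Q^2` (default 2).
#' @return List with `valid` (logical per point), `fraction` (share of valid
#'   points) and `uq2` (the `<u2> * Q^2` values).
#' @export
gaussian_validity <- function(msd, scan, limit = 2) {
  stopifnot(inherits(scan, "elastic_scan"))
  if (msd < 0) stop("msd must be >= 0")
  uq2 <- msd * scan$q^2
  valid <- uq2 <= limit
  list(valid = valid, fraction = mean(valid), uq2 = uq2)
}

#' Fit MSD across a collection of scans
#'
#' Applies [select_q_window()] and [fit_msd()] per scan and assembles the
#' MSD(T) series with Gaussian-validity fractions.
#'
#' @param scans List of [elastic_scan()] objects (or an `elastic_dataset`).
#' @param cfg Instrument configuration for windowing; `NULL` skips windowing.
#' @param weighted Passed to [fit_msd()].
#' @return A data frame of class `msd_series` with columns `temperature`,
#'   `msd`, `msd_sigma`, `valid_fraction`, sorted by temperature.
#' @export
fit_msd_series <- function(scans, cfg = NULL, weighted = TRUE) {
  if (inherits(scans, "elastic_dataset")) {
    if (is.null(cfg)) cfg <- scans$cfg
    scans <- scans$scans
  }
  stopifnot(length(scans) >= 1L)
  rows <- lapply(scans, function(sc) {
    if (!is.null(cfg)) sc <- select_q_window(sc, cfg)
    f <- fit_msd(sc, weighted = weighted)
    gv <- gaussian_validity(max(f$msd, 0), sc)
    data.frame(temperature = f$temperature, msd = f$msd,
               msd_sigma = f$msd_sigma, valid_fraction = gv$fraction)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("msd_series", "data.frame")
  out
}

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf("MSD series: %d temperatures, %.1f - %.1f K, <u2> up to %.3g A^2\n",
              nrow(x), min(x$temperature), max(x$temperature), max(x$msd)))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat(sprintf("  ... %d more rows\n", nrow(x) - 8L))
  invisible(x)
}

#' @export
plot.msd_series <- function(x, ...) {
  plot(x$temperature, x$msd, xlab = "Temperature (K)",
       ylab = expression("<u"^2 * "> (" * ring(A)^2 * ")"),
       pch = 1, ...)
  if (any(x$msd_sigma > 0)) {
    graphics::arrows(x$temperature, x$msd - x$msd_sigma,
                     x$temperature, x$msd + x$msd_sigma,
                     angle = 90, code = 3, length = 0.02)
  }
  invisible(x)
}

#' Bin ramp scans into fixed temperature intervals
#'
#' Groups scans into `[T0 + n*bin, T0 + (n+1)*bin)` bins anchored at the
#' lowest scan temperature, averages intensities per Q point and combines
#' uncertainties in quadrature divided by the bin count. The bin centre is
#' reported as the binned scan's temperature.
#'
#' @param scans List of [elastic_scan()] objects sharing one Q grid.
#' @param bin_width Bin width in K; must be > 0.
#' @return List of binned `elastic_scan` objects, ordered by temperature.
#' @export
bin_ramp <- function(scans, bin_width) {
  if (length(scans) == 0L) stop("empty scan collection")
  if (bin_width <= 0) stop("bin_width must be > 0")
  temps <- vapply(scans, scan_temperature, numeric(1))
  t0 <- min(temps)
  idx <- floor((temps - t0) / bin_width + 1e-9)
  q_ref <- scans[[1]]$q
  for (sc in scans) {
    if (length(sc$q) != length(q_ref) || any(abs(sc$q - q_ref) > 1e-9)) {
      stop("all scans must share one Q grid for binning")
    }
  }
  out <- lapply(sort(unique(idx)), function(b) {
    members <- scans[idx == b]
    n <- length(members)
    im <- vapply(members, function(s) s$intensity, numeric(length(q_ref)))
    sm <- vapply(members, function(s) s$sigma, numeric(length(q_ref)))
    if (n == 1L) { im <- matrix(im, ncol = 1); sm <- matrix(sm, ncol = 1) }
    inten <- rowMeans(im)
    sig <- sqrt(rowSums(sm^2)) / n
    elastic_scan(t0 + (b + 0.5) * bin_width, q_ref, inten, sig)
  })
  out
}

#' Normalise an elastic scan against references
#'
#' `I' = (I - empty_cell) / transmission / vanadium`, point-wise, with
#' first-order uncertainty propagation. Absorption is treated as a scalar
#' transmission factor.
#'
#' @param scan Sample [elastic_scan()].
#' @param empty_cell Optional empty-cell scan on the same Q grid.
#' @param vanadium Optional vanadium scan on the same Q grid; must be
#'   non-zero everywhere.
#' @param transmission Scalar transmission in (0, 1]; default 1.
#' @return The normalised `elastic_scan`.
#' @export
normalize_scan <- function(scan, empty_cell = NULL, vanadium = NULL,
                           transmission = 1) {
  stopifnot(inherits(scan, "elastic_scan"))
  if (transmission <= 0) stop("transmission must be > 0")
  check_grid <- function(ref, what) {
    if (length(ref$q) != length(scan$q) || any(abs(ref$q - scan$q) > 1e-9)) {
      stop(sprintf("%s scan Q grid does not match sample scan", what))
    }
  }
  inten <- scan$intensity
  var_i <- scan$sigma^2
  if (!is.null(empty_cell)) {
    check_grid(empty_cell, "empty-cell")
    inten <- inten - empty_cell$intensity
    var_i <- var_i + empty_cell$sigma^2
  }
  inten <- inten / transmission
  var_i <- var_i / transmission^2
  if (!is.null(vanadium)) {
    check_grid(vanadium, "vanadium")
    if (any(vanadium$intensity == 0)) stop("vanadium intensity is zero at some Q")
    var_i <- (var_i / vanadium$intensity^2) +
      (inten^2 * vanadium$sigma^2 / vanadium$intensity^4)
    inten <- inten / vanadium$intensity
  }
  elastic_scan(scan_temperature(scan), scan$q, inten, sqrt(var_i))
}

#' Effective force constants from segmented MSD(T) slopes
#'
#' Splits the MSD series at the given breakpoints and fits a weighted linear
#' model `msd ~ temperature` per segment; the segment's effective force
#' constant is `<k> = 0.00276 / slope` N/m (resilience relation), with the
#' standard error propagated to first order
#' (`se_k = 0.00276 * se_slope / slope^2`). Breakpoint temperatures belong to
#' both adjoining segments, matching a continuous piecewise-linear curve.
#' Segments whose slope is not positive are flagged `rigid/undefined` and get
#' `NA` constants.
#'
#' @param series An `msd_series` (from [fit_msd_series()]) or a data frame
#'   with columns `temperature`, `msd` and optionally `msd_sigma`.
#' @param breakpoints Interior breakpoint temperatures in K; default
#'   `c(200, 250)`.
#' @param weighted Use `1/msd_sigma^2` weights when sigmas are positive.
#' @return Data frame of class `force_segments` with columns `t_low`,
#'   `t_high`, `slope`, `slope_se`, `force_constant`, `force_constant_se`,
#'   `n_points`, `status`.
#' @export
fit_force_constants <- function(series, breakpoints = c(200, 250),
                                weighted = TRUE) {
  stopifnot(is.data.frame(series),
            all(c("temperature", "msd") %in% names(series)))
  tr <- range(series$temperature)
  if (length(breakpoints) > 0 &&
      (any(breakpoints <= tr[1]) || any(breakpoints >= tr[2]))) {
    stop("breakpoints must lie strictly inside the temperature range")
  }
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be increasing")
  edges <- c(tr[1], breakpoints, tr[2])
  sig <- if ("msd_sigma" %in% names(series)) series$msd_sigma else
    rep(0, nrow(series))
  rows <- lapply(seq_len(length(edges) - 1L), function(s) {
    keep <- series$temperature >= edges[s] & series$temperature <= edges[s + 1L]
    if (sum(keep) < 2L) {
      stop(sprintf("segment %g-%g K has fewer than 2 points", edges[s],
                   edges[s + 1L]))
    }
    tt <- series$temperature[keep]
    uu <- series$msd[keep]
    ss <- sig[keep]
    if (weighted && any(ss > 0)) {
      ss[ss <= 0] <- min(ss[ss > 0])
      fit <- stats::lm(uu ~ tt, weights = 1 / ss^2)
    } else {
      fit <- stats::lm(uu ~ tt)
    }
    co <- suppressWarnings(summary(fit))$coefficients  # noise-free data fits exactly
    slope <- unname(co["tt", "Estimate"])
    slope_se <- unname(co["tt", "Std. Error"])
    if (slope > 0) {
      k <- RESILIENCE_CONSTANT / slope
      k_se <- RESILIENCE_CONSTANT * slope_se / slope^2
      status <- "ok"
    } else {
      k <- NA_real_; k_se <- NA_real_; status <- "rigid/undefined"
    }
    data.frame(t_low = edges[s], t_high = edges[s + 1L], slope = slope,
               slope_se = slope_se, force_constant = k,
               force_constant_se = k_se, n_points = sum(keep),
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("force_segments", "data.frame")
  out
}

#' @export
print.force_segments <- function(x, ...) {
  cat("Effective force constants (resilience) per temperature segment\n")
  for (i in seq_len(nrow(x))) {
    if (x$status[i] == "ok") {
      cat(sprintf("  %5.0f - %5.0f K: <k> = %.3g +/- %.2g N/m (slope %.4g A^2/K, n = %d)\n",
                  x$t_low[i], x$t_high[i], x$force_constant[i],
                  x$force_constant_se[i], x$slope[i], x$n_points[i]))
    } else {
      cat(sprintf("  %5.0f - %5.0f K: %s (slope %.4g A^2/K)\n",
                  x$t_low[i], x$t_high[i], x$status[i], x$slope[i]))
    }
  }
  invisible(x)
}

#' @export
coef.force_segments <- function(object, ...) {
  stats::setNames(object$force_constant,
                  sprintf("%g-%gK", object$t_low, object$t_high))
}

#' Exhaustive two-breakpoint search for MSD segmentation
#'
#' Optional alternative to fixed breakpoints: scans all candidate pairs of
#' interior series temperatures (with at least `min_points` per segment) and
#' returns the pair minimising the total weighted residual sum of squares of
#' the three segment fits. Provided for exploration; the default analysis
#' keeps user-chosen breakpoints.
#'
#' @param series An `msd_series`.
#' @param min_points Minimum points per segment (default 3).
#' @param weighted Passed to the per-segment fits.
#' @return List with `breakpoints` (length 2) and `segments`
#'   (a `force_segments` fit at the optimum).
#' @export
search_breakpoints <- function(series, min_points = 3L, weighted = TRUE) {
  temps <- sort(unique(series$temperature))
  n <- length(temps)
  if (n < 3L * min_points) stop("series too short for a two-breakpoint search")
  sig <- if ("msd_sigma" %in% names(series)) series$msd_sigma else
    rep(0, nrow(series))
  seg_rss <- function(keep) {
    tt <- series$temperature[keep]; uu <- series$msd[keep]; ss <- sig[keep]
    if (weighted && any(ss > 0)) {
      ss[ss <= 0] <- min(ss[ss > 0])
      sum(stats::lm(uu ~ tt, weights = 1 / ss^2)$residuals^2 / ss^2)
    } else {
      sum(stats::lm(uu ~ tt)$residuals^2)
    }
  }
  best <- NULL; best_rss <- Inf
  for (i in seq(min_points, n - 2L * min_points)) {
    for (j in seq(i + min_points, n - min_points)) {
      b1 <- temps[i]; b2 <- temps[j]
      rss <- seg_rss(series$temperature <= b1) +
        seg_rss(series$temperature >= b1 & series$temperature <= b2) +
        seg_rss(series$temperature >= b2)
      if (rss < best_rss) { best_rss <- rss; best <- c(b1, b2) }
    }
  }
  list(breakpoints = best,
       segments = fit_force_constants(series, breakpoints = best,
                                      weighted = weighted))
}
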