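#' Isotopic envelope observation
#'
#' A peak list for one peptide, charge state and exchange time. Control
#' envelopes are encoded by convention as `time = -1` (0% deuteration) and
#' `time = -2` (80% deuteration).
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @param peptide_id Identifier linking the envelope to its peptide.
#' @param start,end Residue span on the parent protein.
#' @param charge Charge state.
#' @param time Exchange time in seconds (or -1/-2 for controls).
#' @return Data frame of class `hdx_envelope`, peaks sorted by `mz`.
#' @export
hdx_envelope <- function(peaks, peptide_id, start = NA_integer_,
                         end = NA_integer_, charge = 2L, time = NA_real_) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("negative peak intensity")
  if (!any(peaks$intensity > 0)) stop("envelope has no positive intensity")
  ord <- order(peaks$mz)
  structure(
    data.frame(mz = peaks$mz[ord], intensity = peaks$intensity[ord]),
    peptide_id = peptide_id, start = as.integer(start), end = as.integer(end),
    charge = as.integer(charge), time = as.numeric(time),
    class = c("hdx_envelope", "data.frame")
  )
}

#' @export
print.hdx_envelope <- function(x, ...) {
  tlab <- switch(as.character(attr(x, "time")),
                 "-1" = "0% control", "-2" = "80% control",
                 sprintf("t = %g s", attr(x, "time")))
  cat(sprintf("Envelope %s (z = %d, %s): %d peaks, centroid %.4f\n",
              attr(x, "peptide_id"), attr(x, "charge"), tlab, nrow(x),
              centroid(x)))
  invisible(x)
}

#' Intensity-weighted centroid of an envelope
#'
#' @param env An [hdx_envelope()] or data frame with `mz`, `intensity`.
#' @return Centroid m/z.
#' @export
centroid <- function(env) {
  if (nrow(env) == 0L) stop("empty envelope")
  if (sum(env$intensity) <= 0) stop("all-zero intensities")
  sum(env$mz * env$intensity) / sum(env$intensity)
}

#' Deuterium incorporation from centroids with back-exchange correction
#'
#' Maps the deuterated centroid linearly between the 0% and maximally (80%)
#' deuterated control centroids:
#' `DI = (cent_t - cent_0) / (cent_80 - cent_0) * 0.8 * n_exch`.
#' The charge state cancels in the centroid ratio; the raw mass-domain shift
#' `(cent_t - cent_0) * charge` is also reported, together with the peptide's
#' back-exchange percentage implied by the 80% control:
#' `(1 - (cent_80 - cent_0) * charge / (0.8 * n_exch * 1.00628)) * 100`.
#'
#' Small negative centroid differences (early-time noise) are clamped to
#' `DI = 0` with a warning when below `-tol` D.
#'
#' @param cent_t Centroid of the deuterated envelope.
#' @param cent_0 Centroid of the 0% control.
#' @param cent_80 Centroid of the 80% control.
#' @param charge Charge state; `>= 1`.
#' @param n_exch Number of exchangeable amides.
#' @param max_label Deuteration level of the maximally deuterated control
#'   (default 0.8).
#' @param tol Clamping tolerance in D units (default 0.1).
#' @return List with `di` (D units), `di_raw` (mass-domain Da), and
#'   `back_exchange_percent`.
#' @export
compute_di <- function(cent_t, cent_0, cent_80, charge, n_exch,
                       max_label = 0.8, tol = 0.1) {
  if (cent_80 <= cent_0) stop("cent_80 must exceed cent_0")
  if (charge < 1) stop("charge must be >= 1")
  frac <- (cent_t - cent_0) / (cent_80 - cent_0)
  di <- frac * max_label * n_exch
  if (di < 0) {
    if (di < -tol) {
      warning(sprintf("centroid below 0%% control by %.3g D; clamping to 0", -di))
    }
    di <- 0
  }
  bx <- (1 - (cent_80 - cent_0) * charge / (max_label * n_exch * DEUTERIUM_SHIFT)) * 100
  list(di = di,
       di_raw = (cent_t - cent_0) * charge,
       back_exchange_percent = bx)
}

# Project a peak list onto a regular m/z grid (for envelope comparison).
# Intensity is shared linearly between the two nearest bins so the
# projection is continuous in m/z (no bin-edge flips from rounding noise).
.bin_envelope <- function(env, grid_min, bin_width, n_bins) {
  u <- (env$mz - grid_min) / bin_width
  i <- floor(u)
  frac <- u - i
  out <- numeric(n_bins)
  for (j in seq_along(u)) {
    lo <- i[j] + 1L
    if (lo >= 1L && lo <= n_bins) {
      out[lo] <- out[lo] + env$intensity[j] * (1 - frac[j])
    }
    if (lo + 1L >= 1L && lo + 1L <= n_bins) {
      out[lo + 1L] <- out[lo + 1L] + env$intensity[j] * frac[j]
    }
  }
  out
}

# Deuterated copy of a reference envelope (component model) at mean per-site
# deuteration p. Default shape is Binom(n_exch, p); when per-site intrinsic
# rates are supplied the shape is the Poisson-binomial of
# retention * (1 - exp(-k_i * tau)) with tau chosen so the mean equals p
# (i.e. the random-coil site pattern slowed by one effective protection).
.component_envelope <- function(ref, n_exch, p, charge, rates = NULL,
                                retention = 1) {
  if (is.null(rates)) {
    d_dist <- stats::dbinom(0:n_exch, n_exch, p)
  } else {
    p_sites <- .rate_pattern_sites(rates, p, retention)
    d_dist <- poisson_binomial(p_sites)
  }
  deuterate_envelope(ref, d_dist, charge)
}

# Per-site deuteration probabilities with mean p under the intrinsic-rate
# pattern: retention * (1 - exp(-k * tau)), tau root-found on the mean.
.rate_pattern_sites <- function(rates, p, retention) {
  k <- rates[!is.na(rates)]
  if (p <= 0) return(rep(0, length(k)))
  pmax_mean <- retention
  if (p >= pmax_mean - 1e-12) return(rep(retention, length(k)))
  f <- function(log_tau) {
    retention * mean(1 - exp(-k * exp(log_tau))) - p
  }
  lo <- log(1e-9 / max(k)); hi <- log(1e9 / min(k))
  log_tau <- stats::uniroot(f, lower = lo, upper = hi,
                            tol = .Machine$double.eps^0.4)$root
  retention * (1 - exp(-k * exp(log_tau)))
}

#' Deconvolve an envelope into slow and fast exchanging populations
#'
#' Fits the observed envelope as a mixture of two components, each the 0%
#' reference envelope shape convolved with a binomial deuteration
#' distribution `Binom(n_exch, p)` shifted by 1.00628 Da per D. The mean
#' per-site deuteration `p` of each component and the mixture weight are
#' found by a coarse grid over `p` (exact conditional weight per pair)
#' followed by local refinement. One- versus two-component selection uses a
#' BIC-style penalty: two components are declared (`is_bimodal`) only when
#' `BIC1 - BIC2 > delta_bic`. Near-degenerate two-component fits (component
#' DI separation below `collapse_sep` D, or a weight below `collapse_weight`)
#' are returned as unimodal.
#'
#' @param env Observed [hdx_envelope()].
#' @param reference_0 The 0% control envelope of the same peptide and charge.
#' @param n_exch Number of exchangeable amides.
#' @param rates Optional per-site intrinsic rates (per second, `NA`s
#'   dropped). When given, each component's deuteration distribution is the
#'   Poisson-binomial of the random-coil site pattern slowed by a single
#'   effective protection (mean fixed to the component's `p`), instead of a
#'   plain binomial; this matches rate-heterogeneous peptides much more
#'   closely.
#' @param retention Deuterium retention factor (1 - back-exchange fraction)
#'   applied to the rate-pattern component model (default 1).
#' @param p_grid Grid resolution for the coarse search (default 0.02).
#' @param delta_bic Evidence threshold for bimodality (default 10).
#' @param collapse_sep,collapse_weight Degeneracy guards (0.25 D, 0.02).
#' @param bin_width m/z bin width for envelope comparison (default 0.01).
#' @return Object of class `deconvolved_pair`: `slow` and `fast` lists
#'   (`di`, `p`, `weight`, `centroid`), `is_bimodal`, `model_score`
#'   (two-component RSS), `delta_bic`, `n_exch`.
#' @export
deconvolve_bimodal <- function(env, reference_0, n_exch,
                               rates = NULL, retention = 1,
                               p_grid = 0.02, delta_bic = 10,
                               collapse_sep = 0.25, collapse_weight = 0.02,
                               bin_width = 0.01) {
  if (!is.null(rates)) rates <- rates[!is.na(rates)]
  stopifnot(inherits(env, "data.frame"), inherits(reference_0, "data.frame"))
  charge <- attr(env, "charge")
  if (is.null(charge)) charge <- attr(reference_0, "charge")
  if (is.null(charge)) charge <- 1L
  ref <- data.frame(mz = reference_0$mz,
                    intensity = reference_0$intensity / sum(reference_0$intensity))
  total <- sum(env$intensity)
  grid_min <- min(ref$mz) - bin_width
  grid_max <- max(ref$mz) + (n_exch + 1) * DEUTERIUM_SHIFT / charge + bin_width
  n_bins <- ceiling((grid_max - grid_min) / bin_width) + 1L
  y <- .bin_envelope(data.frame(mz = env$mz, intensity = env$intensity / total),
                     grid_min, bin_width, n_bins)

  p_max <- if (is.null(rates)) 1 else retention
  ps <- seq(0, p_max, by = p_grid)
  comp_for <- function(p) {
    .component_envelope(ref, n_exch, p, charge, rates = rates,
                        retention = retention)
  }
  comp_bins <- lapply(ps, function(p) {
    .bin_envelope(comp_for(p), grid_min, bin_width, n_bins)
  })

  # one-component fit
  rss1_grid <- vapply(comp_bins, function(e) sum((y - e)^2), numeric(1))
  i1 <- which.min(rss1_grid)
  obj1 <- function(p) {
    e <- .bin_envelope(comp_for(p), grid_min, bin_width, n_bins)
    sum((y - e)^2)
  }
  o1 <- stats::optimize(obj1, interval = c(max(0, ps[i1] - p_grid),
                                           min(p_max, ps[i1] + p_grid)))
  rss1 <- o1$objective; p_uni <- o1$minimum

  # two-component coarse search: optimal weight is linear-least-squares
  best <- list(rss = Inf)
  np <- length(ps)
  for (a in 1:(np - 1L)) {
    ea <- comp_bins[[a]]
    for (b in (a + 1L):np) {
      eb <- comp_bins[[b]]
      d <- ea - eb
      den <- sum(d^2)
      if (den == 0) next
      w <- sum((y - eb) * d) / den
      w <- min(1, max(0, w))
      rss <- sum((y - (w * ea + (1 - w) * eb))^2)
      if (rss < best$rss) best <- list(rss = rss, p1 = ps[a], p2 = ps[b], w = w)
    }
  }
  # local refinement of (p1, p2, w)
  obj2 <- function(par) {
    p1 <- min(p_max, max(0, par[1])); p2 <- min(p_max, max(0, par[2]))
    w <- min(1, max(0, par[3]))
    e1 <- .bin_envelope(comp_for(p1), grid_min, bin_width, n_bins)
    e2 <- .bin_envelope(comp_for(p2), grid_min, bin_width, n_bins)
    sum((y - (w * e1 + (1 - w) * e2))^2)
  }
  o2 <- stats::optim(c(best$p1, best$p2, best$w), obj2, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-10))
  p1 <- min(p_max, max(0, o2$par[1])); p2 <- min(p_max, max(0, o2$par[2]))
  w1 <- min(1, max(0, o2$par[3]))
  # coordinate polish: exact conditional weight, then 1-D refits of each p
  # (helps when one component sits at a parameter boundary)
  for (sweep in 1:3) {
    e1 <- .bin_envelope(comp_for(p1), grid_min, bin_width, n_bins)
    e2 <- .bin_envelope(comp_for(p2), grid_min, bin_width, n_bins)
    d <- e1 - e2
    if (sum(d^2) > 0) {
      w1 <- min(1, max(0, sum((y - e2) * d) / sum(d^2)))
    }
    p1 <- stats::optimize(function(p) obj2(c(p, p2, w1)),
                          interval = c(max(0, p1 - 2 * p_grid),
                                       min(p_max, p1 + 2 * p_grid)),
                          tol = 1e-10)$minimum
    p2 <- stats::optimize(function(p) obj2(c(p1, p, w1)),
                          interval = c(max(0, p2 - 2 * p_grid),
                                       min(p_max, p2 + 2 * p_grid)),
                          tol = 1e-10)$minimum
  }
  rss2 <- obj2(c(p1, p2, w1))
  # order so "slow" has the lower deuteration
  if (p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp; w1 <- 1 - w1 }

  nb_obs <- sum(y > 0)
  floor_rss <- 1e-12
  bic1 <- nb_obs * log(max(rss1, floor_rss) / nb_obs) + 1 * log(nb_obs)
  bic2 <- nb_obs * log(max(rss2, floor_rss) / nb_obs) + 3 * log(nb_obs)
  dbic <- bic1 - bic2
  degenerate <- (abs(p2 - p1) * n_exch < collapse_sep) ||
    (min(w1, 1 - w1) < collapse_weight)
  is_bimodal <- (dbic > delta_bic) && !degenerate

  cent_for <- function(p) centroid(comp_for(p))
  if (is_bimodal) {
    slow <- list(di = p1 * n_exch, p = p1, weight = w1, centroid = cent_for(p1))
    fast <- list(di = p2 * n_exch, p = p2, weight = 1 - w1,
                 centroid = cent_for(p2))
  } else {
    slow <- list(di = p_uni * n_exch, p = p_uni, weight = 1,
                 centroid = cent_for(p_uni))
    fast <- NULL
  }
  structure(
    list(slow = slow, fast = fast, is_bimodal = is_bimodal,
         model_score = rss2, rss_unimodal = rss1, delta_bic = dbic,
         n_exch = n_exch, time = attr(env, "time"),
         peptide_id = attr(env, "peptide_id")),
    class = "deconvolved_pair"
  )
}

#' @export
print.deconvolved_pair <- function(x, ...) {
  if (x$is_bimodal) {
    cat(sprintf(
      "Bimodal envelope (dBIC = %.1f): slow DI = %.2f (w = %.3f), fast DI = %.2f (w = %.3f)\n",
      x$delta_bic, x$slow$di, x$slow$weight, x$fast$di, x$fast$weight))
  } else {
    cat(sprintf("Unimodal envelope (dBIC = %.1f): DI = %.2f\n",
                x$delta_bic, x$slow$di))
  }
  invisible(x)
}

#' Minor-to-major relative abundance of a bimodal peptide
#'
#' The population ratio is read at the earliest bimodal time point, where the
#' component centroids are at their largest separation; the major population
#' is assigned abundance one. A peptide with no bimodal time point gets
#' ratio 1 (treated as unimodal). When the first time point is unimodal but a
#' later one is bimodal, the earliest bimodal point is used and the result is
#' flagged.
#'
#' @param pairs List of [deconvolve_bimodal()] results ordered by time (or
#'   carrying `time` fields).
#' @return List with `ratio` (minor/major, in (0, 1]), `time` (the time point
#'   used, or `NA`), `fallback` (`TRUE` when the first point was unimodal),
#'   `minor_population` (`"slow"` or `"fast"`, `NA` if unimodal).
#' @export
relative_abundance <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  times <- vapply(pairs, function(p) {
    if (is.null(p$time) || is.na(p$time)) Inf else p$time
  }, numeric(1))
  ord <- order(times)
  pairs <- pairs[ord]
  bimodal <- vapply(pairs, function(p) isTRUE(p$is_bimodal), logical(1))
  if (!any(bimodal)) {
    return(list(ratio = 1, time = NA_real_, fallback = FALSE,
                minor_population = NA_character_))
  }
  first_bi <- which(bimodal)[1]
  p <- pairs[[first_bi]]
  w <- c(slow = p$slow$weight, fast = p$fast$weight)
  minor <- names(w)[which.min(w)]
  list(ratio = unname(min(w) / max(w)),
       time = if (is.null(p$time)) NA_real_ else p$time,
       fallback = first_bi > 1L,
       minor_population = minor)
}
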