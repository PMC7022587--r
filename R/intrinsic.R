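#' Exchange reaction conditions
#'
#' @param pD Solution pD (glass-electrode pH reading + 0.4); in (0, 14).
#' @param temperature Absolute temperature in K.
#' @param d_fraction Deuterium fraction of the labeling buffer (default 1).
#' @return Object of class `exchange_conditions`.
#' @export
exchange_conditions <- function(pD = 7.2, temperature = 273.15,
                                d_fraction = 1.0) {
  if (pD <= 0 || pD >= 14) stop("pD must be in (0, 14)")
  if (temperature <= 0) stop("temperature must be > 0 K")
  if (d_fraction <= 0 || d_fraction > 1) stop("d_fraction must be in (0, 1]")
  structure(list(pD = pD, temperature = temperature, d_fraction = d_fraction),
            class = "exchange_conditions")
}

#' @export
print.exchange_conditions <- function(x, ...) {
  cat(sprintf("Exchange conditions: pD %.2f, %.2f K (%.1f C), D fraction %.2f\n",
              x$pD, x$temperature, x$temperature - 273.15, x$d_fraction))
  invisible(x)
}

# Effective log10 side-chain factor for one channel, titrating D/E/H forms
# between protonated and deprotonated by pD (log-space mixing).
.side_factor <- function(res, column, pD, cst) {
  base_val <- cst$side_chain[res, column]
  t <- cst$titratable[[res]]
  if (is.null(t) || is.na(base_val)) return(base_val)
  prot <- t$protonated[match(column, colnames(cst$side_chain))]
  log10((10^(prot - pD) + 10^(base_val - t$pK)) /
          (10^(-pD) + 10^(-t$pK)))
}

#' Random-coil (intrinsic) amide exchange rates per residue
#'
#' Computes the sequence-, pD- and temperature-dependent exchange rate each
#' backbone amide would have in an unstructured chain:
#' `k_rc = kA * [D+] * A_L * A_R + kB * [OD-] * B_L * B_R + kW * B_L * B_R`,
#' with acid/base/water reference rates from the poly-DL-alanine calibration
#' ([exchange_constants()]), left/right side-chain factors (a residue's own
#' `lambda` and the preceding residue's `rho`), terminal-group factors, and
#' Arrhenius temperature scaling with separate activation energies per
#' channel. `[D+] = 10^-pD` and `[OD-] = 10^(pD - pKD)`.
#'
#' Prolines and the excluded N-terminal positions carry `NA`.
#'
#' @param peptide A [peptide_record()] or amino-acid string.
#' @param cond [exchange_conditions()].
#' @param n_term_excluded N-terminal positions without a reported rate
#'   (default 2; see [count_exchangeable()]).
#' @param constants Calibration list; defaults to [exchange_constants()].
#' @return Object of class `intrinsic_rates`: data frame with columns
#'   `position` (within-peptide), `residue`, `k_rc` (per second; `NA` for
#'   prolines/excluded positions), plus attributes `conditions`, `peptide`.
#' @export
intrinsic_rates <- function(peptide, cond = exchange_conditions(),
                            n_term_excluded = 2L,
                            constants = exchange_constants()) {
  if (!inherits(peptide, "peptide_record")) peptide <- peptide_record(peptide)
  stopifnot(inherits(cond, "exchange_conditions"))
  cst <- constants
  res <- strsplit(peptide$sequence, "")[[1]]
  n <- length(res)
  bad <- which(!(res %in% rownames(cst$side_chain)))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1]], bad[1]))
  }
  pD <- cond$pD
  tk <- cond$temperature
  arr <- function(channel) {
    exp(-cst$Ea_kcal[[channel]] / cst$gas_constant_kcal *
          (1 / tk - 1 / cst$ref_temperature_K))
  }
  kA <- 10^cst$log_kA * 10^(-pD) * arr("acid")
  kB <- 10^cst$log_kB * 10^(pD - cst$pKD) * arr("base")
  kW <- 10^cst$log_kW * arr("water")

  k_rc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i <= n_term_excluded || res[i] == "P") next
    # own side chain: lambda; preceding residue: rho
    a_log <- .side_factor(res[i], "acid_lambda", pD, cst) +
      .side_factor(res[i - 1L], "acid_rho", pD, cst)
    b_log <- .side_factor(res[i], "base_lambda", pD, cst) +
      .side_factor(res[i - 1L], "base_rho", pD, cst)
    if (i == 2L) {  # free N-terminal amine next door
      a_log <- a_log + cst$terminal$n_term[["acid_rho"]]
      b_log <- b_log + cst$terminal$n_term[["base_rho"]]
    }
    if (i == n) {   # C-terminal carboxyl on the residue itself
      ct <- cst$terminal
      a_ct <- log10((10^(ct$c_term_protonated[["acid_lambda"]] - pD) +
                       10^(ct$c_term[["acid_lambda"]] - ct$c_term_pK)) /
                      (10^(-pD) + 10^(-ct$c_term_pK)))
      a_log <- a_log + a_ct
      b_log <- b_log + ct$c_term[["base_lambda"]]
    }
    # rates in /min; convert to /s
    k_rc[i] <- (kA * 10^a_log + kB * 10^b_log + kW * 10^b_log) / 60
  }
  out <- data.frame(position = seq_len(n), residue = res, k_rc = k_rc)
  structure(out, conditions = cond, peptide = peptide,
            constants_version = cst$version,
            class = c("intrinsic_rates", "data.frame"))
}

#' @export
print.intrinsic_rates <- function(x, ...) {
  pep <- attr(x, "peptide")
  cond <- attr(x, "conditions")
  cat(sprintf("Intrinsic (random-coil) rates for %s at pD %.2f, %.2f K [%s]\n",
              pep$id, cond$pD, cond$temperature, attr(x, "constants_version")))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Analytic random-coil deuterium-uptake curve
#'
#' `DI(t) = d_fraction * sum_i (1 - exp(-k_rc,i * t))` over the exchangeable
#' residues of the peptide. Monotone non-decreasing in `t`, bounded by
#' `d_fraction * N_exch`.
#'
#' @param peptide A [peptide_record()] or amino-acid string.
#' @param cond [exchange_conditions()].
#' @param times Exchange times in seconds; `>= 0`.
#' @param rates Optional precomputed [intrinsic_rates()] (overrides
#'   `peptide`/`cond`).
#' @return Numeric vector of deuterium incorporation (D units).
#' @export
random_coil_curve <- function(peptide, cond = exchange_conditions(),
                              times, rates = NULL) {
  stopifnot(all(times >= 0))
  if (is.null(rates)) rates <- intrinsic_rates(peptide, cond)
  k <- rates$k_rc[!is.na(rates$k_rc)]
  dfrac <- attr(rates, "conditions")$d_fraction
  vapply(times, function(t) dfrac * sum(1 - exp(-k * t)), numeric(1))
}

# Times at which the multi-exponential uptake reaches the given average
# completion fractions (root-found on the analytic curve).
.completion_times <- function(k, fractions = c(0.01, 0.99)) {
  n <- length(k)
  f <- function(t) sum(1 - exp(-k * t)) / n
  vapply(fractions, function(target) {
    lo <- 1 / max(k) * 1e-6
    hi <- 1 / min(k) * 1e6
    stats::uniroot(function(t) f(t) - target, lower = lo, upper = hi,
                   tol = .Machine$double.eps^0.5)$root
  }, numeric(1))
}

#' Adaptive log-spaced time grid for stretched-exponential fitting
#'
#' 30 log-spaced times between the 1% and 99% average-completion times of
#' the peptide's analytic uptake curve. Using a completion-anchored grid
#' makes the fitted average rate exactly scale-equivariant: dividing all
#' rates by a constant divides the fitted rate by the same constant.
#'
#' @param rates An [intrinsic_rates()] object, or a bare numeric vector of
#'   rates in per second.
#' @param n_points Number of grid times (default 30).
#' @param span Completion fractions anchoring the grid ends.
#' @return Numeric vector of times in seconds.
#' @export
adaptive_time_grid <- function(rates, n_points = 30L, span = c(0.01, 0.99)) {
  k <- if (is.data.frame(rates)) rates$k_rc[!is.na(rates$k_rc)] else
    rates[!is.na(rates)]
  stopifnot(length(k) >= 1L, all(k > 0))
  tt <- .completion_times(k, span)
  exp(seq(log(tt[1]), log(tt[2]), length.out = n_points))
}

#' Average random-coil rate by single stretched-exponential fit
#'
#' Fits `DI(t) = N_exch * (1 - exp(-(k_avg * t)^beta))` to the analytic
#' random-coil curve on an adaptive log-time grid (or supplied times),
#' yielding the peptide-average intrinsic rate and heterogeneity exponent.
#'
#' @param peptide A [peptide_record()] or amino-acid string.
#' @param cond [exchange_conditions()].
#' @param times Optional fit times in seconds; default is
#'   [adaptive_time_grid()] of the peptide's intrinsic rates.
#' @param rates Optional precomputed [intrinsic_rates()].
#' @param beta_bounds Bounds on the stretch exponent (default `c(0.05, 1)`).
#' @return Object of class `stretch_fit`: `k_avg` (per second), `beta`,
#'   `n_exch`, `times`, `di`, `fitted`, `residual_norm`.
#' @export
average_rc_rate <- function(peptide, cond = exchange_conditions(),
                            times = NULL, rates = NULL,
                            beta_bounds = c(0.05, 1)) {
  if (is.null(rates)) rates <- intrinsic_rates(peptide, cond)
  k <- rates$k_rc[!is.na(rates$k_rc)]
  if (length(k) == 0L) stop("peptide has no exchangeable residues")
  if (is.null(times)) times <- adaptive_time_grid(k)
  di <- random_coil_curve(rates = rates, times = times, peptide = NULL)
  n_exch <- length(k) * attr(rates, "conditions")$d_fraction
  fit <- fit_stretched(times, di, n_exch, beta_bounds = beta_bounds)
  structure(c(fit, list(n_exch = n_exch, times = times, di = di)),
            class = "stretch_fit")
}

# Single stretched-exponential least squares with fixed amplitude.
# Multistart over log k around the curve midpoint; bounded beta.
fit_stretched <- function(times, di, amplitude, beta_bounds = c(0.05, 1)) {
  stopifnot(length(times) == length(di), amplitude > 0)
  model <- function(p, t) amplitude * (1 - exp(-(exp(p[1]) * t)^p[2]))
  obj <- function(p) sum((di - model(p, times))^2)
  # midpoint-crossing time seeds the rate scale
  mid <- times[which.min(abs(di - amplitude / 2))]
  k0 <- log(log(2)) - log(mid)
  best <- NULL
  for (lk in k0 + c(-2, -1, 0, 1, 2)) {
    for (b0 in c(0.5, 0.8, 1.0)) {
      o <- stats::optim(c(lk, b0), obj, method = "L-BFGS-B",
                        lower = c(k0 - 12, beta_bounds[1]),
                        upper = c(k0 + 12, beta_bounds[2]),
                        control = list(maxit = 500))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  if (is.null(best)) stop("stretched-exponential fit failed to converge")
  list(k_avg = exp(best$par[1]), beta = best$par[2],
       residual_norm = sqrt(best$value),
       fitted = model(best$par, times))
}

#' @export
print.stretch_fit <- function(x, ...) {
  cat(sprintf(
    "Stretched-exponential fit: k_avg = %.4g /s, beta = %.3f (N = %.3g, resid %.2g)\n",
    x$k_avg, x$beta, x$n_exch, x$residual_norm))
  invisible(x)
}
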