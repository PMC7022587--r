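#' Piecewise-linear mean-square-displacement model
#'
#' Ground-truth MSD(T) used by the synthetic elastic-scan generator. The curve
#' is continuous and piecewise linear in absolute temperature, with one linear
#' domain per temperature segment. Each segment's slope is expressed through
#' its effective force constant `<k>` via the resilience relation
#' `<k> = 0.00276 / (d<u2>/dT)` (`<k>` in N/m when `<u2>` is in square
#' Angstrom and T in K), so the generator and the fitting arm share a single
#' parameterisation. Hydrated protein and lipoprotein powders typically show
#' three such domains with slope changes near 200 K and 250 K.
#'
#' @param breakpoints Temperatures (K) where the slope changes; default
#'   `c(200, 250)`.
#' @param force_constants Effective force constant per segment in N/m;
#'   length must be `length(breakpoints) + 1`. All must be > 0.
#' @param msd_at_min_t MSD in square Angstrom at the lowest evaluated
#'   temperature offset (the model's anchor; MSD(T) = `msd_at_min_t` at
#'   `t_anchor`).
#' @param t_anchor Temperature (K) at which `msd_at_min_t` applies.
#' @return An object of class `msd_model`.
#' @export
msd_model <- function(breakpoints = c(200, 250),
                      force_constants = c(1.00, 0.25, 0.15),
                      msd_at_min_t = 0.05, t_anchor = 20) {
  stopifnot(is.numeric(breakpoints), is.numeric(force_constants))
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be increasing")
  if (length(force_constants) != length(breakpoints) + 1L) {
    stop("need one force constant per segment (length(breakpoints) + 1)")
  }
  if (any(force_constants <= 0)) stop("force constants must be > 0")
  if (msd_at_min_t < 0) stop("msd_at_min_t must be >= 0")
  structure(
    list(breakpoints = as.numeric(breakpoints),
         force_constants = as.numeric(force_constants),
         slopes = RESILIENCE_CONSTANT / as.numeric(force_constants),
         msd_at_min_t = msd_at_min_t,
         t_anchor = t_anchor),
    class = "msd_model"
  )
}

#' Resilience conversion constant between MSD slope and force constant
#'
#' `<k> = 0.00276 / (d<u2>/dT)` with `<k>` in N/m, `<u2>` in square Angstrom
#' and T in K.
#' @keywords internal
RESILIENCE_CONSTANT <- 0.00276

#' Evaluate a piecewise-linear MSD model
#'
#' @param model An `msd_model`.
#' @param temperature Temperatures in K (vectorised).
#' @return MSD values in square Angstrom.
#' @export
msd_at <- function(model, temperature) {
  stopifnot(inherits(model, "msd_model"))
  knots <- c(model$t_anchor, model$breakpoints)
  vapply(temperature, function(tt) {
    u <- model$msd_at_min_t
    for (s in seq_along(model$slopes)) {
      lo <- knots[s]
      hi <- if (s < length(model$slopes)) knots[s + 1L] else Inf
      if (tt <= lo) break
      u <- u + model$slopes[s] * (min(tt, hi) - lo)
      if (tt <= hi) break
    }
    u
  }, numeric(1))
}

#' @export
print.msd_model <- function(x, ...) {
  cat("Piecewise-linear MSD model\n")
  knots <- c(x$t_anchor, x$breakpoints, Inf)
  for (s in seq_along(x$slopes)) {
    cat(sprintf("  %6.1f - %6s K: slope %.5g A^2/K  (<k> = %.4g N/m)\n",
                knots[s], ifelse(is.finite(knots[s + 1]),
                                 sprintf("%.1f", knots[s + 1]), "Inf"),
                x$slopes[s], x$force_constants[s]))
  }
  cat(sprintf("  anchor: %.3g A^2 at %.1f K\n", x$msd_at_min_t, x$t_anchor))
  invisible(x)
}
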