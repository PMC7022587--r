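# Isotopic fine structure of peptides by elemental convolution.
#
# Distributions are kept as aggregated isotopic variants: probability and
# intensity-weighted mean mass per nominal mass-shift bin, built by repeated
# convolution of single-element distributions with pruning at a relative
# abundance threshold.

# Elemental composition (named C,H,N,O,S) of a peptide: residue sums + H2O.
peptide_composition <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, rownames(RESIDUE_FORMULAS))
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ","))
  comp <- colSums(RESIDUE_FORMULAS[res, , drop = FALSE])
  comp["H"] <- comp["H"] + 2
  comp["O"] <- comp["O"] + 1
  comp
}

# One element's distribution as (prob, mass) vectors on nominal-shift bins.
.element_dist <- function(element) {
  iso <- ISOTOPES[[element]]
  shift <- round(iso$mass - iso$mass[1])
  nb <- max(shift) + 1L
  prob <- numeric(nb); mass <- numeric(nb)
  for (j in seq_along(iso$mass)) {
    b <- shift[j] + 1L
    prob[b] <- prob[b] + iso$abundance[j]
    mass[b] <- mass[b] + iso$abundance[j] * iso$mass[j]
  }
  mass[prob > 0] <- mass[prob > 0] / prob[prob > 0]
  list(prob = prob, mass = mass)
}

# Convolve two aggregated distributions; prune below `prune` relative.
.convolve_dist <- function(a, b, prune = 1e-4) {
  na <- length(a$prob); nb <- length(b$prob)
  prob <- numeric(na + nb - 1L)
  mexp <- numeric(na + nb - 1L)  # probability-weighted mass sum
  for (i in seq_len(na)) {
    if (a$prob[i] == 0) next
    idx <- i + seq_len(nb) - 1L
    w <- a$prob[i] * b$prob
    prob[idx] <- prob[idx] + w
    mexp[idx] <- mexp[idx] + w * (a$mass[i] + b$mass)
  }
  mass <- numeric(length(prob))
  pos <- prob > 0
  mass[pos] <- mexp[pos] / prob[pos]
  keep <- prob / max(prob) >= prune
  last <- max(which(keep))
  list(prob = prob[seq_len(last)], mass = mass[seq_len(last)])
}

# Distribution of element^n by binary exponentiation.
.element_power <- function(element, n, prune = 1e-4) {
  unit <- .element_dist(element)
  result <- NULL
  base <- unit
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else .convolve_dist(result, base, prune)
    }
    n <- n %/% 2
    if (n > 0) base <- .convolve_dist(base, base, prune)
  }
  if (is.null(result)) list(prob = 1, mass = 0) else result
}

#' Isotopic envelope of an undeuterated peptide ion
#'
#' Aggregated isotopic distribution from the peptide's elemental composition
#' (standard residue formula table plus one water), truncated at a relative
#' abundance of `prune`, reported as an m/z peak list for the given charge
#' state (protonation with `z` protons).
#'
#' @param peptide A [peptide_record()] or amino-acid string.
#' @param charge Charge state; defaults to the record's charge (or 2).
#' @param prune Relative-abundance truncation threshold (default 1e-4).
#' @return Data frame with columns `mz`, `intensity` (summing to 1), sorted
#'   by `mz`.
#' @export
isotope_envelope <- function(peptide, charge = NULL, prune = 1e-4) {
  if (inherits(peptide, "peptide_record")) {
    if (is.null(charge)) charge <- peptide$charge
    sequence <- peptide$sequence
  } else {
    if (is.null(charge)) charge <- 2L
    sequence <- peptide
  }
  comp <- peptide_composition(sequence)
  dist <- NULL
  for (el in names(comp)) {
    if (comp[[el]] == 0) next
    d <- .element_power(el, comp[[el]], prune)
    dist <- if (is.null(dist)) d else .convolve_dist(dist, d, prune)
  }
  keep <- dist$prob / max(dist$prob) >= prune
  mz <- (dist$mass[keep] + charge * PROTON_MASS) / charge
  data.frame(mz = mz, intensity = dist$prob[keep] / sum(dist$prob[keep]))
}

# Poisson-binomial distribution of the number of exchanged sites given
# per-site probabilities (exact, by sequential convolution).
poisson_binomial <- function(p) {
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  dist
}

# Convolve an m/z peak list with a deuteration count distribution:
# each D adds DEUTERIUM_SHIFT / z to m/z. Peaks closer than `merge_tol`
# are merged (intensity-weighted).
deuterate_envelope <- function(env, d_dist, charge, merge_tol = 1e-6) {
  shifts <- (seq_along(d_dist) - 1L) * DEUTERIUM_SHIFT / charge
  mz <- as.vector(outer(env$mz, shifts, `+`))
  inten <- as.vector(outer(env$intensity, d_dist, `*`))
  keep <- inten > 0
  mz <- mz[keep]; inten <- inten[keep]
  ord <- order(mz)
  mz <- mz[ord]; inten <- inten[ord]
  # merge near-coincident peaks
  grp <- cumsum(c(TRUE, diff(mz) > merge_tol))
  data.frame(
    mz = as.numeric(tapply(mz * inten, grp, sum) / tapply(inten, grp, sum)),
    intensity = as.numeric(tapply(inten, grp, sum))
  )
}
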