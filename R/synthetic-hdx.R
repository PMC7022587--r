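#' Emulated proteolytic digestion into overlapping peptides
#'
#' Draws random overlapping spans along the protein until the requested
#' peptide count is reached and at least 95% of the sequence is covered.
#' The cut-site model is deliberately generic (acid proteases such as pepsin
#' produce many ragged, overlapping products); lengths are drawn around
#' `mean_length` and starts uniformly, then gap-filling spans are added if
#' coverage falls short.
#'
#' @param sequence Parent protein amino-acid string.
#' @param mean_length Mean peptide length in residues; `>= 4`.
#' @param coverage_target Number of peptides to draw (default 150).
#' @param seed Integer seed; fixed seed gives an identical span list.
#' @param charge_policy Function mapping peptide length to charge state;
#'   default gives z = 2 up to 15 residues, z = 3 above.
#' @return List of [peptide_record()]s.
#' @export
digest_protein <- function(sequence, mean_length = 12, coverage_target = 150,
                           seed = 1L,
                           charge_policy = function(len) if (len <= 15) 2L else 3L) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("empty sequence")
  if (mean_length < 4) stop("mean_length must be >= 4")
  if (mean_length >= L) {
    return(list(peptide_record(sequence, 1L, L,
                               charge = charge_policy(L), id = sprintf("1-%d", L))))
  }
  set.seed(as.integer(seed))
  draw_span <- function() {
    len <- round(stats::rnorm(1, mean_length, mean_length / 4))
    len <- max(4L, min(L, as.integer(len)))
    start <- sample.int(L - len + 1L, 1L)
    c(start, start + len - 1L)
  }
  spans <- t(vapply(seq_len(coverage_target), function(i) draw_span(),
                    integer(2)))
  covered <- function(sp) {
    hit <- logical(L)
    for (r in seq_len(nrow(sp))) hit[sp[r, 1]:sp[r, 2]] <- TRUE
    hit
  }
  # fill residual gaps with targeted spans
  tries <- 0L
  while (mean(covered(spans)) < 0.95 && tries < 10L * L) {
    gap <- which(!covered(spans))[1]
    len <- max(4L, min(L, as.integer(round(stats::rnorm(1, mean_length,
                                                        mean_length / 4)))))
    start <- max(1L, min(L - len + 1L, gap - len %/% 2L))
    spans <- rbind(spans, c(start, start + len - 1L))
    tries <- tries + 1L
  }
  if (mean(covered(spans)) < 0.95) {
    warning("coverage target unreachable with given parameters; best effort returned")
  }
  lapply(seq_len(nrow(spans)), function(r) {
    s <- spans[r, 1]; e <- spans[r, 2]
    peptide_record(substr(sequence, s, e), s, e,
                   charge = charge_policy(e - s + 1L))
  })
}

#' Ground truth for a synthetic HDX-MS dataset
#'
#' Bundles everything the generator needs: the protein, the peptide set,
#' per-residue protection factors for the two chain pools (helical-dimer and
#' hairpin-monomer), per-peptide population weights, exchange conditions,
#' the sampling times, and the back-exchange fraction. Default conditions
#' follow the labeling protocol emulated throughout the package: pD 7.2 at
#' 0 C with time points 30, 100, 300, 1000, 3000 and 10000 s and 12% average
#' back exchange.
#'
#' @param sequence Protein amino-acid string.
#' @param peptides List of [peptide_record()]s (e.g. from
#'   [digest_protein()]).
#' @param pf_dimer,pf_monomer Per-residue protection factors (length
#'   `nchar(sequence)`), `>= 1` where assigned; `NA` allowed only at
#'   positions no peptide covers.
#' @param mixture_weights Either a single length-2 numeric
#'   `c(dimer, monomer)` applied to every peptide (must sum to 1) or a list
#'   of such vectors, one per peptide. A weight of 1 for one pool makes the
#'   peptide unimodal.
#' @param conditions [exchange_conditions()].
#' @param times Exchange times in seconds, strictly increasing.
#' @param back_exchange Uniform fractional loss of incorporated D (default
#'   0.12).
#' @param seed Integer seed for envelope noise.
#' @return Object of class `hdx_truth`.
#' @export
hdx_truth <- function(sequence, peptides, pf_dimer, pf_monomer,
                      mixture_weights = c(dimer = 2 / 3, monomer = 1 / 3),
                      conditions = exchange_conditions(),
                      times = c(30, 100, 300, 1000, 3000, 10000),
                      back_exchange = 0.12, seed = 1L) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stopifnot(length(pf_dimer) == L, length(pf_monomer) == L)
  if (any(stats::na.omit(c(pf_dimer, pf_monomer)) < 1)) {
    stop("protection factors must be >= 1 where assigned")
  }
  if (any(diff(times) <= 0) || any(times <= 0)) {
    stop("times must be positive and strictly increasing")
  }
  if (back_exchange < 0 || back_exchange >= 1) {
    stop("back_exchange must be in [0, 1)")
  }
  if (!is.list(mixture_weights)) {
    mixture_weights <- rep(list(mixture_weights), length(peptides))
  }
  stopifnot(length(mixture_weights) == length(peptides))
  for (w in mixture_weights) {
    if (length(w) != 2L || abs(sum(w) - 1) > 1e-9 || any(w < 0)) {
      stop("each mixture weight must be a length-2 non-negative vector summing to 1")
    }
  }
  for (pep in peptides) {
    if (pep$start < 1L || pep$end > L) stop("peptide span outside sequence")
    if (substr(sequence, pep$start, pep$end) != pep$sequence) {
      stop(sprintf("peptide %s does not match the sequence at %d-%d",
                   pep$id, pep$start, pep$end))
    }
  }
  structure(
    list(sequence = sequence, peptides = peptides,
         pf = list(dimer = as.numeric(pf_dimer),
                   monomer = as.numeric(pf_monomer)),
         mixture_weights = mixture_weights,
         conditions = conditions, times = as.numeric(times),
         back_exchange = back_exchange, seed = as.integer(seed)),
    class = "hdx_truth"
  )
}

#' @export
print.hdx_truth <- function(x, ...) {
  cat(sprintf(
    "HDX ground truth: %d-residue protein, %d peptides, %d time points, back exchange %.0f%%\n",
    nchar(x$sequence), length(x$peptides), length(x$times),
    100 * x$back_exchange))
  invisible(x)
}

# Per-residue exchange probabilities for one peptide and pool at time t.
.site_probabilities <- function(truth, pep, pool, t, rates) {
  pos_local <- exchangeable_positions(pep)
  pf <- truth$pf[[pool]][pep$start + pos_local - 1L]
  if (anyNA(pf)) {
    miss <- pep$start + pos_local[which(is.na(pf))[1]] - 1L
    stop(sprintf("missing %s-pool protection factor for residue %d (peptide %s)",
                 pool, miss, pep$id))
  }
  k <- rates$k_rc[pos_local] / pf
  dfrac <- truth$conditions$d_fraction
  dfrac * (1 - exp(-k * t)) * (1 - truth$back_exchange)
}

#' Generate a synthetic HDX-MS envelope dataset
#'
#' For every peptide and time point the envelope is the mixture-weighted sum
#' of the two population envelopes (helical-dimer pool = slow, hairpin
#' monomer pool = fast, by convention of the default protection maps). A
#' population envelope is the peptide's undeuterated isotopic fine structure
#' convolved with the exact Poisson-binomial distribution of exchanged-site
#' counts, each site deuterated with probability
#' `d_fraction * (1 - exp(-(k_rc / Pf) * t)) * (1 - back_exchange)`.
#' A 0% control (`time = -1`) and an 80% control (`time = -2`, all sites at
#' `0.8 * (1 - back_exchange)`) are emitted per peptide. Optional Gaussian
#' noise of relative scale `noise_fraction` perturbs peak intensities
#' (seeded; per-peak standard deviation
#' `noise_fraction * sqrt(I / max I) * max I`).
#'
#' @param truth An [hdx_truth()].
#' @param noise_fraction Relative intensity noise; `>= 0` (default 0).
#' @return Object of class `hdx_dataset`: `envelopes` (list of
#'   [hdx_envelope()]; controls included), `truth`.
#' @export
make_hdx_dataset <- function(truth, noise_fraction = 0) {
  stopifnot(inherits(truth, "hdx_truth"))
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  set.seed(truth$seed)
  envelopes <- list()
  for (pi in seq_along(truth$peptides)) {
    pep <- truth$peptides[[pi]]
    weights <- truth$mixture_weights[[pi]]
    base <- isotope_envelope(pep)
    rates <- intrinsic_rates(pep, truth$conditions)
    n_exch <- count_exchangeable(pep)

    add_env <- function(peaks, time) {
      if (noise_fraction > 0) {
        m <- max(peaks$intensity)
        sd_pk <- noise_fraction * sqrt(peaks$intensity / m) * m
        peaks$intensity <- peaks$intensity + stats::rnorm(nrow(peaks), sd = sd_pk)
        peaks$intensity[peaks$intensity < 0] <- 0
        peaks <- peaks[peaks$intensity > 0, , drop = FALSE]
      }
      envelopes[[length(envelopes) + 1L]] <<- hdx_envelope(
        peaks, pep$id, pep$start, pep$end, pep$charge, time)
    }

    add_env(base, -1)
    p80 <- rep(0.8 * (1 - truth$back_exchange), n_exch)
    add_env(deuterate_envelope(base, poisson_binomial(p80), pep$charge), -2)

    for (t in truth$times) {
      parts <- list()
      for (pool in c("dimer", "monomer")) {
        w <- weights[[if (pool == "dimer") 1L else 2L]]
        if (w <= 0) next
        p <- .site_probabilities(truth, pep, pool, t, rates)
        env <- deuterate_envelope(base, poisson_binomial(p), pep$charge)
        env$intensity <- env$intensity * w
        parts[[length(parts) + 1L]] <- env
      }
      mix <- do.call(rbind, parts)
      ord <- order(mix$mz)
      mix <- mix[ord, , drop = FALSE]
      grp <- cumsum(c(TRUE, diff(mix$mz) > 1e-6))
      peaks <- data.frame(
        mz = as.numeric(tapply(mix$mz * mix$intensity, grp, sum) /
                          tapply(mix$intensity, grp, sum)),
        intensity = as.numeric(tapply(mix$intensity, grp, sum))
      )
      add_env(peaks, t)
    }
  }
  structure(list(envelopes = envelopes, truth = truth), class = "hdx_dataset")
}

#' @export
print.hdx_dataset <- function(x, ...) {
  cat(sprintf("Synthetic HDX dataset: %d envelopes (%d peptides x %d times + controls)\n",
              length(x$envelopes), length(x$truth$peptides),
              length(x$truth$times)))
  invisible(x)
}
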