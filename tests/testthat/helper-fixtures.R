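# Shared fixture builders. Everything is generated in code; no files.

# Single-peptide ground truth with a strongly protected (slow) and a weakly
# protected (fast) population mixed 2:1, on the full-length carrier protein.
bimodal_truth <- function(pf_slow = 2000, pf_fast = 2, weights = c(2, 1) / 3,
                          back_exchange = 0.12, seed = 3L) {
  seqp <- apoa1_sequence()
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126, charge = 2)
  pfd <- rep(NA_real_, nchar(seqp)); pfm <- pfd
  pfd[115:126] <- pf_slow
  pfm[115:126] <- pf_fast
  hdx_truth(seqp, list(pep), pfd, pfm,
            mixture_weights = c(dimer = weights[1], monomer = weights[2]),
            back_exchange = back_exchange, seed = seed)
}

# Envelope synthesized directly from binomial populations (the component
# family the deconvolution fits), bypassing the rate model.
binomial_mixture_envelope <- function(pep, w_slow, p_slow, p_fast,
                                      time = 30, noise_fraction = 0,
                                      seed = 1L) {
  base <- isotope_envelope(pep)
  n <- count_exchangeable(pep)
  e1 <- einshdx:::deuterate_envelope(base, dbinom(0:n, n, p_slow), pep$charge)
  e2 <- einshdx:::deuterate_envelope(base, dbinom(0:n, n, p_fast), pep$charge)
  e1$intensity <- e1$intensity * w_slow
  e2$intensity <- e2$intensity * (1 - w_slow)
  mix <- rbind(e1, e2)
  mix <- mix[order(mix$mz), ]
  if (noise_fraction > 0) {
    set.seed(seed)
    m <- max(mix$intensity)
    mix$intensity <- mix$intensity +
      rnorm(nrow(mix), sd = noise_fraction * sqrt(mix$intensity / m) * m)
    mix$intensity[mix$intensity < 0] <- 0
  }
  hdx_envelope(mix, pep$id, pep$start, pep$end, pep$charge, time)
}

ref0_envelope <- function(pep) {
  hdx_envelope(isotope_envelope(pep), pep$id, pep$start, pep$end,
               pep$charge, -1)
}

# Short carrier protein for fast whole-pipeline runs.
tiny_sequence <- function() {
  paste(rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 2), collapse = "")
}
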