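test_that("a single-rate curve is fitted as one phase with the right rate", {
  k <- 0.01
  tg <- exp(seq(log(1), log(2e3), length.out = 12))
  di <- 8 * (1 - exp(-k * tg))
  fit <- fit_biphasic(tg, di, 8)
  expect_equal(fit$n_phases, 1L)
  expect_equal(fit$phases$k, k, tolerance = 0.01)
  expect_equal(fit$phases$beta, 1, tolerance = 0.01)
  expect_error(fit_biphasic(c(1, 10, 100), c(1, 2, 3), 8), ">= 4")
})

test_that("two well-separated phases are recovered within five percent", {
  k1 <- 1e-1; k2 <- 1e-4
  tg <- exp(seq(log(0.1 / k1), log(50 / k2), length.out = 30))
  di <- 4 * (1 - exp(-k1 * tg)) + 4 * (1 - exp(-k2 * tg))
  fit <- fit_biphasic(tg, di, 8)
  expect_equal(fit$n_phases, 2L)
  expect_equal(fit$phases$phase, c("fast", "slow"))
  expect_lt(abs(fit$phases$k[1] - k1) / k1, 0.05)
  expect_lt(abs(fit$phases$k[2] - k2) / k2, 0.05)
  expect_lt(abs(sum(fit$phases$n_sites) - 8), 0.5)
  # independent coarse grid oracle: the fit must beat every grid candidate
  grid_rss <- min(sapply(10^seq(-5, 0, by = 0.25), function(g1) {
    sapply(10^seq(-6, -2, by = 0.25), function(g2) {
      sum((di - 4 * (1 - exp(-g1 * tg)) - 4 * (1 - exp(-g2 * tg)))^2)
    })
  }))
  expect_lte(fit$residual_norm^2, grid_rss + 1e-12)
})

test_that("the six-point experimental grid still resolves two phases", {
  tp <- c(30, 100, 300, 1000, 3000, 10000)
  di <- 4 * (1 - exp(-0.05 * tp)) + 4 * (1 - exp(-2e-4 * tp))
  fit <- fit_biphasic(tp, di, 8)
  expect_equal(fit$n_phases, 2L)
  expect_lt(abs(fit$phases$k[1] - 0.05) / 0.05, 0.1)
  expect_lt(abs(fit$phases$k[2] - 2e-4) / 2e-4, 0.1)
})

test_that("protection factors are the rate ratio with the blue infinity case", {
  expect_equal(protection_factor(1e-3, 1e-3), 1)
  expect_equal(protection_factor(1e-5, 1e-2), 1000)
  expect_equal(protection_factor(0, 1e-2), Inf)
  expect_equal(classify_pf(protection_factor(0, 1e-2)), "blue")
  expect_error(protection_factor(1e-3, 0), "> 0")
})

test_that("colour classes use half-open thresholds with proline black", {
  expect_equal(classify_pf(c(5, 50, 500, 5000)),
               c("red", "orange", "green", "blue"))
  expect_equal(classify_pf(10), "orange")
  expect_equal(classify_pf(10 - 1e-9), "red")
  expect_equal(classify_pf(100), "green")
  expect_equal(classify_pf(1000), "blue")
  expect_equal(classify_pf(NA), "grey")
  expect_equal(classify_pf(c(5, 5), is_proline = c(FALSE, TRUE)),
               c("red", "black"))
})

test_that("largest-remainder rounding conserves the site total", {
  expect_equal(round_site_counts(c(3.6, 4.4), 8), c(4L, 4L))
  expect_equal(round_site_counts(c(2.3, 5.7), 8), c(2L, 6L))
  expect_equal(sum(round_site_counts(c(2.5, 5.5), 8)), 8L)
  expect_equal(sum(round_site_counts(c(1.2, 3.4, 2.4), 7)), 7L)
  expect_equal(round_site_counts(c(0.4, 7.6), 8), c(0L, 8L))
})

test_that("peptides are pooled by relative abundance with the 0.75 cutoff", {
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126)
  phases <- function(pf) data.frame(pf = pf, n_sites = c(5L, 4L))
  bimodal <- list(peptide = pep, is_bimodal = TRUE, ratio = 0.5,
                  populations = list(major = list(pf_phases = phases(c(100, 1000))),
                                     minor = list(pf_phases = phases(c(1, 10)))))
  unimodal <- list(peptide = pep, is_bimodal = FALSE,
                   populations = list(single = list(pf_phases = phases(c(5, 50)))))
  ambiguous <- list(peptide = pep, is_bimodal = TRUE, ratio = 0.9,
                    populations = list(major = list(pf_phases = phases(c(100, 1000))),
                                       minor = list(pf_phases = phases(c(1, 10)))))
  pools <- pool_peptides(list(bimodal, unimodal, ambiguous))
  # bimodal: major -> dimer (abundance 1), minor -> monomer (abundance 0.5)
  expect_equal(pools$dimer[[1]]$pf_phases$pf, c(100, 1000))
  expect_equal(pools$dimer[[1]]$abundance, 1)
  expect_equal(pools$monomer[[1]]$pf_phases$pf, c(1, 10))
  expect_equal(pools$monomer[[1]]$abundance, 0.5)
  # unimodal joins both pools
  expect_equal(pools$dimer[[2]]$pf_phases$pf, c(5, 50))
  expect_equal(pools$monomer[[2]]$pf_phases$pf, c(5, 50))
  # ratio 0.9: both populations flagged ambiguous, abundance treated as one
  amb <- pools$dimer[3:4]
  expect_true(all(vapply(amb, `[[`, logical(1), "ambiguous")))
  expect_equal(length(pools$monomer), 2L)
})

test_that("a single one-phase peptide paints all its exchangeable residues", {
  seqs <- "MKTAYIAKQR"
  pep <- peptide_record(seqs, 1, 10)
  pool <- list(list(peptide = pep,
                    pf_phases = data.frame(pf = 40, n_sites = 8L)))
  m <- assign_residue_pf(pool, seqs, seed = 1)
  expect_equal(m$pf[3:10], rep(40, 8))
  expect_equal(m$class[3:10], rep("orange", 8))
  expect_equal(m$status[1:2], rep("undetermined", 2))
  expect_true(attr(m, "converged"))
})

test_that("overlapping peptides recover a uniquely pinned class pattern", {
  # peptide B is uniform, pinning the overlap; A's split is then forced
  seqs <- "AAKAAEAAKAAEAA"
  pA <- peptide_record(substr(seqs, 1, 10), 1, 10)    # exch 3..10
  pB <- peptide_record(substr(seqs, 5, 14), 5, 14)    # exch 7..14
  pool <- list(
    list(peptide = pA, pf_phases = data.frame(pf = c(5, 500),
                                              n_sites = c(4L, 4L))),
    list(peptide = pB, pf_phases = data.frame(pf = 500, n_sites = 8L))
  )
  m <- assign_residue_pf(pool, seqs, seed = 11)
  expect_true(attr(m, "converged"))
  expect_equal(m$pf[3:6], rep(5, 4))     # forced to the non-overlap part of A
  expect_equal(m$pf[7:14], rep(500, 8))
  # independent brute-force oracle over all arrangements of A
  positions <- 3:10
  vals <- c(5, 5, 5, 5, 500, 500, 500, 500)
  best <- NULL
  for (sel in utils::combn(8, 4, simplify = FALSE)) {
    v <- rep(500, 8); v[sel] <- 5
    # cost against B's fixed 500s on the overlap 7..10 (positions 5..8 of A)
    cost <- sum((log10(v[5:8]) - log10(500))^2 > 0)
    if (is.null(best) || cost < best$cost) best <- list(cost = cost, v = v)
  }
  expect_equal(best$cost, 0)
  expect_equal(best$v, unname(m$pf[3:10]))
})

test_that("non-overlapping peptides are consistent at initialisation", {
  seqs <- "MKTAYIAKQRQISFVKSHFS"
  pool <- list(
    list(peptide = peptide_record(substr(seqs, 1, 8), 1, 8),
         pf_phases = data.frame(pf = c(2, 200), n_sites = c(3L, 3L))),
    list(peptide = peptide_record(substr(seqs, 11, 18), 11, 18),
         pf_phases = data.frame(pf = 30, n_sites = 6L))
  )
  m <- assign_residue_pf(pool, seqs, seed = 2)
  expect_true(attr(m, "converged"))
  expect_equal(attr(m, "cost"), 0)
})

test_that("greedy descent conserves each peptide's Pf multiset", {
  seqs <- "MKTAYIAKQRQISFVKSHFS"
  pool <- list(
    list(peptide = peptide_record(substr(seqs, 1, 12), 1, 12),
         pf_phases = data.frame(pf = c(3, 300), n_sites = c(5L, 5L))),
    list(peptide = peptide_record(substr(seqs, 5, 16), 5, 16),
         pf_phases = data.frame(pf = c(3, 300), n_sites = c(6L, 4L))),
    list(peptide = peptide_record(substr(seqs, 9, 20), 9, 20),
         pf_phases = data.frame(pf = c(3, 300), n_sites = c(4L, 6L)))
  )
  # force the stochastic path by disabling exhaustive enumeration
  m <- assign_residue_pf(pool, seqs, seed = 4, exhaustive_limit = 0)
  for (entry in pool) {
    pos <- entry$peptide$start + exchangeable_positions(entry$peptide) - 1L
    single_cover <- pos[m$n_cover[pos] == 1L]
    # wherever this peptide is the only cover, the map value is its own
    # assignment; the multiset there must be a sub-multiset of the truth
    vals <- m$pf[single_cover]
    full <- with(entry$pf_phases, rep(pf, n_sites))
    expect_true(all(table(vals) <= table(full)[names(table(vals))]))
  }
  # contradictory peptides: best assignment returned with a warning
  pool_bad <- list(
    list(peptide = peptide_record(substr(seqs, 1, 8), 1, 8),
         pf_phases = data.frame(pf = 2, n_sites = 6L)),
    list(peptide = peptide_record(substr(seqs, 1, 8), 1, 8),
         pf_phases = data.frame(pf = 5000, n_sites = 6L))
  )
  expect_warning(mb <- assign_residue_pf(pool_bad, seqs, seed = 1),
                 "consistent")
  expect_false(attr(mb, "converged"))
  expect_gt(length(attr(mb, "conflicts")), 0)
})

test_that("the three-chain chart duplicates the dimer map", {
  seqs <- "MKTAYIAKQR"
  pool <- list(list(peptide = peptide_record(seqs, 1, 10),
                    pf_phases = data.frame(pf = 40, n_sites = 8L)))
  md <- assign_residue_pf(pool, seqs, seed = 1)
  pool_m <- list(list(peptide = peptide_record(substr(seqs, 1, 6), 1, 6),
                      pf_phases = data.frame(pf = 3, n_sites = 4L)))
  mm <- assign_residue_pf(pool_m, seqs, seed = 1)
  chart <- build_pf_chart(md, mm)
  expect_equal(nrow(chart), 30)
  expect_equal(chart$pf[chart$chain == "dimer1"],
               chart$pf[chart$chain == "dimer2"])
  # residue covered only by the dimer pool is grey on the monomer chain
  expect_equal(chart$class[chart$chain == "monomer" & chart$residue == 9],
               "grey")
})
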