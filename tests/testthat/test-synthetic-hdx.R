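test_that("digestion reaches the requested depth and coverage, deterministically", {
  seqp <- apoa1_sequence()
  peps <- digest_protein(seqp, mean_length = 12, coverage_target = 150,
                         seed = 7)
  expect_gte(length(peps), 150)
  hit <- logical(nchar(seqp))
  for (p in peps) hit[p$start:p$end] <- TRUE
  expect_gte(mean(hit), 0.95)
  peps2 <- digest_protein(seqp, mean_length = 12, coverage_target = 150,
                          seed = 7)
  expect_identical(vapply(peps, `[[`, character(1), "id"),
                   vapply(peps2, `[[`, character(1), "id"))
  # mean length above the sequence length degenerates to one full span
  short <- digest_protein("MKTAYIAK", mean_length = 20, coverage_target = 5,
                          seed = 1)
  expect_length(short, 1)
  expect_equal(short[[1]]$sequence, "MKTAYIAK")
  expect_error(digest_protein("", 12, 10), "empty")
  expect_error(digest_protein("MKTAYIAK", mean_length = 2), "mean_length")
})

test_that("generated envelopes are normalised at every time point", {
  truth <- bimodal_truth()
  ds <- make_hdx_dataset(truth)
  sums <- vapply(ds$envelopes, function(e) sum(e$intensity), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("unprotected single population reproduces the random-coil curve", {
  seqp <- apoa1_sequence()
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126, charge = 2)
  pf1 <- rep(NA_real_, nchar(seqp)); pf1[115:126] <- 1
  truth <- hdx_truth(seqp, list(pep), pf1, pf1,
                     mixture_weights = c(dimer = 1, monomer = 0),
                     back_exchange = 0, seed = 1)
  ds <- make_hdx_dataset(truth)
  times <- vapply(ds$envelopes, attr, numeric(1), "time")
  c0 <- centroid(ds$envelopes[[which(times == -1)]])
  c80 <- centroid(ds$envelopes[[which(times == -2)]])
  rc <- random_coil_curve(pep, truth$conditions, truth$times)
  for (i in seq_along(truth$times)) {
    ct <- centroid(ds$envelopes[[which(times == truth$times[i])]])
    di <- compute_di(ct, c0, c80, 2, count_exchangeable(pep))$di
    expect_lt(abs(di - rc[i]), 0.05)
  }
})

test_that("back exchange is recovered through the 80% control correction", {
  seqp <- apoa1_sequence()
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126, charge = 2)
  pf <- rep(NA_real_, nchar(seqp)); pf[115:126] <- 20
  truth <- hdx_truth(seqp, list(pep), pf, pf,
                     mixture_weights = c(dimer = 1, monomer = 0),
                     back_exchange = 0.12, seed = 1)
  ds <- make_hdx_dataset(truth)
  times <- vapply(ds$envelopes, attr, numeric(1), "time")
  c0 <- centroid(ds$envelopes[[which(times == -1)]])
  c80 <- centroid(ds$envelopes[[which(times == -2)]])
  n <- count_exchangeable(pep)
  r <- intrinsic_rates(pep, truth$conditions)
  k <- r$k_rc[!is.na(r$k_rc)] / 20
  for (t in c(100, 1000)) {
    ct <- centroid(ds$envelopes[[which(times == t)]])
    res <- compute_di(ct, c0, c80, 2, n)
    # corrected DI matches the pre-back-exchange generated incorporation
    expect_lt(abs(res$di - sum(1 - exp(-k * t))), 0.05)
    expect_equal(res$back_exchange_percent, 12, tolerance = 1e-6)
  }
})

test_that("missing protection factors are reported with the residue index", {
  seqp <- apoa1_sequence()
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126, charge = 2)
  pf <- rep(NA_real_, nchar(seqp)); pf[115:120] <- 10  # 121+ missing
  truth <- hdx_truth(seqp, list(pep), pf, pf,
                     mixture_weights = c(dimer = 1, monomer = 0), seed = 1)
  expect_error(make_hdx_dataset(truth), "12[1-9]")
})

test_that("a 2:1 mixture is visibly bimodal early and merged late", {
  truth <- bimodal_truth(pf_slow = 2000, pf_fast = 2)
  ds <- make_hdx_dataset(truth)
  times <- vapply(ds$envelopes, attr, numeric(1), "time")
  # bimodality shows as strong excess spread over the 0% fine structure
  spread <- function(e) {
    mu <- centroid(e)
    sqrt(sum(e$intensity * (e$mz - mu)^2) / sum(e$intensity))
  }
  e30 <- ds$envelopes[[which(times == 30)]]
  e1e4 <- ds$envelopes[[which(times == 10000)]]
  ref <- ds$envelopes[[which(times == -1)]]
  expect_gt(spread(e30), 3 * spread(ref))
  # centroids converge as the slow population saturates
  pep <- truth$peptides[[1]]
  sr <- intrinsic_rates(pep, truth$conditions)$k_rc[exchangeable_positions(pep)]
  d30 <- deconvolve_bimodal(e30, ref, 9, rates = sr, retention = 0.88)
  d1e4 <- deconvolve_bimodal(e1e4, ref, 9, rates = sr, retention = 0.88)
  expect_true(d30$is_bimodal)
  sep30 <- (d30$fast$centroid - d30$slow$centroid) * 2
  sep1e4 <- (d1e4$fast$centroid - d1e4$slow$centroid) * 2
  expect_lt(sep1e4, sep30 / 1.5)
})

test_that("fixed seeds give byte-identical output files", {
  truth <- bimodal_truth(seed = 9)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_peak_table(make_hdx_dataset(truth, noise_fraction = 0.01), f1)
  write_peak_table(make_hdx_dataset(truth, noise_fraction = 0.01), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})
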