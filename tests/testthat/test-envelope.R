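test_that("centroid is the intensity-weighted mean m/z", {
  e <- data.frame(mz = 655.4, intensity = 3)
  expect_equal(centroid(e), 655.4)
  e2 <- data.frame(mz = c(650, 652), intensity = c(1, 1))
  expect_equal(centroid(e2), 651)
  set.seed(1)
  e3 <- data.frame(mz = sort(runif(20, 600, 700)), intensity = runif(20))
  expect_equal(centroid(e3), sum(e3$mz * e3$intensity) / sum(e3$intensity))
  expect_error(centroid(data.frame(mz = 1, intensity = 0)), "all-zero")
})

test_that("centroid DI interpolates linearly between the controls", {
  c0 <- 655.0; c80 <- 659.0
  expect_equal(compute_di(c0, c0, c80, 2, 10)$di, 0)
  expect_equal(compute_di(c80, c0, c80, 2, 10)$di, 8)
  expect_equal(compute_di((c0 + c80) / 2, c0, c80, 2, 10)$di, 4)
  # the ratio form is invariant to the charge state
  expect_equal(compute_di(657, c0, c80, 1, 10)$di,
               compute_di(657, c0, c80, 3, 10)$di)
  # mass-domain raw shift does scale with charge
  expect_equal(compute_di(657, c0, c80, 3, 10)$di_raw, 6)
  expect_error(compute_di(657, c80, c0, 2, 10), "cent_80")
  expect_warning(di <- compute_di(c0 - 0.5, c0, c80, 2, 10)$di, "clamping")
  expect_equal(di, 0)
  # back-exchange percent from a consistent 80% control
  n <- 10; z <- 2; bx <- 0.12
  c80b <- c0 + 0.8 * n * (1 - bx) * 1.00627675 / z
  expect_equal(compute_di(c0, c0, c80b, z, n)$back_exchange_percent, 12,
               tolerance = 1e-9)
})

test_that("a single-population envelope is returned as unimodal", {
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126, charge = 2)
  env <- binomial_mixture_envelope(pep, w_slow = 1, p_slow = 0.4, p_fast = 0)
  dec <- deconvolve_bimodal(env, ref0_envelope(pep), count_exchangeable(pep))
  expect_false(dec$is_bimodal)
  expect_equal(dec$slow$weight, 1)
  expect_equal(dec$slow$di, 0.4 * 9, tolerance = 0.02)
})

test_that("a 2:1 mixture is recovered and matches the grid-search oracle", {
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126, charge = 2)
  n <- count_exchangeable(pep)
  env <- binomial_mixture_envelope(pep, w_slow = 2 / 3, p_slow = 0.1,
                                   p_fast = 0.7)  # ~5.4 D apart => >= 3 Da
  ref0 <- ref0_envelope(pep)
  dec <- deconvolve_bimodal(env, ref0, n)
  expect_true(dec$is_bimodal)
  expect_lt(abs(dec$slow$weight - 2 / 3), 0.02)
  expect_lt(abs(dec$fast$weight - 1 / 3), 0.02)

  # independent oracle: exhaustive 0.01-resolution grid over the two
  # component deuterations with the closed-form conditional weight,
  # using its own binning of the peak lists
  base <- isotope_envelope(pep)
  gmin <- min(base$mz) - 0.005
  nb <- ceiling((max(base$mz) + (n + 1) * 1.00627675 / 2 - gmin) / 0.005) + 1
  obin <- function(e) {
    v <- numeric(nb)
    ix <- pmin(nb, pmax(1, round((e$mz - gmin) / 0.005) + 1))
    for (j in seq_along(ix)) v[ix[j]] <- v[ix[j]] + e$intensity[j]
    v
  }
  yv <- obin(data.frame(mz = env$mz, intensity = env$intensity /
                          sum(env$intensity)))
  ps <- seq(0, 1, by = 0.01)
  comps <- lapply(ps, function(p) {
    obin(einshdx:::deuterate_envelope(base, dbinom(0:n, n, p), 2))
  })
  best <- c(Inf, NA, NA, NA)
  for (a in seq_along(ps)) for (b in seq_along(ps)) {
    if (b <= a) next
    d <- comps[[a]] - comps[[b]]
    den <- sum(d^2)
    if (den == 0) next
    w <- min(1, max(0, sum((yv - comps[[b]]) * d) / den))
    rss <- sum((yv - (w * comps[[a]] + (1 - w) * comps[[b]]))^2)
    if (rss < best[1]) best <- c(rss, ps[a], ps[b], w)
  }
  expect_lt(abs(dec$slow$p - best[2]), 0.015)
  expect_lt(abs(dec$fast$p - best[3]), 0.015)
  expect_lt(abs(dec$slow$weight - best[4]), 0.02)
})

test_that("weight recovery stays within bounds across a seeded sweep", {
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126, charge = 2)
  n <- count_exchangeable(pep)
  ref0 <- ref0_envelope(pep)
  shift_per_d <- 1.00627675
  cases <- expand.grid(w = c(0.25, 0.5, 0.7), sep_da = c(2.5, 5))
  for (i in seq_len(nrow(cases))) {
    w <- cases$w[i]
    p1 <- 0.15
    p2 <- p1 + cases$sep_da[i] / (n * shift_per_d)
    env <- binomial_mixture_envelope(pep, w, p1, p2)
    dec <- deconvolve_bimodal(env, ref0, n)
    expect_true(dec$is_bimodal)
    expect_lt(abs(dec$slow$weight - w), 0.02)
  }
  # 1% intensity noise loosens recovery to 0.05
  for (seed in c(7, 8)) {
    env <- binomial_mixture_envelope(pep, 0.6, 0.15, 0.7,
                                     noise_fraction = 0.01, seed = seed)
    dec <- deconvolve_bimodal(env, ref0, n)
    expect_lt(abs(dec$slow$weight - 0.6), 0.05)
  }
})

test_that("fitted components reconstruct a noise-free envelope", {
  pep <- peptide_record("YRQKVEPLRAEL", 115, 126, charge = 2)
  n <- count_exchangeable(pep)
  env <- binomial_mixture_envelope(pep, 0.6, 0.12, 0.65)
  ref0 <- ref0_envelope(pep)
  dec <- deconvolve_bimodal(env, ref0, n)
  base <- isotope_envelope(pep)
  recon <- rbind(
    transform(einshdx:::deuterate_envelope(base, dbinom(0:n, n, dec$slow$p), 2),
              intensity = intensity * dec$slow$weight),
    transform(einshdx:::deuterate_envelope(base, dbinom(0:n, n, dec$fast$p), 2),
              intensity = intensity * dec$fast$weight)
  )
  # compare on a common grid
  gmin <- min(base$mz) - 0.01
  nb <- ceiling((max(base$mz) + (n + 1) * 1.00627675 / 2 - gmin) / 0.01) + 2
  yv <- einshdx:::.bin_envelope(
    data.frame(mz = env$mz, intensity = env$intensity / sum(env$intensity)),
    gmin, 0.01, nb)
  rv <- einshdx:::.bin_envelope(recon, gmin, 0.01, nb)
  expect_lt(sqrt(sum((yv - rv)^2)) / sqrt(sum(yv^2)), 1e-6)
})

test_that("late-time envelopes report nearly merged component centroids", {
  # both populations close to saturation by 10^4 s: centroids converge
  truth <- bimodal_truth(pf_slow = 50, pf_fast = 2)
  ds <- make_hdx_dataset(truth)
  times <- vapply(ds$envelopes, attr, numeric(1), "time")
  ref0 <- ds$envelopes[[which(times == -1)]]
  pep <- truth$peptides[[1]]
  sr <- intrinsic_rates(pep, truth$conditions)$k_rc[exchangeable_positions(pep)]
  late <- deconvolve_bimodal(ds$envelopes[[which(times == 10000)]], ref0,
                             9, rates = sr, retention = 0.88)
  early <- deconvolve_bimodal(ds$envelopes[[which(times == 30)]], ref0,
                              9, rates = sr, retention = 0.88)
  sep <- function(d) {
    if (!d$is_bimodal) 0 else
      abs(d$fast$centroid - d$slow$centroid) * attr(ref0, "charge")
  }
  expect_lt(sep(late), 0.5)
  expect_gt(sep(early), 3)
})

test_that("relative abundance reads the earliest bimodal time point", {
  mk <- function(bi, w_slow, t) {
    structure(list(is_bimodal = bi,
                   slow = list(weight = w_slow),
                   fast = if (bi) list(weight = 1 - w_slow),
                   time = t), class = "deconvolved_pair")
  }
  ra <- relative_abundance(list(mk(TRUE, 2 / 3, 30), mk(TRUE, 0.5, 100)))
  expect_equal(ra$ratio, 0.5)
  expect_equal(ra$time, 30)
  expect_false(ra$fallback)
  expect_equal(relative_abundance(list(mk(TRUE, 0.5, 30)))$ratio, 1)
  # all-unimodal series is treated as unimodal
  ra_u <- relative_abundance(list(mk(FALSE, 1, 30), mk(FALSE, 1, 100)))
  expect_equal(ra_u$ratio, 1)
  expect_true(is.na(ra_u$minor_population))
  # first point unimodal: fall back to the earliest bimodal point, flagged
  ra_f <- relative_abundance(list(mk(FALSE, 1, 30), mk(TRUE, 0.6, 100)))
  expect_equal(ra_f$ratio, 0.4 / 0.6)
  expect_true(ra_f$fallback)
  expect_equal(ra_f$time, 100)
})
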