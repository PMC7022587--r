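test_that("Q windowing keeps exactly the in-window points, in order", {
  sc <- elastic_scan(300, c(0.3, 0.6, 1.0, 2.0, 2.3), c(5, 4, 3, 2, 1))
  win <- select_q_window(sc, in13_config())
  expect_equal(win$q, c(0.6, 1.0, 2.0))
  expect_equal(win$intensity, c(4, 3, 2))
  # window containing everything is the identity
  all_in <- select_q_window(sc, c(0.1, 3))
  expect_equal(as.data.frame(all_in), as.data.frame(sc))
  # window excluding all points errors
  expect_error(select_q_window(sc, c(5, 6)), "window too narrow")
  # windowing is idempotent: fitting pre-windowed points gives the same MSD
  expect_equal(fit_msd(select_q_window(win, in13_config()))$msd,
               fit_msd(win)$msd)
})

test_that("MSD fit inverts the Gaussian approximation exactly when noise-free", {
  q <- in13_config()$q_grid
  # ambient-temperature MSD of the spherical particle on the thermal setup
  sc <- elastic_scan(305, q, 0.7 * exp(-2.1 * q^2 / 6))
  f <- fit_msd(sc)
  expect_equal(f$msd, 2.1, tolerance = 1e-12)
  expect_equal(f$i0, 0.7, tolerance = 1e-9)
  # constant intensity means zero MSD
  flat <- elastic_scan(100, q, rep(2, length(q)))
  expect_equal(fit_msd(flat)$msd, 0)
  # I0 cancels: scaling all intensities leaves the slope untouched
  sc2 <- elastic_scan(305, q, 123.4 * (0.7 * exp(-2.1 * q^2 / 6)))
  expect_equal(fit_msd(sc2)$msd, f$msd, tolerance = 1e-12)
  expect_error(fit_msd(elastic_scan(10, q, -q)), "non-positive")
})

test_that("noisy MSD fit matches the closed-form weighted regression oracle", {
  cfg <- in13_config()
  model <- msd_model(breakpoints = numeric(0), force_constants = 1,
                     msd_at_min_t = 1.5, t_anchor = 300)
  cfg2 <- instrument_config("one", cfg$q_window, cfg$q_grid,
                            temperatures = 300)
  ds <- make_elastic_dataset(cfg2, model, noise_fraction = 0.01, seed = 11)
  sc <- ds$scans[[1]]
  f <- fit_msd(sc)
  # independent oracle: weighted normal equations on (Q^2, ln I)
  x <- sc$q^2; y <- log(sc$intensity); w <- (sc$intensity / sc$sigma)^2
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  expect_equal(f$msd, -6 * slope, tolerance = 1e-10)
  # recovery within 3 propagated sigmas of the generating value
  expect_lt(abs(f$msd - 1.5), 3 * f$msd_sigma)
})

test_that("Gaussian validity masks points with msd * Q^2 above 2", {
  sc <- elastic_scan(300, c(1, 2, 2.06), c(1, 1, 1))
  gv <- gaussian_validity(0.4, sc)
  expect_true(gv$valid[2])          # 0.4 * 4 = 1.6
  expect_equal(gv$uq2[2], 1.6)
  gv2 <- gaussian_validity(2.1, sc)
  expect_false(gv2$valid[3])        # 2.1 * 2.06^2 = 8.91
  expect_equal(gv2$uq2[3], 2.1 * 2.06^2)
  expect_true(all(gaussian_validity(0, sc)$valid))
})

test_that("ramp binning groups scans into 5 K bins anchored at the start", {
  q <- c(0.6, 1.0, 1.5)
  temps <- seq(20, 310, by = 0.3)
  scans <- lapply(temps, function(tt) elastic_scan(tt, q, rep(1, 3)))
  b <- bin_ramp(scans, 5)
  expect_length(b, 58)  # brute-force count of occupied [20 + 5n, 20 + 5(n+1)) bins
  expect_equal(length(unique(floor((temps - 20) / 5))), 58)
  # single scan passes through with the bin centre as temperature
  one <- bin_ramp(scans[1], 5)
  expect_length(one, 1)
  expect_equal(one[[1]]$intensity, rep(1, 3))
  # two scans in one bin average their intensities
  two <- bin_ramp(list(elastic_scan(100, q, rep(2, 3)),
                       elastic_scan(101, q, rep(4, 3))), 5)
  expect_length(two, 1)
  expect_equal(two[[1]]$intensity, rep(3, 3))
  expect_error(bin_ramp(list(), 5), "empty")
})

test_that("normalisation subtracts empty cell and divides by vanadium", {
  q <- c(0.6, 1.0)
  sc <- elastic_scan(300, q, c(10, 10))
  ec <- elastic_scan(300, q, c(2, 2))
  vn <- elastic_scan(300, q, c(4, 4))
  out <- normalize_scan(sc, ec, vn, transmission = 1)
  expect_equal(out$intensity, c(2, 2))
  # identity references change nothing
  id <- normalize_scan(sc, elastic_scan(300, q, c(0, 0)),
                       elastic_scan(300, q, c(1, 1)), 1)
  expect_equal(id$intensity, sc$intensity)
  expect_error(normalize_scan(sc, elastic_scan(300, c(0.7, 1.0), c(0, 0))),
               "Q grid")
  expect_error(normalize_scan(sc, vanadium = elastic_scan(300, q, c(0, 1))),
               "zero")
})

test_that("segment fits return the generating force constants (quotient form)", {
  cfg <- in13_config()
  # the three spherical-particle constants on the thermal instrument
  model <- msd_model(breakpoints = c(200, 250),
                     force_constants = c(1.00, 0.25, 0.15))
  ds <- make_elastic_dataset(cfg, model)
  series <- fit_msd_series(ds)
  seg <- fit_force_constants(series, breakpoints = c(200, 250))
  expect_equal(unname(coef(seg)), c(1.00, 0.25, 0.15), tolerance = 1e-9)
  # segment constants are inversely ordered with segment slopes
  expect_equal(order(seg$slope), order(-seg$force_constant))
  # exactly linear single-segment series: k * slope = 0.00276 identically
  tt <- seq(100, 300, by = 10)
  series1 <- data.frame(temperature = tt, msd = 0.01 + 0.004 * (tt - 100))
  seg1 <- fit_force_constants(series1, breakpoints = numeric(0))
  expect_equal(seg1$force_constant * seg1$slope, 0.00276, tolerance = 1e-12)
  # non-positive slope is flagged, not converted
  series_flat <- data.frame(temperature = tt, msd = rep(1, length(tt)))
  segf <- fit_force_constants(series_flat, breakpoints = numeric(0))
  expect_equal(segf$status, "rigid/undefined")
  expect_true(is.na(segf$force_constant))
  expect_error(fit_force_constants(series1, breakpoints = 400), "inside")
})

test_that("noisy segment fits agree with an independent OLS oracle", {
  cfg <- in13_config()
  model <- msd_model(force_constants = c(1.0, 0.3, 0.1), msd_at_min_t = 0.05)
  ds <- make_elastic_dataset(cfg, model, noise_fraction = 0.005, seed = 5)
  series <- fit_msd_series(ds)
  seg <- fit_force_constants(series, breakpoints = c(200, 250),
                             weighted = FALSE)
  for (s in seq_len(nrow(seg))) {
    keep <- series$temperature >= seg$t_low[s] &
      series$temperature <= seg$t_high[s]
    ols <- stats::coef(stats::lm(msd ~ temperature, data = series[keep, ]))
    expect_equal(seg$slope[s], unname(ols[2]), tolerance = 1e-10)
    expect_lt(abs(seg$force_constant[s] - model$force_constants[s]),
              2 * seg$force_constant_se[s] + 1e-12)
  }
})

test_that("noise-free generate-fit round trip reproduces the MSD model", {
  for (k in list(c(1.00, 0.25, 0.15), c(1.13, 0.49, 0.067))) {
    model <- msd_model(force_constants = k)
    ds <- make_elastic_dataset(in13_config(), model)
    series <- fit_msd_series(ds)
    expect_lt(max(abs(series$msd - ds$truth$msd) /
                    pmax(ds$truth$msd, 1e-12)), 1e-9)
    seg <- fit_force_constants(series)
    expect_lt(max(abs(coef(seg) - k) / k), 1e-6)
  }
})
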