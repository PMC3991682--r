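# Temporal descriptors: moments, periodogram, band powers, high-frequency
# fraction, extrema/jumps, autocorrelations, dynamic spectrum metrics.

test_that("time-course moments match analytic values", {
  alt <- rep(c(-1, 1), 30)
  m <- tc_moments(alt)
  expect_equal(unname(m[["skewness"]]), 0)
  expect_equal(unname(m[["kurtosis"]]), 1)
  expect_equal(unname(m[["mean"]]), 0)

  expect_nc_error(tc_moments(rep(2, 50)), "degenerate")

  withr::local_seed(12)
  g <- rnorm(1e5)
  expect_lt(abs(tc_moments(g)[["kurtosis"]] - 3), 0.2)
})

test_that("periodogram is the normalized mean-removed DFT power", {
  tt <- 256; tr <- 2
  x <- sin(2 * pi * 0.03 * (0:(tt - 1)) * tr)
  sp <- periodogram(x, tr)
  expect_equal(sum(sp$power), 1, tolerance = 1e-10)
  expect_equal(sp$power[[1]], 0, tolerance = 1e-12)       # DC removed
  f_peak <- sp$freq[which.max(sp$power)]
  expect_lt(abs(f_peak - 0.03), 1 / (tt * tr) + 1e-12)    # within one bin
  expect_equal(max(sp$freq), 1 / (2 * tr))

  # direct DFT oracle
  withr::local_seed(4)
  x2 <- rnorm(64)
  sp2 <- periodogram(x2, 1.5)
  want <- oracle_periodogram(x2, 1.5)
  expect_equal(sp2$freq, want$freq, tolerance = 1e-12)
  expect_equal(sp2$power, want$power, tolerance = 1e-10)

  expect_nc_error(periodogram(rnorm(5), 2), "input")
})

test_that("band powers partition the spectrum below 0.25 Hz", {
  tt <- 256; tr <- 2
  tsec <- (0:(tt - 1)) * tr
  # 0.03125 Hz = bin 16 of 512 s: an integral number of cycles, so the tone
  # lands on one bin with no leakage
  sp1 <- periodogram(sin(2 * pi * 0.03125 * tsec), tr)
  bp1 <- band_power(sp1)
  expect_gte(bp1[["power_band_0.02_0.05"]], 0.99)
  expect_true(all(bp1[names(bp1) != "power_band_0.02_0.05"] <= 0.01))

  # two equal tones in different bands split the power evenly
  two <- sin(2 * pi * 0.01 * tsec) + sin(2 * pi * 0.07 * tsec)
  bp2 <- band_power(periodogram(two, tr))
  expect_lt(abs(bp2[["power_band_0.008_0.02"]] - 0.5), 0.02)
  expect_lt(abs(bp2[["power_band_0.05_0.1"]] - 0.5), 0.02)

  withr::local_seed(2)
  bp3 <- band_power(periodogram(rnorm(200), tr))
  expect_lte(sum(bp3), 1)
})

test_that("high-frequency fraction isolates power above the cutoff", {
  tt <- 200; tr <- 1
  tsec <- (0:(tt - 1)) * tr
  expect_gte(high_freq_fraction(periodogram(sin(2 * pi * 0.2 * tsec), tr)), 0.99)
  expect_lte(high_freq_fraction(periodogram(sin(2 * pi * 0.03 * tsec), tr)), 0.01)

  # with tr = 2 s (Nyquist 0.25 Hz) the 5 bands + the Nyquist bin tile the
  # axis: the high-frequency fraction equals the top band plus the leftover
  withr::local_seed(6)
  sp <- periodogram(rnorm(128), 2)
  bands <- band_power(sp)
  expect_equal(high_freq_fraction(sp, 0.1),
               bands[["power_band_0.1_0.25"]] + (1 - sum(bands)),
               tolerance = 1e-10)
})

test_that("extrema metrics enumerate interior strict extrema and jumps", {
  expect_equal(unname(extrema_metrics(1:50)), rep(0, 6))

  alt <- rep(c(1, -1), length.out = 11)
  em <- extrema_metrics(alt)
  expect_equal(unname(em[["n_maxima"]]), 4)
  expect_equal(unname(em[["n_minima"]]), 5)
  expect_equal(unname(em[["avg_jump"]]), 2)
  expect_equal(unname(em[["biggest_jump"]]), 2)

  # enumeration oracle on random walks
  for (s in 1:10) {
    withr::local_seed(s)
    x <- cumsum(rnorm(80))
    em2 <- extrema_metrics(x)
    i <- 2:(length(x) - 1)
    mx <- i[x[i] > x[i - 1] & x[i] > x[i + 1]]
    mn <- i[x[i] < x[i - 1] & x[i] < x[i + 1]]
    expect_equal(unname(em2[["n_maxima"]]), length(mx))
    expect_equal(unname(em2[["n_minima"]]), length(mn))
    if (length(mx) >= 2) expect_equal(unname(em2[["avg_dist_maxima"]]), mean(diff(mx)))
    merged <- sort(c(mx, mn))
    jumps <- c()
    for (j in seq_len(length(merged) - 1)) {
      if (merged[j] %in% mn && merged[j + 1] %in% mx) {
        jumps <- c(jumps, x[merged[j + 1]] - x[merged[j]])
      }
    }
    if (length(jumps)) {
      expect_equal(unname(em2[["avg_jump"]]), mean(jumps))
      expect_equal(unname(em2[["biggest_jump"]]), max(jumps))
    }
  }

  # triangle wave with period 20 time points
  tri <- rep(c(0:9, 10:1), 5)
  expect_equal(unname(extrema_metrics(tri)[["avg_dist_maxima"]]), 20)
})

test_that("autocorrelations are Pearson correlations at lags 1..5", {
  alt <- rep(c(-1, 1), 20)
  ac <- autocorrelation(alt)
  expect_equal(unname(ac[["autocorr_lag1"]]), -1)
  expect_equal(unname(ac[["autocorr_lag2"]]), 1)

  withr::local_seed(21)
  x <- numeric(20000)
  for (t in 2:20000) x[t] <- 0.8 * x[t - 1] + rnorm(1)
  ac2 <- autocorrelation(x)
  for (k in 1:5) expect_lt(abs(ac2[[k]] - 0.8^k), 0.03)

  expect_nc_error(autocorrelation(rep(1, 100)), "degenerate")
  expect_nc_error(autocorrelation(rnorm(8)), "input")
})

test_that("dynamic spectrum metrics measure peak-to-side-minimum drops", {
  # peak in the lowest bin: nothing to its left
  sp_low <- make_spectrum(seq(0, 0.25, length.out = 33),
                          c(10, 9:1, rep(0.5, 23)))
  dm <- dynamic_spectrum_metrics(sp_low)
  expect_equal(unname(dm[["dyn_range_low"]]), 0)
  expect_gt(dm[["dyn_range_high"]], 0)

  # flat spectrum: every metric vanishes
  sp_flat <- make_spectrum(seq(0, 0.25, length.out = 129), rep(1, 129))
  expect_equal(max(abs(dynamic_spectrum_metrics(sp_flat))), 0, tolerance = 1e-10)

  # single tone vs a direct min/max scan
  tt <- 128; tr <- 2
  sp <- periodogram(sin(2 * pi * 0.06 * (0:(tt - 1)) * tr) + rnorm(tt) * 0.01, tr)
  got <- dynamic_spectrum_metrics(sp)
  i_star <- which.max(sp$power)
  expect_equal(unname(got[["dyn_range_high"]]),
               sp$power[i_star] - min(sp$power[(i_star + 1):nrow(sp)]))
  expect_equal(unname(got[["dyn_range_low"]]),
               sp$power[i_star] - min(sp$power[1:(i_star - 1)]))
  expect_true(all(got >= 0))
})

test_that("temporal features respect shift and scale invariances", {
  withr::local_seed(31)
  x <- rnorm(120)
  shift <- x + 57.3
  scale2 <- x * 4.2

  expect_equal(autocorrelation(shift), autocorrelation(x))
  expect_equal(autocorrelation(scale2), autocorrelation(x))
  expect_equal(periodogram(shift, 2)$power, periodogram(x, 2)$power,
               tolerance = 1e-9)
  expect_equal(periodogram(scale2, 2)$power, periodogram(x, 2)$power,
               tolerance = 1e-9)
  expect_equal(tc_moments(shift)[["kurtosis"]], tc_moments(x)[["kurtosis"]])
  expect_equal(tc_moments(shift)[["mean"]], tc_moments(x)[["mean"]] + 57.3)
  em_x <- extrema_metrics(x); em_s <- extrema_metrics(shift)
  expect_equal(em_s[["n_maxima"]], em_x[["n_maxima"]])
  expect_equal(em_s[["avg_jump"]], em_x[["avg_jump"]])
})
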