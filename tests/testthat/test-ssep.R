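# Spectral analysis and cycle-resolved summaries, validated on surrogate
# signals with analytically known content, plus trial-level properties of
# the driven network.

test_that("a pure tone yields a single dominant bin at its frequency", {
  tr <- make_surrogate_eeg(freqs = 40, amps = 1, duration_ms = 1000)
  sp <- power_spectrum(tr, segment_ms = 1000, window = "rect")
  expect_equal(sp$freq[which.max(sp$power)], 40)
  bp <- band_powers(sp)
  expect_lt(bp[["20"]], 0.01 * bp[["40"]])
  expect_lt(bp[["30"]], 0.01 * bp[["40"]])
  # analytic tone power a^2 / 2
  expect_equal(bp[["40"]], 0.5, tolerance = 0.02)
})

test_that("spectra are additive over well-separated tones", {
  a <- make_surrogate_eeg(freqs = 20, amps = 1, duration_ms = 1000)
  b <- make_surrogate_eeg(freqs = 40, amps = 0.5, duration_ms = 1000)
  ab <- make_surrogate_eeg(freqs = c(20, 40), amps = c(1, 0.5),
                           duration_ms = 1000)
  for (f in c(20, 40)) {
    pa <- band_power(power_spectrum(a, 1000, window = "rect"), f)
    pb <- band_power(power_spectrum(b, 1000, window = "rect"), f)
    pab <- band_power(power_spectrum(ab, 1000, window = "rect"), f)
    expect_equal(pab, pa + pb, tolerance = 0.02 * (pa + pb) + 1e-6)
  }
})

test_that("total spectral power equals the time-domain variance (Parseval)", {
  tr <- make_surrogate_eeg(freqs = c(17, 40), amps = c(1, 0.7),
                           noise_sd = 0.5, duration_ms = 1000, seed = 4)
  sp <- power_spectrum(tr, segment_ms = 1000, window = "rect")
  x <- tr$x - mean(tr$x)
  expect_equal(sum(sp$power) * sp$df, mean(x^2), tolerance = 0.01)
})

test_that("band extraction integrates density and handles degenerate width", {
  tr <- make_surrogate_eeg(freqs = 40, amps = 1, duration_ms = 1000)
  sp <- power_spectrum(tr, segment_ms = 500)
  expect_gt(band_power(sp, 40), band_power(sp, 30))
  expect_equal(band_power(sp, 40, halfwidth = 0),
               sp$power[which.min(abs(sp$freq - 40))] * sp$df)
  expect_error(band_power(sp, 1e6), "outside")
  short <- make_surrogate_eeg(freqs = 40, duration_ms = 80)
  expect_error(power_spectrum(short, segment_ms = 200), "shorter")
})

test_that("band power scales with the square of the trace amplitude", {
  t1 <- make_surrogate_eeg(freqs = c(20, 30, 40), amps = c(1, 0.7, 0.5),
                           duration_ms = 500)
  t3 <- t1; t3$x <- 3 * t1$x
  p1 <- band_powers(power_spectrum(t1, 500))
  p3 <- band_powers(power_spectrum(t3, 500))
  expect_equal(unname(p3 / p1), rep(9, 3), tolerance = 1e-9)
})

test_that("cycle averaging reproduces periodic structure exactly", {
  # noiseless 40 Hz tone: the two cycles of the averaged window coincide
  tr <- make_surrogate_eeg(freqs = 40, amps = 1, duration_ms = 500, dt_ms = 0.25)
  av <- cycle_average(tr, 40, n_cycles = 2)
  half <- nrow(av) / 2
  expect_equal(av$value[1:half], av$value[(half + 1):(2 * half)],
               tolerance = 1e-6)
  # the average of a noiseless periodic signal is one period of it
  expect_equal(av$value, tr$x[1:nrow(av)], tolerance = 1e-6)
  # 20 + 40 Hz mixture: alternating cycles differ (beat skipping)
  mix <- make_surrogate_eeg(freqs = c(20, 40), amps = c(0.8, 1),
                            duration_ms = 500, dt_ms = 0.25)
  avm <- cycle_average(mix, 40, n_cycles = 2)
  expect_gt(max(abs(avm$value[1:half] - avm$value[(half + 1):(2 * half)])),
            0.5)
  expect_error(cycle_average(make_surrogate_eeg(40, duration_ms = 60,
                                                dt_ms = 0.25), 40),
               "cycles")
})

test_that("spike histograms bin phase correctly and normalise to probability", {
  mk <- function(times, type = "pyramidal") {
    data.frame(cell = seq_along(times), type = rep(type, length(times)),
               time_ms = times)
  }
  # all spikes at phase zero occupy a single bin
  h <- spike_histogram(mk(c(0.1, 50.1, 100.1)), "pyramidal", drive_freq = 40,
                       n_cycles = 2, bins = 20, n_cells = 3,
                       duration_ms = 200)
  expect_equal(sum(h$counts > 0), 1)
  # empty record: all-zero histogram, not an error
  h0 <- spike_histogram(mk(numeric(0)), "PV", drive_freq = 40, bins = 10,
                        n_cells = 5, duration_ms = 200)
  expect_equal(h0$counts, rep(0L, 10))
  expect_equal(h0$rate_hz, 0)
  # uniform spikes: flat within multinomial tolerance
  set.seed(1)
  n <- 20000
  hu <- spike_histogram(mk(runif(n, 0, 1000)), "pyramidal", drive_freq = 40,
                        n_cycles = 2, bins = 20, n_cells = n,
                        duration_ms = 1000)
  expect_true(all(abs(hu$counts - n / 20) < 5 * sqrt(n / 20)))
  # alternating-cycle raster: unequal first- vs second-cycle mass
  tt <- rep(seq(0, 975, by = 50), each = 10) + runif(200, 0, 3)
  ha <- spike_histogram(mk(tt), "pyramidal", drive_freq = 40, n_cycles = 2,
                        bins = 20, n_cells = 10, duration_ms = 1000)
  first <- sum(ha$counts[1:10]); second <- sum(ha$counts[11:20])
  expect_gt(first, 3 * second)
})

test_that("SSEP trials are reproducible and silent without drive", {
  net <- tiny_net()
  a <- run_ssep_trial(net, short_drive(40), seed = 5)
  b <- run_ssep_trial(net, short_drive(40), seed = 5)
  expect_identical(a$trace$x, b$trace$x)
  expect_identical(a$spikes, b$spikes)
  c <- run_ssep_trial(net, short_drive(40), seed = 6)
  expect_false(identical(a$trace$x, c$trace$x))

  silent <- run_ssep_trial(net, drive_spec(40, g_max_nS = 0,
                                           duration_ms = 700,
                                           transient_ms = 200), seed = 5)
  bp <- band_powers(power_spectrum(silent$trace))
  driven <- band_powers(power_spectrum(a$trace))
  expect_lt(max(bp), 1e-6 * max(driven)) # below any sensible noise floor
})

test_that("the driven control network entrains to its drive frequency", {
  net <- tiny_net()
  for (f in c(20, 30, 40)) {
    tr <- run_ssep_trial(net, short_drive(f), seed = 2)
    bp <- band_powers(power_spectrum(tr$trace))
    expect_equal(as.numeric(names(bp)[which.max(bp)]), f)
    expect_gt(sum(tr$spikes$type == "pyramidal"), 0)
  }
})
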