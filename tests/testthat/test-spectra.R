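test_that("common-average reference zeroes the channel mean at every sample", {
  seg <- fixture_segment(nch = 19, seconds = 2, seed = 2)
  rr <- rereference_common_average(seg)
  expect_lt(max(abs(colMeans(rr$data))), 1e-10)
  # oracle: explicit column-mean subtraction
  expect_equal(rr$data, sweep(seg$data, 2, colMeans(seg$data)))

  same <- eeg_segment(matrix(rep(sin(1:512), 3), 3, byrow = TRUE,
                             dimnames = list(c("O1", "O2", "Cz"), NULL)), 256)
  expect_equal(max(abs(rereference_common_average(same)$data)), 0)

  x <- rnorm(512)
  anti <- eeg_segment(rbind(O1 = x, O2 = -x), 256)
  expect_equal(rereference_common_average(anti)$data, anti$data)

  single <- eeg_segment(matrix(rnorm(512), 1, dimnames = list("Cz", NULL)), 256)
  expect_error(rereference_common_average(single), "2 channels")
})

test_that("epoching yields the documented epoch counts", {
  seg20 <- fixture_segment(nch = 2, seconds = 20, seed = 3)
  eps <- epoch_segment(seg20, 1, 0.9)          # step round(0.1 * 256) = 26
  expect_length(eps, floor((5120 - 256) / 26) + 1)
  expect_length(eps, 188)
  expect_length(epoch_segment(seg20, 1, 0), 20)
  seg1 <- fixture_segment(nch = 2, seconds = 1, seed = 3)
  expect_length(epoch_segment(seg1, 1, 0.9), 1)
  expect_error(epoch_segment(seg1, 2, 0.9), "shorter")
})

test_that("spectral pipeline equals the naive DFT oracle and normalizes rows", {
  seg <- rereference_common_average(fixture_segment(nch = 3, seconds = 2,
                                                    seed = 4))
  ps <- power_spectrum(seg)
  expect_equal(unname(rowSums(ps$power)), rep(1, 3), tolerance = 1e-12)
  oracle <- naive_power_spectrum(seg)
  expect_lt(max(abs(ps$power - oracle) / pmax(abs(oracle), 1e-12)), 1e-8)
})

test_that("white noise gives a near-uniform relative spectrum", {
  seg <- rereference_common_average(
    generate_segment(oscillator_spec(10, 2, 0, 0), noise_spec(0, 5),
                     seed = 6))
  ps <- power_spectrum(seg)
  expect_true(all(abs(ps$power - 1 / 19) < 0.35 / 19))
})

test_that("spectra and shifts are invariant to signal gain", {
  seg <- rereference_common_average(fixture_segment(nch = 4, seconds = 2,
                                                    seed = 7))
  seg_scaled <- seg
  seg_scaled$data <- seg$data * 37.5
  ps1 <- power_spectrum(seg); ps2 <- power_spectrum(seg_scaled)
  expect_equal(ps1$power, ps2$power, tolerance = 1e-12)
  expect_equal(alpha_shift(ps1)$global, alpha_shift(ps2)$global,
               tolerance = 1e-12)
})

test_that("alpha shift computes the log2 low/high band ratio", {
  flat <- structure(list(power = matrix(1 / 19, 2, 19,
                                        dimnames = list(c("O1", "O2"), 2:20)),
                         freqs = 2:20), class = "eeg_power_spectrum")
  pr <- alpha_shift(flat)
  expect_equal(unname(pr$per_channel), c(0, 0))
  expect_equal(pr$global, 0)

  hand <- flat
  hand$power[, ] <- 0.01
  hand$power[, as.character(6:9)] <- 0.02      # low-band mean 0.02
  hand$power[, as.character(10:11)] <- 0.04    # high-band mean 0.04
  expect_equal(unname(alpha_shift(hand)$per_channel), c(-1, -1))
  expect_equal(alpha_shift(hand)$global, -1)

  spiked <- flat
  spiked$power[, ] <- 1e-6
  spiked$power[, "8"] <- 1 - 18e-6
  expect_gt(alpha_shift(spiked)$global, 5)

  degenerate <- flat
  degenerate$power[, as.character(10:11)] <- 0
  expect_error(alpha_shift(degenerate), "high-alpha")
})

test_that("slowing the generator peak strictly increases the global shift", {
  noi <- noise_spec(1, 10)
  sh_of <- function(peak) {
    seg <- generate_segment(oscillator_spec(peak, 2, 20, 0.2), noi, seed = 31)
    alpha_shift(power_spectrum(rereference_common_average(seg)))$global
  }
  expect_gt(sh_of(8), sh_of(10.5))
})

test_that("individual alpha frequency finds the spectral peak with a low tie-break", {
  seg <- rereference_common_average(
    generate_segment(oscillator_spec(10, 0.01, 10, 0.5), noise_spec(0, 0),
                     seed = 12))
  expect_equal(individual_alpha_frequency(power_spectrum(seg)), 10)

  seg8 <- rereference_common_average(
    generate_segment(oscillator_spec(8, 2, 20, 0.2), noise_spec(1, 10),
                     seed = 13))
  expect_lte(abs(individual_alpha_frequency(power_spectrum(seg8)) - 8), 1)

  flat <- structure(list(power = matrix(1 / 19, 1, 19,
                                        dimnames = list("Cz", 2:20)),
                         freqs = 2:20), class = "eeg_power_spectrum")
  expect_equal(individual_alpha_frequency(flat), 6)
  expect_error(individual_alpha_frequency(flat, c(21, 25)), "no spectral bins")
})
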