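lay <- montage_1020()

test_that("generation is deterministic and validates its inputs", {
  osc <- oscillator_spec(10.5, 2, 20, 0.2)
  noi <- noise_spec(1, 10)
  s1 <- generate_segment(osc, noi, lay, seed = 5)
  s2 <- generate_segment(osc, noi, lay, seed = 5)
  expect_identical(s1$data, s2$data)
  expect_equal(dim(s1$data), c(19L, 20L * 256L))
  s3 <- generate_segment(osc, noi, lay, seed = 6)
  expect_false(identical(s1$data, s3$data))

  expect_error(generate_segment(osc, noi, lay, seed = 1, channels = "Oz"),
               "Oz")
  expect_error(generate_segment(oscillator_spec(10), noi, lay, fs = 16,
                                duration = 2, seed = 1),
               "alias")
  expect_error(oscillator_spec(peak_freq = 25), "peak_freq")
  expect_error(oscillator_spec(bandwidth = 0), "bandwidth")
})

test_that("zero oscillator amplitude leaves only background noise", {
  seg <- generate_segment(oscillator_spec(10, 2, 0, 0.2), noise_spec(0, 5),
                          lay, seed = 3)
  ps <- power_spectrum(rereference_common_average(seg))
  # 10 Hz bin indistinguishable from its neighbours beyond sampling error
  p10 <- mean(ps$power[, "10"])
  neigh <- mean(ps$power[, c("8", "9", "11", "12")])
  expect_lt(abs(p10 - neigh) / neigh, 0.2)
})

test_that("a pure noiseless 10 Hz oscillator concentrates spectral power at 10 Hz", {
  seg <- generate_segment(oscillator_spec(10, 0.01, 10, 0.5),
                          noise_spec(0, 0), lay, seed = 11)
  seg <- rereference_common_average(seg)
  # oracle: direct DFT of the full segment puts > 95% of 2-20 Hz power at 10 Hz
  x <- seg$data["O1", ]
  co <- fft(x - mean(x))
  bins <- (2:20) * length(x) / seg$fs + 1
  p <- Mod(co[bins])^2
  expect_gt(p[9] / sum(p), 0.95)
  # The Hann-tapered pipeline peaks at the same bin, with the taper spreading
  # an exact on-bin tone into the two adjacent 1 Hz bins with weight 1/4
  # each. The central (y = 0) channels are excluded: the common average of a
  # rank-1 noiseless topography cancels them exactly (mid-gradient amplitude
  # equals the montage mean), leaving no signal to analyze there.
  ps <- power_spectrum(seg)
  keep <- abs(lay$xy[, "y"]) > 1e-9
  expect_equal(unname(ps$freqs[apply(ps$power[keep, ], 1, which.max)]),
               rep(10, sum(keep)))
  expect_equal(mean(ps$power[keep, "10"]), 2 / 3, tolerance = 0.02)
})

test_that("anterior_spread controls frontal but not occipital alpha power", {
  noi <- noise_spec(0, 0.01)
  s0 <- generate_segment(oscillator_spec(10, 2, 20, 0), noi, lay, seed = 9)
  s1 <- generate_segment(oscillator_spec(10, 2, 20, 1), noi, lay, seed = 9)
  band_power <- function(seg, ch) {
    # absolute 9-11 Hz power from the raw (unreferenced) channel
    x <- seg$data[ch, ]
    co <- fft(x - mean(x))
    bins <- (9:11) * length(x) / seg$fs + 1
    sum(Mod(co[bins])^2)
  }
  for (occ in c("O1", "O2")) {
    expect_equal(band_power(s0, occ), band_power(s1, occ), tolerance = 1e-10)
  }
  for (fro in c("Fp1", "Fp2")) {
    expect_gt(band_power(s1, fro), band_power(s0, fro))
  }
  # amplitude is monotone non-increasing in the anterior coordinate
  # (checked on the noiseless alpha component, where sd equals the gradient)
  s_pure <- generate_segment(oscillator_spec(10, 2, 20, 0), noise_spec(0, 0),
                             lay, seed = 9)
  amps <- apply(s_pure$data, 1, sd)
  ord <- order(lay$xy[, "y"])
  expect_true(all(diff(amps[ord]) <= 1e-9 * max(amps)))
})

test_that("cohort generation matches the design and the dichotomization rule", {
  design <- cohort_design(seed = 17)
  co <- generate_cohort(design)
  expect_equal(nrow(co$table), 102L)
  expect_equal(as.vector(table(co$table$cohort_group)[c("HS", "GSC", "PSC")]),
               c(39L, 25L, 38L))
  expect_length(co$segments, 102L)

  co2 <- generate_cohort(design)
  expect_identical(co$table, co2$table)
  expect_identical(co$segments[["S001"]]$data, co2$segments[["S001"]]$data)

  hs <- co$table[co$table$group == "HS", ]
  expect_true(all(hs$aed_load == 0))
  expect_true(all(hs$syndrome == "none" & hs$seizure_control == "none"))
  pat <- co$table[co$table$group == "patient", ]
  expect_true(all((pat$seizure_count_12m >= 4) ==
                    (pat$seizure_control == "PSC")))
  expect_true(all(pat$syndrome %in% c("FE", "IGE")))

  expect_error(cohort_design(n_per_group = c(HS = 1, GSC = 5)), "at least 2")
  expect_error(cohort_design(n_per_group = c(HS = 5, XX = 5)), "XX")
})

test_that("slower poor-control oscillators yield larger global shifts downstream", {
  design <- cohort_design(
    n_per_group = c(GSC = 8, PSC = 8),
    group_oscillators = list(GSC = oscillator_spec(10.5, 2, 20, 0.2),
                             PSC = oscillator_spec(8, 2, 20, 0.6)),
    seed = 23)
  co <- generate_cohort(design)
  sh <- cohort_alpha_shifts(co$segments)
  grp <- co$table$cohort_group
  expect_gt(mean(sh$global[grp == "PSC"]), mean(sh$global[grp == "GSC"]))
})
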