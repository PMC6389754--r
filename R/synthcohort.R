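#' Alpha-oscillator specification for the synthetic EEG generator
#'
#' Describes the narrowband alpha component of a synthetic resting EEG
#' segment: its spectral peak, bandwidth, amplitude and how far the
#' posterior-dominant topography spreads anteriorly.
#'
#' @param peak_freq Peak frequency in Hz, inside (2, 20).
#' @param bandwidth Spectral width of the alpha component in Hz (> 0); the
#'   component occupies `peak_freq` +/- `bandwidth/2`.
#' @param amplitude Root-mean-square amplitude (arbitrary units, >= 0) of the
#'   alpha component at the most posterior electrode.
#' @param anterior_spread Number in \[0, 1\]: 0 gives a strictly posterior
#'   topography (alpha amplitude decaying to zero at the most anterior
#'   electrode), 1 gives a spatially uniform alpha amplitude.
#' @return An object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(peak_freq = 10.5, bandwidth = 2, amplitude = 20,
                            anterior_spread = 0.2) {
  stop_if_not_scalar_number(peak_freq, "peak_freq", 2, 20, strict = TRUE)
  stop_if_not_scalar_number(bandwidth, "bandwidth", 0, Inf, strict = TRUE)
  stop_if_not_scalar_number(amplitude, "amplitude", 0)
  stop_if_not_scalar_number(anterior_spread, "anterior_spread", 0, 1)
  structure(list(peak_freq = peak_freq, bandwidth = bandwidth,
                 amplitude = amplitude, anterior_spread = anterior_spread),
            class = "oscillator_spec")
}

#' Background-noise specification for the synthetic EEG generator
#'
#' The background is spectrally shaped noise with power spectral density
#' proportional to `1/f^one_over_f_exponent`; exponent 0 gives white noise.
#'
#' @param one_over_f_exponent Spectral slope (>= 0; default 1).
#' @param white_sd Standard deviation of the background (arbitrary units,
#'   >= 0).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(one_over_f_exponent = 1, white_sd = 10) {
  stop_if_not_scalar_number(one_over_f_exponent, "one_over_f_exponent", 0)
  stop_if_not_scalar_number(white_sd, "white_sd", 0)
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 white_sd = white_sd), class = "noise_spec")
}

# random-phase spectral synthesis of `ncol` real-valued signals of length n:
# `weight(f)` gives the target amplitude-spectrum weight at frequency f (Hz).
# Returns an n x ncol matrix of zero-mean, unit-SD signals (zero if degenerate).
.spectral_synth <- function(n, fs, weight, ncol = 1L) {
  k <- seq_len(floor(n / 2) - 1L)           # positive frequencies, excl. DC/Nyquist
  f <- k * fs / n
  a <- weight(f)
  if (all(a == 0)) return(matrix(0, n, ncol))
  phases <- matrix(stats::runif(length(k) * ncol, 0, 2 * pi), length(k), ncol)
  full <- matrix(complex(real = 0), n, ncol)
  coef <- a * exp(1i * phases)
  full[k + 1L, ] <- coef
  full[n + 1L - k, ] <- Conj(coef)
  x <- Re(stats::mvfft(full, inverse = TRUE)) / n
  x <- sweep(x, 2, colMeans(x))
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

#' Generate one synthetic eyes-closed EEG segment
#'
#' Synthesizes a multichannel segment as a shared narrowband alpha waveform
#' (random-phase spectral synthesis within `peak_freq` +/- `bandwidth/2`,
#' raised-cosine band profile) scaled per channel by a posterior-to-anterior
#' amplitude gradient, plus independent per-channel 1/f-shaped background
#' noise.
#'
#' The per-channel alpha amplitude is
#' `amplitude * (spread + (1 - spread) * w)`, where `w` decreases linearly
#' from 1 at the most posterior electrode to 0 at the most anterior one, so
#' `anterior_spread = 1` gives a uniform topography and occipital amplitude
#' is independent of the spread parameter.
#'
#' @param osc An [oscillator_spec()].
#' @param noise A [noise_spec()].
#' @param montage A [montage_1020()] layout (positions for all channels).
#' @param duration Segment length in seconds (default 20).
#' @param fs Sampling rate in Hz (default 256); must exceed twice the alpha
#'   peak frequency.
#' @param seed Integer seed; identical arguments give identical output.
#' @param channels Channel labels to generate (default: all montage labels).
#' @return An [eeg_segment()].
#' @export
generate_segment <- function(osc, noise, montage = montage_1020(),
                             duration = 20, fs = 256, seed = 1,
                             channels = montage$labels) {
  stopifnot(inherits(osc, "oscillator_spec"), inherits(noise, "noise_spec"),
            inherits(montage, "montage_layout"))
  stop_if_not_scalar_number(duration, "duration", 0, strict = TRUE)
  stop_if_not_scalar_number(fs, "fs", 0, strict = TRUE)
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9 || n < fs) {
    stop("duration x fs must be an integer number of samples >= fs (1 s)")
  }
  n <- as.integer(round(n))
  if (fs <= 2 * osc$peak_freq) {
    stop(sprintf("fs = %g Hz aliases the %g Hz alpha peak (need fs > 2 * peak_freq)",
                 fs, osc$peak_freq))
  }
  idx <- match(channels, montage$labels)
  if (anyNA(idx)) {
    stop(sprintf("unknown montage label(s): %s",
                 paste(channels[is.na(idx)], collapse = ", ")))
  }
  xy <- montage$xy[idx, , drop = FALSE]
  nch <- length(channels)

  # posterior-to-anterior amplitude gradient over the montage's y range
  yr <- range(montage$xy[, "y"])
  w <- (yr[2] - xy[, "y"]) / diff(yr)
  amp <- osc$amplitude * (osc$anterior_spread + (1 - osc$anterior_spread) * w)

  half_bw <- osc$bandwidth / 2
  f0 <- osc$peak_freq
  df <- fs / n
  alpha_weight <- function(f) {
    a <- ifelse(abs(f - f0) <= half_bw, cos(pi * (f - f0) / osc$bandwidth)^2, 0)
    if (all(a == 0)) a[which.min(abs(f - f0))] <- 1   # band narrower than df
    a
  }
  noise_weight <- function(f) f^(-noise$one_over_f_exponent / 2)

  data <- with_seed(seed, {
    alpha_wave <- if (osc$amplitude > 0) {
      .spectral_synth(n, fs, alpha_weight)[, 1]
    } else numeric(n)
    out <- tcrossprod(amp, alpha_wave)               # nch x n alpha component
    if (noise$white_sd > 0) {
      out <- out + noise$white_sd * t(.spectral_synth(n, fs, noise_weight, nch))
    }
    out
  })
  rownames(data) <- channels
  eeg_segment(data, fs = fs, labels = channels, xy = xy)
}

#' Cohort design for the synthetic-EEG generator
#'
#' Defines group sizes, per-group alpha oscillators, background noise,
#' covariate distributions and between-subject variability for a synthetic
#' resting-EEG cohort. Defaults emulate a three-group cohort (39 healthy
#' subjects, 25 patients with good and 38 with poor seizure control) with a
#' slowed, anteriorized alpha rhythm in the poor-control group.
#'
#' @param n_per_group Named integer vector of group sizes (names are group
#'   labels; `"HS"` is treated as the healthy group). All counts >= 2.
#' @param group_oscillators Named list of [oscillator_spec()] per group.
#' @param noise A [noise_spec()] shared by all subjects.
#' @param age_mean,age_sd Named numeric vectors (per group), years.
#' @param female_prop Named numeric vector of female proportions per group.
#' @param aed_mean,aed_sd Named numeric vectors for patient groups (gamma
#'   distributed AED load, arbitrary units).
#' @param fe_prop Named numeric vector: proportion of focal-epilepsy syndrome
#'   among patients per patient group.
#' @param gsc_count_mu,gsc_count_size Negative-binomial parameters for
#'   12-month seizure counts in the good-control group (truncated at 3, so
#'   good control always means fewer than four seizures).
#' @param psc_count_mu,psc_count_size Negative-binomial parameters for counts
#'   in excess of 4 in the poor-control group.
#' @param subject_peak_sd Between-subject SD of the alpha peak frequency (Hz).
#' @param subject_amp_sdlog Between-subject log-normal SD of alpha amplitude.
#' @param duration,fs Segment length (s) and sampling rate (Hz).
#' @param montage A [montage_1020()] layout.
#' @param seed Integer seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(HS = 39, GSC = 25, PSC = 38),
                          group_oscillators = list(
                            HS = oscillator_spec(10.5, 2, 20, 0.2),
                            GSC = oscillator_spec(10.5, 2, 20, 0.2),
                            PSC = oscillator_spec(8.0, 2, 20, 0.6)),
                          noise = noise_spec(1, 10),
                          age_mean = c(HS = 30, GSC = 33, PSC = 38),
                          age_sd = c(HS = 9, GSC = 12, PSC = 14),
                          female_prop = c(HS = 0.49, GSC = 0.60, PSC = 0.50),
                          aed_mean = c(GSC = 1.4, PSC = 1.5),
                          aed_sd = c(GSC = 0.9, PSC = 0.8),
                          fe_prop = c(GSC = 0.40, PSC = 0.71),
                          gsc_count_mu = 1, gsc_count_size = 1,
                          psc_count_mu = 8, psc_count_size = 1.2,
                          subject_peak_sd = 1.0, subject_amp_sdlog = 0.5,
                          duration = 20, fs = 256,
                          montage = montage_1020(), seed = 1) {
  groups <- names(n_per_group)
  if (is.null(groups) || anyDuplicated(groups)) {
    stop("n_per_group must be a named vector with unique group labels")
  }
  if (any(n_per_group < 2)) {
    stop("every group must have at least 2 subjects")
  }
  missing_osc <- setdiff(groups, names(group_oscillators))
  if (length(missing_osc)) {
    stop(sprintf("no oscillator specified for group(s): %s",
                 paste(missing_osc, collapse = ", ")))
  }
  if (any(female_prop[groups] < 0 | female_prop[groups] > 1, na.rm = TRUE)) {
    stop("female_prop must be in [0, 1]")
  }
  structure(list(n_per_group = n_per_group,
                 group_oscillators = group_oscillators, noise = noise,
                 age_mean = age_mean, age_sd = age_sd,
                 female_prop = female_prop,
                 aed_mean = aed_mean, aed_sd = aed_sd, fe_prop = fe_prop,
                 gsc_count_mu = gsc_count_mu, gsc_count_size = gsc_count_size,
                 psc_count_mu = psc_count_mu, psc_count_size = psc_count_size,
                 subject_peak_sd = subject_peak_sd,
                 subject_amp_sdlog = subject_amp_sdlog,
                 duration = duration, fs = fs, montage = montage,
                 seed = seed),
            class = "cohort_design")
}

# truncated negative binomial draw: good-control counts are < 4 by definition
.rnbinom_below <- function(n, mu, size, upper) {
  x <- stats::rnbinom(n, mu = mu, size = size)
  for (i in seq_len(50)) {
    bad <- x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnbinom(sum(bad), mu = mu, size = size)
  }
  pmin(x, upper)
}

#' Generate a synthetic EEG cohort
#'
#' Draws one covariate record and one resting EEG segment per subject
#' according to a [cohort_design()]. Seizure-control labels are consistent
#' with the dichotomization rule (poor control iff at least four seizures in
#' the previous 12 months); healthy subjects carry zero AED load, no
#' syndrome and no seizure-control label.
#'
#' @param design A [cohort_design()].
#' @return A list with `table` (a `cohort_table` data frame: subject_id,
#'   group, syndrome, seizure_control, age, gender, aed_load,
#'   seizure_count_12m) and `segments` (named list of [eeg_segment()], one
#'   per subject).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- names(design$n_per_group)
  n_total <- sum(design$n_per_group)

  tab <- with_seed(design$seed, {
    rows <- vector("list", n_total)
    osc_jitter <- matrix(NA_real_, n_total, 2)   # peak offset, log-amp factor
    i <- 0L
    for (g in groups) {
      ng <- design$n_per_group[[g]]
      healthy <- identical(g, "HS")
      for (s in seq_len(ng)) {
        i <- i + 1L
        age <- round(stats::rnorm(1, design$age_mean[[g]], design$age_sd[[g]]))
        age <- max(18, age)
        gender <- if (stats::runif(1) < design$female_prop[[g]]) "F" else "M"
        if (healthy) {
          syndrome <- "none"; control <- "none"; aed <- 0; count <- 0L
        } else {
          syndrome <- if (stats::runif(1) < design$fe_prop[[g]]) "FE" else "IGE"
          m <- design$aed_mean[[g]]; sdv <- design$aed_sd[[g]]
          aed <- round(stats::rgamma(1, shape = (m / sdv)^2,
                                     rate = m / sdv^2), 2)
          count <- if (identical(g, "GSC")) {
            .rnbinom_below(1, design$gsc_count_mu, design$gsc_count_size, 3L)
          } else {
            4L + stats::rnbinom(1, mu = design$psc_count_mu,
                                size = design$psc_count_size)
          }
          control <- if (count >= 4) "PSC" else "GSC"
        }
        osc_jitter[i, ] <- c(stats::rnorm(1, 0, design$subject_peak_sd),
                             stats::rnorm(1, 0, design$subject_amp_sdlog))
        rows[[i]] <- data.frame(
          subject_id = sprintf("S%03d", i),
          group = if (healthy) "HS" else "patient",
          cohort_group = g,
          syndrome = syndrome, seizure_control = control,
          age = age, gender = gender, aed_load = aed,
          seizure_count_12m = as.integer(count),
          stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, rows), jitter = osc_jitter)
  })

  table <- tab$table
  class(table) <- c("cohort_table", "data.frame")
  segments <- vector("list", n_total)
  names(segments) <- table$subject_id
  for (i in seq_len(n_total)) {
    g <- table$cohort_group[i]
    base <- design$group_oscillators[[g]]
    peak <- min(19.5, max(2.5, base$peak_freq + tab$jitter[i, 1]))
    osc <- oscillator_spec(peak, base$bandwidth,
                           base$amplitude * exp(tab$jitter[i, 2]),
                           base$anterior_spread)
    segments[[i]] <- generate_segment(osc, design$noise, design$montage,
                                      duration = design$duration,
                                      fs = design$fs,
                                      seed = child_seed(design$seed, i))
  }
  list(table = table, segments = segments)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Synthetic cohort table: %d subjects\n", nrow(x)))
  print(table(x$cohort_group))
  NextMethod()
}
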