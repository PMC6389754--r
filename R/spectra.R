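#' Re-reference a segment to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that at each sample the channel mean is zero.
#'
#' @param seg An [eeg_segment()] with at least two channels.
#' @return The re-referenced [eeg_segment()].
#' @export
rereference_common_average <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (nrow(seg$data) < 2) {
    stop("common-average reference needs at least 2 channels")
  }
  seg$data <- sweep(seg$data, 2, colMeans(seg$data))
  seg
}

#' Cut a segment into overlapping epochs
#'
#' @param seg An [eeg_segment()].
#' @param epoch_len Epoch length in seconds; `epoch_len * fs` must be an
#'   integer.
#' @param overlap Fractional overlap in `[0, 1)`; the hop between epoch
#'   starts is `round((1 - overlap) * epoch_len * fs)` samples (>= 1).
#' @return List of channels x samples matrices, one per epoch; the epoch
#'   count is `floor((n_samples - L) / step) + 1`.
#' @export
epoch_segment <- function(seg, epoch_len = 1, overlap = 0.9) {
  stopifnot(inherits(seg, "eeg_segment"))
  stop_if_not_scalar_number(overlap, "overlap", 0, 1)
  if (overlap >= 1) stop("overlap must be < 1")
  L <- epoch_len * seg$fs
  if (abs(L - round(L)) > 1e-9 || L < 1) {
    stop("epoch_len x fs must be a positive integer")
  }
  L <- as.integer(round(L))
  n <- ncol(seg$data)
  if (n < L) stop("segment is shorter than one epoch")
  step <- max(1L, as.integer(round((1 - overlap) * L)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  lapply(starts, function(s) seg$data[, s:(s + L - 1L), drop = FALSE])
}

# periodic Hann taper (w[n] = 0.5 - 0.5 cos(2 pi n / N), n = 0..N-1)
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)

#' Per-channel normalized power spectrum
#'
#' Cuts the (re-referenced) segment into 1-s epochs with 90% overlap, demeans
#' each epoch per channel, applies a periodic Hann taper, zero-pads to
#' `pad_factor` times the epoch length, computes the FFT, averages the
#' squared modulus over epochs, extracts the bins at the integer frequencies
#' `freqs` (2..20 Hz by default) and normalizes each channel by its summed
#' power over those bins.
#'
#' @param seg An [eeg_segment()] (re-reference it first for the standard
#'   pipeline).
#' @param pad_factor Integer zero-padding factor >= 1 (default 2, i.e. 1-s
#'   epochs padded to 2 s, giving 0.5 Hz native resolution).
#' @param epoch_len,overlap Passed to [epoch_segment()].
#' @param freqs Integer frequencies (Hz) to extract.
#' @return An object of class `eeg_power_spectrum`: list with `power`
#'   (channels x frequencies matrix of relative power, rows summing to 1)
#'   and `freqs`.
#' @export
power_spectrum <- function(seg, pad_factor = 2, epoch_len = 1, overlap = 0.9,
                           freqs = 2:20) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (pad_factor < 1 || abs(pad_factor - round(pad_factor)) > 1e-9) {
    stop("pad_factor must be an integer >= 1")
  }
  pad_factor <- as.integer(round(pad_factor))
  if (max(freqs) > seg$fs / 2) {
    stop(sprintf("sampling rate %g Hz cannot resolve %g Hz", seg$fs, max(freqs)))
  }
  nch <- nrow(seg$data)
  L <- epoch_len * seg$fs
  if (abs(L - round(L)) > 1e-9 || L < 1) {
    stop("epoch_len x fs must be a positive integer")
  }
  L <- as.integer(round(L))
  n <- ncol(seg$data)
  if (n < L) stop("segment is shorter than one epoch")
  step <- max(1L, as.integer(round((1 - overlap) * L)))
  starts <- seq.int(1L, n - L + 1L, by = step)
  ne <- length(starts)
  nfft <- pad_factor * L
  taper <- .hann(L)
  bin_hz <- seg$fs / nfft
  bins <- freqs / bin_hz + 1
  if (any(abs(bins - round(bins)) > 1e-9)) {
    stop("requested frequencies do not fall on FFT bins; adjust pad_factor")
  }

  # The zero-padded DFT at bin f equals sum_n x[n] exp(-2i pi f n / fs) over
  # the unpadded samples, so the requested bins are evaluated directly with a
  # (freqs x L) DFT matrix applied to all tapered epochs at once.
  S <- outer(0:(L - 1L), starts, "+")                # L x ne sample indices
  X <- matrix(t(seg$data)[as.vector(S), , drop = FALSE], nrow = L)
  X <- (X - rep(colMeans(X), each = L)) * taper      # demean + taper per column
  ang <- -2 * pi * outer(freqs, 0:(L - 1L)) / seg$fs
  pw <- (cos(ang) %*% X)^2 + (sin(ang) %*% X)^2      # squared modulus per bin
  # columns are epoch-within-channel blocks; average each channel's block
  power <- t(pw %*% kronecker(diag(nch), matrix(1 / ne, ne, 1)))
  tot <- rowSums(power)
  if (any(tot <= 0)) stop("zero total power in at least one channel")
  power <- power / tot
  dimnames(power) <- list(seg$labels, freqs)
  structure(list(power = power, freqs = freqs), class = "eeg_power_spectrum")
}

#' @export
print.eeg_power_spectrum <- function(x, ...) {
  cat(sprintf("Normalized power spectrum: %d channels, %d-%d Hz in %d bins\n",
              nrow(x$power), min(x$freqs), max(x$freqs), length(x$freqs)))
  invisible(x)
}

#' @export
plot.eeg_power_spectrum <- function(x, ...) {
  graphics::matplot(x$freqs, t(x$power), type = "l", lty = 1,
                    xlab = "frequency (Hz)", ylab = "relative power", ...)
  invisible(x)
}

.band_mean <- function(power, freqs, band) {
  cols <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(cols)) stop("band contains no spectral bins")
  rowMeans(power[, cols, drop = FALSE])
}

#' Alpha-power shift of a normalized spectrum
#'
#' The alpha-power shift is the ratio of mean relative power in the low-alpha
#' band (6-9 Hz, bins 6,7,8,9) over mean relative power in the high-alpha
#' band (10-11 Hz, bins 10,11), reported on a binary-log scale. Values above
#' 0 indicate slowing of the alpha rhythm. The global shift is computed from
#' the channel-averaged spectrum (spectra are averaged across channels first,
#' then the ratio is formed); the mean of the per-channel log2 ratios is
#' exposed as an alternative summary.
#'
#' @param ps An `eeg_power_spectrum` containing the 6..11 Hz bins.
#' @param low_band,high_band Inclusive band limits in Hz.
#' @return An object of class `alpha_shift_profile`: list with
#'   `per_channel` (named vector of per-channel log2 shifts), `global`
#'   (log2 shift of the channel-averaged spectrum),
#'   `mean_channel_shift` (mean of per-channel log2 shifts), and the bands.
#' @export
alpha_shift <- function(ps, low_band = c(6, 9), high_band = c(10, 11)) {
  stopifnot(inherits(ps, "eeg_power_spectrum"))
  need <- seq(low_band[1], high_band[2])
  if (!all(need %in% ps$freqs)) {
    stop("spectrum must contain all integer frequencies from 6 to 11 Hz")
  }
  low <- .band_mean(ps$power, ps$freqs, low_band)
  high <- .band_mean(ps$power, ps$freqs, high_band)
  if (any(high <= 0)) stop("zero high-alpha power: shift ratio undefined")
  per_channel <- log2(low / high)
  gmean <- colMeans(ps$power)
  glow <- mean(gmean[ps$freqs >= low_band[1] & ps$freqs <= low_band[2]])
  ghigh <- mean(gmean[ps$freqs >= high_band[1] & ps$freqs <= high_band[2]])
  if (ghigh <= 0) stop("zero high-alpha power: shift ratio undefined")
  structure(list(per_channel = per_channel, global = log2(glow / ghigh),
                 mean_channel_shift = mean(per_channel),
                 low_band = low_band, high_band = high_band),
            class = "alpha_shift_profile")
}

#' @export
print.alpha_shift_profile <- function(x, ...) {
  cat(sprintf("Alpha-power shift (log2 %g-%g Hz over %g-%g Hz)\n",
              x$low_band[1], x$low_band[2], x$high_band[1], x$high_band[2]))
  cat(sprintf("  global: %.3f  (channel-mean: %.3f)\n",
              x$global, x$mean_channel_shift))
  invisible(x)
}

#' Individual alpha frequency
#'
#' Frequency of the maximum of the channel-averaged normalized spectrum
#' within a search band (default 6-13 Hz); ties are broken toward the lower
#' frequency.
#'
#' @param ps An `eeg_power_spectrum`.
#' @param search_band Two-element Hz interval within the spectrum's range.
#' @return Peak frequency in Hz.
#' @export
individual_alpha_frequency <- function(ps, search_band = c(6, 13)) {
  stopifnot(inherits(ps, "eeg_power_spectrum"))
  sel <- ps$freqs >= search_band[1] & ps$freqs <= search_band[2]
  if (!any(sel)) stop("search band contains no spectral bins")
  gmean <- colMeans(ps$power)[sel]
  fr <- ps$freqs[sel]
  fr[which.max(gmean)]          # which.max returns the first (lowest) maximum
}

#' Per-subject global alpha shifts for a cohort
#'
#' Convenience wrapper running the standard spectral pipeline
#' (common-average reference, Hann/overlap/zero-pad spectrum, alpha shift)
#' over a list of segments.
#'
#' @param segments Named list of [eeg_segment()].
#' @param pad_factor Zero-padding factor, see [power_spectrum()].
#' @return A list with `global` (named vector of global log2 shifts),
#'   `per_channel` (subjects x channels matrix) and `spectra` (list of
#'   `eeg_power_spectrum`).
#' @export
cohort_alpha_shifts <- function(segments, pad_factor = 2) {
  spectra <- lapply(segments, function(s) {
    power_spectrum(rereference_common_average(s), pad_factor = pad_factor)
  })
  shifts <- lapply(spectra, alpha_shift)
  per_channel <- do.call(rbind, lapply(shifts, `[[`, "per_channel"))
  rownames(per_channel) <- names(segments)
  list(global = vapply(shifts, `[[`, numeric(1), "global"),
       per_channel = per_channel, spectra = spectra)
}
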