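# Independent oracles and small fixture builders shared across tests.

# Naive per-epoch Hann/zero-pad spectrum: explicit loops and textbook DFT
# sums, kept deliberately independent of the package's vectorized path.
naive_power_spectrum <- function(seg, pad_factor = 2, epoch_len = 1,
                                 overlap = 0.9, freqs = 2:20) {
  eps <- epoch_segment(seg, epoch_len, overlap)
  L <- ncol(eps[[1]])
  nfft <- pad_factor * L
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
  acc <- matrix(0, nrow(seg$data), length(freqs))
  for (ep in eps) {
    for (ch in seq_len(nrow(ep))) {
      x <- ep[ch, ] - mean(ep[ch, ])
      x <- c(x * taper, rep(0, nfft - L))
      for (j in seq_along(freqs)) {
        bin <- freqs[j] * nfft / seg$fs          # integer bin index
        co <- sum(x * exp(-2i * pi * bin * (0:(nfft - 1)) / nfft))
        acc[ch, j] <- acc[ch, j] + Mod(co)^2
      }
    }
  }
  acc <- acc / length(eps)
  acc / rowSums(acc)
}

# textbook Hedges' g from first principles
textbook_hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  correction <- 1 - 3 / (4 * (na + nb) - 9)
  correction * (mean(a) - mean(b)) / sp
}

# random multichannel fixture segment
fixture_segment <- function(nch = 3, seconds = 2, fs = 256, seed = 1,
                            labels = montage_1020()$labels[seq_len(nch)]) {
  set.seed(seed)
  d <- matrix(rnorm(nch * seconds * fs), nch, seconds * fs)
  rownames(d) <- labels
  eeg_segment(d, fs = fs, labels = labels)
}

# small two-group map fixture: subjects x nodes matrix of gaussians
fixture_maps <- function(n1, n2, nodes, delta = 0, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm((n1 + n2) * nodes), n1 + n2, nodes)
  Y[seq_len(n1), ] <- Y[seq_len(n1), ] + delta
  list(Y = Y, groups = factor(rep(c("a", "b"), c(n1, n2))))
}
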