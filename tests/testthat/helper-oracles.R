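# Independent oracles used across the suite. These are written separately
# from (and more slowly than) the package code paths they check.

# Direct double-loop evaluation of the CWT integral: for every (scale,
# shift), (1/sqrt(a)) * sum_i f(t_i) * Conj(psi((t_i - b)/a)) * dt.
direct_cwt <- function(f, fs, scales, sigma = 1) {
  n <- length(f)
  out <- matrix(0i, length(scales), n)
  for (s in seq_along(scales)) {
    a <- scales[s]
    for (b0 in 0:(n - 1)) {
      acc <- 0i
      for (i in 0:(n - 1)) {
        tt <- (i - b0) / (fs * a)
        acc <- acc + f[i + 1] *
          Conj(exp(2i * pi * tt) * exp(-tt^2 / (2 * sigma^2)))
      }
      out[s, b0 + 1] <- acc / (sqrt(a) * fs)
    }
  }
  out
}

# Magnitude of the analytic signal (FFT Hilbert transform).
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  h[floor(n / 2) + 1] <- 1
  h[2:floor(n / 2)] <- 2
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Dominant nonzero-frequency DFT bin (in Hz) of a signal.
dominant_freq <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))[2:(n %/% 2)]
  which.max(p) * fs / n
}

# Simple spectral-peak + envelope rule classifier for the four synthetic
# rhythm morphologies; a fixture-sanity guard, not a shipped method.
rule_features <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  fr <- (1:(n %/% 2 - 1)) * fs / n
  pk <- which.max(sp)
  conc <- sum(sp[abs(fr - fr[pk]) <= 0.75]) / sum(sp)
  env <- hilbert_envelope(x)
  pe <- Mod(stats::fft(env - mean(env)))[2:(n %/% 2)]^2
  slow <- sum(pe[fr < 1.2]) / sum(pe)
  ac <- stats::acf(x, lag.max = fs / 2, plot = FALSE)$acf[-1]
  reg <- max(ac[round(fs / 8):round(fs / 2)])
  c(conc = conc, slow = slow, reg = reg)
}

rule_classify <- function(x, fs) {
  f <- rule_features(x, fs)
  if (f["conc"] > 0.75 && f["reg"] > 0.8) "C1"
  else if (f["slow"] < 0.06) "C4"
  else if (f["reg"] > 0.6) "C3"
  else "C2"
}

# Brute-force k nearest neighbours by full distance sort.
brute_knn <- function(x, k) {
  n <- nrow(x)
  t(sapply(seq_len(n), function(i) {
    d2 <- colSums((t(x) - x[i, ])^2)
    d2[i] <- Inf
    order(d2)[seq_len(k)]
  }))
}

# Brute-force one-vs-rest tallies from label vectors.
brute_metrics <- function(truth, pred, classes) {
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    data.frame(
      class = cl,
      precision = ifelse(tp + fp > 0, tp / (tp + fp), 0),
      recall = ifelse(tp + fn > 0, tp / (tp + fn), 0),
      specificity = ifelse(tn + fp > 0, tn / (tn + fp), 0)
    )
  }))
}

# Small synthetic scalogram dataset shared by training-path tests.
make_tiny_scalograms <- function(n_per_class = 15, size = 32, seed = 101) {
  frags <- generate_dataset(
    stats::setNames(rep(n_per_class, 4), shock_classes),
    synth_config(seed = seed)
  )
  fragments_to_scalograms(frags, size = size)
}
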