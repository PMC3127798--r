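# Independent brute-force oracles used to cross-check the vectorized
# implementations, plus small shared fixtures.  The oracles deliberately
# use naive elementwise loops so they share no code path with the package.

make_signal <- function(y, dt = 1, t0 = 0) {
  tibble::tibble(time = t0 + (seq_along(y) - 1) * dt, value = y)
}

random_spectrogram <- function(seed, n_bands = 8, n_frames = 8, dt = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(n_bands * n_frames), n_bands, n_frames)
  structure(
    list(X = X, f = (seq_len(n_bands) - 1) / (2 * max(n_bands - 1, 1) * dt),
         t = seq_len(n_frames) * 10,
         config = stft_config(), preprocessed = TRUE),
    class = "tfa_spectrogram"
  )
}

brute_mean_frequency <- function(spec) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(spec$X))) for (j in seq_len(ncol(spec$X))) {
    num <- num + spec$f[i] * spec$X[i, j]
    den <- den + spec$X[i, j]
  }
  num / den
}

brute_total_variation <- function(spec) {
  V <- numeric(nrow(spec$X))
  for (i in seq_len(nrow(spec$X))) {
    for (j in seq_len(ncol(spec$X) - 1)) {
      V[i] <- V[i] + abs(spec$X[i, j + 1] - spec$X[i, j])
    }
  }
  V
}

brute_symmetric_kl <- function(p, q, epsilon) {
  p <- p + epsilon; p <- p / sum(p)
  q <- q + epsilon; q <- q / sum(q)
  d <- 0
  for (i in seq_along(p)) {
    d <- d + p[i] * log(p[i] / q[i]) + q[i] * log(q[i] / p[i])
  }
  d
}

brute_ks <- function(p, q) {
  cp <- 0; cq <- 0; m <- 0
  for (i in seq_along(p)) {
    cp <- cp + p[i]; cq <- cq + q[i]
    m <- max(m, abs(cp - cq))
  }
  m
}

# Discrete first-order low-pass filter (time constant tau minutes).
smooth_first_order <- function(signal, tau) {
  dt <- signal$time[2] - signal$time[1]
  a <- dt / (tau + dt)
  y <- Reduce(function(acc, u) acc + a * (u - acc), signal$value,
              accumulate = TRUE)
  tibble::tibble(time = signal$time, value = y)
}
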