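# Short-time Fourier transform spectrograms and their preprocessing.

#' STFT configuration
#'
#' @param window_length Frame length in samples (Hamming window).
#' @param hop Hop between successive frames in samples; must satisfy
#'   `0 < hop <= window_length`.
#' @param threshold_db Dynamic-range threshold: power coefficients more
#'   than this many dB below the spectrogram maximum are zeroed during
#'   preprocessing.
#' @param scaling Either `"nm_uniform"` (divide every coefficient by the
#'   product of band and frame counts, `1/(N*M)`) or `"none"`.  All
#'   downstream statistics are invariant to any uniform scaling.
#' @return An `stft_config` object.
#' @export
stft_config <- function(window_length = 256L, hop = 128L,
                        threshold_db = 80, scaling = c("nm_uniform", "none")) {
  scaling <- match.arg(scaling)
  window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  if (hop <= 0 || hop > window_length) {
    rlang::abort("need 0 < hop <= window_length.", class = "tfanet_config_error")
  }
  if (threshold_db <= 0) {
    rlang::abort("`threshold_db` must be positive.", class = "tfanet_config_error")
  }
  structure(list(window_length = window_length, hop = hop,
                 threshold_db = threshold_db, scaling = scaling),
            class = "stft_config")
}

new_spectrogram <- function(X, f, t, config, preprocessed = FALSE) {
  structure(list(X = X, f = f, t = t, config = config,
                 preprocessed = preprocessed),
            class = "tfa_spectrogram")
}

#' @export
print.tfa_spectrogram <- function(x, ...) {
  cat("<tfa_spectrogram> ", nrow(x$X), " bands x ", ncol(x$X), " frames",
      if (x$preprocessed) " (preprocessed)", "\n", sep = "")
  cat("  f: 0 .. ", format(max(x$f), digits = 4), " cycles/min; t: ",
      format(x$t[1], digits = 4), " .. ", format(x$t[length(x$t)], digits = 4),
      " min\n", sep = "")
  invisible(x)
}

#' Compute the power spectrogram of a signal
#'
#' The signal is zero-meaned, split into frames of `window_length` samples
#' every `hop` samples, each frame is tapered with a Hamming window and
#' transformed with the DFT; coefficients are squared magnitudes (power).
#' `N = window_length/2 + 1` frequency bands (DC to Nyquist) and
#' `M = floor((L - window_length)/hop) + 1` frames result.
#'
#' @param signal A signal tibble on a uniform grid.
#' @param config An [stft_config()].
#' @return A `tfa_spectrogram` with matrix `X` (bands x frames), band
#'   center frequencies `f` (cycles/min) and frame center times `t` (min).
#' @export
compute_spectrogram <- function(signal, config = stft_config()) {
  signal <- as_signal(signal)
  wl <- config$window_length
  hop <- config$hop
  L <- nrow(signal)
  if (wl > L) {
    rlang::abort("window_length exceeds signal length.",
                 class = "tfanet_spectrogram_error")
  }
  dt <- signal_dt(signal)
  y <- signal$value - mean(signal$value)
  M <- (L - wl) %/% hop + 1L
  starts <- (seq_len(M) - 1L) * hop
  frames <- vapply(starts, function(s) y[(s + 1L):(s + wl)], numeric(wl))
  w <- signal::hamming(wl)
  F <- stats::mvfft(frames * w)
  N <- wl %/% 2L + 1L
  X <- Mod(F[seq_len(N), , drop = FALSE])^2
  f <- (seq_len(N) - 1L) / (wl * dt)
  t <- signal$time[1] + (starts + (wl - 1) / 2) * dt
  new_spectrogram(X, f, t, config)
}

#' Threshold and rescale a spectrogram
#'
#' Coefficients more than `threshold_db` dB below the maximum (on the
#' power scale, `10*log10`) are set to zero; remaining coefficients are
#' divided by `N*M` when `scaling = "nm_uniform"`.  The operation is
#' idempotent: preprocessed spectrograms pass through unchanged, and an
#' all-zero spectrogram is returned as is.
#'
#' @param spec A `tfa_spectrogram`.
#' @param config An [stft_config()]; defaults to the one the spectrogram
#'   was built with.
#' @return The preprocessed `tfa_spectrogram`.
#' @export
preprocess_spectrogram <- function(spec, config = NULL) {
  stopifnot(inherits(spec, "tfa_spectrogram"))
  if (isTRUE(spec$preprocessed)) return(spec)
  if (is.null(config)) config <- spec$config
  X <- spec$X
  mx <- max(X)
  if (mx > 0) {
    X[10 * log10(X / mx) < -config$threshold_db] <- 0
    if (config$scaling == "nm_uniform") X <- X / (nrow(X) * ncol(X))
  }
  new_spectrogram(X, spec$f, spec$t, config, preprocessed = TRUE)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spectrogram into a long tibble
#'
#' @param x A `tfa_spectrogram`.
#' @param ... Unused.
#' @return A tibble with columns `frequency`, `time`, `power`.
#' @export
tidy.tfa_spectrogram <- function(x, ...) {
  tibble::tibble(
    frequency = rep(x$f, times = ncol(x$X)),
    time = rep(x$t, each = nrow(x$X)),
    power = as.vector(x$X)
  )
}
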