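# Noise-suppression and responsiveness statistics computed from paired
# input/output spectrograms.
#
# Conventions: band sums S_i aggregate power over time within band i; the
# mean frequency is the S-weighted mean of the band frequencies; the
# per-band total variation V_i sums absolute successive differences along
# time.  Distribution comparisons use unit-sum normalizations of S and V.
# Kullback-Leibler divergences are symmetrized as the plain sum of the two
# directed divergences (no halving) after additive-epsilon smoothing;
# inverse divergences are floored at epsilon before inversion, so an
# identical pair attains the cap 1/epsilon.

check_same_axes <- function(a, b) {
  if (!identical(dim(a$X), dim(b$X)) ||
      max(abs(a$f - b$f)) > 1e-12 * max(a$f)) {
    rlang::abort("spectrograms must share frequency/time axes.",
                 class = "tfanet_stat_error")
  }
}

#' Per-band power sums of a spectrogram
#' @param spec A `tfa_spectrogram`.
#' @return Vector `S` with one nonnegative entry per frequency band.
#' @export
band_sums <- function(spec) {
  stopifnot(inherits(spec, "tfa_spectrogram"))
  rowSums(spec$X)
}

#' Per-band total variation of a spectrogram
#'
#' For each frequency band the sum of absolute differences between
#' consecutive frames, `V_i = sum_j |X[i, j+1] - X[i, j]|`.
#'
#' @param spec A `tfa_spectrogram` with at least two frames.
#' @return Vector `V` with one nonnegative entry per band.
#' @export
band_total_variation <- function(spec) {
  stopifnot(inherits(spec, "tfa_spectrogram"))
  M <- ncol(spec$X)
  if (M < 2) {
    rlang::abort("total variation needs at least 2 frames.",
                 class = "tfanet_stat_error")
  }
  rowSums(abs(spec$X[, -1, drop = FALSE] - spec$X[, -M, drop = FALSE]))
}

#' Mean frequency of a spectrogram
#'
#' The band-power-weighted mean of the band center frequencies,
#' `mu = sum_i f_i S_i / sum_i S_i`.
#'
#' @param spec A `tfa_spectrogram` with at least one nonzero coefficient.
#' @return Mean frequency in cycles/min.
#' @export
mean_frequency <- function(spec) {
  S <- band_sums(spec)
  tot <- sum(S)
  if (tot <= 0) {
    rlang::abort("degenerate (all-zero) spectrogram has no mean frequency.",
                 class = "tfanet_degenerate_error")
  }
  sum(spec$f * S) / tot
}

#' Noise suppression xi
#'
#' The ratio of input to output spectrogram mean frequencies,
#' `xi = mu_in / mu_out`.  Values above 1 indicate the response spectrum
#' is shifted toward lower frequencies than the stimulus (low-pass,
#' fluctuation-filtering behavior); values below 1 indicate the response
#' contains higher harmonics than the input.
#'
#' @param spec_in,spec_out Input and output `tfa_spectrogram`s on the same
#'   axes.
#' @return The dimensionless ratio `xi`.
#' @export
noise_suppression <- function(spec_in, spec_out) {
  check_same_axes(spec_in, spec_out)
  mean_frequency(spec_in) / mean_frequency(spec_out)
}

unit_norm <- function(v, what) {
  tot <- sum(v)
  if (tot <= 0) {
    rlang::abort(paste0("zero-sum ", what, " distribution."),
                 class = "tfanet_degenerate_error")
  }
  v / tot
}

smooth_renorm <- function(p, epsilon) {
  p <- p + epsilon
  p / sum(p)
}

# Symmetric Kullback-Leibler divergence (sum of both directions) between
# unit-sum vectors after additive smoothing.
symmetric_kl <- function(p, q, epsilon) {
  p <- smooth_renorm(p, epsilon)
  q <- smooth_renorm(q, epsilon)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

# Kolmogorov-Smirnov distance between unit-sum vectors over the ordered
# frequency bands: the sup of absolute cumulative differences.
ks_distance <- function(p, q) {
  max(abs(cumsum(p) - cumsum(q)))
}

#' Responsiveness rho
#'
#' The inverse symmetric Kullback-Leibler divergence between the unit-sum
#' normalized per-band total-variation distributions of input and output.
#' Both distributions are smoothed by adding `epsilon` and renormalizing;
#' the divergence is floored at `epsilon` before inversion, capping rho at
#' `1/epsilon` for identical distributions.  Greater rho means the output
#' tracks the temporal detail of the input more faithfully.
#'
#' @param spec_in,spec_out Input and output `tfa_spectrogram`s on the same
#'   axes.
#' @param epsilon Smoothing constant and divergence floor.
#' @return The dimensionless responsiveness `rho`.
#' @export
responsiveness <- function(spec_in, spec_out, epsilon = 1e-12) {
  check_same_axes(spec_in, spec_out)
  p <- unit_norm(band_total_variation(spec_in), "input total-variation")
  q <- unit_norm(band_total_variation(spec_out), "output total-variation")
  D <- symmetric_kl(p, q, epsilon)
  1 / max(D, epsilon)
}

#' Alternative noise-suppression and responsiveness statistics
#'
#' `xi1` is the symmetric Kullback-Leibler divergence between the
#' normalized band-sum distributions of input and output; `xi2` is the
#' Kolmogorov-Smirnov distance between the same distributions; `rho1` is
#' the inverse Kolmogorov-Smirnov distance between the normalized
#' total-variation distributions (floored at `epsilon` before inversion).
#'
#' @inheritParams responsiveness
#' @return A named list with `xi1`, `xi2`, `rho1`.
#' @export
alternative_statistics <- function(spec_in, spec_out, epsilon = 1e-12) {
  check_same_axes(spec_in, spec_out)
  s_in <- unit_norm(band_sums(spec_in), "input band-sum")
  s_out <- unit_norm(band_sums(spec_out), "output band-sum")
  v_in <- unit_norm(band_total_variation(spec_in), "input total-variation")
  v_out <- unit_norm(band_total_variation(spec_out), "output total-variation")
  list(
    xi1 = symmetric_kl(s_in, s_out, epsilon),
    xi2 = ks_distance(s_in, s_out),
    rho1 = 1 / max(ks_distance(v_in, v_out), epsilon)
  )
}

#' Full time-frequency comparison of a stimulus/response pair
#'
#' The single entry point composing the TFA pipeline on both signals:
#' zero-meaning, spectrogram computation, thresholding/rescaling, then all
#' five statistics plus the two mean frequencies.
#'
#' @param stimulus,response Signal tibbles on the same time grid.
#' @param stft An [stft_config()].
#' @param epsilon Smoothing constant for the divergence-based statistics.
#' @return A one-row tibble with columns `xi`, `rho`, `xi1`, `xi2`,
#'   `rho1`, `mu_in`, `mu_out`, `rho_capped`, `rho1_capped`.
#' @export
analyze_pair <- function(stimulus, response, stft = stft_config(),
                         epsilon = 1e-12) {
  stimulus <- as_signal(stimulus)
  response <- as_signal(response)
  if (nrow(stimulus) != nrow(response) ||
      max(abs(stimulus$time - response$time)) > 1e-9 * signal_dt(stimulus)) {
    rlang::abort("stimulus and response must share the time grid.",
                 class = "tfanet_stat_error")
  }
  sp_in <- preprocess_spectrogram(compute_spectrogram(zero_mean(stimulus), stft))
  sp_out <- preprocess_spectrogram(compute_spectrogram(zero_mean(response), stft))
  mu_in <- mean_frequency(sp_in)
  mu_out <- mean_frequency(sp_out)
  rho <- responsiveness(sp_in, sp_out, epsilon)
  alt <- alternative_statistics(sp_in, sp_out, epsilon)
  cap <- 1 / epsilon
  tibble::tibble(
    xi = mu_in / mu_out, rho = rho,
    xi1 = alt$xi1, xi2 = alt$xi2, rho1 = alt$rho1,
    mu_in = mu_in, mu_out = mu_out,
    rho_capped = rho >= cap, rho1_capped = alt$rho1 >= cap
  )
}
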