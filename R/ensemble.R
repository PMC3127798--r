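# Ensemble runs: many stimuli through one model, one statistics row each.

#' Normalized-derivative distance between stimulus and response
#'
#' Both signals are differentiated, each derivative vector is divided by
#' its own Euclidean norm (a zero-norm derivative maps to the zero
#' vector), and the Euclidean distance between the two unit vectors is
#' returned.  Identical signals give 0; uncorrelated derivatives give
#' sqrt(2); sign-inverted responses give 2 (antiparallel unit vectors).
#' The non-physiological screen (see [sweep_loop_strengths()]) flags
#' distances above 1.5, clearly beyond the near-orthogonal floor that
#' noise-dominated input derivatives impose even on faithful low-pass
#' responses.
#'
#' @param stimulus,response Signal tibbles on the same grid.
#' @return A scalar distance in `[0, 2]`.
#' @export
physiological_distance <- function(stimulus, response) {
  d_in <- signal_derivative(stimulus)$value
  d_out <- signal_derivative(response)$value
  nrm <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) rep(0, length(v)) else v / n
  }
  sqrt(sum((nrm(d_in) - nrm(d_out))^2))
}

#' Run a stimulus ensemble through a network model
#'
#' Each stimulus is rescaled to the model's physiological input maximum,
#' simulated from the basal steady state, and compared to its response
#' with [analyze_pair()].  Failed integrations are recorded in the
#' `error` column rather than dropped; more than 10% failures abort the
#' run with an ensemble-quality error.
#'
#' @param model A `network_model`.
#' @param stimuli An ensemble tibble from [generate_ensemble()] (columns
#'   `stimulus_id`, `family`, `signal`) or a bare list of signal tibbles.
#' @param stft An [stft_config()].
#' @param settings A [simulation_settings()].
#' @param epsilon Smoothing constant passed to [analyze_pair()].
#' @param rescale Rescale stimuli to `model$max_stimulus` (default TRUE).
#' @return A `tfa_ensemble` tibble with one row per stimulus: the five
#'   statistics, mean frequencies, cap flags, response `amplitude`
#'   (max - min), `physio_distance`, and `error`.  The model name is
#'   attached as attribute `model`.
#' @export
run_ensemble <- function(model, stimuli, stft = stft_config(),
                         settings = simulation_settings(),
                         epsilon = 1e-12, rescale = TRUE) {
  if (is.data.frame(stimuli)) {
    ids <- stimuli$stimulus_id
    fams <- stimuli$family
    sigs <- stimuli$signal
  } else {
    sigs <- stimuli
    ids <- seq_along(sigs)
    fams <- vapply(sigs, function(s) {
      f <- attr(s, "family", exact = TRUE)
      if (is.null(f)) NA_character_ else f
    }, character(1))
  }
  n <- length(sigs)
  empty_row <- tibble::tibble(
    xi = NA_real_, rho = NA_real_, xi1 = NA_real_, xi2 = NA_real_,
    rho1 = NA_real_, mu_in = NA_real_, mu_out = NA_real_,
    rho_capped = NA, rho1_capped = NA, amplitude = NA_real_,
    physio_distance = NA_real_, error = NA_character_
  )
  if (n == 0) {
    out <- tibble::tibble(stimulus_id = integer(), family = character())
    out <- dplyr::bind_cols(out, empty_row[0, ])
    return(structure(out, class = c("tfa_ensemble", class(out)),
                     model = model$name))
  }
  y0 <- if (model$kind == "identity") NULL else basal_state(model, settings)
  rows <- purrr::map(sigs, function(sig) {
    sig <- as_signal(sig)
    stim <- if (rescale && model$kind != "identity") {
      scale_amplitude(sig, model$max_stimulus)
    } else {
      sig
    }
    tryCatch({
      resp <- simulate_response(model, stim, settings, y0 = y0)
      stats <- analyze_pair(stim, resp, stft, epsilon)
      stats$amplitude <- max(resp$value) - min(resp$value)
      stats$physio_distance <- physiological_distance(stim, resp)
      stats$error <- NA_character_
      stats
    }, error = function(e) {
      r <- empty_row
      r$error <- conditionMessage(e)
      r
    })
  })
  out <- dplyr::bind_cols(
    tibble::tibble(stimulus_id = ids, family = fams),
    dplyr::bind_rows(rows)
  )
  n_failed <- sum(!is.na(out$error))
  if (n_failed > 0.1 * n) {
    rlang::abort(
      sprintf("%d of %d integrations failed for %s.", n_failed, n, model$name),
      class = "tfanet_ensemble_quality_error"
    )
  }
  structure(out, class = c("tfa_ensemble", class(out)), model = model$name)
}

#' Summarize ensemble statistics
#'
#' Mean, sample standard deviation and coefficient of variation of xi and
#' rho, pooled and optionally per stimulus family.  Capped rho values are
#' censoring artifacts of the inverse-divergence floor and are excluded
#' from the rho moments; their count is reported separately.
#'
#' @param result A `tfa_ensemble` from [run_ensemble()].
#' @param by_family Also emit one row per stimulus family.
#' @return A tibble with columns `family` (`"all"` for the pooled row),
#'   `n`, `xi_mean`, `xi_sd`, `xi_cv`, `rho_mean`, `rho_sd`, `rho_cv`,
#'   `n_rho_capped`, `n_failed`.
#' @export
summarize_ensemble <- function(result, by_family = FALSE) {
  if (nrow(result) == 0) {
    rlang::abort("cannot summarize an empty ensemble.",
                 class = "tfanet_stat_error")
  }
  one <- function(df, label) {
    ok <- is.na(df$error)
    rho_ok <- ok & !df$rho_capped
    xi <- df$xi[ok]
    rho <- df$rho[rho_ok]
    msd <- function(v) {
      if (length(v) == 0) c(NA_real_, NA_real_)
      else c(mean(v), stats::sd(v))
    }
    x <- msd(xi); r <- msd(rho)
    tibble::tibble(
      family = label, n = nrow(df),
      xi_mean = x[1], xi_sd = x[2], xi_cv = x[2] / x[1],
      rho_mean = r[1], rho_sd = r[2], rho_cv = r[2] / r[1],
      n_rho_capped = sum(df$rho_capped[ok]),
      n_failed = sum(!ok)
    )
  }
  out <- one(result, "all")
  if (by_family) {
    fams <- unique(result$family[!is.na(result$family)])
    out <- dplyr::bind_rows(
      out,
      purrr::map(fams, function(f) one(result[result$family %in% f, ], f))
    )
  }
  out
}

#' @rdname summarize_ensemble
#' @param x A `tfa_ensemble`.
#' @param ... Unused.
#' @export
glance.tfa_ensemble <- function(x, ...) summarize_ensemble(x)

#' Bivariate Gaussian kernel density of the (xi, rho) cloud
#'
#' Evaluates a bivariate Gaussian kernel density estimate on a rectangular
#' grid covering the data range (with a margin of one bandwidth), used for
#' the responsiveness/noise-suppression contour "clouds".
#'
#' @param data A data frame of per-stimulus statistics.
#' @param x,y Column names of the two coordinates.
#' @param n Grid resolution per axis.
#' @param bandwidth Optional length-2 bandwidth; defaults to the
#'   normal-reference rule.
#' @return A tibble with columns `x`, `y`, `density`.
#' @export
kde_density <- function(data, x = "xi", y = "rho", n = 50, bandwidth = NULL) {
  xs <- data[[x]]
  ys <- data[[y]]
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 2) {
    rlang::abort("need at least 2 finite points for a density.",
                 class = "tfanet_stat_error")
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    rlang::abort("degenerate point cloud: zero spread in x or y.",
                 class = "tfanet_degenerate_error")
  }
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(xs), MASS::bandwidth.nrd(ys))
  }
  lims <- c(range(xs) + c(-1, 1) * bandwidth[1],
            range(ys) + c(-1, 1) * bandwidth[2])
  k <- MASS::kde2d(xs, ys, h = bandwidth, n = n, lims = lims)
  tibble::tibble(
    x = rep(k$x, times = length(k$y)),
    y = rep(k$y, each = length(k$x)),
    density = as.vector(k$z)
  )
}
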