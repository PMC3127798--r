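# Loop-strength parameter sweeps: the heat-map "portraits".

#' Log-spaced loop-strength grid
#'
#' @param from,to Grid end points (multipliers; wild type is 1).
#' @param length.out Number of grid points.
#' @return A numeric vector of log-spaced multipliers.
#' @export
loop_strength_grid <- function(from = 1e-2, to = 1e2, length.out = 51) {
  lg <- seq(log(from), log(to), length.out = length.out)
  g <- exp(lg)
  g[abs(lg) < 1e-12] <- 1  # keep the wild-type multiplier exact
  g
}

#' Sweep loop strengths over a stimulus ensemble
#'
#' Builds a model at every `(s_pos, s_neg)` grid point, runs the identical
#' stimulus ensemble at each point (matched seeds, so grid cells are
#' directly comparable), and records ensemble means of noise suppression,
#' responsiveness, response amplitude and normalized-derivative distance.
#' Cells whose ensembles fail the integration-quality gate are marked
#' `missing` rather than zero.  Cells whose mean derivative distance
#' exceeds 1.5 -- clearly beyond the near-orthogonal distance floor of
#' noisy derivatives, toward the reversed-direction value 2 -- are flagged
#' `non_physiological` but still reported.
#'
#' @param model_builder A function `(s_pos, s_neg) -> network_model`, e.g.
#'   `ole_model` or `gal_model`.
#' @param s_pos_grid,s_neg_grid Multiplier grids (see
#'   [loop_strength_grid()]).
#' @param stimuli An ensemble tibble from [generate_ensemble()].
#' @param stft An [stft_config()].
#' @param settings A [simulation_settings()].
#' @param by_family Also emit per-family rows (`family != "all"`).
#' @param epsilon Smoothing constant for the divergence statistics.
#' @return A `tfa_sweep` tibble with one row per grid cell (and family):
#'   `s_pos`, `s_neg`, `family`, `n`, `xi_mean`, `rho_mean`,
#'   `amplitude_mean`, `physio_mean`, `n_rho_capped`, `n_failed`,
#'   `missing`, `non_physiological`.
#' @export
sweep_loop_strengths <- function(model_builder, s_pos_grid, s_neg_grid,
                                 stimuli, stft = stft_config(),
                                 settings = simulation_settings(),
                                 by_family = FALSE, epsilon = 1e-12) {
  grid <- tidyr::expand_grid(s_pos = s_pos_grid, s_neg = s_neg_grid)
  cell_summary <- function(ens, fam_label, sub) {
    amp_ok <- is.na(sub$error)
    s <- summarize_ensemble(sub)
    tibble::tibble(
      family = fam_label, n = nrow(sub),
      xi_mean = s$xi_mean, rho_mean = s$rho_mean,
      amplitude_mean = mean(sub$amplitude[amp_ok]),
      physio_mean = mean(sub$physio_distance[amp_ok]),
      n_rho_capped = s$n_rho_capped, n_failed = s$n_failed,
      missing = FALSE
    )
  }
  rows <- purrr::pmap(grid, function(s_pos, s_neg) {
    model <- model_builder(s_pos, s_neg)
    res <- tryCatch(
      run_ensemble(model, stimuli, stft, settings, epsilon = epsilon),
      tfanet_ensemble_quality_error = function(e) NULL,
      tfanet_integration_error = function(e) NULL
    )
    fams <- if (by_family) c("all", unique(stimuli$family)) else "all"
    cells <- purrr::map(fams, function(f) {
      if (is.null(res)) {
        return(tibble::tibble(
          family = f, n = nrow(stimuli), xi_mean = NA_real_,
          rho_mean = NA_real_, amplitude_mean = NA_real_,
          physio_mean = NA_real_, n_rho_capped = NA_integer_,
          n_failed = NA_integer_, missing = TRUE
        ))
      }
      sub <- if (f == "all") res else res[res$family %in% f, ]
      cell_summary(res, f, sub)
    })
    dplyr::bind_cols(tibble::tibble(s_pos = s_pos, s_neg = s_neg),
                     dplyr::bind_rows(cells))
  })
  out <- dplyr::bind_rows(rows)
  out$non_physiological <- !out$missing & out$physio_mean > 1.5
  structure(out, class = c("tfa_sweep", class(out)),
            s_pos_grid = s_pos_grid, s_neg_grid = s_neg_grid)
}

#' Wild-type tolerance masks for a sweep
#'
#' Marks the grid cells whose ensemble-mean statistics lie within a
#' relative tolerance of the wild-type values: `|value - wt| / wt <=
#' tolerance_frac`, separately for xi and rho.
#'
#' @param sweep A `tfa_sweep` (rows with `family == "all"` are used).
#' @param wt_xi,wt_rho Finite, nonzero wild-type reference values.
#' @param tolerance_frac Relative tolerance (default 0.15, i.e. +/-15%).
#' @return The sweep rows with added logical columns `xi_within_tol` and
#'   `rho_within_tol`.
#' @export
wt_tolerance_mask <- function(sweep, wt_xi, wt_rho, tolerance_frac = 0.15) {
  if (!is.finite(wt_xi) || !is.finite(wt_rho) || wt_xi == 0 || wt_rho == 0) {
    rlang::abort("wild-type reference values must be finite and nonzero.",
                 class = "tfanet_stat_error")
  }
  out <- sweep[sweep$family == "all", ]
  out$xi_within_tol <- abs(out$xi_mean - wt_xi) / abs(wt_xi) <= tolerance_frac
  out$rho_within_tol <- abs(out$rho_mean - wt_rho) / abs(wt_rho) <= tolerance_frac
  out
}

#' @export
glance.tfa_sweep <- function(x, ...) {
  all_rows <- x[x$family == "all", ]
  tibble::tibble(
    n_cells = nrow(all_rows),
    n_missing = sum(all_rows$missing),
    n_non_physiological = sum(all_rows$non_physiological, na.rm = TRUE),
    xi_min = min(all_rows$xi_mean, na.rm = TRUE),
    xi_max = max(all_rows$xi_mean, na.rm = TRUE),
    rho_min = min(all_rows$rho_mean, na.rm = TRUE),
    rho_max = max(all_rows$rho_mean, na.rm = TRUE)
  )
}
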