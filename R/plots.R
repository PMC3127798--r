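# Figures and their machine-readable twins.  Every render_* call writes
# both an image and delimited text files carrying the same numbers, so
# downstream checks can assert on data rather than pixels.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrogram
#'
#' Frequency on the vertical axis, time on the horizontal, fill mapped to
#' log10 power (zero coefficients are shown at the floor of the scale).
#'
#' @param object A `tfa_spectrogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfa_spectrogram <- function(object, ...) {
  df <- tidy(object)
  pos <- df$power[df$power > 0]
  floor_val <- if (length(pos)) min(pos) else 1e-300
  df$log_power <- log10(pmax(df$power, floor_val))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                   fill = .data$log_power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (min)", y = "frequency (cycles/min)") +
    ggplot2::theme_minimal()
}

#' Responsiveness/noise-suppression cloud of an ensemble
#'
#' Scatter of per-stimulus (xi, rho) values with kernel-density contours;
#' degenerate clouds (too few or zero-spread points) fall back to a
#' scatter-only plot with a warning.
#'
#' @param object A `tfa_ensemble`.
#' @param by_family Color points by stimulus family.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfa_ensemble <- function(object, by_family = FALSE, ...) {
  df <- object[is.na(object$error) & !object$rho_capped, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$xi, y = .data$rho))
  p <- if (by_family) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$family),
                            alpha = 0.6, size = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  }
  dens <- tryCatch(kde_density(df), error = function(e) NULL)
  if (is.null(dens)) {
    rlang::warn("degenerate (xi, rho) cloud: rendering scatter only.")
  } else {
    p <- p + ggplot2::geom_contour(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$y, z = .data$density),
      color = "grey30", linewidth = 0.3
    )
  }
  p + ggplot2::labs(x = expression(xi ~ "(noise suppression)"),
                    y = expression(rho ~ "(responsiveness)"),
                    title = attr(object, "model", exact = TRUE)) +
    ggplot2::theme_minimal()
}

#' Heat map of a sweep field
#'
#' Log-scaled multiplier axes with wild-type cross-hair lines at
#' multiplier 1; missing cells are drawn in grey.
#'
#' @param object A `tfa_sweep`.
#' @param field One of `"xi"`, `"rho"`, `"amplitude"`, `"physio"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfa_sweep <- function(object, field = c("xi", "rho", "amplitude",
                                                 "physio"), ...) {
  field <- match.arg(field)
  col <- paste0(field, "_mean")
  df <- object[object$family == "all", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_pos, y = .data$s_neg,
                                   fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = field, na.value = "grey70") +
    ggplot2::geom_vline(xintercept = 1, color = "white", linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 1, color = "white", linewidth = 0.4) +
    ggplot2::labs(x = "positive loop strength", y = "negative loop strength") +
    ggplot2::theme_minimal()
}

# Write a numeric matrix as a TSV together with a companion axis file.
write_matrix_txt <- function(X, path, row_axis, col_axis,
                             row_name = "row", col_name = "col") {
  utils::write.table(X, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  axis_path <- paste0(path, ".axes")
  con <- file(axis_path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", row_name), con)
  writeLines(paste(format(row_axis, digits = 12, trim = TRUE), collapse = "\t"),
             con)
  writeLines(paste0("# ", col_name), con)
  writeLines(paste(format(col_axis, digits = 12, trim = TRUE), collapse = "\t"),
             con)
  invisible(path)
}

save_plot <- function(p, path, width = 6, height = 4.5) {
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

#' Render a spectrogram to an image plus data twin
#'
#' @param spec A `tfa_spectrogram`.
#' @param path Image path (extension selects the device, e.g. `.png`).
#' @return `path`, invisibly.
#' @export
render_spectrogram <- function(spec, path) {
  save_plot(autoplot(spec), path)
  write_matrix_txt(spec$X, paste0(path, ".tsv"), spec$f, spec$t,
                   "frequency_cycles_per_min", "time_min")
  invisible(path)
}

#' Render an ensemble cloud to an image plus data twin
#'
#' @param ensemble A `tfa_ensemble`.
#' @param path Image path.
#' @param by_family Color points by stimulus family.
#' @return `path`, invisibly.
#' @export
render_tfa_cloud <- function(ensemble, path, by_family = FALSE) {
  save_plot(autoplot(ensemble, by_family = by_family), path)
  utils::write.table(as.data.frame(ensemble), paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a sweep heat map to an image plus data twin
#'
#' @param sweep A `tfa_sweep`.
#' @param field One of `"xi"`, `"rho"`, `"amplitude"`, `"physio"`.
#' @param path Image path.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(sweep, field, path) {
  field <- match.arg(field, c("xi", "rho", "amplitude", "physio"))
  save_plot(autoplot(sweep, field = field), path)
  all_rows <- sweep[sweep$family == "all", ]
  sp <- attr(sweep, "s_pos_grid", exact = TRUE)
  sn <- attr(sweep, "s_neg_grid", exact = TRUE)
  X <- matrix(all_rows[[paste0(field, "_mean")]],
              nrow = length(sp), ncol = length(sn), byrow = TRUE)
  write_matrix_txt(X, paste0(path, ".tsv"), sp, sn,
                   "s_pos_grid", "s_neg_grid")
  invisible(path)
}
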