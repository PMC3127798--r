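# Stimulus generation and signal utilities.
#
# A "signal" throughout the package is a tibble with two columns:
# `time` (minutes, strictly increasing uniform grid) and `value`
# (concentration or abundance in model-specific units).  Metadata such as
# the stimulus family and seed travel as attributes ("family", "seed",
# "label") that downstream functions read but never require.

#' Validate and normalize a signal data frame
#'
#' Checks the signal contract: a `time` column on a uniform, strictly
#' increasing grid with at least two points, and a finite `value` column of
#' the same length.  Data frames with two unnamed numeric columns are
#' accepted and renamed.
#'
#' @param data A data frame with columns `time` and `value` (or two numeric
#'   columns in that order).
#' @return A tibble with columns `time` and `value`.
#' @export
as_signal <- function(data) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data.frame with columns `time` and `value`.",
                 class = "tfanet_signal_error")
  }
  if (!all(c("time", "value") %in% names(data))) {
    if (ncol(data) >= 2 && is.numeric(data[[1]]) && is.numeric(data[[2]])) {
      data <- tibble::tibble(time = data[[1]], value = data[[2]])
    } else {
      rlang::abort("signal needs `time` and `value` columns.",
                   class = "tfanet_signal_error")
    }
  }
  t <- data$time
  y <- data$value
  if (length(t) < 2) {
    rlang::abort("signal needs at least 2 samples.", class = "tfanet_signal_error")
  }
  if (length(t) != length(y)) {
    rlang::abort("`time` and `value` lengths differ.", class = "tfanet_signal_error")
  }
  if (!all(is.finite(t)) || !all(is.finite(y))) {
    rlang::abort("signal values must be finite.", class = "tfanet_signal_error")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    rlang::abort("`time` must be strictly increasing.", class = "tfanet_signal_error")
  }
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1])) {
    rlang::abort("`time` must be a uniform grid (relative tolerance 1e-9).",
                 class = "tfanet_signal_error")
  }
  out <- tibble::as_tibble(data[c("time", "value")])
  for (a in c("family", "seed", "label")) {
    if (!is.null(attr(data, a, exact = TRUE))) {
      attr(out, a) <- attr(data, a, exact = TRUE)
    }
  }
  out
}

#' Sampling interval of a signal
#' @param signal A signal tibble (see [as_signal()]).
#' @return The grid spacing in minutes.
#' @export
signal_dt <- function(signal) {
  signal <- as_signal(signal)
  (signal$time[nrow(signal)] - signal$time[1]) / (nrow(signal) - 1)
}

#' Stimulus generator configuration
#'
#' Bundles the parameters of the random noisy stimulus families.  Defaults
#' describe the reference study conditions: 3000 min of signal sampled
#' every minute, 5--30 random segments for the piecewise families, three
#' sinusoidal components with log-uniform frequencies spanning slow
#' (1/1500 cycles/min) to fast (1/20 cycles/min) regimes, and additive
#' white Gaussian noise with standard deviation 5% of the maximum
#' amplitude, clipped to the physical range `[0, max_amplitude]`.
#'
#' @param family One of `"block"` (piecewise constant), `"saw"` (piecewise
#'   linear), `"sine"` (sum of sinusoids).
#' @param duration Signal duration in minutes.
#' @param dt Sampling interval in minutes.
#' @param max_amplitude Maximum stimulus amplitude, model units.
#' @param n_segments_range Integer pair, range of segment counts for the
#'   block and saw families.
#' @param freq_range Frequency range (cycles/min) for sinusoidal
#'   components; must respect the Nyquist bound `1/(2 dt)`.
#' @param n_components Number of sinusoidal components.
#' @param noise_sd_frac Noise standard deviation as a fraction of
#'   `max_amplitude`.
#' @param seed Optional integer seed; identical seeds give identical
#'   signals.
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(family = c("block", "saw", "sine"),
                            duration = 3000,
                            dt = 1,
                            max_amplitude = 1,
                            n_segments_range = c(5L, 30L),
                            freq_range = c(1 / 1500, 1 / 20),
                            n_components = 3L,
                            noise_sd_frac = 0.05,
                            seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(dt) || dt <= 0) {
    rlang::abort("`duration` and `dt` must be positive.",
                 class = "tfanet_config_error")
  }
  if (duration / dt < 64) {
    rlang::abort("`duration/dt` must be at least 64 samples.",
                 class = "tfanet_config_error")
  }
  if (max_amplitude <= 0) {
    rlang::abort("`max_amplitude` must be positive.", class = "tfanet_config_error")
  }
  if (noise_sd_frac < 0) {
    rlang::abort("`noise_sd_frac` must be nonnegative.", class = "tfanet_config_error")
  }
  if (length(freq_range) != 2 || any(freq_range <= 0) ||
      freq_range[2] > 1 / (2 * dt) + 1e-15 || freq_range[1] > freq_range[2]) {
    rlang::abort("`freq_range` must lie within (0, 1/(2 dt)].",
                 class = "tfanet_config_error")
  }
  if (length(n_segments_range) != 2 || any(n_segments_range < 1) ||
      n_segments_range[1] > n_segments_range[2]) {
    rlang::abort("`n_segments_range` must be an increasing pair of positive integers.",
                 class = "tfanet_config_error")
  }
  structure(
    list(family = family, duration = duration, dt = dt,
         max_amplitude = max_amplitude,
         n_segments_range = as.integer(n_segments_range),
         freq_range = freq_range, n_components = as.integer(n_components),
         noise_sd_frac = noise_sd_frac, seed = seed),
    class = "stimulus_config"
  )
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.  `seed = NULL` uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one random noisy stimulus
#'
#' Draws a random time-varying stimulus from one of three families:
#' piecewise-constant levels over randomly partitioned segments
#' (`"block"`), piecewise-linear interpolation between random breakpoint
#' levels (`"saw"`), or a sum of random sinusoids affinely mapped into the
#' amplitude range (`"sine"`).  Zero-mean Gaussian noise of standard
#' deviation `noise_sd_frac * max_amplitude` is added, then values are
#' clipped to `[0, max_amplitude]` so concentrations stay physical.
#'
#' @param config A [stimulus_config()].
#' @return A signal tibble with attributes `family` and `seed`.
#' @export
generate_stimulus <- function(config) {
  if (!inherits(config, "stimulus_config")) {
    rlang::abort("`config` must be a stimulus_config.", class = "tfanet_config_error")
  }
  t <- seq(0, config$duration, by = config$dt)
  n <- length(t)
  A <- config$max_amplitude
  y <- with_seed(config$seed, {
    base <- switch(
      config$family,
      block = {
        n_seg <- sample(config$n_segments_range[1]:config$n_segments_range[2], 1L)
        bounds <- sort(stats::runif(n_seg - 1L, 0, config$duration))
        levels <- stats::runif(n_seg, 0, A)
        levels[findInterval(t, bounds) + 1L]
      },
      saw = {
        n_seg <- sample(config$n_segments_range[1]:config$n_segments_range[2], 1L)
        node_t <- c(0, sort(stats::runif(n_seg - 1L, 0, config$duration)),
                    config$duration)
        node_y <- stats::runif(n_seg + 1L, 0, A)
        stats::approx(node_t, node_y, xout = t)$y
      },
      sine = {
        k <- config$n_components
        lf <- log(config$freq_range)
        freq <- exp(stats::runif(k, lf[1], lf[2]))
        phase <- stats::runif(k, 0, 2 * pi)
        amp <- stats::runif(k, 0.5, 1)
        raw <- colSums(amp * sin(outer(freq, t) * 2 * pi + phase))
        rng <- range(raw)
        if (diff(rng) == 0) rep(A / 2, n)
        else (raw - rng[1]) / diff(rng) * A
      }
    )
    if (config$noise_sd_frac > 0) {
      base <- base + stats::rnorm(n, 0, config$noise_sd_frac * A)
    }
    pmin(pmax(base, 0), A)
  })
  out <- tibble::tibble(time = t, value = y)
  attr(out, "family") <- config$family
  attr(out, "seed") <- config$seed
  out
}

# Reproducible per-stimulus seed derived from a master seed; kept below
# 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * as.numeric(i)) %% 2147483647)
}

#' Generate a stimulus ensemble
#'
#' Builds a mixed ensemble of block, saw and sinusoidal stimuli with
#' reproducible per-stimulus seeds derived from a single master seed, so
#' that the identical stimulus list can be replayed against different
#' network models (matched-seed comparisons).
#'
#' @param n_block,n_saw,n_sine Number of stimuli per family.
#' @param base_config A [stimulus_config()] whose family and seed fields
#'   are overridden per stimulus.
#' @param seed Master integer seed.
#' @return A tibble with one row per stimulus: `stimulus_id`, `family`,
#'   `seed`, and a `signal` list-column of signal tibbles.
#' @export
generate_ensemble <- function(n_block, n_saw, n_sine,
                              base_config = stimulus_config(),
                              seed = 1L) {
  if (any(c(n_block, n_saw, n_sine) < 0)) {
    rlang::abort("ensemble counts must be nonnegative.", class = "tfanet_config_error")
  }
  fams <- rep(c("block", "saw", "sine"), times = c(n_block, n_saw, n_sine))
  n <- length(fams)
  if (n == 0) {
    return(tibble::tibble(stimulus_id = integer(), family = character(),
                          seed = integer(), signal = list()))
  }
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  signals <- purrr::map2(fams, seeds, function(fam, s) {
    cfg <- base_config
    cfg$family <- fam
    cfg$seed <- s
    generate_stimulus(cfg)
  })
  tibble::tibble(stimulus_id = seq_len(n), family = fams, seed = seeds,
                 signal = signals)
}

#' Rescale a signal to a target maximum amplitude
#'
#' Multiplies the values by `target_max / max(value)` so the scaled maximum
#' equals `target_max`.  Used to map unit-amplitude random stimuli onto the
#' physiological input range of each network (e.g. 11.1 mM galactose for
#' the GAL model, 4.25e-6 M oleate for the OLE model, 1500 molecules/cell
#' nuclear NF-kB for the LPS model).
#'
#' @param signal A signal tibble.
#' @param target_max Desired maximum, model units.
#' @return The rescaled signal.
#' @export
scale_amplitude <- function(signal, target_max) {
  signal <- as_signal(signal)
  m <- max(signal$value)
  if (m <= 0) {
    rlang::abort("cannot rescale a signal with nonpositive maximum.",
                 class = "tfanet_signal_error")
  }
  signal$value <- signal$value * (target_max / m)
  signal
}

#' Remove the mean of a signal
#'
#' @param signal A signal tibble.
#' @return The signal with `value` shifted to zero mean.
#' @export
zero_mean <- function(signal) {
  signal <- as_signal(signal)
  signal$value <- signal$value - mean(signal$value)
  signal
}

#' Numerical time derivative of a signal
#'
#' Central differences on the interior, one-sided differences at the two
#' endpoints; the returned signal has the same length and grid.
#'
#' @param signal A signal tibble.
#' @return A signal tibble of derivative values (units per minute).
#' @export
signal_derivative <- function(signal) {
  signal <- as_signal(signal)
  y <- signal$value
  n <- length(y)
  dt <- signal_dt(signal)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  signal$value <- d
  signal
}

#' Read a signal from a delimited text file
#'
#' Expects two columns (time, value) separated by commas, tabs or
#' whitespace; lines starting with `#` are comments; a single header line
#' is detected and skipped.  The time grid must be uniform.
#'
#' @param path File path.
#' @return A signal tibble.
#' @export
read_signal <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    rlang::abort("empty signal file.", class = "tfanet_io_error")
  }
  sep <- if (grepl(",", lines[[1]])) "," else ""
  first_numeric <- !anyNA(suppressWarnings(
    as.numeric(strsplit(trimws(lines[[1]]), if (sep == ",") "," else "\\s+")[[1]])
  ))
  if (!first_numeric) lines <- lines[-1]
  df <- utils::read.table(text = lines, sep = sep, header = FALSE,
                          col.names = c("time", "value"),
                          colClasses = "numeric")
  as_signal(df)
}

#' Write a signal to a delimited text file
#'
#' Tab-separated columns `time` and `value` with 12 significant digits and
#' a commented header, the format [read_signal()] parses.
#'
#' @param signal A signal tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  signal <- as_signal(signal)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_min\tvalue", con)
  writeLines(paste(format(signal$time, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   format(signal$value, digits = 12, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}
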