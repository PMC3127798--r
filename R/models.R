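# Kinetic models of the three gene circuits and their simulation.
#
# All three models share canonical Hill kinetics: each production term is
# basal + Vmax * activation * repression with activations x^n/(K^n + x^n),
# repressions 1/(1 + s*(x/K)^n), and first-order decay.  Default rate
# parameters are implementation-calibrated (see the methods vignette):
# degradation half-lives between 15 and 60 min, Hill constants near the
# middle of each state's steady operating range, and Vmax values that
# drive the target gene at least five-fold above basal under a sustained
# maximal stimulus.  The loop-strength multipliers s_pos and s_neg scale
# the Vmax of the designated positive/negative regulatory arms
# (wild type = 1), matching the axes of the parameter-sweep portraits.

gal_default_params <- function() {
  d15 <- log(2) / 15
  c(b3 = 0.01, V3 = 1, d3 = d15,
    b80 = 0.02, V80 = 0.5, d80 = d15,
    bT = 0.005, VT = 1, dT = d15,
    Ku = 5.55, nu = 2, Kseq = 0.2, K80 = 0.15, n80 = 4)
}

ole_default_params <- function() {
  d60 <- log(2) / 60
  d30 <- log(2) / 30
  c(bA = 0.01, VA = 1, dA = d60,
    bO = 0.01, VO = 1, dO = d30,
    bP = 0.01, VP = 1, dP = d60,
    bT = 0.005, VT = 1, dT = d60,
    Ko = 2.125e-6, no = 2, KuA = 2.125e-6, nuA = 2, KuO = 2.125e-6, nuO = 2,
    KA = 30, nA = 2, K3 = 30, n3 = 2, Kp = 8, np = 2,
    wP1 = 1, wP2 = 0.35, w1 = 0.32, w2 = 0.68, c0 = 0.025)
}

lps_default_params <- function() {
  d60 <- log(2) / 60
  c(bA = 0.01, VA = 1, dA = d60,
    bC = 0.01, VC = 1, dC = d60,
    bT = 0.005, VT = 1, dT = d60,
    Kn = 750, nn = 2, KC = 60, nC = 2, KA3 = 30, nA3 = 2)
}

check_params <- function(params) {
  if (any(!is.finite(params)) || any(params < 0)) {
    rlang::abort("all rate parameters must be finite and nonnegative.",
                 class = "tfanet_model_error")
  }
  deg <- params[grepl("^d", names(params))]
  if (any(deg <= 0)) {
    rlang::abort("degradation rates must be positive.", class = "tfanet_model_error")
  }
  hills <- params[grepl("^n", names(params))]
  if (any(hills < 1)) {
    rlang::abort("Hill exponents must be at least 1.", class = "tfanet_model_error")
  }
  invisible(params)
}

check_multipliers <- function(s_pos, s_neg) {
  if (!is.numeric(s_pos) || !is.numeric(s_neg) || s_pos < 0 || s_neg < 0 ||
      !is.finite(s_pos) || !is.finite(s_neg)) {
    rlang::abort("loop-strength multipliers must be finite and nonnegative.",
                 class = "tfanet_model_error")
  }
}

new_network_model <- function(kind, name, states, params, s_pos, s_neg,
                              variants = character(), output_state,
                              max_stimulus, stimulus_name, delays = NULL) {
  structure(
    list(kind = kind, name = name, states = states, params = params,
         s_pos = s_pos, s_neg = s_neg, variants = variants,
         output_state = output_state, max_stimulus = max_stimulus,
         stimulus_name = stimulus_name, delays = delays),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", x$name, "\n", sep = "")
  cat("  states: ", paste(names(x$states), collapse = ", "),
      " (output: ", x$output_state, ")\n", sep = "")
  cat("  stimulus: ", x$stimulus_name, " (max ",
      format(x$max_stimulus), ")\n", sep = "")
  cat("  loop multipliers: s_pos = ", x$s_pos, ", s_neg = ", x$s_neg, "\n",
      sep = "")
  if (length(x$variants)) {
    cat("  variants: ", paste(x$variants, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Yeast galactose (GAL) network model
#'
#' Dual positive and negative feedback loops: galactose activates Gal3,
#' active Gal3 sequesters the repressor Gal80, and free Gal80 represses
#' Gal4 activity, which drives Gal3 (positive feedback, scaled by
#' `s_pos`), Gal80 (negative feedback, scaled by `s_neg`) and the target
#' gene.  The stimulus is external galactose with a physiological maximum
#' of 11.1 mM.
#'
#' @param s_pos,s_neg Nonnegative loop-strength multipliers (wild type 1).
#' @param params Optional named vector overriding default rate parameters.
#' @return A `network_model`.
#' @export
gal_model <- function(s_pos = 1, s_neg = 1, params = NULL) {
  check_multipliers(s_pos, s_neg)
  p <- gal_default_params()
  if (!is.null(params)) p[names(params)] <- params
  check_params(p)
  name <- if (s_pos == 1 && s_neg == 1) "WT-GAL" else
    sprintf("GAL(s_pos=%g,s_neg=%g)", s_pos, s_neg)
  new_network_model(
    kind = "gal", name = name,
    states = c(Gal3 = NA_real_, Gal80 = NA_real_, Target = NA_real_),
    params = p, s_pos = s_pos, s_neg = s_neg,
    output_state = "Target", max_stimulus = 11.1,
    stimulus_name = "galactose (mM)"
  )
}

ole_allowed_variants <- c("adr1_delta", "oaf3_delta", "no_positive_feedback")

#' Yeast oleate (OLE) network model
#'
#' A positive feedback loop on PIP2 overlapped with coherent type-1
#' (activating, via Adr1) and type-2 (repressing, via Oaf3) feed-forward
#' loops.  Oleate activates Oaf1 instantaneously; the Oaf1--Pip2
#' heterodimer drives PIP2 (autoregulation) and the target gene; Adr1 adds
#' a slower activating arm to both (weight scaled by `s_pos`); Oaf3
#' applies slow repression on the target (weight scaled by `s_neg`).  The
#' stimulus is intracellular oleate with maximum 4.25e-6 M.
#'
#' @param s_pos,s_neg Nonnegative loop-strength multipliers (wild type 1).
#' @param variants Character subset of `"adr1_delta"` (remove the Adr1
#'   state and its arms), `"oaf3_delta"` (remove Oaf3), and
#'   `"no_positive_feedback"` (PIP2 no longer upregulates its own gene;
#'   target regulation unchanged).
#' @param params Optional named vector overriding default rate parameters.
#' @return A `network_model`.
#' @export
ole_model <- function(s_pos = 1, s_neg = 1, variants = character(),
                      params = NULL) {
  check_multipliers(s_pos, s_neg)
  variants <- unique(as.character(variants))
  unknown <- setdiff(variants, ole_allowed_variants)
  if (length(unknown)) {
    rlang::abort(paste0("unknown OLE variant flag(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "tfanet_model_error")
  }
  p <- ole_default_params()
  if (!is.null(params)) p[names(params)] <- params
  check_params(p)
  vtag <- if (length(variants)) paste0("-", paste(sort(variants), collapse = "+"))
          else ""
  name <- if (s_pos == 1 && s_neg == 1 && !length(variants)) "WT-OLE" else
    sprintf("OLE%s(s_pos=%g,s_neg=%g)", vtag, s_pos, s_neg)
  new_network_model(
    kind = "ole", name = name,
    states = c(Adr1 = NA_real_, Oaf3 = NA_real_, Pip2 = NA_real_,
               Target = NA_real_),
    params = p, s_pos = s_pos, s_neg = s_neg, variants = variants,
    output_state = "Target", max_stimulus = 4.25e-6,
    stimulus_name = "oleate (M)"
  )
}

#' LPS-induced innate-immune network model
#'
#' Coherent type-1 and type-2 feed-forward loops with delayed arms:
#' nuclear NF-kB (the stimulus) activates ATF3 and C/EBPd after discrete
#' transcriptional delays `tau_a` and `tau_c`; production of the IL6-like
#' target requires both NF-kB and C/EBPd activation and is repressed by
#' ATF3.  `s_pos` scales every NF-kB activation weight, `s_neg` the ATF3
#' repression weight.  The stimulus maximum is 1500 molecules/cell.
#'
#' @param s_pos,s_neg Nonnegative loop-strength multipliers (wild type 1).
#' @param params Optional named vector overriding default rate parameters.
#' @param tau_a,tau_c Delays in minutes for the ATF3 and C/EBPd arms.
#' @return A `network_model`.
#' @export
lps_model <- function(s_pos = 1, s_neg = 1, params = NULL,
                      tau_a = 60, tau_c = 240) {
  check_multipliers(s_pos, s_neg)
  if (tau_a < 0 || tau_c < 0) {
    rlang::abort("delays must be nonnegative.", class = "tfanet_model_error")
  }
  p <- lps_default_params()
  if (!is.null(params)) p[names(params)] <- params
  check_params(p)
  name <- if (s_pos == 1 && s_neg == 1) "WT-LPS" else
    sprintf("LPS(s_pos=%g,s_neg=%g)", s_pos, s_neg)
  new_network_model(
    kind = "lps", name = name,
    states = c(ATF3 = NA_real_, CEBPd = NA_real_, Target = NA_real_),
    params = p, s_pos = s_pos, s_neg = s_neg,
    output_state = "Target", max_stimulus = 1500,
    stimulus_name = "nuclear NF-kB (molecules/cell)",
    delays = c(tau_a = tau_a, tau_c = tau_c)
  )
}

#' Identity "model"
#'
#' Returns the stimulus unchanged; useful as a null system whose noise
#' suppression is exactly 1 and whose responsiveness attains the cap.
#'
#' @return A `network_model` of kind `"identity"`.
#' @export
identity_model <- function() {
  new_network_model(
    kind = "identity", name = "identity",
    states = c(Output = NA_real_), params = numeric(),
    s_pos = 1, s_neg = 1, output_state = "Output",
    max_stimulus = 1, stimulus_name = "arbitrary"
  )
}

#' Integrator settings
#'
#' @param rel_tol,abs_tol Solver tolerances.
#' @param equilibrate_time Minutes of zero-stimulus pre-run used to locate
#'   the basal steady state.
#' @param delay_handling How delayed stimulus arms are realized:
#'   `"history_interpolation"` evaluates the interpolated stimulus at
#'   `t - tau` (stimulus is zero before onset); `"linear_chain"`
#'   approximates each discrete delay by a cascade of `chain_length`
#'   first-order stages with total mean delay `tau`.
#' @param chain_length Number of stages in the linear-chain approximation.
#' @return A `simulation_settings` object.
#' @export
simulation_settings <- function(rel_tol = 1e-6, abs_tol = 1e-8,
                                equilibrate_time = 6000,
                                delay_handling = c("history_interpolation",
                                                   "linear_chain"),
                                chain_length = 3L) {
  if (rel_tol <= 0 || abs_tol <= 0) {
    rlang::abort("solver tolerances must be positive.",
                 class = "tfanet_config_error")
  }
  structure(
    list(rel_tol = rel_tol, abs_tol = abs_tol,
         equilibrate_time = equilibrate_time,
         delay_handling = match.arg(delay_handling),
         chain_length = as.integer(chain_length)),
    class = "simulation_settings"
  )
}

# Parameter vector in the order expected by the compiled right-hand sides.
model_param_vector <- function(model) {
  p <- model$params
  switch(
    model$kind,
    gal = c(p[c("b3", "V3", "d3", "b80", "V80", "d80", "bT", "VT", "dT",
                "Ku", "nu", "Kseq", "K80", "n80")],
            spos = model$s_pos, sneg = model$s_neg),
    ole = c(p[c("bA", "VA", "dA", "bO", "VO", "dO", "bP", "VP", "dP",
                "bT", "VT", "dT", "Ko", "no", "KuA", "nuA", "KuO", "nuO",
                "KA", "nA", "K3", "n3", "Kp", "np",
                "wP1", "wP2", "w1", "w2", "c0")],
            spos = model$s_pos, sneg = model$s_neg,
            adr1_del = as.numeric("adr1_delta" %in% model$variants),
            oaf3_del = as.numeric("oaf3_delta" %in% model$variants),
            no_pf = as.numeric("no_positive_feedback" %in% model$variants)),
    lps = c(p[c("bA", "VA", "dA", "bC", "VC", "dC", "bT", "VT", "dT",
                "Kn", "nn", "KC", "nC", "KA3", "nA3")],
            spos = model$s_pos, sneg = model$s_neg),
    rlang::abort("no parameter vector for this model kind.",
                 class = "tfanet_model_error")
  )
}

model_dll_entry <- function(kind) {
  list(func = paste0(kind, "_derivs"), initfunc = paste0(kind, "_init"),
       initforc = paste0(kind, "_forc"))
}

n_forcings <- function(kind) if (kind == "lps") 3L else 1L

# Low-level wrapper around deSolve::ode for the compiled models.
integrate_model <- function(model, times, y0, forcings, settings) {
  entry <- model_dll_entry(model$kind)
  out <- deSolve::ode(
    y = y0, times = times, func = entry$func,
    parms = model_param_vector(model), dllname = "tfanet",
    initfunc = entry$initfunc, initforc = entry$initforc,
    forcings = forcings, fcontrol = list(method = "linear", rule = 2),
    method = "lsoda", rtol = settings$rel_tol, atol = settings$abs_tol
  )
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    rlang::abort(
      sprintf("integration of %s failed (s_pos=%g, s_neg=%g).",
              model$name, model$s_pos, model$s_neg),
      class = "tfanet_integration_error",
      model = model$name, s_pos = model$s_pos, s_neg = model$s_neg
    )
  }
  out
}

# First-order cascade approximating a discrete delay; exact passthrough
# when tau = 0.  Stage rate is m/tau so the total mean lag equals tau.
# Each stage's time constant (tau/m) can be much shorter than the sampling
# interval, so the cascade is integrated on an internal grid fine enough
# to resolve it, then sampled back onto the signal grid.
chain_filter <- function(y, dt, tau, m) {
  if (tau <= 0) return(y)
  dt_f <- min(dt, tau / (5 * m))
  n_sub <- max(1L, ceiling(dt / dt_f))
  dt_f <- dt / n_sub
  t_coarse <- (seq_along(y) - 1) * dt
  t_fine <- seq(0, t_coarse[length(t_coarse)], by = dt_f)
  x <- stats::approx(t_coarse, y, xout = t_fine)$y
  alpha <- 1 - exp(-m / tau * dt_f)
  for (stage in seq_len(m)) {
    # zero initial condition: the pre-onset stimulus history is zero,
    # matching the history_interpolation convention
    x <- as.numeric(stats::filter(alpha * x, 1 - alpha,
                                  method = "recursive", init = 0))
  }
  x[seq(1, length(t_fine), by = n_sub)]
}

# Delayed copies of the stimulus for the LPS model.  The stimulus history
# before onset is the equilibration level (zero).
delayed_forcings <- function(stimulus, delays, settings) {
  t <- stimulus$time
  shift_one <- function(tau) {
    if (settings$delay_handling == "history_interpolation") {
      v <- stats::approx(t, stimulus$value, xout = t - tau, rule = 1)$y
      v[is.na(v)] <- 0
      v
    } else {
      chain_filter(stimulus$value, signal_dt(stimulus), tau,
                   settings$chain_length)
    }
  }
  list(cbind(t, stimulus$value),
       cbind(t, shift_one(delays[["tau_a"]])),
       cbind(t, shift_one(delays[["tau_c"]])))
}

stimulus_forcings <- function(model, stimulus, settings) {
  if (model$kind == "lps") delayed_forcings(stimulus, model$delays, settings)
  else list(cbind(stimulus$time, stimulus$value))
}

#' Basal steady state of a model under zero stimulus
#'
#' Locates the zero-stimulus fixed point by integrating the model for
#' `equilibrate_time` minutes from a crude production/degradation guess,
#' then polishing with a second run of equal length.
#'
#' @param model A `network_model`.
#' @param settings A [simulation_settings()].
#' @return Named vector of basal state values.
#' @export
basal_state <- function(model, settings = simulation_settings()) {
  if (model$kind == "identity") return(c(Output = 0))
  pv <- model$params
  y0 <- switch(
    model$kind,
    gal = c(pv[["b3"]] / pv[["d3"]], pv[["b80"]] / pv[["d80"]],
            pv[["bT"]] / pv[["dT"]]),
    ole = c(pv[["bA"]] / pv[["dA"]], pv[["bO"]] / pv[["dO"]],
            pv[["bP"]] / pv[["dP"]], pv[["bT"]] / pv[["dT"]]),
    lps = c(pv[["bA"]] / pv[["dA"]], pv[["bC"]] / pv[["dC"]],
            pv[["bT"]] / pv[["dT"]])
  )
  names(y0) <- names(model$states)
  times <- c(0, settings$equilibrate_time)
  zero_forc <- lapply(seq_len(n_forcings(model$kind)),
                      function(i) cbind(times, c(0, 0)))
  for (pass in 1:2) {
    out <- integrate_model(model, times, y0, zero_forc, settings)
    y0 <- out[nrow(out), names(y0)]
  }
  y0
}

#' Simulate a model response to a stimulus
#'
#' Integrates the circuit from its basal steady state with the stimulus
#' linearly interpolated between samples, and returns the trajectory of
#' the reported target-gene product on the stimulus time grid.
#'
#' @param model A `network_model`.
#' @param stimulus A signal tibble (stimulus units of the model).
#' @param settings A [simulation_settings()].
#' @param y0 Optional precomputed basal state (from [basal_state()]);
#'   avoids re-equilibration when simulating many stimuli.
#' @return A signal tibble of the output state; attribute `states` holds
#'   the full state matrix.
#' @export
simulate_response <- function(model, stimulus,
                              settings = simulation_settings(),
                              y0 = NULL) {
  stimulus <- as_signal(stimulus)
  if (model$kind == "identity") {
    out <- stimulus
    attr(out, "label") <- model$name
    return(out)
  }
  if (is.null(y0)) y0 <- basal_state(model, settings)
  forc <- stimulus_forcings(model, stimulus, settings)
  out <- integrate_model(model, stimulus$time, y0, forc, settings)
  states <- out[, names(model$states), drop = FALSE]
  res <- tibble::tibble(time = stimulus$time,
                        value = states[, model$output_state])
  attr(res, "states") <- states
  attr(res, "label") <- model$name
  attr(res, "family") <- attr(stimulus, "family", exact = TRUE)
  res
}
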