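short_cfg <- function(fam = "block", seed = 1) {
  stimulus_config(fam, duration = 600, dt = 1, seed = seed)
}

test_that("model constructors validate multipliers, variants and parameters", {
  expect_error(gal_model(s_pos = -1), class = "tfanet_model_error")
  expect_error(ole_model(variants = "pip2_delta"), class = "tfanet_model_error")
  expect_error(lps_model(tau_a = -5), class = "tfanet_model_error")
  expect_error(gal_model(params = c(d3 = 0)), class = "tfanet_model_error")
  expect_error(gal_model(params = c(n80 = 0.5)), class = "tfanet_model_error")
  expect_identical(gal_model()$name, "WT-GAL")
  expect_identical(ole_model()$name, "WT-OLE")
  expect_identical(lps_model()$name, "WT-LPS")
})

test_that("zero stimulus holds every state at the basal steady state", {
  for (model in list(gal_model(), ole_model(), lps_model())) {
    y0 <- basal_state(model)
    zero <- make_signal(rep(0, 1001))
    resp <- simulate_response(model, zero, y0 = y0)
    states <- attr(resp, "states")
    drift <- apply(states, 2, function(s) max(abs(s - s[1])) / max(s[1], 1e-12))
    expect_lt(max(drift), 0.01)
  }
})

test_that("uniformly doubling production and decay rates preserves the
           steady state (dimensional consistency)", {
  p <- gal_default_parameters <- gal_model()$params
  doubled <- p * ifelse(grepl("^(b|V|d)", names(p)), 2, 1)
  a <- basal_state(gal_model())
  b <- basal_state(gal_model(params = doubled))
  expect_equal(a, b, tolerance = 1e-4)
})

test_that("a sustained maximal step drives the GAL target far above basal", {
  m <- gal_model()
  step <- make_signal(c(rep(0, 10), rep(11.1, 2991)))
  resp <- simulate_response(m, step)
  expect_gt(max(resp$value), 5 * resp$value[1])
  after <- resp$value[resp$time >= 100]
  expect_true(all(diff(after) > -1e-6))  # monotone approach to the new state
})

test_that("zero loop multipliers sever the corresponding arms", {
  # GAL: s_pos = 0 leaves only basal Gal3 production
  m0 <- gal_model(s_pos = 0)
  y0 <- basal_state(m0)
  expect_equal(unname(y0["Gal3"]),
               m0$params[["b3"]] / m0$params[["d3"]], tolerance = 1e-3)
  # OLE: s_neg = 0 disables Oaf3 repression entirely
  s <- generate_stimulus(short_cfg(seed = 21))
  a <- simulate_response(ole_model(s_neg = 0),
                         scale_amplitude(s, 4.25e-6))
  b <- simulate_response(ole_model(variants = "oaf3_delta"),
                         scale_amplitude(s, 4.25e-6))
  expect_equal(a$value, b$value, tolerance = 1e-5)
})

test_that("state trajectories stay nonnegative for every stimulus family", {
  set <- simulation_settings()
  for (model in list(gal_model(), ole_model(), lps_model())) {
    for (fam in c("block", "saw", "sine")) {
      s <- scale_amplitude(generate_stimulus(short_cfg(fam, seed = 31)),
                           model$max_stimulus)
      resp <- simulate_response(model, s, set)
      expect_gte(min(attr(resp, "states")), -set$abs_tol)
    }
  }
})

test_that("responses smooth fast stimuli relative to the input", {
  s <- generate_stimulus(stimulus_config("block", seed = 33))
  m <- ole_model()
  r <- simulate_response(m, scale_amplitude(s, m$max_stimulus))
  tv <- function(x) sum(abs(diff(x / max(x))))
  expect_lt(tv(r$value), tv(s$value))
})

test_that("the adr1/oaf3 double deletion is independent of loop multipliers", {
  s <- scale_amplitude(generate_stimulus(short_cfg(seed = 41)), 4.25e-6)
  vv <- c("adr1_delta", "oaf3_delta")
  base <- simulate_response(ole_model(1, 1, variants = vv), s)
  alt <- simulate_response(ole_model(0.1, 8, variants = vv), s)
  expect_equal(base$value, alt$value, tolerance = 1e-10)
})

test_that("LPS delayed arms stay flat before their delay elapses", {
  m <- lps_model(tau_a = 60, tau_c = 240)
  step <- make_signal(c(0, rep(1500, 600)))
  resp <- simulate_response(m, step)
  states <- attr(resp, "states")
  pre <- states[resp$time < 55, "ATF3"]
  expect_lt(max(abs(pre - pre[1])) / pre[1], 1e-3)
  preC <- states[resp$time < 235, "CEBPd"]
  expect_lt(max(abs(preC - preC[1])) / preC[1], 1e-3)
  # the target stays basal until the C/EBPd gate opens, then induces
  expect_lt(abs(resp$value[200] - resp$value[1]) / resp$value[1], 0.05)
  expect_gt(resp$value[590], 2 * resp$value[1])
})

test_that("the linear delay chain converges to the interpolated-history
           solution as the chain lengthens", {
  # smooth (noise-free) stimulus: the Erlang kernel converges to a pure
  # shift only where the input is smooth on the kernel's width
  s <- generate_stimulus(stimulus_config("saw", duration = 600, dt = 1,
                                         noise_sd_frac = 0, seed = 51))
  s <- scale_amplitude(s, 1500)
  m <- lps_model(tau_a = 10, tau_c = 20)
  hist <- simulate_response(m, s, simulation_settings())
  chain <- simulate_response(
    m, s, simulation_settings(delay_handling = "linear_chain",
                              chain_length = 40L)
  )
  rel <- max(abs(chain$value - hist$value)) / max(hist$value)
  expect_lt(rel, 0.02)
  # zero delays: both handlings coincide with the plain ODE solution
  m0 <- lps_model(tau_a = 0, tau_c = 0)
  a <- simulate_response(m0, s, simulation_settings())
  b <- simulate_response(m0, s,
                         simulation_settings(delay_handling = "linear_chain"))
  expect_equal(a$value, b$value, tolerance = 1e-8)
})

test_that("identity model echoes its stimulus", {
  s <- generate_stimulus(short_cfg(seed = 61))
  expect_equal(simulate_response(identity_model(), s)$value, s$value)
})
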