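test_that("stimulus generation is a pure function of config and seed", {
  for (fam in c("block", "saw", "sine")) {
    cfg <- stimulus_config(fam, seed = 1)
    a <- generate_stimulus(cfg)
    b <- generate_stimulus(cfg)
    expect_identical(a$value, b$value)
    expect_false(identical(
      a$value, generate_stimulus(stimulus_config(fam, seed = 2))$value
    ))
  }
})

test_that("generated stimuli respect grid length and amplitude clipping", {
  for (fam in c("block", "saw", "sine")) {
    s <- generate_stimulus(stimulus_config(fam, duration = 3000, dt = 1,
                                           max_amplitude = 2, seed = 11))
    expect_equal(nrow(s), 3001)
    expect_equal(max(s$time), 3000)
    expect_true(all(s$value >= 0 & s$value <= 2))
  }
})

test_that("degenerate one-segment noise-free block stimulus is constant", {
  s <- generate_stimulus(stimulus_config("block", noise_sd_frac = 0,
                                         n_segments_range = c(1, 1),
                                         seed = 4))
  expect_equal(length(unique(s$value)), 1)
})

test_that("invalid stimulus configurations are rejected", {
  expect_error(stimulus_config("block", duration = -1),
               class = "tfanet_config_error")
  expect_error(stimulus_config("block", dt = 0), class = "tfanet_config_error")
  expect_error(stimulus_config("sine", freq_range = c(0.1, 10)),
               class = "tfanet_config_error")
  expect_error(stimulus_config("pulse"))
})

test_that("ensembles have requested composition and reproducible derived seeds", {
  cfg <- stimulus_config()
  ens <- generate_ensemble(3, 2, 4, cfg, seed = 9)
  expect_equal(nrow(ens), 9)
  expect_equal(as.vector(table(ens$family)[c("block", "saw", "sine")]),
               c(3L, 2L, 4L))
  ens2 <- generate_ensemble(3, 2, 4, cfg, seed = 9)
  expect_identical(ens$signal, ens2$signal)
  expect_equal(nrow(generate_ensemble(0, 0, 0, cfg, seed = 9)), 0)
  # distinct derived seeds produce distinct signals
  expect_false(identical(ens$signal[[1]]$value, ens$signal[[2]]$value))
})

test_that("amplitude scaling hits the target maximum and is idempotent", {
  s <- generate_stimulus(stimulus_config("block", seed = 2))
  g <- scale_amplitude(s, 11.1)
  expect_equal(max(g$value), 11.1, tolerance = 1e-12)
  o <- scale_amplitude(s, 4.25e-6)
  expect_equal(max(o$value), 4.25e-6, tolerance = 1e-12)
  expect_equal(scale_amplitude(g, 11.1)$value, g$value, tolerance = 1e-12)
  expect_error(scale_amplitude(make_signal(c(0, 0, 0)), 1),
               class = "tfanet_signal_error")
})

test_that("zero_mean removes the mean without changing shape", {
  s <- generate_stimulus(stimulus_config("block", seed = 3))
  z <- zero_mean(s)
  expect_lt(abs(mean(z$value)), 1e-10 * stats::sd(z$value))
  expect_equal(diff(z$value), diff(s$value))
  expect_equal(zero_mean(make_signal(rep(5, 10)))$value, rep(0, 10))
})

test_that("signal derivative matches closed forms", {
  ramp <- make_signal(2 * (0:50), dt = 1)
  expect_equal(signal_derivative(ramp)$value, rep(2, 51))
  expect_equal(signal_derivative(make_signal(rep(3, 20)))$value, rep(0, 20))
  dt <- 0.01
  t <- seq(0, 2 * pi, by = dt)
  w <- 2
  d <- signal_derivative(make_signal(sin(w * t), dt = dt))
  interior <- 2:(length(t) - 1)
  expect_equal(d$value[interior], w * cos(w * t[interior]),
               tolerance = 10 * dt^2)
})

test_that("signal files round-trip and both delimiters parse", {
  s <- generate_stimulus(stimulus_config("saw", seed = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signal(s, path)
  r <- read_signal(path)
  expect_equal(r$time, s$time, tolerance = 1e-12)
  expect_equal(r$value, s$value, tolerance = 1e-12)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,value", paste(0:9, sin(0:9), sep = ",")), csv)
  expect_equal(nrow(read_signal(csv)), 10)
  bad <- withr::local_tempfile()
  writeLines("0\t1", bad)
  expect_error(read_signal(bad), class = "tfanet_signal_error")
  nonuni <- withr::local_tempfile()
  writeLines(c("0\t1", "1\t2", "3\t4"), nonuni)
  expect_error(read_signal(nonuni), class = "tfanet_signal_error")
})
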