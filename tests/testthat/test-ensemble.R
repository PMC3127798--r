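small_ensemble <- function(n = 2, seed = 5) {
  generate_ensemble(n, n, n, stimulus_config(duration = 600, dt = 1),
                    seed = seed)
}

test_that("run_ensemble produces one record per stimulus and propagates
           identity statistics", {
  ens <- small_ensemble(2)
  res <- run_ensemble(identity_model(), ens)
  expect_equal(nrow(res), 6)
  expect_equal(res$xi, rep(1, 6), tolerance = 1e-12)
  expect_true(all(res$rho_capped))
  expect_true(all(is.na(res$error)))
  expect_equal(res$physio_distance, rep(0, 6), tolerance = 1e-12)
  empty <- run_ensemble(identity_model(), ens[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("run_ensemble rescales stimuli to the model input range", {
  ens <- small_ensemble(1)
  res <- run_ensemble(ole_model(), ens)
  expect_true(all(is.finite(res$xi)))
  expect_true(all(res$amplitude > 0))
})

test_that("ensemble summaries match hand arithmetic and brute-force CV", {
  ens <- small_ensemble(1)
  res <- run_ensemble(identity_model(), ens)
  # three synthetic records with xi = 1, 2, 3 and uncapped rho
  res <- res[1:3, ]
  res$xi <- c(1, 2, 3)
  res$rho <- c(2, 4, 6)
  res$rho_capped <- FALSE
  s <- summarize_ensemble(res)
  expect_equal(s$xi_mean, 2)
  expect_equal(s$xi_sd, 1)
  expect_equal(s$rho_mean, 4)
  expect_equal(s$xi_cv, 0.5)
  set.seed(77)
  res100 <- res[rep(1, 100), ]
  res100$xi <- stats::runif(100, 0.5, 20)
  res100$rho <- stats::runif(100, 0.1, 5)
  s100 <- summarize_ensemble(res100)
  expect_equal(s100$xi_cv, stats::sd(res100$xi) / mean(res100$xi),
               tolerance = 1e-12)
})

test_that("capped rho records are excluded from moments but counted", {
  ens <- small_ensemble(1)
  res <- run_ensemble(identity_model(), ens)[1:4, ]
  res$xi <- c(1, 1, 1, 1)
  res$rho <- c(5, 7, 1e12, 1e12)
  res$rho_capped <- c(FALSE, FALSE, TRUE, TRUE)
  s <- summarize_ensemble(res)
  expect_equal(s$rho_mean, 6)
  expect_equal(s$n_rho_capped, 2)
})

test_that("per-family summaries partition a mixed ensemble", {
  ens <- small_ensemble(2)
  res <- run_ensemble(identity_model(), ens)
  s <- summarize_ensemble(res, by_family = TRUE)
  expect_equal(nrow(s), 4)
  expect_setequal(s$family, c("all", "block", "saw", "sine"))
  expect_equal(sum(s$n[s$family != "all"]), s$n[s$family == "all"])
  expect_error(summarize_ensemble(res[0, ]), class = "tfanet_stat_error")
})

test_that("kde density integrates to one and resolves separated clusters", {
  set.seed(8)
  df <- data.frame(xi = c(rnorm(200, 0, 0.1), rnorm(200, 10, 0.1)),
                   rho = c(rnorm(200, 0, 0.1), rnorm(200, 10, 0.1)))
  d <- kde_density(df, n = 80)
  dx <- diff(sort(unique(d$x)))[1]
  dy <- diff(sort(unique(d$y)))[1]
  expect_equal(sum(d$density) * dx * dy, 1, tolerance = 0.02)
  # two local maxima: mass near each cluster centre
  near <- function(cx, cy) max(d$density[abs(d$x - cx) < 1 & abs(d$y - cy) < 1])
  far <- max(d$density[abs(d$x - 5) < 1])
  expect_gt(near(0, 0), far)
  expect_gt(near(10, 10), far)
  expect_error(kde_density(data.frame(xi = rep(1, 5), rho = rep(2, 5))),
               class = "tfanet_degenerate_error")
  expect_error(kde_density(data.frame(xi = 1, rho = 2)),
               class = "tfanet_stat_error")
})

test_that("physiological distance separates tracking from reversed responses", {
  s <- generate_stimulus(stimulus_config("block", seed = 12,
                                         duration = 600))
  expect_equal(physiological_distance(s, s), 0, tolerance = 1e-12)
  inv <- s
  inv$value <- max(s$value) - s$value
  expect_equal(physiological_distance(s, inv), 2, tolerance = 1e-12)
  lag <- smooth_first_order(s, tau = 50)
  d <- physiological_distance(s, lag)
  expect_gt(d, 0)
  expect_lt(d, sqrt(2))
})
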