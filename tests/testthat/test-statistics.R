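test_that("mean frequency handles point masses, symmetry, and degeneracy", {
  sp <- random_spectrogram(1)
  sp$X[] <- 0
  sp$X[3, ] <- 2
  expect_equal(mean_frequency(sp), sp$f[3])
  sp$X[] <- 0
  sp$X[1, ] <- 1; sp$X[3, ] <- 1
  expect_equal(mean_frequency(sp), (sp$f[1] + sp$f[3]) / 2)
  sp$X[] <- 0
  expect_error(mean_frequency(sp), class = "tfanet_degenerate_error")
})

test_that("mean frequency, total variation, KL and KS match brute force", {
  for (seed in 1:100) {
    set.seed(3 * seed + 1)
    nb <- sample(2:10, 1)
    nf <- sample(2:10, 1)
    sp <- random_spectrogram(seed, n_bands = nb, n_frames = nf)
    sq <- random_spectrogram(seed + 5000, nrow(sp$X), ncol(sp$X))
    expect_equal(mean_frequency(sp), brute_mean_frequency(sp),
                 tolerance = 1e-10)
    expect_equal(band_total_variation(sp), brute_total_variation(sp),
                 tolerance = 1e-10)
    p <- band_sums(sp) / sum(band_sums(sp))
    q <- band_sums(sq) / sum(band_sums(sq))
    alt <- alternative_statistics(sp, sq)
    expect_equal(alt$xi1, brute_symmetric_kl(p, q, 1e-12), tolerance = 1e-10)
    expect_equal(alt$xi2, brute_ks(p, q), tolerance = 1e-10)
    vp <- band_total_variation(sp); vp <- vp / sum(vp)
    vq <- band_total_variation(sq); vq <- vq / sum(vq)
    expect_equal(1 / alt$rho1, brute_ks(vp, vq), tolerance = 1e-10)
    expect_equal(1 / responsiveness(sp, sq),
                 brute_symmetric_kl(vp, vq, 1e-12), tolerance = 1e-10)
  }
})

test_that("band total variation satisfies its contracts", {
  sp <- random_spectrogram(3, n_bands = 1, n_frames = 3)
  sp$X[1, ] <- c(2, 2, 2)
  expect_equal(band_total_variation(sp), 0)
  sp$X[1, ] <- c(0, 1, 0)
  expect_equal(band_total_variation(sp), 2)
  one_col <- random_spectrogram(4, n_bands = 3, n_frames = 1)
  expect_error(band_total_variation(one_col), class = "tfanet_stat_error")
})

test_that("noise suppression compares spectral centroids directionally", {
  sp <- random_spectrogram(8)
  expect_identical(noise_suppression(sp, sp), 1)
  shifted <- sp
  shifted$X <- rbind(sp$X[-1, ], 0)  # all power one band lower
  expect_gt(noise_suppression(sp, shifted), 1)
  raised <- sp
  raised$X <- rbind(0, sp$X[-nrow(sp$X), ])  # higher harmonics in output
  expect_lt(noise_suppression(sp, raised), 1)
  dead <- sp; dead$X[] <- 0
  expect_error(noise_suppression(sp, dead), class = "tfanet_degenerate_error")
})

test_that("responsiveness is capped at identity, symmetric, and matches a
           hand-computed two-bin divergence", {
  sp <- random_spectrogram(9)
  sq <- random_spectrogram(10)
  eps <- 1e-12
  expect_equal(responsiveness(sp, sp, eps), 1 / eps)
  expect_equal(responsiveness(sp, sq, eps), responsiveness(sq, sp, eps))
  # two bands with TV distributions (0.5, 0.5) and (0.9, 0.1)
  a <- random_spectrogram(11, n_bands = 2, n_frames = 2)
  a$X <- matrix(c(0, 0, 0.5, 0.5), 2, 2)   # TV = (0.5, 0.5)
  b <- a
  b$X <- matrix(c(0, 0, 0.9, 0.1), 2, 2)   # TV = (0.9, 0.1)
  d_hand <- 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1) +
    0.9 * log(0.9 / 0.5) + 0.1 * log(0.1 / 0.5)
  expect_equal(1 / responsiveness(a, b, eps), d_hand, tolerance = 1e-6)
})

test_that("alternative statistics hit their identity and disjoint extremes", {
  sp <- random_spectrogram(12)
  alt <- alternative_statistics(sp, sp)
  expect_equal(alt$xi1, 0, tolerance = 1e-9)
  expect_equal(alt$xi2, 0)
  expect_equal(alt$rho1, 1e12)
  a <- random_spectrogram(13, n_bands = 2, n_frames = 2)
  a$X <- matrix(c(1, 0, 2, 0), 2, 2)  # all mass in band 1
  b <- a
  b$X <- matrix(c(0, 1, 0, 2), 2, 2)  # all mass in band 2
  expect_equal(alternative_statistics(a, b)$xi2, 1)
})

test_that("analyze_pair composes the pipeline end to end", {
  s <- generate_stimulus(stimulus_config("block", seed = 14))
  idn <- analyze_pair(s, s)
  expect_equal(idn$xi, 1, tolerance = 1e-12)
  expect_equal(idn$xi1, 0, tolerance = 1e-9)
  expect_equal(idn$xi2, 0)
  expect_true(idn$rho_capped && idn$rho1_capped)
  other <- generate_stimulus(stimulus_config("block", seed = 15))
  expect_error(analyze_pair(s, other[-1, ]), class = "tfanet_stat_error")
})

test_that("smoothing raises xi and differentiation lowers it", {
  s <- generate_stimulus(stimulus_config("block", seed = 16))
  lo <- analyze_pair(s, smooth_first_order(s, tau = 100))
  expect_gt(lo$xi, 1)
  hi <- analyze_pair(s, signal_derivative(s))
  expect_lt(hi$xi, 1)
})
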