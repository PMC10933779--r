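test_that("spherical-harmonics fit recovers constants and single basis functions", {
  p <- make_ukb_protocol(seed = 7)
  dirs <- p$bvecs[p$shells[["1"]], ]
  # constant signal: spherical mean recovered, degree-2 coefficients zero
  C <- fit_sh_coefficients(rep(0.37, 50), dirs)
  expect_equal(degree_power(C, 0), 0.37, tolerance = 1e-10)
  expect_lt(max(abs(C[-1])), 1e-10)
  # a pure Y2,0 component comes back alone
  B <- real_sh_basis(dirs, 2)
  C2 <- fit_sh_coefficients(0.8 * B[, "l2m0"], dirs)
  expect_equal(unname(C2[["l2m0"]]), 0.8, tolerance = 1e-8)
  expect_lt(max(abs(C2[setdiff(names(C2), "l2m0")])), 1e-8)
  # underdetermined fit errors
  expect_error(fit_sh_coefficients(rep(1, 4), dirs[1:4, ]),
               "underdetermined")
})

test_that("degree powers match a brute-force sum and the l2 formula", {
  C <- c(l0m0 = 0.3, stats::setNames(stats::rnorm(5, sd = 0.2),
                                     paste0("l2m", -2:2)))
  expect_equal(degree_power(C, 2), sum(C[2:6]^2) / 5)
  expect_equal(degree_power(c(l0m0 = 1, l2m0 = 0.5,
                              stats::setNames(rep(0, 4),
                                              paste0("l2m", c(-2, -1, 1, 2)))),
                            2), 0.25 / 5)
  expect_equal(degree_power(C * 0, 2), 0)
})

test_that("the default protocol yields 5 summaries in the documented order", {
  p <- make_ukb_protocol(seed = 1)
  s <- simulate_signal(tissue_params(), p)
  y <- summarize_signal(s, p)
  expect_equal(names(y), c("b0_mean", "b1_mean", "b1_l2", "b2_mean",
                           "b2_l2"))
  expect_equal(length(y), 5L)
  expect_equal(attr(y, "types"), c("mean", "mean", "log", "mean", "log"))
  # means are non-negative for physical signals, l2 powers finite
  expect_true(all(y[c(1, 2, 4)] >= 0))
  expect_true(all(is.finite(y)))
})

test_that("a pure isotropic voxel has directional power at the floor", {
  p <- make_ukb_protocol(seed = 1)
  s <- simulate_signal(list(s_iso = 1, s_in = 0, s_ex = 0, d_iso = 3,
                            d_in_a = 1.7, d_ex_a = 1.7, tau = 0.5,
                            odi = 0.3), p)
  y <- summarize_signal(s, p)
  expect_equal(unname(y[["b1_mean"]]), exp(-3), tolerance = 1e-10)
  expect_lt(y[["b1_l2"]], log(1e-10))
  expect_lt(y[["b2_l2"]], log(1e-10))
})

test_that("summaries are invariant under joint rotation of bvecs and fibre", {
  p <- make_ukb_protocol(seed = 2)
  P <- sample_prior(sm_prior(), 1, seed = 31)
  mu0 <- c(0, 0, 1)
  y0 <- summarize_signal(
    drop(benchmri:::simulate_signal_batch(P, p, mu = mu0)), p)
  set.seed(42)
  worst <- 0
  for (r in 1:100) {
    R <- oracle_random_rotation()
    yr <- summarize_signal(
      drop(benchmri:::simulate_signal_batch(P, rotate_protocol(p, R),
                                            mu = drop(R %*% mu0))),
      rotate_protocol(p, R))
    worst <- max(worst, max(abs(yr - y0)))
  }
  expect_lt(worst, 1e-5)
})

test_that("normalising a pair by the baseline b0 mean behaves homogeneously", {
  p <- make_ukb_protocol(seed = 2)
  s <- simulate_signal(tissue_params(s_iso = 0.1, s_in = 0.5, s_ex = 0.4), p)
  y1 <- summarize_signal(2.4 * s, p)
  dy1 <- summarize_signal(2.4 * 1.05 * s, p) - y1
  n1 <- normalize_pair(y1, dy1)
  y2 <- summarize_signal(s, p)
  dy2 <- summarize_signal(1.05 * s, p) - y2
  n2 <- normalize_pair(y2, dy2)
  # scaling the raw signal leaves normalised mean coordinates unchanged
  mean_i <- attr(y1, "types") == "mean"
  expect_equal(n1$y[mean_i], n2$y[mean_i], tolerance = 1e-10)
  expect_equal(n1$dy[mean_i], n2$dy[mean_i], tolerance = 1e-10)
  # log coordinates are shifted by -2 log b0 in the baseline
  expect_equal(unname(n1$y[!mean_i] - (y1[!mean_i] - 2 * log(y1[[1]]))),
               c(0, 0))
  # b0_mean = 1 baseline (fractions sum to one): identity
  expect_equal(y2[[1]], 1, tolerance = 1e-12)
  n3 <- normalize_pair(y2, dy2)
  expect_equal(n3$y, y2, tolerance = 1e-10)
  expect_equal(n3$dy, dy2, tolerance = 1e-10)
  # zero change stays zero
  zero <- normalize_pair(y1, dy1 * 0)
  expect_equal(max(abs(zero$dy)), 0)
  expect_error(normalize_pair(c(-1, y1[-1]), dy1), "positive")
})

test_that("noise covariance of paired differences matches its analytic scale", {
  p <- make_ukb_protocol(seed = 3)
  s <- simulate_signal(tissue_params(), p)
  expect_equal(max(abs(estimate_noise_covariance(s, p, 0, seed = 1))), 0)
  Sn <- estimate_noise_covariance(s, p, 0.01, n_rep = 4000, seed = 5)
  expect_equal(Sn, t(Sn))
  ev <- eigen(Sn, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  # var of b0-mean difference: two means of 5 iid N(0, sigma^2) draws
  analytic <- 2 * 0.01^2 / 5
  expect_lt(abs(Sn[1, 1] - analytic) / analytic, 0.15)
})
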