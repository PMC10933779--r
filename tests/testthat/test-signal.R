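test_that("signal is the fraction-weighted sum of compartment attenuations", {
  p <- make_ukb_protocol(seed = 4)
  tp <- tissue_params(s_iso = 0.2, s_in = 0.5, s_ex = 0.3, odi = 0.25,
                      tau = 0.6)
  s <- simulate_signal(tp, p)
  # b = 0: all attenuations are 1, signal = sum of fractions
  expect_equal(unname(s[p$bvals == 0]), rep(1, 5), tolerance = 1e-12)
  # manual recombination from the exported attenuations
  manual <- 0.2 * attenuation_iso(p$bvals, 3) +
    0.5 * watson_stick_attenuation(p, 1.7, 0.25) +
    0.3 * watson_zeppelin_attenuation(p, 1.7, 0.6, 0.25)
  expect_equal(s, manual, tolerance = 1e-12)
  # all-zero fractions give a zero signal
  z <- simulate_signal(list(s_iso = 0, s_in = 0, s_ex = 0, d_iso = 3,
                            d_in_a = 1.7, d_ex_a = 1.7, tau = 0.5,
                            odi = 0.3), p)
  expect_equal(max(abs(z)), 0)
})

test_that("a pure isotropic voxel decays identically across directions", {
  p <- make_ukb_protocol(seed = 4)
  s <- simulate_signal(list(s_iso = 1, s_in = 0, s_ex = 0, d_iso = 3,
                            d_in_a = 1.7, d_ex_a = 1.7, tau = 0.5,
                            odi = 0.3), p)
  expect_equal(s, exp(-p$bvals * 3), tolerance = 1e-12)
  expect_lt(stats::sd(s[p$shells[["2"]]]), 1e-14)
})

test_that("batch and scalar forward models agree and rotation leaves signal invariant", {
  p <- make_ukb_protocol(seed = 5)
  P <- sample_prior(sm_prior(), 4, seed = 6)
  S <- benchmri:::simulate_signal_batch(P, p)
  for (i in 1:4)
    expect_equal(S[i, ], simulate_signal(as.list(P[i, ]), p),
                 tolerance = 1e-12)
  # joint rotation of bvecs and mu
  set.seed(9)
  R <- oracle_random_rotation()
  mu <- c(0.2, 0.6, sqrt(1 - 0.04 - 0.36))
  s1 <- benchmri:::simulate_signal_batch(P[1, , drop = FALSE], p, mu = mu)
  s2 <- benchmri:::simulate_signal_batch(P[1, , drop = FALSE],
                                         rotate_protocol(p, R),
                                         mu = drop(R %*% mu))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("prior sampling matches its declared marginals", {
  P <- sample_prior(sm_prior(), 1e5, seed = 21)
  # fractions sum to exactly one
  expect_equal(max(abs(rowSums(P[, c("s_iso", "s_in", "s_ex")]) - 1)), 0)
  # Beta(2, 5) mean 2/7 within 3 standard errors
  se_odi <- stats::sd(P[, "odi"]) / sqrt(nrow(P))
  expect_lt(abs(mean(P[, "odi"]) - 2 / 7), 3 * se_odi + 1e-4)
  # diffusivity normals centred at 3 and 1.7
  expect_lt(abs(mean(P[, "d_iso"]) - 3), 3 * 0.1 / sqrt(nrow(P)) + 1e-3)
  expect_lt(abs(mean(P[, "d_in_a"]) - 1.7), 3 * 0.3 / sqrt(nrow(P)) + 1e-2)
  expect_lt(abs(stats::sd(P[, "d_iso"]) - 0.1), 5e-3)
  # all samples satisfy the parameter invariants
  expect_true(all(P[, "odi"] > 0 & P[, "odi"] < 1))
  expect_true(all(P[, "tau"] >= 0 & P[, "tau"] <= 1))
  expect_true(all(P >= 0))
  # the s_iso delta/uniform mixture leaves a point mass at zero
  expect_gt(mean(P[, "s_iso"] == 0), 0.4)
  # reproducibility
  expect_identical(sample_prior(sm_prior(), 50, seed = 3),
                   sample_prior(sm_prior(), 50, seed = 3))
})

test_that("additive noise has the declared scale and is seed-stable", {
  s <- rep(0.5, 1e5)
  expect_identical(add_noise(s, 0), s)
  n1 <- add_noise(s, 0.01, seed = 4)
  expect_identical(n1, add_noise(s, 0.01, seed = 4))
  expect_lt(abs(stats::sd(n1 - s) - 0.01), 3 * 0.01 / sqrt(2 * length(s)))
  expect_error(add_noise(s, -1), "non-negative")
})

test_that("constrained model fixes diffusivities and ties tortuosity", {
  th <- c(s_iso = 0.1, s_in = 0.6, s_ex = 0.3, odi = 0.2)
  P <- constrained_to_standard(th)
  expect_equal(unname(P[1, c("d_iso", "d_in_a", "d_ex_a")]), c(3, 1.7, 1.7))
  expect_equal(unname(P[1, "tau"]), 0.6 / 0.9)
  expect_equal(length(constrained_param_names()), 4L)
  expect_equal(length(sm_param_names()), 8L)
})
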