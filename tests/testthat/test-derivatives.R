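test_that("patterns are unit vectors aligned with single parameters", {
  pats <- single_param_patterns("standard")
  expect_equal(length(pats), 8L)
  expect_equal(names(pats), sm_param_names())
  for (p in pats) {
    expect_equal(sum(p$vec^2), 1)
    expect_equal(sum(p$vec != 0), 1L)
  }
  expect_equal(length(single_param_patterns("constrained")), 4L)
  cp <- change_pattern("both", c(3, 4, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(cp$vec[1:2]), c(0.6, 0.8))
  expect_error(change_pattern("bad", rep(0, 8)), "non-zero")
})

test_that("b0-mean derivative of a fraction change is exactly one", {
  p <- make_ukb_protocol(seed = 3)
  # pure iso / pure stick mixture
  v <- c(s_iso = 0.5, s_in = 0.5, s_ex = 0, d_iso = 3, d_in_a = 1.7,
         d_ex_a = 1.7, tau = 0.5, odi = 0.3)
  g <- directional_derivative(as.list(v), single_param_patterns()$s_iso, p)
  expect_equal(unname(g[["b0_mean"]]), 1, tolerance = 1e-6)
})

test_that("a parameter absent from the signal has zero derivative", {
  p <- make_ukb_protocol(seed = 3)
  v <- c(s_iso = 0, s_in = 0.6, s_ex = 0.4, d_iso = 3, d_in_a = 1.7,
         d_ex_a = 1.7, tau = 0.5, odi = 0.3)
  g <- directional_derivative(as.list(v), single_param_patterns()$d_iso, p)
  expect_lt(max(abs(g)), 1e-8)
})

test_that("finite differences are first-order consistent (Richardson)", {
  p <- make_ukb_protocol(seed = 3)
  v <- c(s_iso = 0.2, s_in = 0.5, s_ex = 0.3, d_iso = 3, d_in_a = 1.6,
         d_ex_a = 1.8, tau = 0.4, odi = 0.25)
  pat <- single_param_patterns()$d_in_a
  g1 <- directional_derivative(as.list(v), pat, p, rel_step = 1e-3)
  g2 <- directional_derivative(as.list(v), pat, p, rel_step = 5e-4)
  g3 <- directional_derivative(as.list(v), pat, p, rel_step = 2.5e-4)
  # central differences: error ~ t^2, so successive refinements converge
  e12 <- max(abs(g1 - g2)); e23 <- max(abs(g2 - g3))
  expect_lt(e23, e12)
  expect_lt(max(abs(g3 - g2)) / max(abs(g3)), 1e-4)
})

test_that("boundary samples fall back to one-sided differences", {
  p <- make_ukb_protocol(seed = 3)
  # s_iso = 0 sits on the boundary: forward difference must engage
  v <- c(s_iso = 0, s_in = 0.6, s_ex = 0.4, d_iso = 3, d_in_a = 1.7,
         d_ex_a = 1.7, tau = 0.5, odi = 0.3)
  g <- directional_derivative(as.list(v), single_param_patterns()$s_iso, p)
  expect_true(all(is.finite(g)))
  expect_equal(unname(g[["b0_mean"]]), 1, tolerance = 1e-5)
})

test_that("training sets are reproducible and have unit baseline b0", {
  p <- make_ukb_protocol(seed = 3)
  pat <- single_param_patterns()$s_ex
  ts1 <- build_training_set(sm_prior(), pat, p, n = 50, seed = 17)
  ts2 <- build_training_set(sm_prior(), pat, p, n = 50, seed = 17)
  expect_identical(ts1$y, ts2$y)
  expect_identical(ts1$g, ts2$g)
  expect_lt(max(abs(ts1$y[, "b0_mean"] - 1)), 1e-12)
  expect_true(all(is.finite(ts1$g)))
  expect_equal(ncol(ts1$y), ncol(ts1$g))
})

test_that("the component-reuse fast path matches the general finite-difference path", {
  p <- make_ukb_protocol(n_dir_per_shell = 12, n_b0 = 2, seed = 8)
  for (model in c("standard", "constrained")) {
    prior <- if (model == "standard") sm_prior() else constrained_prior()
    P <- sample_prior(prior, 40, seed = 23)
    for (pat in single_param_patterns(model)) {
      g_fast <- benchmri:::derivative_batch_single(P, pat$name, p, model,
                                                   1e-4, 2, c(0, 0, 1))
      g_gen <- benchmri:::derivative_batch_general(P, pat, p, model,
                                                   1e-4, 2, c(0, 0, 1))
      expect_equal(g_fast, g_gen, tolerance = 1e-6,
                   label = paste(model, pat$name))
    }
  }
})
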