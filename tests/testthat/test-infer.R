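# A tiny hand-built change model with known weights, used to probe the
# inference layer without any training.
toy_change_model <- function(mu_w, theta, d = 2) {
  ci <- benchmri:::chol_index(d)
  structure(list(
    w_mu = matrix(mu_w, 1, d), w_sigma = matrix(theta, 1, ci$q),
    mean_degree = 0, cov_degree = 0, cross = TRUE,
    center = rep(0, d), scale = rep(1, d), active = rep(TRUE, d),
    d = d, n_train = 0,
    pattern = change_pattern("toy", c(1, rep(0, 7))),
    nll = c(warm_start = 0, bfgs = 0, polish = 0), layout = NULL),
    class = "bench_change_model")
}

test_that("the amount-conditional likelihood matches a dense Gaussian oracle", {
  set.seed(23)
  m <- toy_change_model(c(0.6, -0.2), c(log(0.3), 0.1, log(0.2)))
  Sn <- matrix(c(0.02, 0.005, 0.005, 0.03), 2, 2)
  y <- c(0.5, 0.4)
  for (r in 1:20) {
    dy <- stats::rnorm(2, sd = 0.3)
    a <- stats::runif(1, 0.01, 1)
    pr <- predict(m, y)
    l_or <- oracle_mvn_logdensity(dy, a * pr$mu, a^2 * pr$sigma + Sn)
    l_im <- likelihood_at_amount(dy, y, m, a, Sn, log = TRUE)
    expect_lt(abs(l_or - l_im), 1e-10)
    # grid route agrees with the direct route
    l_grid <- benchmri:::loglik_amount_grid(dy, pr$mu, pr$sigma, Sn, a)
    expect_lt(abs(l_grid - l_im), 1e-10)
  }
  # amount -> 0 approaches the no-change likelihood
  l0 <- likelihood_at_amount(c(0.1, 0), y, m, 1e-12, Sn, log = TRUE)
  expect_lt(abs(l0 - oracle_mvn_logdensity(c(0.1, 0), c(0, 0), Sn)), 1e-6)
  # the density peaks over dy at dy = a * mu
  a <- 0.4
  pr <- predict(m, y)
  peak <- likelihood_at_amount(a * pr$mu, y, m, a, Sn)
  expect_gt(peak, likelihood_at_amount(a * pr$mu + c(0.05, 0), y, m, a, Sn))
  # total covariance singular only when both terms vanish
  expect_error(likelihood_at_amount(c(0, 0), y, m, 0, matrix(0, 2, 2)),
               "singular")
})

test_that("marginal likelihood converges on grid refinement and matches Monte Carlo", {
  set.seed(24)
  m <- toy_change_model(c(0.6, -0.2), c(log(0.3), 0.1, log(0.2)))
  Sn <- matrix(c(0.02, 0.005, 0.005, 0.03), 2, 2)
  prior <- amount_prior(0.1, 1)
  y <- c(0.5, 0.4)
  n_mc <- 2e5
  for (r in 1:50) {
    dy <- stats::rnorm(2, sd = 0.2)
    q <- marginal_likelihood(dy, y, m, Sn, prior)
    q2 <- marginal_likelihood(dy, y, m, Sn, prior, n_grid = 256)
    expect_lt(abs(q2 - q) / q2, 1e-3)      # 0.1% self-convergence
    amounts <- stats::rlnorm(n_mc, prior$meanlog, prior$sdlog)
    vals <- exp(benchmri:::loglik_amount_grid(dy, predict(m, y)$mu,
                                              predict(m, y)$sigma, Sn,
                                              amounts))
    mc <- mean(vals); se <- stats::sd(vals) / sqrt(n_mc)
    expect_lt(abs(q - mc), 3 * se + 1e-12)
  }
})

test_that("posteriors normalise and favour the generating pattern", {
  m1 <- toy_change_model(c(1, 0), c(log(0.05), 0, log(0.05)))
  m2 <- toy_change_model(c(0, 1), c(log(0.05), 0, log(0.05)))
  models <- structure(list(models = list(p1 = m1, p2 = m2),
                           model = "standard",
                           param_names = sm_param_names(),
                           protocol_hash = "x", layout = NULL,
                           meta = list()), class = "bench_models")
  Sn <- diag(1e-5, 2)
  y <- c(0, 0)
  # dy along pattern 1's mean with tiny noise: p1 wins decisively
  post <- posterior_over_models(c(0.12, 0), y, models, Sn)
  expect_equal(sum(post$prob), 1, tolerance = 1e-10)
  expect_true(all(post$prob >= 0))
  expect_gt(post$prob[["p1"]], 0.99)
  expect_equal(post$winner, "p1")
  # dy = 0 with unit noise: no-change dominates spread-out alternatives
  post0 <- posterior_over_models(c(0, 0), y, models, diag(1, 2))
  expect_equal(post0$winner, "no_change")
  expect_gt(post0$prob[["no_change"]], 1 / 3)
})

test_that("the MAP amount recovers a constructed true amount and shrinks sanely", {
  m <- toy_change_model(c(1, 0.5), c(log(1e-4), 0, log(1e-4)))
  Sn <- diag(1e-6, 2)
  y <- c(0, 0)
  t_true <- 0.12
  pr <- amount_prior(0.1, 1)
  res <- infer_amount(t_true * predict(m, y)$mu, y, m, Sn, pr)
  expect_lt(abs(res$map - t_true) / t_true, 0.02)
  expect_lt(abs(res$expected - t_true) / t_true, 0.05)
  expect_false(res$flat)
  # rescaling dy and the noise sd jointly moves the MAP consistently
  res2 <- infer_amount(2 * t_true * predict(m, y)$mu, y, m, 4 * Sn, pr)
  expect_lt(abs(res2$map - 2 * t_true) / (2 * t_true), 0.05)
  # a prior far below the signal scale pulls the MAP down
  res_low <- infer_amount(t_true * predict(m, y)$mu, y, m,
                          diag(0.02, 2), amount_prior(0.001, 0.5))
  expect_lt(res_low$map, res$map)
})

test_that("voxelwise inference is consistent, order-stable and NA-safe", {
  m1 <- toy_change_model(c(1, 0), c(log(0.1), 0, log(0.1)))
  m2 <- toy_change_model(c(0, 1), c(log(0.1), 0, log(0.1)))
  models <- structure(list(models = list(p1 = m1, p2 = m2),
                           model = "standard",
                           param_names = sm_param_names(),
                           protocol_hash = "x", layout = NULL,
                           meta = list()), class = "bench_models")
  Sn <- diag(0.001, 2)
  Y <- rbind(c(0, 0), c(0.1, 0.1), c(NA, 0))
  DY <- rbind(c(0.1, 0), c(0, 0.1), c(0, 0))
  res <- infer_voxelwise(Y, DY, Sn, models)
  single <- posterior_over_models(DY[1, ], Y[1, ], models, Sn)
  expect_equal(res$prob[1, ], single$prob, tolerance = 1e-12)
  expect_equal(res$winner[1], single$winner)
  # permuting voxels permutes outputs
  res_p <- infer_voxelwise(Y[c(2, 1, 3), ], DY[c(2, 1, 3), ], Sn, models)
  expect_equal(res_p$prob[2, ], res$prob[1, ])
  # masked/missing voxel comes back NA and is recorded
  expect_true(all(is.na(res$prob[3, ])))
  expect_equal(res$failures, 3L)
})
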