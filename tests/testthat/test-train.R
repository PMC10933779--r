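test_that("the analytic likelihood gradient matches finite differences", {
  set.seed(13)
  n <- 300; d <- 3
  y <- matrix(stats::rnorm(n * 4), n, 4)
  g <- matrix(stats::rnorm(n * d), n, d)
  ci <- benchmri:::chol_index(d)
  Fm <- polynomial_design(y, 2); Fs <- polynomial_design(y, 1)
  par <- stats::rnorm(ncol(Fm) * d + ncol(Fs) * ci$q) * 0.3
  ga <- benchmri:::nll_grad(par, Fm, Fs, g, ci)
  h <- 1e-6
  idx <- sample(length(par), 25)
  for (i in idx) {
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    gn <- (benchmri:::nll_value(pp, Fm, Fs, g, ci) -
             benchmri:::nll_value(pm, Fm, Fs, g, ci)) / (2 * h)
    expect_lt(abs(ga[i] - gn) / (abs(gn) + 1), 1e-5)
  }
})

test_that("MLE recovers a linear-Gaussian generator within Monte-Carlo error", {
  set.seed(14)
  n <- 20000; d <- 2
  y <- matrix(stats::runif(n * 2), n, 2)
  A <- c(0.5, -0.3)
  B <- matrix(c(1, 2, -1, 0.5), 2, 2)
  C <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2)
  L <- t(chol(C))
  g <- t(A + B %*% t(y)) + t(L %*% matrix(stats::rnorm(n * 2), 2, n))
  fit <- fit_change_model(y, g, mean_degree = 1, cov_degree = 1)
  # NLL is non-increasing across optimiser stages
  expect_true(all(diff(fit$nll) <= 1e-8))
  yc <- colMeans(y)
  pred <- predict(fit, yc)
  truth_mu <- A + drop(B %*% yc)
  # 3 SE of the conditional mean at the centroid
  se_mu <- sqrt(diag(C) / n) * 3
  expect_true(all(abs(pred$mu - truth_mu) < 3 * se_mu + 0.01))
  # covariance recovered at the centroid (element-wise ~ 3 SE of a
  # sample covariance at n draws)
  se_cov <- 3 * sqrt((diag(C) %o% diag(C) + C^2) / n)
  expect_true(all(abs(pred$sigma - C) < se_cov + 0.003))
  expect_true(all(eigen(pred$sigma, only.values = TRUE)$values > 0))
})

test_that("with constant covariance the MLE mean equals ordinary least squares", {
  set.seed(15)
  n <- 4000
  y <- matrix(stats::runif(n * 2, -1, 1), n, 2)
  W_true <- stats::rnorm(6 * 2)
  Fm <- polynomial_design(scale(y), 2)[, 1:6]  # quadratic, pure + cross
  g <- matrix(stats::rnorm(n * 2, sd = 0.05), n, 2)
  fit <- fit_change_model(y, g, mean_degree = 2, cov_degree = 0)
  # OLS oracle on the model's own standardised design
  ys <- sweep(sweep(y, 2, fit$center), 2, fit$scale, "/")
  D <- polynomial_design(ys, 2)
  W_ols <- qr.solve(D, g)
  expect_lt(max(abs(fit$w_mu - W_ols)), 1e-4)
})

test_that("scalar (1-D) fits match the closed-form Gaussian MLE", {
  set.seed(16)
  n <- 3000
  y <- matrix(stats::runif(n), n, 1)
  g <- matrix(2 + 3 * y + stats::rnorm(n, sd = 0.2), n, 1)
  fit <- fit_change_model(y, g, mean_degree = 1, cov_degree = 0)
  ys <- (y - fit$center) / fit$scale
  D <- cbind(1, ys)
  beta <- qr.solve(D, g)            # OLS = MLE mean
  resid <- g - D %*% beta
  sigma2 <- mean(resid^2)           # MLE variance (1/n)
  expect_lt(max(abs(fit$w_mu - beta)), 1e-4)
  pred <- predict(fit, y[1, ])
  expect_lt(abs(drop(pred$sigma) - sigma2) / sigma2, 1e-3)
})

test_that("prediction is deterministic, SPD, and shape-checked", {
  set.seed(17)
  y <- matrix(stats::runif(600 * 2), 600, 2)
  g <- y + matrix(stats::rnorm(1200, sd = 0.1), 600, 2)
  fit <- fit_change_model(y, g, mean_degree = 1, cov_degree = 1)
  p1 <- predict(fit, c(0.4, 0.6))
  p2 <- predict(fit, c(0.4, 0.6))
  expect_identical(p1, p2)
  expect_gt(min(eigen(p1$sigma, only.values = TRUE)$values), 0)
  expect_error(predict(fit, c(1, 2, 3)), "dimension")
  # binned empirical check: mean derivative near a narrow y-bin
  bin <- which(abs(y[, 1] - 0.4) < 0.05 & abs(y[, 2] - 0.6) < 0.05)
  emp <- colMeans(g[bin, , drop = FALSE])
  se <- apply(g[bin, , drop = FALSE], 2, stats::sd) / sqrt(length(bin))
  expect_true(all(abs(p1$mu - emp) < 3 * se + 0.05))
})

test_that("underpowered training sets are rejected", {
  y <- matrix(stats::runif(100 * 5), 100, 5)
  g <- y
  expect_error(fit_change_model(y, g), "at least 10 samples")
})

test_that("change models round-trip through disk bit-exactly", {
  p <- make_ukb_protocol(n_dir_per_shell = 12, n_b0 = 2, seed = 5)
  prior <- constrained_prior()
  models <- train_change_models(prior, p, n = 800, seed = 19,
                                mean_degree = 1, cov_degree = 0)
  tf <- tempfile(fileext = ".json")
  save_change_models(models, tf)
  back <- load_change_models(tf, protocol = p)
  y0 <- c(1, 0.5, -4.5, 0.3, -4.4)
  pr1 <- predict(models$models$s_in, y0)
  pr2 <- predict(back$models$s_in, y0)
  expect_identical(pr1$mu, pr2$mu)
  expect_identical(pr1$sigma, pr2$sigma)
  # tampered files are refused
  txt <- readLines(tf)
  txt <- sub("\"n\":800", "\"n\":801", txt, fixed = TRUE)
  tf2 <- tempfile(fileext = ".json")
  writeLines(txt, tf2)
  ser <- jsonlite::read_json(tf)
  ser$models[[1]]$w_mu[[1]][[1]] <- 999
  jsonlite::write_json(ser, tf2, digits = NA, auto_unbox = TRUE)
  expect_error(load_change_models(tf2), "integrity")
  # wrong protocol is refused
  p2 <- make_ukb_protocol(n_dir_per_shell = 12, n_b0 = 2, seed = 6)
  expect_error(load_change_models(tf, protocol = p2),
               "different acquisition")
  expect_error(load_change_models(tempfile()), "not found")
})
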