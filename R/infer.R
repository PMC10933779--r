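#' Log-normal prior over the amount of change
#'
#' The pattern of change fixes the direction of a parameter change; its
#' (positive) amount gets a log-normal prior so that changes across
#' several orders of magnitude remain plausible.
#'
#' @param median median of the amount (location `exp(meanlog)`), default
#'   0.1 in native parameter units.
#' @param sdlog log-scale standard deviation (> 0), default 1.
#' @return Object of class `amount_prior`.
#' @export
amount_prior <- function(median = 0.1, sdlog = 1) {
  if (sdlog <= 0) stop("sdlog must be positive")
  if (median <= 0) stop("median must be positive")
  structure(list(meanlog = log(median), sdlog = sdlog),
            class = "amount_prior")
}

# Deterministic log-spaced quadrature grid spanning the prior's
# 0.01%-99.99% quantiles (the truncated tail mass, 2e-4, is below the
# quadrature's accuracy target); trapezoid weights in x = log(amount).
amount_quadrature <- function(prior, n_grid = 128) {
  x <- seq(stats::qnorm(1e-4, prior$meanlog, prior$sdlog),
           stats::qnorm(1 - 1e-4, prior$meanlog, prior$sdlog),
           length.out = n_grid)
  dx <- x[2] - x[1]
  w <- rep(dx, n_grid); w[c(1, n_grid)] <- dx / 2
  list(x = x, a = exp(x), logw = log(w))
}

# Gaussian log-density with covariance Sigma (stable, via Cholesky).
mvn_logdensity <- function(x, mean, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("singular covariance in likelihood evaluation"))
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi)) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

#' Likelihood of an observed summary change at a given amount of change
#'
#' Evaluates N(dy; a * mu(y), a^2 * Sigma(y) + Sigma_n) where (mu, Sigma)
#' is the derivative distribution predicted by the change model at the
#' baseline y, a is the amount of change, and Sigma_n the measurement
#' noise covariance. As a -> 0 this approaches the no-change likelihood
#' N(dy; 0, Sigma_n).
#'
#' @param dy observed change in the summary vector.
#' @param y baseline summary vector.
#' @param model a fitted `bench_change_model`.
#' @param amount amount of change (scalar or vector, > 0).
#' @param Sigma_n noise covariance matrix.
#' @param log return the log-density (default FALSE).
#' @return Density value(s), one per amount.
#' @export
likelihood_at_amount <- function(dy, y, model, amount, Sigma_n,
                                 log = FALSE) {
  if (any(amount < 0)) stop("amount must be non-negative")
  pr <- predict(model, y)
  ld <- vapply(amount, function(a)
    mvn_logdensity(dy, a * pr$mu, a^2 * pr$sigma + Sigma_n), numeric(1))
  if (log) ld else exp(ld)
}

# Vectorised log-likelihood over a grid of amounts via simultaneous
# whitening: with Sigma_n = Ln Ln' and B = Ln^-1 Sigma Ln^-T = Q diag(lam) Q',
# the total covariance a^2 Sigma + Sigma_n has log-determinant
# logdet(Sigma_n) + sum(log(1 + a^2 lam)) and a diagonal quadratic form.
loglik_amount_grid <- function(dy, mu, Sigma, Sigma_n, amounts) {
  d <- length(dy)
  Ln <- t(tryCatch(chol(Sigma_n), error = function(e)
    stop("noise covariance is not positive definite")))
  zd <- forwardsolve(Ln, dy)
  zm <- forwardsolve(Ln, mu)
  A1 <- forwardsolve(Ln, Sigma)
  B <- t(forwardsolve(Ln, t(A1)))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  dt <- drop(crossprod(e$vectors, zd))
  mt <- drop(crossprod(e$vectors, zm))
  logdet_n <- 2 * sum(log(diag(Ln)))
  vapply(amounts, function(a) {
    den <- 1 + a^2 * lam
    -0.5 * (d * log(2 * pi) + logdet_n + sum(log(den)) +
              sum((dt - a * mt)^2 / den))
  }, numeric(1))
}

#' Marginal likelihood of an observed change under one pattern
#'
#' Integrates the amount-conditional likelihood over the log-normal
#' amount prior by deterministic trapezoid quadrature on a log-spaced
#' grid (the grid spans the prior's 0.1%-99.9% quantiles). All
#' accumulation happens in log space.
#'
#' @inheritParams likelihood_at_amount
#' @param prior an [amount_prior()].
#' @param n_grid number of quadrature nodes (default 128).
#' @param log return the log marginal likelihood.
#' @return Scalar marginal likelihood (or its log).
#' @export
marginal_likelihood <- function(dy, y, model, Sigma_n, prior = amount_prior(),
                                n_grid = 128, log = FALSE) {
  qd <- amount_quadrature(prior, n_grid)
  pr <- predict(model, y)
  ll <- loglik_amount_grid(dy, pr$mu, pr$sigma, Sigma_n, qd$a)
  lp <- stats::dlnorm(qd$a, prior$meanlog, prior$sdlog, log = TRUE)
  terms <- qd$logw + qd$x + lp + ll   # + x: Jacobian da = a dx
  out <- logsumexp(terms)
  if (!is.finite(out)) stop("marginal-likelihood quadrature is not finite")
  if (log) out else exp(out)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Posterior over patterns of change
#'
#' Computes the posterior probability that each hypothesised pattern of
#' change (or no change at all) explains the observed change in summary
#' measures, with a uniform prior over the models. The no-change model
#' has likelihood N(dy; 0, Sigma_n).
#'
#' @param dy observed change in the summary vector.
#' @param y baseline summary vector.
#' @param models a `bench_models` collection from
#'   [train_change_models()].
#' @param Sigma_n noise covariance matrix.
#' @param prior an [amount_prior()].
#' @param n_grid quadrature nodes for the amount marginalisation.
#' @return Object of class `bench_posterior`: posterior probabilities
#'   (no-change first, then the patterns in registration order), log
#'   marginal likelihoods, winning model, and per-pattern MAP/expected
#'   amounts of change.
#' @export
posterior_over_models <- function(dy, y, models, Sigma_n,
                                  prior = amount_prior(), n_grid = 128) {
  stopifnot(inherits(models, "bench_models"))
  lm_nochange <- mvn_logdensity(dy, numeric(length(dy)), Sigma_n)
  lmls <- vapply(models$models, function(m)
    marginal_likelihood(dy, y, m, Sigma_n, prior, n_grid, log = TRUE),
    numeric(1))
  logp <- c(no_change = lm_nochange, lmls)
  if (all(!is.finite(logp)))
    stop("all model likelihoods underflowed")
  probs <- exp(logp - logsumexp(logp))
  probs <- probs / sum(probs)
  amounts <- lapply(models$models, function(m)
    infer_amount(dy, y, m, Sigma_n, prior, n_grid))
  winner <- names(probs)[which.max(probs)]  # deterministic: first max wins
  structure(list(prob = probs, log_marginal = logp, winner = winner,
                 amounts = data.frame(
                   pattern = names(models$models),
                   map = vapply(amounts, `[[`, numeric(1), "map"),
                   expected = vapply(amounts, `[[`, numeric(1), "expected"),
                   row.names = NULL)),
            class = "bench_posterior")
}

#' @export
print.bench_posterior <- function(x, ...) {
  cat("Posterior over patterns of change:\n")
  p <- sort(x$prob, decreasing = TRUE)
  for (i in seq_along(p))
    cat(sprintf("  %-10s %6.4f%s\n", names(p)[i], p[i],
                if (names(p)[i] == x$winner) "  <- winner" else ""))
  invisible(x)
}

#' Posterior amount of change for one pattern
#'
#' Maximum a posteriori and expected amount of change under
#' P(amount | dy, y, pattern) (proportional to the amount-conditional
#' likelihood times the log-normal prior), computed on the quadrature
#' grid with a local golden-section refinement of the MAP.
#'
#' @inheritParams marginal_likelihood
#' @return `list(map, expected, flat)`; `flat` is `TRUE` when the
#'   posterior is essentially constant over the grid (MAP unreliable).
#' @export
infer_amount <- function(dy, y, model, Sigma_n, prior = amount_prior(),
                         n_grid = 128) {
  qd <- amount_quadrature(prior, n_grid)
  pr <- predict(model, y)
  ll <- loglik_amount_grid(dy, pr$mu, pr$sigma, Sigma_n, qd$a)
  lpost <- ll + stats::dlnorm(qd$a, prior$meanlog, prior$sdlog, log = TRUE)
  k <- which.max(lpost)
  lo <- qd$x[max(1, k - 1)]; hi <- qd$x[min(n_grid, k + 1)]
  opt <- stats::optimize(function(x) {
    a <- exp(x)
    loglik_amount_grid(dy, pr$mu, pr$sigma, Sigma_n, a) +
      stats::dlnorm(a, prior$meanlog, prior$sdlog, log = TRUE)
  }, c(lo, hi), maximum = TRUE, tol = 1e-8)
  # posterior expectation of the amount via the same quadrature
  terms <- qd$logw + qd$x + lpost
  norm <- logsumexp(terms)
  expected <- exp(logsumexp(terms + qd$x) - norm)
  flat <- diff(range(lpost)) < 1e-3
  list(map = exp(opt$maximum), expected = expected, flat = flat)
}

#' Voxelwise inference over maps of summaries
#'
#' Applies [posterior_over_models()] independently to each voxel. Voxels
#' with missing inputs, or where inference fails, yield `NA` outputs and
#' are recorded rather than aborting the run.
#'
#' @param Y n_voxel x d matrix of baseline summary vectors.
#' @param DY n_voxel x d matrix of observed changes.
#' @param Sigma_n one d x d matrix shared by all voxels, or a
#'   d x d x n_voxel array.
#' @param models a `bench_models` collection.
#' @param prior an [amount_prior()].
#' @param n_grid quadrature nodes.
#' @return A list with `prob` (n_voxel x n_model matrix), `winner`
#'   (character), `map_amount` (n_voxel x n_pattern matrix) and
#'   `failures` (integer indices of failed voxels).
#' @export
infer_voxelwise <- function(Y, DY, Sigma_n, models, prior = amount_prior(),
                            n_grid = 128) {
  Y <- as.matrix(Y); DY <- as.matrix(DY)
  nv <- nrow(Y)
  model_names <- c("no_change", names(models$models))
  prob <- matrix(NA_real_, nv, length(model_names),
                 dimnames = list(NULL, model_names))
  map_amount <- matrix(NA_real_, nv, length(models$models),
                       dimnames = list(NULL, names(models$models)))
  winner <- rep(NA_character_, nv)
  failures <- integer(0)
  for (v in seq_len(nv)) {
    if (anyNA(Y[v, ]) || anyNA(DY[v, ])) { failures <- c(failures, v); next }
    Sn <- if (length(dim(Sigma_n)) == 3) Sigma_n[, , v] else Sigma_n
    res <- tryCatch(
      posterior_over_models(DY[v, ], Y[v, ], models, Sn, prior, n_grid),
      error = function(e) NULL)
    if (is.null(res)) { failures <- c(failures, v); next }
    prob[v, ] <- res$prob[model_names]
    map_amount[v, ] <- res$amounts$map
    winner[v] <- res$winner
  }
  list(prob = prob, winner = winner, map_amount = map_amount,
       failures = failures)
}
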