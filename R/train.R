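# Heteroscedastic Gaussian regression of derivative distributions:
# g_i | y_i ~ N(F(y_i) W, T(G(y_i) V)) with T the Cholesky-vector map.
# The negative log-likelihood and its analytic gradient are fully
# vectorised across samples (per-sample triangular solves unrolled over
# the d <= 5 summary coordinates).

# Feature augmentation for log-power summary coordinates: the derivative
# of log(y_2) with respect to a signal fraction scales with the inverse
# root power exp(-l2 / 2), which no low-order polynomial in l2 can track
# across its range. Appending that transform (winsorised against the
# near-isotropic tail, where the log power is tiny and its derivative
# explodes) lets the quadratic design capture it.
augment_features <- function(Y, log_cols, clip = 60) {
  if (!length(log_cols)) return(Y)
  aug <- pmin(exp(-Y[, log_cols, drop = FALSE] / 2), clip)
  colnames(aug) <- paste0("invroot", seq_along(log_cols))
  cbind(Y, aug)
}

nll_parts <- function(par, Fm, Fs, g, ci) {
  n <- nrow(g); d <- ncol(g)
  p <- ncol(Fm); ps <- ncol(Fs); q <- ci$q
  W <- matrix(par[seq_len(p * d)], p, d)
  V <- matrix(par[p * d + seq_len(ps * q)], ps, q)
  theta <- Fs %*% V                       # n x q
  r <- g - Fm %*% W                       # n x d
  IDX <- matrix(0L, d, d)
  IDX[cbind(ci$i, ci$j)] <- seq_len(q)
  Ldiag <- exp(theta[, IDX[cbind(1:d, 1:d)], drop = FALSE])  # n x d
  u <- matrix(0, n, d)
  for (i in seq_len(d)) {
    acc <- r[, i]
    if (i > 1) for (j in seq_len(i - 1))
      acc <- acc - theta[, IDX[i, j]] * u[, j]
    u[, i] <- acc / Ldiag[, i]
  }
  list(W = W, V = V, theta = theta, r = r, u = u, Ldiag = Ldiag, IDX = IDX,
       n = n, d = d, p = p, ps = ps, q = q)
}

nll_value <- function(par, Fm, Fs, g, ci) {
  z <- nll_parts(par, Fm, Fs, g, ci)
  diag_cols <- z$IDX[cbind(seq_len(z$d), seq_len(z$d))]
  0.5 * z$n * z$d * log(2 * pi) + sum(z$theta[, diag_cols]) +
    0.5 * sum(z$u^2)
}

nll_grad <- function(par, Fm, Fs, g, ci) {
  z <- nll_parts(par, Fm, Fs, g, ci)
  d <- z$d
  w <- matrix(0, z$n, d)                  # w = L^{-T} u
  for (i in rev(seq_len(d))) {
    acc <- z$u[, i]
    if (i < d) for (j in seq.int(i + 1L, d))
      acc <- acc - z$theta[, z$IDX[j, i]] * w[, j]
    w[, i] <- acc / z$Ldiag[, i]
  }
  Dtheta <- matrix(0, z$n, z$q)
  for (kk in seq_len(z$q)) {
    i <- ci$i[kk]; j <- ci$j[kk]
    Dtheta[, kk] <- if (i == j) 1 - w[, i] * z$u[, i] * z$Ldiag[, i]
                    else -w[, i] * z$u[, j]
  }
  gW <- -crossprod(Fm, w)                 # p x d
  gV <- crossprod(Fs, Dtheta)             # ps x q
  c(as.vector(gW), as.vector(gV))
}

#' Fit a change model by maximum likelihood
#'
#' Fits the per-pattern regression model for the distribution of
#' directional derivatives of the summary measures: given training pairs
#' (y, g) the derivative is modelled as Gaussian with mean `F(y) w_mu`
#' (polynomial design of degree `mean_degree`) and covariance
#' `T(F(y) w_sigma)` where T rebuilds a positive-definite matrix from the
#' log-Cholesky vector (see [covariance_from_vector()]). Weights are
#' estimated by maximising the joint likelihood with a BFGS stage started
#' from an ordinary-least-squares warm start (covariance fixed at the
#' pooled residual covariance), followed by a Nelder-Mead polish; the best
#' stage is kept.
#'
#' @param y n x d matrix of baseline summary vectors (or a training set
#'   list from [build_training_set()], in which case `g` is taken from
#'   it).
#' @param g n x d matrix of directional derivatives.
#' @param mean_degree polynomial degree of the mean regression (default
#'   2, full quadratic with cross terms).
#' @param cov_degree polynomial degree of the covariance regression
#'   (default 1; 0 fits a constant covariance).
#' @param cross include cross terms in degree-2 designs.
#' @param maxit BFGS iteration cap.
#' @param augment append inverse-root-power transforms of log-type
#'   summary coordinates (columns named `*_l2`) to the features before
#'   the polynomial expansion; the derivative of a log power with
#'   respect to a signal fraction scales with exactly that transform, so
#'   this markedly reduces surrogate misfit. Ignored when no log-type
#'   columns are present.
#' @return An object of class `bench_change_model` with weight matrices
#'   `w_mu`, `w_sigma`, the design specification, input standardisation
#'   constants, and the negative log-likelihood trace across stages.
#' @export
fit_change_model <- function(y, g = NULL, mean_degree = 2, cov_degree = 1,
                             cross = TRUE, maxit = 400, augment = FALSE) {
  pattern <- NULL
  if (is.list(y) && !is.null(y$y)) {
    pattern <- y$pattern; g <- y$g; y <- y$y
  }
  y <- as.matrix(y); g <- as.matrix(g)
  log_cols <- if (augment) grep("_l2$", colnames(y)) else integer(0)
  y <- augment_features(y, log_cols)
  n <- nrow(y); d <- ncol(g)
  ci <- chol_index(d)
  n_w <- n_design_cols(ncol(y), mean_degree, cross) * d +
    n_design_cols(ncol(y), cov_degree, cross) * ci$q
  if (n < 10 * n_w)
    stop("need at least 10 samples per weight (", 10 * n_w, "), got ", n)
  ctr <- colMeans(y)
  scl <- apply(y, 2, stats::sd)
  active <- scl > 1e-10   # constant covariates carry no information
  scl[!active] <- 1
  ys <- sweep(sweep(y, 2, ctr), 2, scl, "/")[, active, drop = FALSE]
  Fm <- polynomial_design(ys, mean_degree, cross)
  Fs <- polynomial_design(ys, cov_degree, cross)
  # warm start: OLS mean, pooled residual covariance
  W0 <- qr.solve(Fm, g)
  R0 <- g - Fm %*% W0
  S0 <- stats::cov(R0) + diag(1e-10, d)
  L0 <- t(chol(S0))
  th0 <- L0[cbind(ci$i, ci$j)]
  th0[ci$diag] <- log(th0[ci$diag])
  V0 <- matrix(0, ncol(Fs), ci$q)
  V0[1, ] <- th0
  par0 <- c(as.vector(W0), as.vector(V0))
  fn <- function(par) nll_value(par, Fm, Fs, g, ci)
  grf <- function(par) nll_grad(par, Fm, Fs, g, ci)
  nll0 <- fn(par0)
  fit1 <- stats::optim(par0, fn, grf, method = "BFGS",
                       control = list(maxit = maxit, reltol = 1e-10))
  best <- if (fit1$value <= nll0) fit1$par else par0
  nll1 <- min(fit1$value, nll0)
  fit2 <- stats::optim(best, fn, method = "Nelder-Mead",
                       control = list(maxit = 500))
  if (fit2$value <= nll1) { best <- fit2$par; nll2 <- fit2$value }
  else nll2 <- nll1
  if (nll2 > nll0 + 1e-8)
    stop("change-model optimisation failed to improve on the warm start ",
         "(nll ", format(nll0), " -> ", format(nll2), ")")
  p <- ncol(Fm)
  W <- matrix(best[seq_len(p * d)], p, d)
  V <- matrix(best[p * d + seq_len(ncol(Fs) * ci$q)], ncol(Fs), ci$q)
  structure(list(w_mu = W, w_sigma = V, mean_degree = mean_degree,
                 cov_degree = cov_degree, cross = cross, center = ctr,
                 scale = scl, active = active, log_cols = log_cols,
                 n_raw = ncol(y) - length(log_cols), d = d, n_train = n,
                 pattern = pattern,
                 nll = c(warm_start = nll0, bfgs = nll1, polish = nll2),
                 layout = colnames(y)),
            class = "bench_change_model")
}

#' Predict the derivative distribution at a baseline summary vector
#'
#' @param object a fitted `bench_change_model`.
#' @param y summary vector (or matrix of rows) at which to predict.
#' @param ... unused.
#' @return For a single vector, `list(mu, sigma)`; for a matrix, a list
#'   with `mu` (n x d) and `sigma` (d x d x n). `sigma` is symmetric
#'   positive definite by construction.
#' @export
predict.bench_change_model <- function(object, y, ...) {
  single <- !is.matrix(y)
  Y <- if (single) matrix(y, 1) else y
  n_raw <- if (is.null(object$n_raw)) length(object$center) else object$n_raw
  if (ncol(Y) != n_raw)
    stop("summary vector dimension does not match the trained model")
  if (length(object$log_cols))
    Y <- augment_features(Y, object$log_cols)
  act <- if (is.null(object$active)) rep(TRUE, ncol(Y)) else object$active
  ys <- sweep(sweep(Y, 2, object$center), 2, object$scale,
              "/")[, act, drop = FALSE]
  Fm <- polynomial_design(ys, object$mean_degree, object$cross)
  Fs <- polynomial_design(ys, object$cov_degree, object$cross)
  mu <- Fm %*% object$w_mu
  # clamp the regressed log-Cholesky vector: far outside the training
  # domain the linear extrapolation can overflow the exponential
  theta <- pmin(pmax(Fs %*% object$w_sigma, -150), 150)
  d <- object$d
  sig <- array(0, c(d, d, nrow(Y)))
  for (i in seq_len(nrow(Y)))
    sig[, , i] <- covariance_from_vector(theta[i, ])
  if (single) list(mu = drop(mu), sigma = sig[, , 1])
  else list(mu = mu, sigma = sig)
}

#' @export
print.bench_change_model <- function(x, ...) {
  cat("Change model", if (!is.null(x$pattern)) paste0("'", x$pattern$name,
                                                      "'"), "\n")
  cat("  summaries:", paste(x$layout, collapse = ", "), "\n")
  cat(sprintf("  mean degree %d (%d weights), covariance degree %d (%d weights)\n",
              x$mean_degree, length(x$w_mu), x$cov_degree,
              length(x$w_sigma)))
  cat(sprintf("  trained on %d samples, NLL %.2f\n", x$n_train,
              x$nll[["polish"]]))
  invisible(x)
}

#' @export
coef.bench_change_model <- function(object, ...) {
  list(w_mu = object$w_mu, w_sigma = object$w_sigma)
}

#' @export
logLik.bench_change_model <- function(object, ...) {
  structure(-object$nll[["polish"]], df = length(object$w_mu) +
              length(object$w_sigma), class = "logLik")
}

#' Train change models for a set of patterns
#'
#' Samples one training set from the prior (shared baselines across
#' patterns), computes per-pattern directional derivatives of the
#' noise-free summary measures, and fits one change model per pattern by
#' maximum likelihood. The returned collection is what the Bayesian
#' inference step consumes.
#'
#' @param prior a [sm_prior()] or [constrained_prior()].
#' @param protocol a [dmri_protocol()].
#' @param patterns named list of [change_pattern()]s (default: one
#'   positive pattern per free parameter).
#' @param n training samples (default 100000; scale down for speed).
#' @param seed integer seed; training is reproducible end to end.
#' @param model forward model; defaults to the prior's.
#' @param l_max maximum even degree of the summary fit.
#' @param mean_degree,cov_degree,cross,augment regression design, see
#'   [fit_change_model()]; augmentation is on by default here because the
#'   summary layout contains log-power coordinates.
#' @return An object of class `bench_models`: named list of fitted
#'   models plus protocol hash and training metadata.
#' @export
train_change_models <- function(prior, protocol, patterns = NULL,
                                n = 100000, seed = 1, model = NULL,
                                l_max = 2, mean_degree = 2, cov_degree = 1,
                                cross = TRUE, augment = TRUE) {
  if (is.null(model)) model <- prior$model
  if (is.null(patterns)) patterns <- single_param_patterns(model)
  P <- sample_prior(prior, n, seed = seed)
  y <- baseline_summaries(P, protocol, model, l_max)
  models <- lapply(patterns, function(pat) {
    g <- derivative_batch(P, pat, protocol, model, l_max = l_max)
    keep <- stats::complete.cases(g)
    fit <- fit_change_model(list(y = y[keep, , drop = FALSE],
                                 g = g[keep, , drop = FALSE],
                                 pattern = pat),
                            mean_degree = mean_degree,
                            cov_degree = cov_degree, cross = cross,
                            augment = augment)
    fit
  })
  structure(list(models = models, model = model,
                 param_names = model_forward(model)$param_names,
                 protocol_hash = protocol_hash(protocol),
                 layout = colnames(y),
                 meta = list(n = n, seed = seed, l_max = l_max,
                             mean_degree = mean_degree,
                             cov_degree = cov_degree, cross = cross)),
            class = "bench_models")
}

#' @export
print.bench_models <- function(x, ...) {
  cat("Trained change models (", x$model, " model): ",
      paste(names(x$models), collapse = ", "), "\n", sep = "")
  cat("  trained on n =", x$meta$n, "samples, seed", x$meta$seed, "\n")
  invisible(x)
}

model_checksum <- function(models) {
  s <- paste(vapply(models$models, function(m)
    paste(format(c(m$w_mu, m$w_sigma), digits = 12), collapse = ","),
    character(1)), collapse = ";")
  string_hash(s)
}

#' Save and load trained change models
#'
#' Serialises a `bench_models` collection to JSON with full floating
#' point precision, together with the protocol hash and a weight
#' checksum. Loading verifies the checksum (refusing tampered files) and,
#' if a protocol is supplied, refuses models trained on a different
#' acquisition.
#'
#' @param models a `bench_models` object.
#' @param path file path.
#' @param protocol optional [dmri_protocol()] to validate against.
#' @return `load_change_models` returns the `bench_models` object;
#'   `save_change_models` the path, invisibly.
#' @export
save_change_models <- function(models, path) {
  ser <- list(
    model = models$model, param_names = models$param_names,
    protocol_hash = models$protocol_hash, layout = models$layout,
    meta = models$meta, checksum = model_checksum(models),
    models = lapply(models$models, function(m) {
      # weights as %.17g strings: IEEE doubles round-trip bit-exactly,
      # which jsonlite's numeric serialisation does not guarantee
      list(w_mu = num_to_chr(m$w_mu), w_sigma = num_to_chr(m$w_sigma),
           dim_mu = dim(m$w_mu), dim_sigma = dim(m$w_sigma),
           mean_degree = m$mean_degree, cov_degree = m$cov_degree,
           cross = m$cross, center = as.list(num_to_chr(m$center)),
           scale = as.list(num_to_chr(m$scale)), active = m$active,
           log_cols = m$log_cols, n_raw = m$n_raw,
           d = m$d, n_train = m$n_train,
           nll = as.list(m$nll), layout = m$layout,
           pattern = list(name = m$pattern$name,
                          vec = as.list(m$pattern$vec)))
    }))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_change_models
#' @export
load_change_models <- function(path, protocol = NULL) {
  if (!file.exists(path)) stop("change-model file not found: ", path)
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(seq_len(nrow_safe(ser$models)), function(i) NULL)
  ms <- ser$models
  out_models <- lapply(names(ms), function(nm) {
    m <- ms[[nm]]
    pat <- change_pattern(m$pattern$name, unlist(m$pattern$vec),
                          names(m$pattern$vec))
    structure(list(w_mu = chr_to_num(m$w_mu, m$dim_mu),
                   w_sigma = chr_to_num(m$w_sigma, m$dim_sigma),
                   mean_degree = m$mean_degree, cov_degree = m$cov_degree,
                   cross = m$cross,
                   center = chr_to_num(unlist(m$center), NULL,
                                       names(m$center)),
                   scale = chr_to_num(unlist(m$scale), NULL,
                                      names(m$scale)),
                   active = m$active,
                   log_cols = if (length(m$log_cols)) as.integer(unlist(m$log_cols))
                              else integer(0),
                   n_raw = m$n_raw,
                   d = m$d, n_train = m$n_train,
                   nll = unlist(m$nll), pattern = pat, layout = m$layout),
              class = "bench_change_model")
  })
  names(out_models) <- names(ms)
  obj <- structure(list(models = out_models, model = ser$model,
                        param_names = ser$param_names,
                        protocol_hash = ser$protocol_hash,
                        layout = ser$layout, meta = ser$meta),
                   class = "bench_models")
  if (!identical(model_checksum(obj), ser$checksum))
    stop("change-model file failed its integrity check (tampered or corrupt)")
  if (!is.null(protocol) &&
      !identical(protocol_hash(protocol), obj$protocol_hash))
    stop("change models were trained on a different acquisition protocol")
  obj
}

nrow_safe <- function(x) if (is.null(x)) 0L else length(x)

num_to_chr <- function(x) {
  out <- sprintf("%.17g", x)
  dim(out) <- dim(x)
  out
}

chr_to_num <- function(x, dims = NULL, nms = NULL) {
  out <- as.numeric(x)
  if (!is.null(dims)) dim(out) <- unlist(dims)
  if (!is.null(nms)) names(out) <- nms
  out
}
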