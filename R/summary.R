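#' Real spherical-harmonics basis (even degrees)
#'
#' Orthonormal real spherical harmonics (Condon-Shortley-free sign) of
#' even degree up to `l_max`, sampled at unit directions. Odd degrees are
#' omitted because the diffusion signal is antipodally symmetric.
#'
#' @param dirs matrix of unit direction vectors (rows).
#' @param l_max maximum even degree (0, 2 or 4).
#' @return A matrix with one row per direction and one column per basis
#'   function, columns named `l<degree>m<order>`.
#' @export
real_sh_basis <- function(dirs, l_max = 2) {
  if (l_max %% 2 != 0 || l_max < 0 || l_max > 4)
    stop("l_max must be 0, 2 or 4")
  dirs <- as.matrix(dirs)
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  B <- matrix(0.5 / sqrt(pi), nrow(dirs), 1)
  nm <- "l0m0"
  if (l_max >= 2) {
    B <- cbind(B,
      0.5 * sqrt(15 / pi) * x * y,
      0.5 * sqrt(15 / pi) * y * z,
      0.25 * sqrt(5 / pi) * (3 * z^2 - 1),
      0.5 * sqrt(15 / pi) * x * z,
      0.25 * sqrt(15 / pi) * (x^2 - y^2))
    nm <- c(nm, paste0("l2m", -2:2))
  }
  if (l_max >= 4) {
    B <- cbind(B,
      0.75 * sqrt(35 / pi) * x * y * (x^2 - y^2),
      0.75 * sqrt(35 / (2 * pi)) * y * z * (3 * x^2 - y^2),
      0.75 * sqrt(5 / pi) * x * y * (7 * z^2 - 1),
      0.75 * sqrt(5 / (2 * pi)) * y * z * (7 * z^2 - 3),
      (3 / 16) * sqrt(1 / pi) * (35 * z^4 - 30 * z^2 + 3),
      0.75 * sqrt(5 / (2 * pi)) * x * z * (7 * z^2 - 3),
      (3 / 8) * sqrt(5 / pi) * (x^2 - y^2) * (7 * z^2 - 1),
      0.75 * sqrt(35 / (2 * pi)) * x * z * (x^2 - 3 * y^2),
      (3 / 16) * sqrt(35 / pi) * (x^2 * (x^2 - 3 * y^2) -
                                    y^2 * (3 * x^2 - y^2)))
    nm <- c(nm, paste0("l4m", -4:4))
  }
  colnames(B) <- nm
  B
}

#' Least-squares spherical-harmonics coefficients for one shell
#'
#' Fits the even-degree real spherical-harmonics expansion of the signal
#' sampled at the shell's gradient directions by ordinary least squares.
#'
#' @param shell_signal numeric vector of signals at the directions.
#' @param shell_directions matrix of unit directions (rows).
#' @param l_max maximum even degree of the fit.
#' @return Named coefficient vector (one entry per basis function).
#' @export
fit_sh_coefficients <- function(shell_signal, shell_directions, l_max = 2) {
  B <- real_sh_basis(shell_directions, l_max)
  if (nrow(B) < ncol(B))
    stop("underdetermined spherical-harmonics fit: ", nrow(B),
         " directions for ", ncol(B), " basis functions")
  fit <- stats::lm.fit(B, shell_signal)
  stats::setNames(fit$coefficients, colnames(B))
}

#' Rotation-invariant power of one spherical-harmonics degree
#'
#' For degree l > 0 this is the mean square of the 2l + 1 coefficients,
#' y_l = sum(C_lm^2) / (2l + 1), which is invariant under rotations. For
#' l = 0 the single coefficient is returned scaled so that it equals the
#' spherical mean of the signal (a constant signal s yields s).
#'
#' @param C named coefficient vector from [fit_sh_coefficients()].
#' @param l even degree.
#' @return Scalar invariant.
#' @export
degree_power <- function(C, l) {
  idx <- grep(paste0("^l", l, "m"), names(C))
  if (!length(idx)) stop("no degree-", l, " coefficients present")
  if (l == 0) return(unname(C[idx]) * 0.5 / sqrt(pi))
  sum(C[idx]^2) / (2 * l + 1)
}

# Per-protocol summary layout: coordinate names and types ("mean"/"log").
summary_layout <- function(protocol) {
  bnz <- protocol$shell_b[protocol$shell_b > 0]
  names <- c("b0_mean",
             as.vector(rbind(paste0("b", format(bnz, trim = TRUE), "_mean"),
                             paste0("b", format(bnz, trim = TRUE), "_l2"))))
  types <- c("mean", rep(c("mean", "log"), length(bnz)))
  list(names = names, types = types)
}

# Precompute per-shell least-squares operators for fast batch summaries.
summary_operator <- function(protocol, l_max = 2) {
  if (!any(protocol$shell_b == 0)) stop("protocol has no b = 0 shell")
  ops <- list()
  for (i in seq_along(protocol$shell_b)) {
    b <- protocol$shell_b[i]
    idx <- protocol$shells[[i]]
    if (b == 0) {
      ops[[i]] <- list(b = 0, idx = idx)
    } else {
      B <- real_sh_basis(protocol$bvecs[idx, , drop = FALSE], l_max)
      if (nrow(B) < ncol(B))
        stop("shell b = ", b, " has too few directions for l_max = ", l_max)
      pinv <- solve(crossprod(B), t(B))   # coefficient operator
      ops[[i]] <- list(b = b, idx = idx, pinv = pinv,
                       cn = colnames(B))
    }
  }
  ops
}

#' Rotation-invariant summary measures of a diffusion signal
#'
#' Decomposes each non-zero shell into even-degree real spherical
#' harmonics and keeps, per shell, the spherical mean (degree-0 invariant)
#' and the log of the degree-2 power, plus the mean b = 0 signal. For the
#' default two-shell protocol this yields the 5-vector
#' `[b0_mean, b1_mean, b1_l2, b2_mean, b2_l2]`.
#'
#' @param signal per-measurement signal vector (or n x m matrix of
#'   signals, one row per voxel/sample).
#' @param protocol a [dmri_protocol()].
#' @param l_max maximum even degree of the per-shell fit (default 2).
#' @param eps floor added inside the log of the degree-2 power so that
#'   perfectly isotropic noise-free signals stay finite.
#' @return A named summary vector (or matrix with one row per input row)
#'   with attribute `"types"` marking coordinates as `"mean"` or `"log"`.
#' @export
summarize_signal <- function(signal, protocol, l_max = 2, eps = 1e-12) {
  S <- if (is.matrix(signal)) signal else matrix(signal, 1)
  if (ncol(S) != length(protocol$bvals))
    stop("signal length does not match the protocol")
  ops <- summary_operator(protocol, l_max)
  lay <- summary_layout(protocol)
  out <- matrix(0, nrow(S), length(lay$names),
                dimnames = list(NULL, lay$names))
  col <- 1L
  for (op in ops) {
    if (op$b == 0) {
      out[, "b0_mean"] <- rowMeans(S[, op$idx, drop = FALSE])
    } else {
      Cf <- S[, op$idx, drop = FALSE] %*% t(op$pinv)    # n x n_coef
      l2i <- grep("^l2m", op$cn)
      mean_name <- paste0("b", format(op$b, trim = TRUE), "_mean")
      l2_name <- paste0("b", format(op$b, trim = TRUE), "_l2")
      out[, mean_name] <- Cf[, 1] * 0.5 / sqrt(pi)
      out[, l2_name] <- log(rowSums(Cf[, l2i, drop = FALSE]^2) / 5 + eps)
    }
    col <- col + 1L
  }
  attr(out, "types") <- lay$types
  if (!is.matrix(signal)) {
    v <- stats::setNames(out[1, ], lay$names)
    attr(v, "types") <- lay$types
    return(v)
  }
  out
}

#' Normalise a baseline/change summary pair by the baseline b0 mean
#'
#' Mean-type coordinates of both the baseline `y` and the change `dy` are
#' divided by the baseline `b0_mean`. Log-type (degree-2 power)
#' coordinates of the baseline are shifted by `-2 * log(b0_mean)` (the
#' log-domain image of the same scaling); the change in a log coordinate
#' is scale-invariant and passed through unchanged.
#'
#' @param y baseline summary vector from [summarize_signal()].
#' @param dy change in the summary vector (same layout).
#' @return `list(y, dy)` with normalised coordinates.
#' @export
normalize_pair <- function(y, dy) {
  types <- attr(y, "types")
  if (is.null(types))
    types <- c("mean", rep(c("mean", "log"), (length(y) - 1) / 2))
  b0 <- y[[1]]
  if (!is.finite(b0) || b0 <= 0) stop("baseline b0_mean must be positive")
  mean_i <- types == "mean"
  y2 <- y; dy2 <- dy
  y2[mean_i] <- y[mean_i] / b0
  y2[!mean_i] <- y[!mean_i] - 2 * log(b0)
  dy2[mean_i] <- dy[mean_i] / b0
  attr(y2, "types") <- types; attr(dy2, "types") <- types
  list(y = y2, dy = dy2)
}

#' Noise covariance of paired summary-measure differences
#'
#' Generates `n_rep` independent noisy realisations of a pair of clean
#' signals, summarises each, and returns the sample covariance of the
#' difference of the two summary vectors. This is the noise covariance
#' `Sigma_n` entering the no-change likelihood and the amount-marginalised
#' change likelihood.
#'
#' @param signal_a,signal_b clean per-measurement signals of the pair
#'   (`signal_b` defaults to `signal_a`).
#' @param protocol a [dmri_protocol()].
#' @param sigma Gaussian noise standard deviation.
#' @param n_rep number of noisy realisations (>= 2; default 100).
#' @param seed optional integer seed.
#' @param l_max maximum even degree of the summary fit.
#' @return Symmetric positive semi-definite covariance matrix over the
#'   summary coordinates.
#' @export
estimate_noise_covariance <- function(signal_a, protocol, sigma,
                                      signal_b = signal_a, n_rep = 100,
                                      seed = NULL, l_max = 2) {
  if (n_rep < 2) stop("n_rep must be >= 2")
  run <- function() {
    Sa <- add_noise(matrix(signal_a, n_rep, length(signal_a),
                           byrow = TRUE), sigma)
    Sb <- add_noise(matrix(signal_b, n_rep, length(signal_b),
                           byrow = TRUE), sigma)
    summarize_signal(Sb, protocol, l_max) - summarize_signal(Sa, protocol,
                                                             l_max)
  }
  D <- if (is.null(seed)) run() else with_seed(seed, run())
  stats::cov(D)
}
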