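#' Tissue parameters of the three-compartment standard model
#'
#' The standard model of white matter diffusion has 8 free microstructural
#' parameters: signal fractions `s_iso`, `s_in`, `s_ex` (unitless, >= 0),
#' diffusivities `d_iso`, `d_in_a`, `d_ex_a` (um^2/ms, >= 0), the
#' extra-axonal radial/axial diffusivity ratio `tau` in \[0, 1\] and the
#' orientation dispersion index `odi` in (0, 1). The mean fibre orientation
#' `mu` is a nuisance direction, not a free parameter of inference.
#'
#' @param s_iso,s_in,s_ex compartment signal fractions (>= 0).
#' @param d_iso,d_in_a,d_ex_a diffusivities in um^2/ms (>= 0).
#' @param tau radial-to-axial diffusivity ratio, in \[0, 1\].
#' @param odi orientation dispersion index, in (0, 1).
#' @param mu unit 3-vector mean fibre orientation.
#' @return A named list of class `tissue_params`.
#' @export
tissue_params <- function(s_iso = 0, s_in = 0.6, s_ex = 0.4, d_iso = 3,
                          d_in_a = 1.7, d_ex_a = 1.7, tau = 0.5, odi = 0.2,
                          mu = c(0, 0, 1)) {
  p <- c(s_iso = s_iso, s_in = s_in, s_ex = s_ex, d_iso = d_iso,
         d_in_a = d_in_a, d_ex_a = d_ex_a, tau = tau, odi = odi)
  check_tissue_params(p)
  if (abs(sqrt(sum(mu^2)) - 1) > 1e-8) stop("mu must be a unit vector")
  structure(list(params = p, mu = mu), class = "tissue_params")
}

#' Names of the free standard-model parameters
#'
#' @return Character vector of the 8 free parameter names, in the
#'   conventional order (fractions, diffusivities, tau, ODI).
#' @export
sm_param_names <- function() {
  c("s_iso", "s_in", "s_ex", "d_iso", "d_in_a", "d_ex_a", "tau", "odi")
}

#' @rdname sm_param_names
#' @export
constrained_param_names <- function() c("s_iso", "s_in", "s_ex", "odi")

check_tissue_params <- function(p) {
  if (any(p[c("s_iso", "s_in", "s_ex")] < 0)) stop("fractions must be >= 0")
  if (any(p[c("d_iso", "d_in_a", "d_ex_a")] < 0))
    stop("diffusivities must be >= 0")
  if (p[["tau"]] < 0 || p[["tau"]] > 1) stop("tau must lie in [0, 1]")
  if (p[["odi"]] <= 0 || p[["odi"]] >= 1) stop("odi must lie in (0, 1)")
  invisible(p)
}

# Valid ranges used for boundary checks when parameters are perturbed.
sm_param_bounds <- function() {
  list(lower = c(s_iso = 0, s_in = 0, s_ex = 0, d_iso = 0, d_in_a = 0,
                 d_ex_a = 0, tau = 0, odi = 1e-3),
       upper = c(s_iso = 1, s_in = 1, s_ex = 1, d_iso = Inf, d_in_a = Inf,
                 d_ex_a = Inf, tau = 1, odi = 1 - 1e-3))
}

#' Simulate multi-shell diffusion signal from the standard model
#'
#' Evaluates S = s_iso * A_iso + s_in * A_in + s_ex * A_ex at every
#' measurement of the protocol, where A_iso is the free-water exponential
#' decay and A_in / A_ex are the Watson-dispersed stick and zeppelin
#' attenuations (see [watson_stick_attenuation()]).
#'
#' @param params a [tissue_params()] object, or a named list/vector with
#'   the 8 free parameters (plus optional `mu`).
#' @param protocol a [dmri_protocol()].
#' @return Numeric vector of per-measurement signals.
#' @export
simulate_signal <- function(params, protocol) {
  if (inherits(params, "tissue_params")) {
    p <- params$params; mu <- params$mu
  } else {
    p <- unlist(params[sm_param_names()])
    mu <- if (!is.null(params$mu)) params$mu else c(0, 0, 1)
  }
  check_tissue_params(p)
  drop(simulate_signal_batch(matrix(p, 1, dimnames = list(NULL, names(p))),
                             protocol, mu = mu))
}

#' Vectorised standard-model forward simulation
#'
#' Evaluates the forward model for a whole matrix of parameter settings
#' at once; the workhorse behind training-set generation and test-pair
#' simulation. Evaluation is chunked so the internal
#' (samples x measurements x quadrature-node) arrays stay small.
#'
#' @param P n x 8 matrix of standard-model parameters (columns
#'   [sm_param_names()]).
#' @param protocol a [dmri_protocol()].
#' @param mu one unit 3-vector shared by all rows, or an n x 3 matrix of
#'   per-sample fibre orientations.
#' @param chunk rows evaluated per block.
#' @return An n x n_measurement signal matrix.
#' @export
simulate_signal_batch <- function(P, protocol, mu = c(0, 0, 1),
                                  chunk = 2000L) {
  P <- as.matrix(P)
  n <- nrow(P); m <- length(protocol$bvals)
  out <- matrix(0, n, m)
  mu_mat <- if (is.matrix(mu)) mu else NULL
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    idx <- s:e
    mch <- if (is.null(mu_mat)) mu else mu_mat[idx, , drop = FALSE]
    out[idx, ] <- signal_chunk(P[idx, , drop = FALSE], protocol, mch)
  }
  out
}

signal_chunk <- function(P, protocol, mu) {
  comps <- components_chunk(P, protocol, mu)
  P[, "s_iso"] * comps$A_iso + P[, "s_in"] * comps$A_in +
    P[, "s_ex"] * comps$A_ex
}

# Direction cosines mu.g as an n x m matrix (shared or per-sample mu).
cpsi_matrix <- function(protocol, mu, n) {
  if (is.matrix(mu)) {
    (mu / sqrt(rowSums(mu^2))) %*% t(protocol$bvecs)
  } else {
    mu <- mu / sqrt(sum(mu^2))
    matrix(as.vector(protocol$bvecs %*% mu), n,
           length(protocol$bvals), byrow = TRUE)
  }
}

# Per-compartment attenuation matrices for one chunk of samples.
components_chunk <- function(P, protocol, mu = c(0, 0, 1), cpsi = NULL) {
  n <- nrow(P); b <- protocol$bvals
  if (is.null(cpsi)) cpsi <- cpsi_matrix(protocol, mu, n)
  kappa <- kappa_from_odi(P[, "odi"])
  list(A_iso = exp(-outer(P[, "d_iso"], b)),
       A_in = stick_att_mat(P[, "d_in_a"], kappa, protocol, cpsi),
       A_ex = zeppelin_att_mat(P[, "d_ex_a"], P[, "tau"], kappa, protocol,
                               cpsi),
       cpsi = cpsi, kappa = kappa)
}

stick_att_mat <- function(d_a, kappa, protocol, cpsi) {
  watson_conv_mat(outer(d_a, protocol$bvals), kappa, cpsi)
}

zeppelin_att_mat <- function(d_a, tau, kappa, protocol, cpsi) {
  exp(-outer(d_a * tau, protocol$bvals)) *
    watson_conv_mat(outer(d_a * (1 - tau), protocol$bvals), kappa, cpsi)
}

# watson_conv over an n x m matrix of kernel strengths with per-row kappa.
# The Watson normaliser Phi(kappa, 0) is shared by all measurements of a
# sample, so it is evaluated once per row rather than once per element.
watson_conv_mat <- function(k, kappa, cpsi) {
  n <- nrow(k); m <- ncol(k)
  out <- matrix(1, n, m)
  nz <- which(k > 0)
  if (!length(nz)) return(out)
  row <- (nz - 1L) %% n + 1L
  kap <- kappa[row]
  tr <- kap - k[nz]
  disc <- sqrt(pmax(0, tr^2 + 4 * kap * k[nz] * (1 - cpsi[nz]^2)))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (max(kappa) <= 700) {
    den <- phi_sphere(kappa, numeric(n))
    out[nz] <- phi_sphere(l1, l2) / den[row]
  } else {
    den <- log_phi_sphere(kappa, numeric(n))
    out[nz] <- exp(log_phi_sphere(l1, l2) - den[row])
  }
  out
}

#' Additive Gaussian measurement noise
#'
#' @param signal numeric vector or matrix of clean signals.
#' @param sigma noise standard deviation in signal units (>= 0).
#' @param seed optional integer seed for reproducible noise.
#' @return `signal` plus i.i.d. Gaussian noise of standard deviation
#'   `sigma`.
#' @export
add_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(signal)
  noise <- if (is.null(seed)) stats::rnorm(length(signal), 0, sigma)
           else with_seed(seed, stats::rnorm(length(signal), 0, sigma))
  signal + array(noise, dim = if (is.null(dim(signal))) length(signal)
                              else dim(signal))
}

#' Map constrained (NODDI-style) parameters to the standard model
#'
#' The constrained model renders the standard model invertible by fixing
#' the diffusivities (d_iso = 3, d_in_a = d_ex_a = 1.7 um^2/ms) and tying
#' the tortuosity to the signal fractions, tau = s_in / (s_in + s_ex).
#' Its four free parameters are s_iso, s_in, s_ex and ODI.
#'
#' @param theta named vector or n x 4 matrix with columns
#'   `s_iso`, `s_in`, `s_ex`, `odi`.
#' @return An n x 8 matrix of standard-model parameters.
#' @export
constrained_to_standard <- function(theta) {
  if (!is.matrix(theta)) theta <- matrix(theta, 1,
    dimnames = list(NULL, names(theta)))
  theta <- theta[, constrained_param_names(), drop = FALSE]
  tot <- theta[, "s_in"] + theta[, "s_ex"]
  tau <- ifelse(tot > 0, theta[, "s_in"] / tot, 0.5)
  P <- cbind(s_iso = theta[, "s_iso"], s_in = theta[, "s_in"],
             s_ex = theta[, "s_ex"], d_iso = 3, d_in_a = 1.7, d_ex_a = 1.7,
             tau = tau, odi = theta[, "odi"])
  P
}

# Forward-model interface shared by training and validation: maps a
# parameter matrix in the model's own free parameters to signals.
model_forward <- function(model = c("standard", "constrained")) {
  model <- match.arg(model)
  if (model == "standard") {
    list(name = "standard", param_names = sm_param_names(),
         signal = function(P, protocol, mu = c(0, 0, 1))
           simulate_signal_batch(P, protocol, mu = mu))
  } else {
    list(name = "constrained", param_names = constrained_param_names(),
         signal = function(P, protocol, mu = c(0, 0, 1))
           simulate_signal_batch(constrained_to_standard(P), protocol,
                                 mu = mu))
  }
}
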