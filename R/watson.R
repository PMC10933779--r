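#' Watson concentration / orientation dispersion index maps
#'
#' The Watson concentration kappa is mapped to the bounded orientation
#' dispersion index ODI = (2/pi) * atan(1/kappa); higher ODI means more
#' fibre dispersion. `kappa_from_odi` is the inverse map,
#' kappa = cot(pi * odi / 2).
#'
#' @param odi orientation dispersion index, in (0, 1).
#' @param kappa Watson concentration, > 0.
#' @return `kappa_from_odi` returns kappa; `odi_from_kappa` returns ODI.
#' @examples
#' kappa_from_odi(0.5)          # 1
#' odi_from_kappa(10)           # (2/pi) * atan(0.1)
#' @export
kappa_from_odi <- function(odi) {
  if (any(odi <= 0 | odi >= 1)) stop("odi must lie strictly in (0, 1)")
  1 / tan(pi * odi / 2)
}

#' @rdname kappa_from_odi
#' @export
odi_from_kappa <- function(kappa) {
  if (any(kappa <= 0)) stop("kappa must be positive")
  (2 / pi) * atan(1 / kappa)
}

# --- Gauss-Legendre nodes (Golub-Welsch), cached per order -----------------

.gl_cache <- new.env(parent = emptyenv())

gauss_legendre_01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  j <- seq_len(n - 1)
  beta <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(j, j + 1)] <- beta
  J[cbind(j + 1, j)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)                       # nodes on [-1, 1]
  w <- 2 * rev(e$vectors[1, ])^2
  out <- list(x = (x + 1) / 2, w = w / 2)  # mapped to \[0, 1\]
  .gl_cache[[key]] <- out
  out
}

# --- Spherical exponential-quadratic integral ------------------------------
#
# log Phi(a, b) with Phi = (1/4pi) * int_{S2} exp(a x^2 + b y^2) dS
#                        = int_0^1 exp(s (a+b)/2) I0(s (a-b)/2) du,  s = 1-u^2.
# This is the confluent hypergeometric function 1F1(1/2; 3/2; diag(a, b, 0))
# of matrix argument, reduced to a 1-D integral; evaluated by Gauss-Legendre
# with exponent shifting so arbitrarily large concentrations stay finite.
log_phi_sphere <- function(a, b, n_nodes = 48) {
  stopifnot(length(a) == length(b))
  big <- pmax(abs(a), abs(b)) > 100
  out <- numeric(length(a))
  for (grp in list(which(!big), which(big))) {
    if (!length(grp)) next
    nn <- if (any(big[grp])) 256 else n_nodes
    gl <- gauss_legendre_01(nn)
    s <- 1 - gl$x^2                                     # length nn
    ex <- outer((a[grp] + b[grp]) / 2, s)               # m x nn
    bx <- outer((a[grp] - b[grp]) / 2, s)
    loggrand <- ex + abs(bx) +
      log(besselI(abs(bx), 0, expon.scaled = TRUE))
    m <- apply(loggrand, 1, max)
    out[grp] <- m + log(as.vector(exp(loggrand - m) %*% gl$w))
  }
  out
}

# Log of the Watson normalisation constant c(kappa) = int exp(kappa (mu.x)^2) dS.
watson_log_c <- function(kappa) {
  log(4 * pi) + log_phi_sphere(kappa, rep(0, length(kappa)))
}

# Quadrature integrand exp(E) * I0(X) evaluated without log-space overhead:
# minimax polynomial approximations to the modified Bessel function I0
# (relative error < 2e-7), split at X = 3.75 so only one exp per element
# is needed. Valid while E + X stays below ~700 (callers guarantee this).
phi_kernel <- function(E, X) {
  out <- numeric(length(E))
  small <- X < 3.75
  if (any(small)) {
    t2 <- (X[small] / 3.75)^2
    p <- 1 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492 +
         t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))))
    out[small] <- exp(E[small]) * p
  }
  if (any(!small)) {
    x <- X[!small]
    t <- 3.75 / x
    p <- 0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
         t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
         t * (-0.01647633 + t * 0.00392377)))))))
    out[!small] <- exp(E[!small] + x) * p / sqrt(x)
  }
  dim(out) <- dim(E)
  out
}

# Linear-scale Phi(a, b); the log-space route takes over for
# concentrations beyond ~700, where exp would overflow. 24 Gauss-Legendre
# nodes are converged to ~2e-6 relative over the admissible range.
phi_sphere <- function(a, b, n_nodes = 24) {
  gl <- gauss_legendre_01(n_nodes)
  s <- 1 - gl$x^2
  E <- outer((a + b) / 2, s)
  X <- abs(outer((a - b) / 2, s))
  drop(phi_kernel(E, X) %*% gl$w)
}

# --- Watson-convolved quadratic-exponential kernel -------------------------
#
# A(k, kappa, cpsi) = int_{S2} exp(-k (g.n)^2) Watson(n; mu, kappa) dn
# with cpsi = mu.g. The integrand exponent is n' (kappa mu mu' - k g g') n;
# the two in-plane eigenvalues of that rank-2 matrix give
# A = Phi(l1, l2) / Phi(kappa, 0). All arguments recycled to equal length.
watson_conv <- function(k, kappa, cpsi) {
  n <- max(length(k), length(kappa), length(cpsi))
  k <- rep_len(k, n); kappa <- rep_len(kappa, n); cpsi <- rep_len(cpsi, n)
  tr <- kappa - k
  disc <- sqrt(pmax(0, (kappa - k)^2 + 4 * kappa * k * (1 - cpsi^2)))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  big <- pmax(l1, kappa) > 700
  out <- numeric(n)
  if (any(!big)) {
    i <- which(!big)
    out[i] <- phi_sphere(l1[i], l2[i]) / phi_sphere(kappa[i], numeric(length(i)))
  }
  if (any(big)) {
    i <- which(big)
    out[i] <- exp(log_phi_sphere(l1[i], l2[i]) -
                    log_phi_sphere(kappa[i], numeric(length(i))))
  }
  out
}

#' Compartment attenuations of the standard model
#'
#' `attenuation_iso` is the free-water exponential decay exp(-b * d_iso).
#' `watson_stick_attenuation` is the spherical convolution of a stick
#' response (axial diffusivity `d_in_a`, zero radial diffusivity) with a
#' Watson orientation distribution of mean direction `mu` and dispersion
#' `odi`. `watson_zeppelin_attenuation` uses an axially symmetric tensor
#' response with radial/axial diffusivity ratio `tau` and the same Watson
#' distribution; its kernel factorises as
#' exp(-b d tau) * stick(b d (1 - tau)), which is used for evaluation.
#'
#' @param b b-value(s), ms/um^2.
#' @param d_iso,d_in_a,d_ex_a diffusivities, um^2/ms.
#' @param protocol a [dmri_protocol()].
#' @param odi orientation dispersion index in (0, 1).
#' @param tau radial-to-axial diffusivity ratio in \[0, 1\].
#' @param mu unit 3-vector mean fibre orientation.
#' @return Per-measurement attenuation values in (0, 1].
#' @export
attenuation_iso <- function(b, d_iso) {
  if (any(b < 0) || any(d_iso < 0))
    stop("b and d_iso must be non-negative")
  exp(-b * d_iso)
}

#' @rdname attenuation_iso
#' @export
watson_stick_attenuation <- function(protocol, d_in_a, odi, mu = c(0, 0, 1)) {
  if (d_in_a < 0) stop("d_in_a must be non-negative")
  kappa <- kappa_from_odi(odi)
  mu <- mu / sqrt(sum(mu^2))
  cpsi <- as.vector(protocol$bvecs %*% mu)
  k <- protocol$bvals * d_in_a
  out <- rep(1, length(k))
  nz <- k > 0
  if (any(nz)) out[nz] <- watson_conv(k[nz], kappa, cpsi[nz])
  out
}

#' @rdname attenuation_iso
#' @export
watson_zeppelin_attenuation <- function(protocol, d_ex_a, tau, odi,
                                        mu = c(0, 0, 1)) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  if (d_ex_a < 0) stop("d_ex_a must be non-negative")
  kappa <- kappa_from_odi(odi)
  mu <- mu / sqrt(sum(mu^2))
  cpsi <- as.vector(protocol$bvecs %*% mu)
  k <- protocol$bvals * d_ex_a * (1 - tau)
  out <- exp(-protocol$bvals * d_ex_a * tau)
  nz <- k > 0
  if (any(nz)) out[nz] <- out[nz] * watson_conv(k[nz], kappa, cpsi[nz])
  out
}
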