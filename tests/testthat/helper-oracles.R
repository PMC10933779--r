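# Independent numerical oracles used to validate the implementation.
# These deliberately take different computational routes from the package
# internals (dense 2-D spherical product quadrature instead of the 1-D
# Bessel reduction; direct dense-matrix Gaussian densities instead of the
# whitened eigen route).

# Dense spherical quadrature: Gauss-Legendre in cos(theta) x trapezoid in
# phi. Returns nodes (rows) and weights summing to 4*pi.
sphere_grid <- function(n_theta = 120, n_phi = 240) {
  j <- seq_len(n_theta - 1)
  beta <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, n_theta, n_theta)
  J[cbind(j, j + 1)] <- beta
  J[cbind(j + 1, j)] <- beta
  e <- eigen(J, symmetric = TRUE)
  ct <- e$values
  wt <- 2 * e$vectors[1, ]^2
  ph <- (seq_len(n_phi) - 1) * 2 * pi / n_phi
  st <- sqrt(pmax(0, 1 - ct^2))
  X <- cbind(rep(st, each = n_phi) * cos(ph),
             rep(st, each = n_phi) * sin(ph),
             rep(ct, each = n_phi))
  w <- rep(wt, each = n_phi) * (2 * pi / n_phi)
  list(X = X, w = w)
}

# Watson-convolved attenuation of an axially symmetric kernel by direct
# integration over fibre orientations (normalising the Watson weights
# numerically on the same grid).
oracle_watson_attenuation <- function(bval, g, d_a, d_r, kappa, mu,
                                      grid = sphere_grid()) {
  wat <- exp(kappa * drop(grid$X %*% mu)^2)
  wat <- wat / sum(wat * grid$w)
  ct2 <- drop(grid$X %*% g)^2
  ker <- exp(-bval * (d_a * ct2 + d_r * (1 - ct2)))
  sum(ker * wat * grid$w)
}

# Watson density integral over the sphere (should be 1 when normalised by
# the package's normalisation constant).
oracle_watson_mass <- function(kappa, mu = c(0, 0, 1),
                               grid = sphere_grid()) {
  logc <- benchmri:::watson_log_c(kappa)
  sum(exp(kappa * drop(grid$X %*% mu)^2 - logc) * grid$w)
}

# Multivariate normal log-density via eigendecomposition (no Cholesky).
oracle_mvn_logdensity <- function(x, mean, Sigma) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  z <- crossprod(e$vectors, x - mean)
  -0.5 * (length(x) * log(2 * pi) + sum(log(e$values)) +
            sum(z^2 / e$values))
}

# Uniformly random rotation matrix (for invariance tests).
oracle_random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rotate_protocol <- function(protocol, R) {
  dmri_protocol(protocol$bvals, protocol$bvecs %*% t(R))
}
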