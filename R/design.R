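#' Polynomial design row for the change-model regressions
#'
#' Maps a summary vector y to the regression features F(y): degree 0 gives
#' an intercept only, degree 1 gives `[1, y]`, degree 2 the full quadratic
#' `[1, y, y_i * y_j (i <= j)]` including cross terms. A 5-vector thus
#' yields 1, 6 or 21 columns.
#'
#' @param y summary vector, or matrix with one summary vector per row.
#' @param degree polynomial degree (0, 1 or 2).
#' @param cross include pairwise cross terms at degree 2 (default TRUE;
#'   `FALSE` keeps pure powers only).
#' @return Design matrix with one row per input row.
#' @export
polynomial_design <- function(y, degree = 2, cross = TRUE) {
  if (!degree %in% 0:2) stop("degree must be 0, 1 or 2")
  Y <- if (is.matrix(y)) y else matrix(y, 1)
  n <- nrow(Y); d <- ncol(Y)
  out <- matrix(1, n, 1)
  if (degree >= 1) out <- cbind(out, Y)
  if (degree == 2) {
    if (cross) {
      for (i in seq_len(d)) for (j in i:d)
        out <- cbind(out, Y[, i] * Y[, j])
    } else {
      out <- cbind(out, Y^2)
    }
  }
  out
}

n_design_cols <- function(d, degree, cross = TRUE) {
  switch(as.character(degree),
         "0" = 1L,
         "1" = 1L + d,
         "2" = if (cross) 1L + d + d * (d + 1L) / 2L else 1L + 2L * d)
}

# Index bookkeeping for the Cholesky parameterisation: theta holds the
# lower-triangular elements column-major (diagonal entries log-scaled).
chol_index <- function(d) {
  ij <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE]
  list(i = ij[, 1], j = ij[, 2], diag = ij[, 1] == ij[, 2],
       q = nrow(ij))
}

#' Covariance matrix from its unconstrained Cholesky parameterisation
#'
#' Rebuilds a symmetric positive-definite covariance from the
#' `d(d+1)/2`-vector holding the lower-triangular Cholesky factor
#' column-major, with the diagonal entries stored on the log scale and
#' exponentiated. Any real vector maps to a valid covariance, which is
#' what makes the parameterisation usable inside unconstrained
#' optimisation.
#'
#' @param theta numeric vector of length `d(d+1)/2`.
#' @return A `d x d` symmetric positive-definite matrix `L %*% t(L)`.
#' @examples
#' covariance_from_vector(c(log(2), 0, log(3)))  # diag(4, 9)
#' @export
covariance_from_vector <- function(theta) {
  q <- length(theta)
  d <- (sqrt(8 * q + 1) - 1) / 2
  if (d != round(d)) stop("theta length must be d(d+1)/2 for some d")
  d <- as.integer(d)
  ci <- chol_index(d)
  L <- matrix(0, d, d)
  vals <- theta
  vals[ci$diag] <- exp(vals[ci$diag])
  L[cbind(ci$i, ci$j)] <- vals
  L %*% t(L)
}
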