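#' Multi-shell diffusion acquisition protocols
#'
#' A protocol bundles per-measurement b-values (ms/um^2), unit gradient
#' directions and a grouping of measurements into shells (b = 0 included).
#' Shells are detected by rounding b to the nearest 0.1 ms/um^2.
#'
#' @param bvals numeric vector of b-values in ms/um^2 (>= 0).
#' @param bvecs numeric matrix with one row per measurement and three
#'   columns; rows must have unit norm for b > 0 (b = 0 rows may be zero).
#' @return An object of class `dmri_protocol` with elements `bvals`,
#'   `bvecs`, `shells` (named list of measurement indices per shell, names
#'   are the rounded b-values) and `shell_b` (numeric, rounded b per shell).
#' @export
dmri_protocol <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (any(bvals < 0)) stop("b-values must be non-negative")
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3)
    stop("bvecs must be a length(bvals) x 3 matrix")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-8
  if (any(bad))
    stop("gradient directions for b > 0 must have unit norm (within 1e-8)")
  b_round <- round(bvals / 0.1) * 0.1
  shell_b <- sort(unique(b_round))
  shells <- lapply(shell_b, function(b) which(abs(b_round - b) < 1e-9))
  names(shells) <- format(shell_b, trim = TRUE)
  structure(list(bvals = bvals, bvecs = bvecs, shells = shells,
                 shell_b = shell_b),
            class = "dmri_protocol")
}

#' @export
print.dmri_protocol <- function(x, ...) {
  cat("Multi-shell diffusion protocol:", length(x$bvals), "measurements\n")
  for (i in seq_along(x$shells))
    cat(sprintf("  b = %-4s : %d directions\n", names(x$shells)[i],
                length(x$shells[[i]])))
  invisible(x)
}

# Spherical Fibonacci point set: deterministic quasi-uniform directions.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Uniformly random 3-D rotation matrix from an RNG stream.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' UK-Biobank-like two-shell acquisition protocol
#'
#' Builds a protocol with shells at b = 1 and b = 2 ms/um^2, each holding
#' `n_dir_per_shell` quasi-uniform unit directions (deterministic spherical
#' Fibonacci point set, rotated by a seed-controlled random rotation per
#' shell), plus `n_b0` b = 0 measurements. The defaults give the
#' conventional 105-measurement two-shell protocol.
#'
#' @param n_dir_per_shell directions per non-zero shell (>= 6, so that a
#'   degree-2 spherical-harmonics fit is determined).
#' @param n_b0 number of b = 0 measurements.
#' @param seed integer seed controlling the shell rotations.
#' @return A [dmri_protocol()] with `2 * n_dir_per_shell + n_b0` rows.
#' @examples
#' p <- make_ukb_protocol()
#' length(p$bvals)  # 105
#' @export
make_ukb_protocol <- function(n_dir_per_shell = 50, n_b0 = 5, seed = 1) {
  if (n_dir_per_shell < 6)
    stop("need at least 6 directions per shell for an l = 2 fit")
  base <- fibonacci_sphere(n_dir_per_shell)
  dirs <- with_seed(seed, {
    lapply(1:2, function(i) base %*% t(random_rotation()))
  })
  bvals <- c(rep(0, n_b0), rep(1, n_dir_per_shell), rep(2, n_dir_per_shell))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs[[1]], dirs[[2]])
  dmri_protocol(bvals, bvecs)
}

#' Read and write FSL-style bval/bvec text files
#'
#' `bvals` is a single whitespace-separated row; `bvecs` holds three rows
#' (x, y, z components), one column per measurement.
#'
#' @param protocol a [dmri_protocol()].
#' @param bvals_path,bvecs_path file paths.
#' @return `read_bvals_bvecs` returns a [dmri_protocol()];
#'   `write_bvals_bvecs` returns the protocol invisibly.
#' @export
write_bvals_bvecs <- function(protocol, bvals_path, bvecs_path) {
  writeLines(paste(format(protocol$bvals, trim = TRUE), collapse = " "),
             bvals_path)
  writeLines(apply(t(protocol$bvecs), 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), bvecs_path)
  invisible(protocol)
}

#' @rdname write_bvals_bvecs
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(bv) != 3)
    stop("bvecs file must contain exactly three rows (x, y, z)")
  if (ncol(bv) != length(bvals))
    stop("bvals/bvecs measurement counts differ")
  bvecs <- t(bv)
  nrm <- sqrt(rowSums(bvecs^2))
  fix <- bvals > 0 & nrm > 0 & abs(nrm - 1) > 1e-8
  if (any(fix)) {
    warning("normalising ", sum(fix), " non-unit gradient directions")
    bvecs[fix, ] <- bvecs[fix, ] / nrm[fix]
  }
  dmri_protocol(bvals, bvecs)
}

# Stable string hash (DJB2 variant in double arithmetic, mod 2^47 so all
# intermediates stay exactly representable); ties trained change models to
# the protocol they were trained on.
string_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^47
  sprintf("%015.0f", h)
}

#' Protocol fingerprint
#'
#' A short deterministic hash of the rounded b-values and gradient
#' directions, used to refuse applying a trained change model to data from
#' a different acquisition.
#' @param protocol a [dmri_protocol()].
#' @return A character scalar.
#' @export
protocol_hash <- function(protocol) {
  s <- paste(c(format(round(protocol$bvals, 6), trim = TRUE),
               format(round(protocol$bvecs, 6), trim = TRUE)),
             collapse = ",")
  string_hash(s)
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
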