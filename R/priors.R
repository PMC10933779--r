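#' Prior distributions over standard-model parameters
#'
#' Builds the prior specification used both to generate training samples
#' for the change models and to simulate test data. Defaults emulate
#' brain-like tissue: the isotropic fraction is a mixture of a point mass
#' at 0 (pure tissue) and a uniform (partial volume), the remaining
#' fractions are uniform and all three are then normalised to sum to 1;
#' the free-water diffusivity is Normal(3, 0.1) and the axial
#' diffusivities Normal(1.7, 0.3) (um^2/ms, truncated at 0); tau is
#' uniform on \[0, 1\] and ODI is Beta(2, 5).
#'
#' @param s_iso_delta_weight probability mass of the point mass at
#'   s_iso = 0 in the delta/uniform mixture.
#' @param normalize_fractions if `TRUE` (default) sampled fractions are
#'   rescaled to sum to 1 exactly.
#' @param mu `"fixed"` pins the fibre orientation to +z (the summary
#'   measures are rotation invariant, so this is the training default);
#'   `"uniform"` samples it uniformly on the sphere.
#' @return An object of class `param_prior` describing one marginal
#'   distribution per free parameter.
#' @export
sm_prior <- function(s_iso_delta_weight = 0.5, normalize_fractions = TRUE,
                     mu = c("fixed", "uniform")) {
  mu <- match.arg(mu)
  structure(list(
    model = "standard",
    params = list(
      s_iso = list(kind = "delta_uniform", weight = s_iso_delta_weight,
                   min = 0, max = 1),
      s_in = list(kind = "uniform", min = 0, max = 1),
      s_ex = list(kind = "uniform", min = 0, max = 1),
      d_iso = list(kind = "normal", mean = 3, sd = 0.1),
      d_in_a = list(kind = "normal", mean = 1.7, sd = 0.3),
      d_ex_a = list(kind = "normal", mean = 1.7, sd = 0.3),
      tau = list(kind = "uniform", min = 0, max = 1),
      odi = list(kind = "beta", shape1 = 2, shape2 = 5, clip = 1e-3)
    ),
    normalize_fractions = normalize_fractions,
    mu = mu), class = "param_prior")
}

#' @rdname sm_prior
#' @export
constrained_prior <- function(s_iso_delta_weight = 0.5,
                              normalize_fractions = TRUE,
                              mu = c("fixed", "uniform")) {
  p <- sm_prior(s_iso_delta_weight, normalize_fractions, mu)
  p$model <- "constrained"
  p$params <- p$params[constrained_param_names()]
  p
}

draw_marginal <- function(spec, n) {
  switch(spec$kind,
    uniform = stats::runif(n, spec$min, spec$max),
    normal = {
      x <- stats::rnorm(n, spec$mean, spec$sd)
      while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), spec$mean,
                                                  spec$sd)
      x
    },
    beta = pmin(1 - spec$clip,
                pmax(spec$clip, stats::rbeta(n, spec$shape1, spec$shape2))),
    delta_uniform = ifelse(stats::runif(n) < spec$weight, 0,
                           stats::runif(n, spec$min, spec$max)),
    fixed = rep(spec$value, n),
    stop("unknown prior kind: ", spec$kind))
}

#' Sample tissue parameters from a prior
#'
#' @param prior a [sm_prior()] or [constrained_prior()] specification.
#' @param n number of samples (>= 1).
#' @param seed optional integer seed.
#' @return An `n x k` matrix of parameter draws (columns named after the
#'   model's free parameters) with the fibre orientations in
#'   `attr(, "mu")` (an `n x 3` matrix).
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "param_prior"), n >= 1)
  draw <- function() {
    P <- vapply(prior$params, draw_marginal, numeric(n), n = n)
    if (n == 1) P <- matrix(P, 1, dimnames = list(NULL, names(prior$params)))
    if (isTRUE(prior$normalize_fractions)) {
      fr <- c("s_iso", "s_in", "s_ex")
      tot <- rowSums(P[, fr, drop = FALSE])
      zero <- tot <= 0
      if (any(zero)) {  # degenerate all-zero draw: resample as uniform simplex
        P[zero, fr] <- matrix(stats::runif(3 * sum(zero)), ncol = 3)
        tot <- rowSums(P[, fr, drop = FALSE])
      }
      P[, fr] <- P[, fr, drop = FALSE] / tot
    }
    mu <- if (prior$mu == "uniform") {
      v <- matrix(stats::rnorm(3 * n), n, 3)
      v / sqrt(rowSums(v^2))
    } else matrix(rep(c(0, 0, 1), each = n), n, 3)
    attr(P, "mu") <- mu
    P
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
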