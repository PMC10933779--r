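#' Patterns of change in parameter space
#'
#' A pattern of change is a unit vector over a model's free parameters,
#' hypothesising the direction (but not the amount) of a sparse parameter
#' change. `single_param_patterns` builds one positive unit pattern per
#' free parameter, the default hypothesis set.
#'
#' @param name pattern label.
#' @param vec numeric vector over the free parameters (will be normalised
#'   to unit Euclidean norm; zero entries mark uninvolved parameters).
#' @param param_names names of the model's free parameters.
#' @return `change_pattern` returns an object of class `change_pattern`;
#'   `single_param_patterns` a named list of them.
#' @export
change_pattern <- function(name, vec, param_names = sm_param_names()) {
  if (length(vec) != length(param_names))
    stop("pattern length must match the number of free parameters")
  nrm <- sqrt(sum(vec^2))
  if (nrm == 0) stop("pattern must be non-zero")
  structure(list(name = name,
                 vec = stats::setNames(vec / nrm, param_names)),
            class = "change_pattern")
}

#' @rdname change_pattern
#' @param model `"standard"` (8 parameters) or `"constrained"` (4).
#' @export
single_param_patterns <- function(model = c("standard", "constrained")) {
  model <- match.arg(model)
  pn <- model_forward(model)$param_names
  out <- lapply(seq_along(pn), function(i) {
    v <- numeric(length(pn)); v[i] <- 1
    change_pattern(pn[i], v, pn)
  })
  stats::setNames(out, pn)
}

# Reference scale per parameter, used for relative finite-difference steps.
param_scales <- function(param_names) {
  sc <- c(s_iso = 1, s_in = 1, s_ex = 1, d_iso = 3, d_in_a = 1.7,
          d_ex_a = 1.7, tau = 1, odi = 1)
  sc[param_names]
}

# Directional derivatives of the noise-free summary measures for a whole
# batch of baseline parameter rows. Central differences where both
# perturbed settings are admissible; one-sided (forward/backward)
# differences where a parameter sits on a range boundary (e.g. the prior
# mass at s_iso = 0); steps are halved while neither side fits and rows
# with no admissible step below 1e-8 * scale come back as NA.
derivative_batch <- function(P, pattern, protocol, model = "standard",
                             rel_step = 1e-4, l_max = 2,
                             mu = c(0, 0, 1)) {
  single <- single_param_of(pattern)
  if (!is.null(single) && !is.matrix(mu))
    return(derivative_batch_single(P, single, protocol, model, rel_step,
                                   l_max, mu))
  derivative_batch_general(P, pattern, protocol, model, rel_step, l_max, mu)
}

# The name of the sole parameter of a single-parameter pattern, else NULL.
single_param_of <- function(pattern) {
  nz <- which(pattern$vec != 0)
  if (length(nz) == 1 && abs(pattern$vec[nz] - 1) < 1e-12)
    names(pattern$vec)[nz] else NULL
}

derivative_batch_general <- function(P, pattern, protocol,
                                     model = "standard", rel_step = 1e-4,
                                     l_max = 2, mu = c(0, 0, 1)) {
  fwd <- model_forward(model)
  pn <- fwd$param_names
  v <- pattern$vec[pn]
  bounds <- sm_param_bounds()
  lo <- bounds$lower[pn]; hi <- bounds$upper[pn]
  scale <- sum(abs(v) * param_scales(pn))
  n <- nrow(P)
  t_step <- rep(rel_step * scale, n)
  ok <- function(M) {
    res <- rep(TRUE, n)
    for (j in seq_along(pn))
      res <- res & M[, j] >= lo[j] & M[, j] <= hi[j]
    res
  }
  min_t <- 1e-8 * scale
  repeat {
    Pp <- P + outer(t_step, v)
    Pm <- P - outer(t_step, v)
    ok_p <- ok(Pp); ok_m <- ok(Pm)
    bad <- !ok_p & !ok_m & t_step >= min_t
    if (!any(bad)) break
    t_step[bad] <- t_step[bad] / 2
  }
  dead <- !ok_p & !ok_m
  Pp[!ok_p, ] <- P[!ok_p, , drop = FALSE]
  Pm[!ok_m, ] <- P[!ok_m, , drop = FALSE]
  Sp <- summarize_signal(fwd$signal(Pp, protocol, mu = mu), protocol, l_max)
  Sm <- summarize_signal(fwd$signal(Pm, protocol, mu = mu), protocol, l_max)
  denom <- t_step * (as.numeric(ok_p) + as.numeric(ok_m))
  g <- (Sp - Sm) / denom
  if (any(dead)) g[dead, ] <- NA_real_
  attr(g, "types") <- NULL
  g
}

# Fast path for single-parameter patterns: the three compartment
# attenuations of the baseline are computed once, and only the factors a
# perturbation actually touches are re-evaluated (nothing at all for the
# signal fractions, whose effect on the signal is linear). One-sided
# differences at parameter boundaries, as in the general path. Agrees
# with derivative_batch_general to finite-difference accuracy (asserted
# in the test suite).
derivative_batch_single <- function(P, param, protocol, model, rel_step,
                                    l_max, mu) {
  bounds <- sm_param_bounds()
  scale <- unname(param_scales(param))
  t0 <- rel_step * scale
  x <- P[, param]
  ok_p <- x + t0 <= bounds$upper[[param]]
  ok_m <- x - t0 >= bounds$lower[[param]]
  n <- nrow(P); m <- length(protocol$bvals)
  lay <- summary_layout(protocol)
  g <- matrix(NA_real_, n, length(lay$names),
              dimnames = list(NULL, lay$names))
  chunk <- 2000L
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    g[idx, ] <- single_deriv_chunk(P[idx, , drop = FALSE], param, protocol,
                                   model, t0, l_max, mu,
                                   ok_p[idx], ok_m[idx])
  }
  g
}

single_deriv_chunk <- function(P, param, protocol, model, t0, l_max, mu,
                               ok_p, ok_m) {
  std <- if (model == "constrained") constrained_to_standard(P) else P
  comps <- components_chunk(std, protocol, mu)
  S0 <- std[, "s_iso"] * comps$A_iso + std[, "s_in"] * comps$A_in +
    std[, "s_ex"] * comps$A_ex
  side <- function(sign) {
    t_eff <- sign * t0
    if (model == "constrained" && param %in% c("s_in", "s_ex")) {
      Pp <- P
      Pp[, param] <- Pp[, param] + t_eff
      stdp <- constrained_to_standard(Pp)
      A_ex_p <- zeppelin_att_mat(stdp[, "d_ex_a"], stdp[, "tau"],
                                 comps$kappa, protocol, comps$cpsi)
      S0 + stdp[, "s_in"] * comps$A_in - std[, "s_in"] * comps$A_in +
        stdp[, "s_ex"] * A_ex_p - std[, "s_ex"] * comps$A_ex
    } else {
      switch(param,
        s_iso = S0 + t_eff * comps$A_iso,
        s_in = S0 + t_eff * comps$A_in,
        s_ex = S0 + t_eff * comps$A_ex,
        d_iso = S0 + std[, "s_iso"] *
          (exp(-outer(std[, "d_iso"] + t_eff, protocol$bvals)) -
             comps$A_iso),
        d_in_a = S0 + std[, "s_in"] *
          (stick_att_mat(std[, "d_in_a"] + t_eff, comps$kappa, protocol,
                         comps$cpsi) - comps$A_in),
        d_ex_a = S0 + std[, "s_ex"] *
          (zeppelin_att_mat(std[, "d_ex_a"] + t_eff, std[, "tau"],
                            comps$kappa, protocol, comps$cpsi) -
             comps$A_ex),
        tau = S0 + std[, "s_ex"] *
          (zeppelin_att_mat(std[, "d_ex_a"], std[, "tau"] + t_eff,
                            comps$kappa, protocol, comps$cpsi) -
             comps$A_ex),
        odi = {
          kap <- kappa_from_odi(std[, "odi"] + t_eff)
          S0 + std[, "s_in"] *
            (stick_att_mat(std[, "d_in_a"], kap, protocol, comps$cpsi) -
               comps$A_in) +
            std[, "s_ex"] *
            (zeppelin_att_mat(std[, "d_ex_a"], std[, "tau"], kap, protocol,
                              comps$cpsi) - comps$A_ex)
        },
        stop("no fast derivative for parameter ", param))
    }
  }
  Sp <- S0; Sm <- S0
  if (any(ok_p)) Sp[ok_p, ] <- side(1)[ok_p, , drop = FALSE]
  if (any(ok_m)) Sm[ok_m, ] <- side(-1)[ok_m, , drop = FALSE]
  Yp <- summarize_signal(Sp, protocol, l_max)
  Ym <- summarize_signal(Sm, protocol, l_max)
  denom <- t0 * (as.numeric(ok_p) + as.numeric(ok_m))
  out <- (Yp - Ym) / denom
  out[!ok_p & !ok_m, ] <- NA_real_
  out
}

#' Directional derivative of the summary measures
#'
#' Approximates the derivative of the noise-free summary vector in the
#' direction of a pattern of change by a central finite difference with a
#' step relative to the parameter scale. If the perturbed parameters would
#' leave their valid ranges, the step is shrunk; an error is raised if no
#' admissible step remains.
#'
#' @param params named parameter vector (free parameters of the model).
#' @param pattern a [change_pattern()].
#' @param protocol a [dmri_protocol()].
#' @param model `"standard"` or `"constrained"`.
#' @param rel_step relative finite-difference step (default 1e-4 of the
#'   pattern-weighted parameter scale).
#' @param l_max maximum even degree of the summary fit.
#' @return Numeric derivative vector, one entry per summary coordinate.
#' @export
directional_derivative <- function(params, pattern, protocol,
                                   model = "standard", rel_step = 1e-4,
                                   l_max = 2) {
  pn <- model_forward(model)$param_names
  P <- matrix(unlist(params[pn]), 1, dimnames = list(NULL, pn))
  g <- derivative_batch(P, pattern, protocol, model, rel_step, l_max)
  if (anyNA(g))
    stop("no admissible finite-difference step for this parameter setting")
  drop(g)
}

#' Training set of (summary, derivative) pairs for one pattern
#'
#' Samples baseline parameters from the prior (signal fractions
#' normalised to sum to 1, so the baseline b0 mean is exactly 1),
#' computes the noise-free summary measures and the directional
#' derivative of the summaries for the given pattern of change.
#'
#' @param prior a [sm_prior()] or [constrained_prior()].
#' @param pattern a [change_pattern()].
#' @param protocol a [dmri_protocol()].
#' @param n number of samples (default 100000, the full-scale training
#'   size; scale down for quick experiments).
#' @param seed integer seed; the set is fully reproducible.
#' @param model `"standard"` or `"constrained"`.
#' @param l_max maximum even degree of the summary fit.
#' @return A list with `y` (n x d baseline summaries), `g` (n x d
#'   derivatives) and metadata (`pattern`, `seed`, `n`).
#' @export
build_training_set <- function(prior, pattern, protocol, n = 100000,
                               seed = 1, model = NULL, l_max = 2) {
  if (is.null(model)) model <- prior$model
  P <- sample_prior(prior, n, seed = seed)
  y <- baseline_summaries(P, protocol, model, l_max)
  g <- derivative_batch(P, pattern, protocol, model, l_max = l_max)
  keep <- stats::complete.cases(g)
  list(y = y[keep, , drop = FALSE], g = g[keep, , drop = FALSE],
       pattern = pattern, seed = seed, n = sum(keep), model = model)
}

baseline_summaries <- function(P, protocol, model, l_max = 2) {
  fwd <- model_forward(model)
  summarize_signal(fwd$signal(P, protocol), protocol, l_max)
}
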