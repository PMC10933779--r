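#' Simulated test pairs with at most one changed parameter
#'
#' Generates balanced classes of signal pairs: for each free parameter of
#' the chosen model a class in which that parameter increases by
#' `effect_size` (baselines resampled until the perturbed setting stays in
#' range), plus a no-change class in which the two signals differ only by
#' noise. Gaussian noise of standard deviation `sigma` is added to both
#' members of every pair.
#'
#' @param prior a [sm_prior()] or [constrained_prior()].
#' @param protocol a [dmri_protocol()].
#' @param effect_size amount added to the changed parameter, in native
#'   units (default 0.1).
#' @param sigma noise standard deviation (default 0.01, i.e. SNR 100 at
#'   unit b0 signal).
#' @param n_per_class pairs per class.
#' @param seed integer seed.
#' @param model forward model; defaults to the prior's.
#' @param classes optional subset of class labels (parameter names and/or
#'   `"no_change"`).
#' @return A list with parameter matrices `params_a`/`params_b`, noisy
#'   signal matrices `signal_a`/`signal_b`, clean signal matrices
#'   `clean_a`/`clean_b` and the true `label` per pair.
#' @export
generate_test_pairs <- function(prior, protocol, effect_size = 0.1,
                                sigma = 0.01, n_per_class = 100, seed = 1,
                                model = NULL, classes = NULL) {
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (is.null(model)) model <- prior$model
  fwd <- model_forward(model)
  pn <- fwd$param_names
  if (is.null(classes)) classes <- c(pn, "no_change")
  bounds <- sm_param_bounds()
  run <- function() {
    P_a <- NULL; P_b <- NULL; labels <- character(0)
    for (cls in classes) {
      need <- n_per_class
      got_a <- NULL; got_b <- NULL
      while (need > 0) {
        cand <- sample_prior(prior, max(need * 2L, 8L))
        if (cls == "no_change" || effect_size == 0) {
          pert <- cand
        } else {
          pert <- cand
          pert[, cls] <- pert[, cls] + effect_size
        }
        valid <- rep(TRUE, nrow(cand))
        for (j in pn)
          valid <- valid & pert[, j] >= bounds$lower[j] &
            pert[, j] <= bounds$upper[j]
        take <- which(valid)[seq_len(min(sum(valid), need))]
        got_a <- rbind(got_a, cand[take, , drop = FALSE])
        got_b <- rbind(got_b, pert[take, , drop = FALSE])
        need <- n_per_class - nrow(got_a)
      }
      P_a <- rbind(P_a, got_a); P_b <- rbind(P_b, got_b)
      labels <- c(labels, rep(cls, n_per_class))
    }
    clean_a <- fwd$signal(P_a, protocol)
    clean_b <- fwd$signal(P_b, protocol)
    list(params_a = P_a, params_b = P_b,
         clean_a = clean_a, clean_b = clean_b,
         signal_a = add_noise(clean_a, sigma),
         signal_b = add_noise(clean_b, sigma),
         label = labels, effect_size = effect_size, sigma = sigma,
         model = model)
  }
  with_seed(seed, run())
}

#' Maximum a posteriori fit of the constrained (invertible) model
#'
#' Fits the four free parameters of the NODDI-style constrained model
#' (s_iso, s_in, s_ex, ODI; diffusivities fixed, tortuosity tied to the
#' fractions) to one diffusion signal by bounded quasi-Newton
#' minimisation of the Gaussian negative log-likelihood, with a Laplace
#' approximation (inverse Hessian at the mode) for the estimate
#' covariance.
#'
#' @param signal per-measurement signal vector.
#' @param protocol a [dmri_protocol()].
#' @param sigma noise standard deviation used in the likelihood.
#' @param n_starts number of multi-start initialisations tried on
#'   failure.
#' @param start optional starting values (named, length 4).
#' @return `list(estimate, covariance, value, convergence)`; the
#'   covariance is forced symmetric positive definite.
#' @export
map_fit_constrained <- function(signal, protocol, sigma = 0.01,
                                n_starts = 3, start = NULL) {
  pn <- constrained_param_names()
  lower <- c(0, 0, 0, 1e-3)
  upper <- c(1.2, 1.2, 1.2, 1 - 1e-3)
  obj <- function(theta) {
    names(theta) <- pn
    pred <- drop(simulate_signal_batch(constrained_to_standard(theta),
                                       protocol))
    0.5 * sum((pred - signal)^2) / sigma^2
  }
  starts <- list(c(s_iso = 0.1, s_in = 0.4, s_ex = 0.4, odi = 0.2),
                 c(s_iso = 0.5, s_in = 0.2, s_ex = 0.3, odi = 0.5),
                 c(s_iso = 0.05, s_in = 0.6, s_ex = 0.35, odi = 0.1))
  if (!is.null(start)) starts <- c(list(start[pn]), starts)
  best <- NULL
  for (s in starts[seq_len(min(length(starts), n_starts + 1L))]) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("constrained MAP fit failed from all starts")
  H <- stats::optimHess(best$par, obj)
  cov <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
  if (is.null(cov) || any(eigen(cov, symmetric = TRUE,
                                only.values = TRUE)$values <= 0)) {
    Hs <- (H + t(H)) / 2
    ev <- eigen(Hs, symmetric = TRUE)
    vals <- pmax(ev$values, max(ev$values) * 1e-8 + 1e-12)
    cov <- ev$vectors %*% diag(1 / vals) %*% t(ev$vectors)
  }
  dimnames(cov) <- list(pn, pn)
  list(estimate = stats::setNames(best$par, pn), covariance = cov,
       value = best$value, convergence = best$convergence)
}

#' z-test comparison of two constrained-model fits
#'
#' Computes per-parameter z-scores from the difference in MAP estimates
#' and the summed Laplace variances, Bonferroni-corrects the two-sided
#' p-values across the free parameters, and labels the pair with the
#' parameter of minimum corrected p-value, or `"no_change"` when the
#' minimum corrected p exceeds `alpha`.
#'
#' @param fitA,fitB results of [map_fit_constrained()] for the two
#'   signals of a pair.
#' @param alpha significance threshold (default 0.05).
#' @return `list(label, z, p_corrected)`.
#' @export
ztest_compare <- function(fitA, fitB, alpha = 0.05) {
  pn <- names(fitA$estimate)
  se <- sqrt(diag(fitA$covariance) + diag(fitB$covariance))
  z <- (fitB$estimate - fitA$estimate) / se
  z[!is.finite(z)] <- 0
  p <- 2 * stats::pnorm(-abs(z))
  p_corr <- pmin(1, p * length(pn))
  label <- if (min(p_corr) > alpha) "no_change" else pn[which.min(p_corr)]
  list(label = label, z = z, p_corrected = p_corr)
}

#' Confusion matrix as column-normalised percentages
#'
#' Rows are predicted labels, columns are true labels; each column sums
#' to 100 (the percentage of pairs of each true class assigned to each
#' predicted class).
#'
#' @param truth,predicted character vectors of class labels.
#' @param labels label alphabet (default: union, truth first); predicted
#'   labels outside it raise an error.
#' @return A labels x labels numeric matrix of percentages.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (is.null(labels)) labels <- unique(c(truth, predicted))
  if (!all(truth %in% labels) || !all(predicted %in% labels))
    stop("labels outside the declared alphabet")
  tab <- table(factor(predicted, labels), factor(truth, labels))
  counts <- colSums(tab)
  out <- sweep(unclass(tab), 2, pmax(counts, 1), "/") * 100
  out[, counts == 0] <- NA_real_
  out
}

# Predict labels for a set of test pairs with BENCH: noise covariance per
# pair from repeated noisy instances, posterior over patterns, argmax.
bench_classify_pairs <- function(pairs, protocol, models,
                                 prior = amount_prior(), n_rep = 100,
                                 seed = 1, l_max = 2, n_grid = 128) {
  n <- nrow(pairs$signal_a)
  Ya <- summarize_signal(pairs$signal_a, protocol, l_max)
  Yb <- summarize_signal(pairs$signal_b, protocol, l_max)
  winners <- character(n)
  probs <- matrix(NA_real_, n, length(models$models) + 1L)
  colnames(probs) <- c("no_change", names(models$models))
  for (i in seq_len(n)) {
    Sn <- estimate_noise_covariance(pairs$clean_a[i, ], protocol,
                                    pairs$sigma,
                                    signal_b = pairs$clean_b[i, ],
                                    n_rep = n_rep, seed = seed + i,
                                    l_max = l_max)
    Sn <- Sn + diag(1e-12, ncol(Sn))
    post <- posterior_over_models(Yb[i, ] - Ya[i, ], Ya[i, ], models, Sn,
                                  prior, n_grid)
    winners[i] <- post$winner
    probs[i, ] <- post$prob[colnames(probs)]
  }
  list(label = winners, prob = probs)
}

# Predict labels for a set of test pairs with the inversion + z-test
# baseline (constrained model only).
inversion_classify_pairs <- function(pairs, protocol, sigma = pairs$sigma,
                                     alpha = 0.05) {
  n <- nrow(pairs$signal_a)
  labels <- character(n)
  for (i in seq_len(n)) {
    fa <- map_fit_constrained(pairs$signal_a[i, ], protocol, sigma,
                              start = pairs$params_a[i, ])
    fb <- map_fit_constrained(pairs$signal_b[i, ], protocol, sigma,
                              start = pairs$params_a[i, ])
    labels[i] <- ztest_compare(fa, fb, alpha)$label
  }
  labels
}

#' Sensitivity of change detection to the effect size
#'
#' For each effect size in `effects` and each free parameter, simulates
#' pairs in which that parameter increases by the effect size, runs the
#' posterior over patterns, and tabulates the posterior probability of
#' the true pattern (mean and 10-90 percentiles) together with the MAP
#' amount of change versus the true amount.
#'
#' @param models a `bench_models` collection.
#' @param prior parameter prior used to draw baselines.
#' @param protocol a [dmri_protocol()].
#' @param effects numeric grid of effect sizes (default 0 to 0.1 by
#'   0.01).
#' @param sigma noise standard deviation.
#' @param n_per_effect pairs per (parameter, effect) cell.
#' @param seed integer seed.
#' @param amount_prior_ an [amount_prior()].
#' @param params subset of parameters to perturb (default: all).
#' @return A data.frame with columns `param`, `effect`, `mean_prob`,
#'   `p10`, `p90`, `median_map_amount`.
#' @export
sensitivity_curves <- function(models, prior, protocol,
                               effects = seq(0, 0.1, by = 0.01),
                               sigma = 0.01, n_per_effect = 20, seed = 1,
                               amount_prior_ = amount_prior(),
                               params = NULL) {
  if (is.null(params)) params <- models$param_names
  rows <- list()
  for (pm in params) {
    for (k in seq_along(effects)) {
      eff <- effects[k]
      pairs <- generate_test_pairs(
        prior, protocol, effect_size = eff, sigma = sigma,
        n_per_class = n_per_effect,
        seed = seed + 1000 * match(pm, params) + k,
        classes = if (eff == 0) "no_change" else pm)
      cls <- bench_classify_pairs(pairs, protocol, models, amount_prior_,
                                  seed = seed + k)
      target <- if (eff == 0) "no_change" else pm
      pr <- cls$prob[, target]
      map_amt <- if (eff == 0) NA_real_ else {
        idx <- match(pm, names(models$models))
        stats::median(vapply(seq_len(nrow(pairs$signal_a)), function(i) {
          Ya <- summarize_signal(pairs$signal_a[i, ], protocol)
          Yb <- summarize_signal(pairs$signal_b[i, ], protocol)
          Sn <- estimate_noise_covariance(pairs$clean_a[i, ], protocol,
                                          sigma,
                                          signal_b = pairs$clean_b[i, ],
                                          seed = seed + 7000 + i)
          infer_amount(Yb - Ya, Ya, models$models[[idx]],
                       Sn + diag(1e-12, ncol(Sn)), amount_prior_)$map
        }, numeric(1)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        param = pm, effect = eff, mean_prob = mean(pr),
        p10 = unname(stats::quantile(pr, 0.1)),
        p90 = unname(stats::quantile(pr, 0.9)),
        median_map_amount = map_amt)
    }
  }
  do.call(rbind, rows)
}
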