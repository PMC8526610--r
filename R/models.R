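# Negative binomial count models: single fits with optional site random
# intercept, univariate screening, all-subsets AICc ranking with full model
# averaging, pairwise IRR contrasts, and the boundary-corrected LRT for the
# random-effect variance.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n-k-1)`; reduces to AIC as `n` grows.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (fixed coefficients + dispersion +
#'   any variance components).
#' @param n Number of observations (must exceed `k + 1`).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  abort_unless(n > k + 1, "AICc undefined for n <= k + 1 (n = %g, k = %g)",
               n, k)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

build_formula <- function(response, terms, random = NULL) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  if (!is.null(random)) rhs <- paste0(rhs, " + (1 | ", random, ")")
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit a negative binomial (NB2) count model
#'
#' Log-link NB2 regression (variance `mu + mu^2/theta`) of an interval count
#' on fixed terms, with an optional location random intercept fitted by
#' Laplace approximation (via glmmTMB, the mixed-model engine standard for
#' this model class). When the fitted random-effect variance is below
#' `re_var_tol` (default 1e-4) the random effect is negligible and the model
#' is refitted without it for parsimony, with the removal flagged. Fixed-only
#' fits use `MASS::glm.nb`.
#'
#' @param data Analysis tibble (e.g. from [assemble_dataset()] or
#'   [simulate_interval_counts()]).
#' @param response Count column name (default `"bat_count"`, falling back to
#'   `"count"` when absent).
#' @param terms Character vector of fixed-effect column names (empty =
#'   intercept only). Factors use their current reference level.
#' @param random Optional grouping column for a random intercept (location).
#' @param re_var_tol Variance threshold below which the random effect is
#'   removed.
#' @return An object of class `nb_fit`: coefficients tibble (`term`,
#'   `estimate`, `se`, `z`, `p`), `theta`, `loglik`, `n`, `k`, `aicc`, and a
#'   `random` list (`variance`, `sd`, `p`, `removed`). The underlying engine
#'   fit is kept in `$engine_fit`.
#' @export
fit_nb <- function(data, response = NULL, terms = character(), random = NULL,
                   re_var_tol = 1e-4) {
  response <- response %||%
    (if ("bat_count" %in% names(data)) "bat_count" else "count")
  abort_unless(response %in% names(data), "response column '%s' missing",
               response)
  abort_unless(all(terms %in% names(data)),
               "missing term column(s): %s",
               paste(setdiff(terms, names(data)), collapse = ", "))
  y <- data[[response]]
  abort_unless(all(y >= 0) && all(y == round(y)),
               "response must be non-negative integers")
  abort_unless(var(y) > 0, "degenerate response: all counts identical")
  n <- nrow(data)

  fit_fixed <- function() {
    f <- build_formula(response, terms)
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(
        f, data = data,
        control = stats::glm.control(maxit = 100, epsilon = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) {
      # glm.nb can fail near the Poisson limit; glmmTMB is more robust there
      fit <- glmmTMB::glmmTMB(f, data = data, family = glmmTMB::nbinom2())
    }
    fit
  }

  re <- list(variance = NA_real_, sd = NA_real_, p = NA_real_, removed = FALSE)
  if (!is.null(random)) {
    abort_unless(random %in% names(data), "random column '%s' missing", random)
    f <- build_formula(response, terms, random)
    fit_re <- glmmTMB::glmmTMB(f, data = data, family = glmmTMB::nbinom2())
    v <- as.numeric(glmmTMB::VarCorr(fit_re)$cond[[random]][1, 1])
    fit0 <- fit_fixed()
    if (v < re_var_tol) {
      re <- list(variance = v, sd = sqrt(v), p = NA_real_, removed = TRUE)
      fit <- fit0
      engine <- "glm.nb"
    } else {
      ll1 <- as.numeric(logLik(fit_re))
      ll0 <- as.numeric(logLik(fit0))
      re <- list(variance = v, sd = sqrt(v),
                 p = lr_boundary_p(2 * (ll1 - ll0)), removed = FALSE)
      fit <- fit_re
      engine <- "glmmTMB"
    }
  } else {
    fit <- fit_fixed()
    engine <- if (inherits(fit, "glmmTMB")) "glmmTMB" else "glm.nb"
  }
  if (inherits(fit, "glmmTMB")) engine <- "glmmTMB"

  if (engine == "glmmTMB") {
    est <- glmmTMB::fixef(fit)$cond
    se <- sqrt(diag(stats::vcov(fit)$cond))
    theta <- glmmTMB::sigma(fit)
    n_vc <- if (re$removed || is.null(random)) 0L else 1L
  } else {
    sm <- summary(fit)
    est <- sm$coefficients[, 1]
    se <- sm$coefficients[, 2]
    theta <- fit$theta
    n_vc <- 0L
  }
  z <- est / se
  coefs <- tibble::tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    z = unname(z), p = unname(2 * pnorm(-abs(z)))
  )
  k <- length(est) + 1L + n_vc  # fixed coefs + theta + variance components
  ll <- as.numeric(logLik(fit))
  structure(list(
    coefficients = coefs,
    theta = theta,
    loglik = ll,
    n = n,
    k = k,
    aicc = aicc(ll, k, n),
    random = re,
    response = response,
    terms = terms,
    random_term = if (!is.null(random) && !re$removed) random else NULL,
    engine = engine,
    engine_fit = fit,
    data = data
  ), class = "nb_fit")
}

# boundary-corrected p for a single variance component LRT (0.5*chi2_0 +
# 0.5*chi2_1 mixture)
lr_boundary_p <- function(stat) {
  if (stat <= 0) return(0.5)
  0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Likelihood-ratio test for a random-intercept variance
#'
#' Compares nested fits with and without the random intercept; the null puts
#' the variance on the boundary of its space, so the statistic is referred to
#' an equal mixture of a point mass at zero and chi-square(1) (p-values are
#' halved; identical likelihoods give p = 0.5).
#'
#' @param fit_with,fit_without `nb_fit` objects on identical data, differing
#'   only in the random intercept.
#' @return A list: `statistic`, `p`.
#' @export
lr_test_random_effect <- function(fit_with, fit_without) {
  abort_unless(inherits(fit_with, "nb_fit") && inherits(fit_without, "nb_fit"),
               "inputs must be nb_fit objects")
  abort_unless(fit_with$n == fit_without$n,
               "fits are not on the same data (n differs)")
  abort_unless(identical(sort(fit_with$terms), sort(fit_without$terms)),
               "fits are not nested: fixed terms differ")
  stat <- max(0, 2 * (fit_with$loglik - fit_without$loglik))
  list(statistic = stat, p = lr_boundary_p(stat))
}

#' Univariate screening of candidate covariates
#'
#' Each candidate is fitted alone (with the same random structure as the full
#' model) and retained for the multivariate candidate set iff its Wald p-value
#' is at or below `alpha` (default 0.1; the boundary is inclusive). For factor
#' candidates the smallest coefficient p-value is used.
#'
#' @inheritParams fit_nb
#' @param candidates Character vector of covariate column names to screen.
#' @param alpha Inclusion threshold (default 0.1).
#' @return Tibble: `term`, `p`, `included`.
#' @export
screen_univariate <- function(data, candidates, response = NULL,
                              random = NULL, alpha = 0.1) {
  purrr::map_dfr(candidates, function(tm) {
    fit <- fit_nb(data, response = response, terms = tm, random = random)
    ps <- fit$coefficients$p[fit$coefficients$term != "(Intercept)"]
    p <- min(ps)
    tibble::tibble(term = tm, p = p, included = p <= alpha)
  })
}

subset_label <- function(terms) {
  if (length(terms) == 0) "(null)" else paste(sort(terms), collapse = " + ")
}

#' All-subsets AICc ranking and full model averaging
#'
#' Fits every combination of the supplied fixed effects (no interactions,
#' including the null model), ranks by AICc, retains the set with
#' `delta AICc <= delta_max` (default 6) relative to the best model, and
#' averages coefficients across that set with Akaike weights using full
#' (zero-substituted) averaging: a model not containing a term contributes a
#' zero estimate with zero variance. Averaged standard errors use the
#' Burnham-Anderson adjustment `sum w_i * sqrt(se_i^2 + (b_i - b_avg)^2)`, and
#' 95% CIs are `estimate +/- 1.96 * se`.
#'
#' When a random intercept is requested, its retention is decided on the full
#' (all-terms) model — the variance threshold rule of [fit_nb()] — and the
#' decision is applied to every subset, so all members share one random
#' structure.
#'
#' @inheritParams fit_nb
#' @param terms Candidate fixed effects (at most 12).
#' @param delta_max AICc window defining the averaged set.
#' @return Object of class `nb_avg`: `coefficients` (averaged tibble with CI,
#'   z, p), `ranking` (all subsets with k, logLik, AICc, delta, Akaike weight
#'   over the full candidate set), `members` (named list of member `nb_fit`s),
#'   `full_fit`, and the random-effect summary from the full model.
#' @export
rank_and_average <- function(data, terms, response = NULL, random = NULL,
                             delta_max = 6, re_var_tol = 1e-4) {
  abort_unless(length(terms) <= 12, "at most 12 candidate terms supported")
  full_fit <- fit_nb(data, response = response, terms = terms, random = random,
                     re_var_tol = re_var_tol)
  random_used <- full_fit$random_term  # NULL when removed or not requested

  n_t <- length(terms)
  subsets <- purrr::map(0:(2^n_t - 1), function(m)
    terms[bitwAnd(m, 2^(seq_len(n_t) - 1)) > 0])
  fits <- vector("list", length(subsets))
  ok <- rep(TRUE, length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(
      if (identical(sort(subsets[[i]]), sort(terms))) full_fit else
        fit_nb(data, response = response, terms = subsets[[i]],
               random = random_used, re_var_tol = 0),
      error = function(e) {
        warning(sprintf("model {%s} failed to fit and was excluded: %s",
                        subset_label(subsets[[i]]), conditionMessage(e)))
        NULL
      })
    ok[i] <- !is.null(fits[[i]])
  }
  subsets <- subsets[ok]; fits <- fits[ok]
  labels <- vapply(subsets, subset_label, character(1))

  ranking <- tibble::tibble(
    model = labels,
    n_terms = lengths(subsets),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1))
  ) |>
    dplyr::mutate(delta = .data$aicc - min(.data$aicc),
                  weight = exp(-.data$delta / 2) /
                    sum(exp(-.data$delta / 2))) |>
    dplyr::arrange(.data$aicc, .data$model)  # lexicographic tie-break

  member_idx <- which(ranking$delta[match(labels, ranking$model)] <= delta_max)
  members <- fits[member_idx]
  names(members) <- labels[member_idx]
  w <- ranking$weight[match(labels[member_idx], ranking$model)]
  w <- w / sum(w)

  all_terms <- unique(unlist(lapply(members, function(f) f$coefficients$term)))
  avg <- purrr::map_dfr(all_terms, function(tm) {
    b <- vapply(members, function(f) {
      i <- match(tm, f$coefficients$term)
      if (is.na(i)) 0 else f$coefficients$estimate[i]
    }, numeric(1))
    s <- vapply(members, function(f) {
      i <- match(tm, f$coefficients$term)
      if (is.na(i)) 0 else f$coefficients$se[i]
    }, numeric(1))
    est <- sum(w * b)
    se <- sum(w * sqrt(s^2 + (b - est)^2))
    z <- if (se > 0) abs(est) / se else NA_real_
    tibble::tibble(term = tm, estimate = est, se = se,
                   conf_low = est - 1.96 * se, conf_high = est + 1.96 * se,
                   z = z, p = 2 * pnorm(-z))
  })

  structure(list(
    coefficients = avg,
    ranking = ranking,
    members = members,
    member_weights = setNames(w, names(members)),
    full_fit = full_fit,
    random = full_fit$random,
    response = full_fit$response,
    terms = terms,
    random_requested = random,
    delta_max = delta_max,
    data = data
  ), class = "nb_avg")
}

#' Pairwise incidence-rate-ratio contrasts of a factor term
#'
#' Reports every pairwise log-rate difference of a (three-level) factor as the
#' original analysis presents them — by refitting with each reference level in
#' turn and reading the re-levelled coefficient — together with Wald z/p and
#' the incidence rate ratio `IRR = exp(estimate)` with its 95% CI. For an
#' averaged model the whole ranking/averaging chain is rerun per reference
#' level.
#'
#' @param x An `nb_fit` or `nb_avg`.
#' @param term Factor column name (default `"category"`).
#' @return Tibble of class `irr_contrasts`: `contrast`, `estimate`, `se`,
#'   `conf_low`, `conf_high`, `z`, `p`, `irr`, `irr_low`, `irr_high`.
#' @export
pairwise_contrasts <- function(x, term = "category") {
  abort_unless(inherits(x, c("nb_fit", "nb_avg")), "x must be nb_fit or nb_avg")
  data <- x$data
  abort_unless(term %in% names(data), "term '%s' not in model data", term)
  levs <- levels(factor(data[[term]]))
  abort_unless(length(levs) >= 3, "pairwise contrasts need >= 3 factor levels")

  refit_with_ref <- function(ref) {
    d <- data
    d[[term]] <- stats::relevel(factor(d[[term]]), ref = ref)
    if (inherits(x, "nb_avg")) {
      rank_and_average(d, terms = x$terms, response = x$response,
                       random = x$random_requested, delta_max = x$delta_max)
    } else {
      fit_nb(d, response = x$response, terms = x$terms,
             random = x$random_requested %||% x$random_term)
    }
  }
  # pairs in presentation order: each later level vs each earlier one, plus
  # the before/between/after convention when present
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  pairs <- lapply(pairs, rev)  # (second vs first)
  refs <- unique(vapply(pairs, function(p) p[2], character(1)))
  fits <- lapply(setNames(refs, refs), refit_with_ref)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    co <- fits[[b]]$coefficients
    i <- match(paste0(term, a), co$term)
    abort_unless(!is.na(i), "coefficient for level '%s' not found", a)
    est <- co$estimate[i]; se <- co$se[i]
    tibble::tibble(
      contrast = sprintf("%s vs %s", a, b),
      estimate = est, se = se,
      conf_low = est - 1.96 * se, conf_high = est + 1.96 * se,
      z = abs(est) / se, p = 2 * pnorm(-abs(est) / se),
      irr = exp(est), irr_low = exp(est - 1.96 * se),
      irr_high = exp(est + 1.96 * se)
    )
  })
  structure(out, class = c("irr_contrasts", class(out)))
}

#' Randomised-quantile residual uniformity check
#'
#' Simple adequacy diagnostic: randomised quantile residuals of the NB2 fit
#' should be approximately uniform; returns them with a Kolmogorov-Smirnov
#' p-value against U(0, 1).
#'
#' @param fit An `nb_fit`.
#' @param seed Seed for the randomisation.
#' @return List: `residuals` (uniform scale), `ks_p`.
#' @export
check_quantile_residuals <- function(fit, seed = 1L) {
  abort_unless(inherits(fit, "nb_fit"), "fit must be an nb_fit")
  y <- fit$data[[fit$response]]
  mu <- if (fit$engine == "glmmTMB") stats::fitted(fit$engine_fit)
        else stats::fitted(fit$engine_fit)
  th <- fit$theta
  with_seed(seed, {
    lo <- stats::pnbinom(y - 1, size = th, mu = mu)
    hi <- stats::pnbinom(y, size = th, mu = mu)
    u <- runif(length(y), lo, hi)
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    list(residuals = u, ks_p = ks$p.value)
  })
}

# ---- broom-style methods -----------------------------------------------------

#' Tidy a negative binomial fit
#'
#' @param x An `nb_fit`.
#' @param ... Ignored.
#' @return Coefficient tibble: `term`, `estimate`, `se`, `z`, `p`.
#' @exportS3Method generics::tidy
tidy.nb_fit <- function(x, ...) x$coefficients

#' @rdname tidy.nb_fit
#' @exportS3Method generics::glance
glance.nb_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, theta = x$theta, loglik = x$loglik, aicc = x$aicc,
    random_variance = x$random$variance, random_sd = x$random$sd,
    random_p = x$random$p, random_removed = x$random$removed
  )
}

#' Tidy an averaged model
#'
#' @param x An `nb_avg`.
#' @param ... Ignored.
#' @return Averaged coefficient tibble with 95% CI, z and p.
#' @exportS3Method generics::tidy
tidy.nb_avg <- function(x, ...) x$coefficients

#' @rdname tidy.nb_avg
#' @exportS3Method generics::glance
glance.nb_avg <- function(x, ...) {
  tibble::tibble(
    n = x$full_fit$n,
    n_candidates = nrow(x$ranking),
    n_members = length(x$members),
    best_aicc = min(x$ranking$aicc),
    delta_max = x$delta_max,
    random_variance = x$random$variance,
    random_removed = x$random$removed
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("NB2 fit (%s): n = %d, theta = %.3g, AICc = %.2f\n",
              x$engine, x$n, x$theta, x$aicc))
  if (!is.null(x$random_term)) {
    cat(sprintf("random intercept (%s): var %.4f, sd %.3f, p %.3g\n",
                x$random_term, x$random$variance, x$random$sd, x$random$p))
  } else if (x$random$removed) {
    cat(sprintf("random intercept removed (variance %.2g < tolerance)\n",
                x$random$variance))
  }
  print(x$coefficients)
  invisible(x)
}

#' @export
print.nb_avg <- function(x, ...) {
  cat(sprintf(
    "AICc model averaging: %d candidate models, %d in delta <= %g set\n",
    nrow(x$ranking), length(x$members), x$delta_max))
  print(x$coefficients)
  invisible(x)
}

#' Forest plot of incidence rate ratios
#'
#' @param object An `irr_contrasts` tibble from [pairwise_contrasts()].
#' @param ... Ignored.
#' @return A ggplot: IRR point estimates with 95% CI on a log scale, unity
#'   marked.
#' @exportS3Method ggplot2::autoplot
autoplot.irr_contrasts <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$irr, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$irr_low,
                                          xmax = .data$irr_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Incidence rate ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
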