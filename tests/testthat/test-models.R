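# NB2 fitting, screening, AICc averaging, contrasts, random-effect LRT.

test_that("AICc matches the closed form and its limits", {
  expect_equal(aicc(-100, 2, 100), 204 + 2 * 2 * 3 / 97)
  expect_equal(aicc(-100, 0, 50), 200)
  # approaches AIC as n grows
  expect_lt(abs(aicc(-100, 3, 1e7) - (200 + 6)), 1e-5)
  expect_error(aicc(-100, 5, 6), "undefined")
})

test_that("intercept-only fit recovers log mean; exp of contrasts is the IRR", {
  set.seed(10)
  d <- tibble::tibble(count = rnbinom(400, size = 5, mu = 7))
  f <- fit_nb(d, terms = character())
  expect_equal(tidy(f)$estimate[1], log(mean(d$count)), tolerance = 1e-6)
  dd <- simulate_interval_counts(n_gaps = 250, seed = 12)
  ct <- pairwise_contrasts(fit_nb(dd, terms = "category"))
  expect_equal(ct$irr, exp(ct$estimate))
  expect_equal(ct$irr_low, exp(ct$estimate - 1.96 * ct$se))
  expect_identical(ct$contrast,
                   c("between vs before", "after vs before",
                     "after vs between"))
})

test_that("NB fit approaches the Poisson fit on equidispersed data", {
  set.seed(11)
  x <- rnorm(500)
  d <- tibble::tibble(count = rpois(500, exp(1 + 0.5 * x)), x = x)
  f <- fit_nb(d, terms = "x")
  pf <- glm(count ~ x, data = d, family = poisson())
  expect_lt(max(abs(tidy(f)$estimate - coef(pf)) / abs(coef(pf))), 0.01)
  expect_gt(f$theta, 50)
})

test_that("fixed-effect fits agree with the independent IRLS oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 120
    x1 <- rnorm(n); x2 <- runif(n)
    mu <- exp(0.8 + 0.6 * x1 - 0.4 * x2)
    d <- tibble::tibble(count = rnbinom(n, size = 3, mu = mu),
                        x1 = x1, x2 = x2)
    f <- fit_nb(d, terms = c("x1", "x2"))
    orc <- oracle_nb_fit(cbind(1, x1, x2), d$count)
    expect_lt(max(abs(tidy(f)$estimate - orc$coefficients)), 1e-6)
    expect_lt(abs(f$loglik - orc$loglik), 1e-6)
  }
})

test_that("screening keeps real effects and usually drops noise", {
  # strong covariate: retained in every one of 20 replicates
  kept <- vapply(1:20, function(s) {
    d <- simulate_interval_counts(n_gaps = 300, seed = 1000 + s)
    screen_univariate(d, "time_since_start_h")$included
  }, logical(1))
  expect_true(all(kept))
  # pure-noise covariate (independent per interval): excluded at roughly
  # 1 - alpha of replicates
  dropped <- vapply(1:50, function(s) {
    d <- simulate_interval_counts(n_gaps = 150, seed = 2000 + s)
    set.seed(7000 + s)
    d$noise <- rnorm(nrow(d))
    !screen_univariate(d, "noise")$included
  }, logical(1))
  expect_gte(mean(dropped), 0.75)  # binomial(50, 0.9) rarely drops below
})

test_that("degenerate candidate sets average sensibly", {
  d <- simulate_interval_counts(n_gaps = 400, seed = 13)
  # single dominant model: average equals that model's estimate
  av <- rank_and_average(d, terms = "category")
  stopifnot(length(av$members) >= 1)
  if (length(av$members) == 1) {
    member <- av$members[[1]]
    expect_equal(
      av$coefficients$estimate[av$coefficients$term == "categoryafter"],
      member$coefficients$estimate[member$coefficients$term == "categoryafter"])
  }
  # duplicated covariate: the two single-term models tie, weights equal
  d$x_copy <- d$time_since_start_h
  av2 <- rank_and_average(d, terms = c("time_since_start_h", "x_copy"))
  r <- av2$ranking
  w1 <- r$weight[r$model == "time_since_start_h"]
  w2 <- r$weight[r$model == "x_copy"]
  expect_equal(w1, w2, tolerance = 1e-6)
  expect_equal(sum(r$weight), 1)
})

test_that("zero-substituted averaging shrinks null effects toward zero", {
  shrunk <- vapply(1:10, function(s) {
    d <- simulate_interval_counts(n_gaps = 200, beta_wind = 0,
                                  seed = 3000 + s)
    av <- rank_and_average(d, terms = c("category", "wind"))
    full <- av$full_fit
    b_avg <- av$coefficients$estimate[av$coefficients$term == "wind"]
    b_full <- full$coefficients$estimate[full$coefficients$term == "wind"]
    if (length(b_avg) == 0) b_avg <- 0
    abs(b_avg) <= abs(b_full) + 1e-12
  }, logical(1))
  expect_true(all(shrunk))
})

test_that("AICc ranking weights sum to one and members obey the window", {
  d <- simulate_interval_counts(n_gaps = 300, seed = 14)
  av <- rank_and_average(d, terms = c("category", "nightly_total", "wind"))
  expect_identical(nrow(av$ranking), 8L)
  expect_equal(sum(av$ranking$weight), 1)
  deltas <- av$ranking$delta[match(names(av$members), av$ranking$model)]
  expect_true(all(deltas <= 6))
  expect_equal(sum(av$member_weights), 1)
})

test_that("random-intercept LRT is boundary-corrected and detects site effects", {
  d <- simulate_interval_counts(n_gaps = 200, seed = 15)
  f <- fit_nb(d, terms = "category")
  same <- lr_test_random_effect(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 0.5)

  # strong simulated site effect: variance retained, LRT small
  set.seed(16)
  site <- rep(sprintf("s%02d", 1:12), each = 60)
  eff <- rnorm(12, 0, 1)[as.integer(factor(site))]
  ds <- tibble::tibble(
    site_id = site,
    count = rnbinom(length(site), size = 5, mu = exp(1.5 + eff))
  )
  fr <- fit_nb(ds, terms = character(), random = "site_id")
  expect_false(fr$random$removed)
  expect_gt(fr$random$variance, 0.2)
  expect_lt(fr$random$p, 0.01)

  # no site effect: the variance-threshold removal rule fires
  ds0 <- tibble::tibble(
    site_id = site,
    count = rnbinom(length(site), size = 5, mu = 4)
  )
  f0 <- fit_nb(ds0, terms = character(), random = "site_id")
  expect_true(f0$random$removed || f0$random$variance < 0.01)
})

test_that("quantile residuals of a well-specified fit look uniform", {
  d <- simulate_interval_counts(n_gaps = 400, seed = 17)
  f <- fit_nb(d, terms = c("category", "nightly_total", "time_since_start_h"))
  qr <- check_quantile_residuals(f)
  expect_gt(qr$ks_p, 0.01)
  expect_true(all(qr$residuals >= 0 & qr$residuals <= 1))
})

test_that("the assembled pipeline estimates suppression on point-process data", {
  st <- simulate_study(n_sites = 6, nights_per_site = 3, seed = 21,
                       sup = suppression_config(factor_s = 0.5,
                                                duration_tau = 120))
  ds <- assemble_dataset(st$calls, st$trains, st$nights, d = 30)
  fit <- fit_nb(ds, terms = "category")
  co <- tidy(fit)
  b_after <- co$estimate[co$term == "categoryafter"]
  # after-interval activity should be visibly suppressed relative to before
  expect_lt(b_after, -0.2)
  expect_gt(exp(b_after), 0.25)
})
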