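# Independent NB2 oracle: IRLS for the regression coefficients at fixed
# theta, profiled over theta by golden-section likelihood maximisation.
# Deliberately shares no code with the package's fitting path.

oracle_nb_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta) + y * log(mu) -
        (theta + y) * log(theta + mu))
}

# IRLS for a log-link NB2 GLM at fixed theta
oracle_nb_irls <- function(X, y, theta, tol = 1e-12, maxit = 200) {
  beta <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta)
    w <- mu^2 / (mu + mu^2 / theta)        # 1 / (V(mu) * g'(mu)^2)
    z <- eta + (y - mu) / mu               # working response
    fit <- lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta
}

# full oracle fit: profile likelihood over log(theta)
oracle_nb_fit <- function(X, y) {
  prof <- function(log_theta) {
    th <- exp(log_theta)
    b <- oracle_nb_irls(X, y, th)
    oracle_nb_loglik(y, exp(as.vector(X %*% b)), th)
  }
  opt <- optimize(prof, interval = log(c(1e-3, 1e5)), maximum = TRUE,
                  tol = 1e-10)
  theta <- exp(opt$maximum)
  beta <- oracle_nb_irls(X, y, theta)
  list(coefficients = beta, theta = theta,
       loglik = oracle_nb_loglik(y, exp(as.vector(X %*% beta)), theta))
}
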